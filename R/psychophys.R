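#' Heart-rate deceleration change score for one trace
#'
#' The change score for a message viewing is computed per second of
#' exposure as the absolute difference between that second's BPM and the
#' last pre-message baseline second, then averaged over the exposure:
#' \deqn{\mathrm{score} = \frac{1}{T}\sum_{t=1}^{T} |\,\mathrm{BPM}_t -
#' \mathrm{baseline}\,|}
#' Greater values indicate greater deceleration, i.e., more cognitive
#' resources allocated to encoding the message. Because the absolute value
#' is taken per second *before* averaging, seconds of acceleration also
#' increase the score; the measure indexes the magnitude of cardiac change
#' from baseline.
#'
#' @param baseline_bpm BPM in the last second before message onset (> 0).
#' @param bpm_by_second Numeric vector of per-second BPM during exposure
#'   (non-empty, all > 0).
#' @return The deceleration change score in BPM units (>= 0).
#' @examples
#' hr_deceleration_score(70, c(68, 66, 64))  # mean of 2, 4, 6
#' @export
hr_deceleration_score <- function(baseline_bpm, bpm_by_second) {
  if (length(baseline_bpm) != 1 || is.na(baseline_bpm) || baseline_bpm <= 0) {
    stop_madm("`baseline_bpm` must be a single positive BPM value.",
              class = "madmsg_data_error")
  }
  if (length(bpm_by_second) == 0 || anyNA(bpm_by_second) ||
      any(bpm_by_second <= 0)) {
    stop_madm("`bpm_by_second` must be a non-empty vector of positive BPM values.",
              class = "madmsg_data_error")
  }
  mean(abs(bpm_by_second - baseline_bpm))
}

#' Per-message heart-rate deceleration summary
#'
#' Scores every participant-message trace with [hr_deceleration_score()]
#' and averages the scores across participants, unweighted, regardless of
#' how many exposure seconds each trace contains.
#'
#' @param traces A data frame with columns `participant_id`, `message_id`,
#'   `second_index`, `bpm`.
#' @param baselines A data frame with columns `participant_id`,
#'   `message_id`, `baseline_bpm`.
#' @return A tibble per message: `message_id`, `hr_decel`, `sd`, `n`.
#' @export
summarize_hr <- function(traces, baselines) {
  traces <- tibble::as_tibble(traces)
  baselines <- tibble::as_tibble(baselines)
  assert_columns(traces, c("participant_id", "message_id", "second_index", "bpm"),
                 "`traces`")
  assert_columns(baselines, c("participant_id", "message_id", "baseline_bpm"),
                 "`baselines`")
  joined <- dplyr::inner_join(traces, baselines,
                              by = c("participant_id", "message_id"))
  if (nrow(joined) == 0) {
    stop_madm("No trace has a matching baseline record.",
              class = "madmsg_data_error")
  }
  per_trace <- joined |>
    dplyr::group_by(.data$participant_id, .data$message_id) |>
    dplyr::summarise(
      score = hr_deceleration_score(.data$baseline_bpm[1], .data$bpm),
      .groups = "drop"
    )
  per_trace |>
    dplyr::group_by(.data$message_id) |>
    dplyr::summarise(
      hr_decel = mean(.data$score),
      sd = stats::sd(.data$score),
      n = dplyr::n(),
      .groups = "drop"
    )
}

#' Recognition accuracy (hit rate) for target fragments
#'
#' Recognition accuracy for a message is the proportion of "yes" responses
#' to target fragments drawn from that message. Foils (fragments from no
#' message) never enter the numerator or denominator. The hit proportion is
#' first computed per participant and then averaged across participants,
#' which equals the pooled proportion when every participant saw the same
#' number of targets and stays unbiased per participant when trials were
#' dropped.
#'
#' @param trials A data frame with columns `participant_id`, `fragment_id`,
#'   `is_target` (logical), `source_message_id` (`NA` for foils),
#'   `response_yes` (logical).
#' @param message_id Optional single message id; if omitted, all messages
#'   with target trials are summarized.
#' @return A tibble per message: `message_id`, `recog_acc`, `sd` (across
#'   participant proportions), `n` (participants).
#' @export
recognition_accuracy <- function(trials, message_id = NULL) {
  trials <- tibble::as_tibble(trials)
  assert_columns(trials,
                 c("participant_id", "fragment_id", "is_target",
                   "source_message_id", "response_yes"),
                 "`trials`")
  targets <- trials[trials$is_target, ]
  if (!is.null(message_id)) {
    targets <- targets[!is.na(targets$source_message_id) &
                         targets$source_message_id %in% message_id, ]
    if (nrow(targets) == 0) {
      stop_madm(sprintf("No target trials for message '%s'.",
                        paste(message_id, collapse = ", ")),
                class = "madmsg_data_error")
    }
  }
  if (nrow(targets) == 0) {
    stop_madm("No target trials in the data.", class = "madmsg_data_error")
  }
  targets |>
    dplyr::group_by(.data$source_message_id, .data$participant_id) |>
    dplyr::summarise(p = mean(.data$response_yes), .groups = "drop_last") |>
    dplyr::summarise(
      recog_acc = mean(.data$p),
      sd = stats::sd(.data$p),
      n = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::rename(message_id = "source_message_id")
}

#' Mean area-of-interest dwell time per message
#'
#' Each record carries three dwell durations (sentence 1, sentence 2,
#' hashtag). The three AOIs are first averaged within the record, then
#' record means are averaged across participants. An AOI with no recorded
#' fixation (`NA`) is treated as 0 ms of dwell — absence of fixation is
#' informative non-attention — and the number of such substitutions is
#' reported as a message.
#'
#' @param records A data frame with columns `participant_id`, `message_id`,
#'   `dwell_s1`, `dwell_s2`, `dwell_hashtag` (milliseconds, >= 0 or `NA`).
#' @param message_id Optional single message id to restrict to.
#' @return A tibble per message: `message_id`, `dwell_ms`, `sd`, `n`.
#' @export
mean_dwell <- function(records, message_id = NULL) {
  records <- tibble::as_tibble(records)
  aoi_cols <- c("dwell_s1", "dwell_s2", "dwell_hashtag")
  assert_columns(records, c("participant_id", "message_id", aoi_cols),
                 "`records`")
  if (!is.null(message_id)) {
    records <- records[records$message_id %in% message_id, ]
  }
  if (nrow(records) == 0) {
    stop_madm("No AOI records to summarize.", class = "madmsg_data_error")
  }
  dwell <- as.matrix(records[aoi_cols])
  n_missing <- sum(is.na(dwell))
  if (n_missing > 0) {
    rlang::inform(sprintf(
      "Treating %d unfixated AOI value(s) as 0 ms dwell.", n_missing))
    dwell[is.na(dwell)] <- 0
  }
  if (any(dwell < 0)) {
    stop_madm("Negative dwell durations are invalid.", class = "madmsg_data_error")
  }
  records$record_mean <- rowMeans(dwell)
  records |>
    dplyr::group_by(.data$message_id) |>
    dplyr::summarise(
      dwell_ms = mean(.data$record_mean),
      sd = stats::sd(.data$record_mean),
      n = dplyr::n(),
      .groups = "drop"
    )
}

#' Per-message psychophysiological attribute summary
#'
#' Combines the three lab measures into the per-message table that forms
#' the lab side of the decision matrix.
#'
#' @param traces,baselines Heart-rate inputs, see [summarize_hr()].
#' @param trials Recognition trials, see [recognition_accuracy()].
#' @param aoi AOI dwell records, see [mean_dwell()].
#' @return A tibble per message: `message_id`, `hr_decel`, `recog_acc`,
#'   `dwell_ms`.
#' @export
summarize_psychophys <- function(traces, baselines, trials, aoi) {
  hr <- summarize_hr(traces, baselines)[, c("message_id", "hr_decel")]
  rec <- recognition_accuracy(trials)[, c("message_id", "recog_acc")]
  dw <- mean_dwell(aoi)[, c("message_id", "dwell_ms")]
  out <- dplyr::full_join(hr, rec, by = "message_id") |>
    dplyr::full_join(dw, by = "message_id")
  if (anyNA(out)) {
    bad <- out$message_id[!stats::complete.cases(out)]
    stop_madm(sprintf("Incomplete lab measures for message(s): %s",
                      paste(bad, collapse = ", ")),
              class = "madmsg_data_error")
  }
  dplyr::arrange(out, .data$message_id)
}
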