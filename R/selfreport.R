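#' Self-report construct scale definitions
#'
#' The four crowdsourced constructs, their item counts, and their response
#' scale bounds: receptivity (9 items, 1-7), engagement (3 items, 1-7),
#' positive attitude (9 semantic-differential items, 1-7), and negative
#' emotion (frightened / anxious / nervous / worried, 4 items, 1-4).
#'
#' @return A tibble with columns `construct`, `n_items`, `scale_min`,
#'   `scale_max`.
#' @export
construct_scales <- function() {
  tibble::tibble(
    construct = c("receptivity", "engagement", "positive_attitude",
                  "negative_emotion"),
    n_items = c(9L, 3L, 9L, 4L),
    scale_min = 1,
    scale_max = c(7, 7, 7, 4)
  )
}

construct_scale <- function(construct) {
  scales <- construct_scales()
  row <- scales[scales$construct == construct, ]
  if (nrow(row) == 0) {
    stop_madm(sprintf("Unknown construct '%s'; expected one of: %s", construct,
                      paste(scales$construct, collapse = ", ")),
              class = "madmsg_input_error")
  }
  row
}

#' Score one participant's responses on a construct
#'
#' A participant's construct score is the arithmetic mean of their item
#' responses. Items are validated against the construct's scale bounds and
#' expected item count; records with missing or out-of-range items are
#' rejected rather than prorated, so a returned score always reflects a
#' complete, in-range response set.
#'
#' @param item_scores Numeric vector of item responses.
#' @param construct Construct name (see [construct_scales()]).
#' @param check_n_items If `TRUE` (default), require exactly the
#'   construct's item count; incomplete records error.
#' @return The construct score (scalar, within scale bounds).
#' @examples
#' score_construct(c(4, 5, 6), "engagement")
#' @export
score_construct <- function(item_scores, construct, check_n_items = TRUE) {
  scale <- construct_scale(construct)
  if (length(item_scores) == 0 || anyNA(item_scores)) {
    stop_madm(sprintf("Empty or missing item responses for construct '%s'.",
                      construct), class = "madmsg_data_error")
  }
  if (check_n_items && length(item_scores) != scale$n_items) {
    stop_madm(sprintf(
      "Construct '%s' expects %d items, got %d; incomplete records are rejected.",
      construct, scale$n_items, length(item_scores)
    ), class = "madmsg_data_error")
  }
  if (any(item_scores < scale$scale_min | item_scores > scale$scale_max)) {
    stop_madm(sprintf(
      "Item response outside the [%g, %g] scale for construct '%s'.",
      scale$scale_min, scale$scale_max, construct
    ), class = "madmsg_data_error")
  }
  mean(item_scores)
}

#' Score all participant-message construct records in a long table
#'
#' Applies [score_construct()] to every participant-message-construct group
#' of an item-level table. Groups with the wrong item count (incomplete
#' records) or out-of-range responses are dropped with a warning that
#' reports how many records were rejected.
#'
#' @param responses A data frame with columns `participant_id`,
#'   `message_id`, `construct`, `item_index`, `score`.
#' @return A tibble with one row per retained participant-message-construct:
#'   `participant_id`, `message_id`, `construct`, `score`.
#' @export
score_selfreport <- function(responses) {
  responses <- tibble::as_tibble(responses)
  assert_columns(responses,
                 c("participant_id", "message_id", "construct", "item_index", "score"),
                 "`responses`")
  scales <- construct_scales()
  unknown <- setdiff(unique(responses$construct), scales$construct)
  if (length(unknown) > 0) {
    stop_madm(sprintf("Unknown construct(s): %s", paste(unknown, collapse = ", ")),
              class = "madmsg_input_error")
  }
  scored <- responses |>
    dplyr::left_join(scales, by = "construct") |>
    dplyr::group_by(.data$participant_id, .data$message_id, .data$construct) |>
    dplyr::summarise(
      # validity is judged on the item vector, so it must be computed before
      # `score` masks the item column with the group mean
      ok = dplyr::n() == .data$n_items[1] &&
        !anyNA(.data$score) &&
        all(.data$score >= .data$scale_min[1] & .data$score <= .data$scale_max[1]),
      score = mean(.data$score),
      .groups = "drop"
    )
  n_bad <- sum(!scored$ok)
  if (n_bad > 0) {
    rlang::warn(sprintf(
      "Rejected %d incomplete or out-of-range participant-message construct record(s).",
      n_bad
    ))
  }
  scored[scored$ok, c("participant_id", "message_id", "construct", "score")]
}

#' Summarize per-participant construct scores for one message
#'
#' @param scores Numeric vector of per-participant construct scores.
#' @param message_id Message identifier.
#' @param construct Construct name.
#' @return A one-row tibble: `message_id`, `construct`, `mean`, `se`
#'   (sample standard deviation over `sqrt(n)`; `NA` when `n = 1`), `n`.
#' @export
summarize_construct <- function(scores, message_id, construct) {
  if (length(scores) == 0 || anyNA(scores)) {
    stop_madm(sprintf("No scores to summarize for message '%s', construct '%s'.",
                      message_id, construct), class = "madmsg_data_error")
  }
  n <- length(scores)
  tibble::tibble(
    message_id = message_id,
    construct = construct,
    mean = mean(scores),
    se = if (n >= 2) stats::sd(scores) / sqrt(n) else NA_real_,
    n = n
  )
}

#' Per-message construct summaries for a scored self-report table
#'
#' Averages per-participant construct scores across participants, message
#' by message — the attribute means that populate the self-report side of
#' the decision matrix.
#'
#' @param scored Output of [score_selfreport()].
#' @return A tibble with one row per message-construct: `message_id`,
#'   `construct`, `mean`, `se`, `n`.
#' @export
summarize_selfreport <- function(scored) {
  scored <- tibble::as_tibble(scored)
  assert_columns(scored, c("participant_id", "message_id", "construct", "score"),
                 "`scored`")
  if (nrow(scored) == 0) {
    stop_madm("No scored records to summarize.", class = "madmsg_data_error")
  }
  scored |>
    dplyr::group_by(.data$message_id, .data$construct) |>
    dplyr::summarise(
      mean = mean(.data$score),
      se = if (dplyr::n() >= 2) stats::sd(.data$score) / sqrt(dplyr::n()) else NA_real_,
      n = dplyr::n(),
      .groups = "drop"
    )
}

#' Cronbach's alpha internal-consistency coefficient
#'
#' \deqn{\alpha = \frac{k}{k-1}\left(1 - \frac{\sum_i s_i^2}{s_T^2}\right)}
#' where \eqn{k} is the number of items, \eqn{s_i^2} the sample variance of
#' item \eqn{i}, and \eqn{s_T^2} the sample variance of the participants'
#' item sums. Used as a quality-control check that a multi-item scale hangs
#' together; can be negative for discordant items.
#'
#' @param item_matrix A numeric matrix or data frame, participants in rows,
#'   items in columns (>= 2 of each), no missing values.
#' @return Alpha (scalar, <= 1).
#' @examples
#' m <- cbind(a = c(1, 2, 3), b = c(1, 2, 3))
#' cronbach_alpha(m)  # duplicated items: alpha = 1
#' @export
cronbach_alpha <- function(item_matrix) {
  m <- as.matrix(item_matrix)
  storage.mode(m) <- "double"
  if (ncol(m) < 2) {
    stop_madm("Cronbach's alpha needs at least 2 items.",
              class = "madmsg_input_error")
  }
  if (nrow(m) < 2) {
    stop_madm("Cronbach's alpha needs at least 2 participants.",
              class = "madmsg_input_error")
  }
  if (anyNA(m)) {
    stop_madm("Item matrix contains missing values.", class = "madmsg_data_error")
  }
  total_var <- stats::var(rowSums(m))
  if (total_var == 0) {
    stop_madm("Total-score variance is zero; alpha is undefined.",
              class = "madmsg_data_error")
  }
  k <- ncol(m)
  item_vars <- apply(m, 2, stats::var)
  (k / (k - 1)) * (1 - sum(item_vars) / total_var)
}
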