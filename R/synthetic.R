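#' Planted per-message truth table from the bundled decision matrix
#'
#' The default "truth" for the synthetic cohorts: the bundled study's
#' published per-message means, relabelled as generator parameters
#' (`recognition_p` as a hit probability, `dwell_mean_ms` in milliseconds).
#'
#' @return A tibble with columns `message_id`, `receptivity`, `engagement`,
#'   `positive_attitude`, `negative_emotion`, `hr_deceleration`,
#'   `recognition_p`, `dwell_mean_ms`.
#' @export
fixture_truth <- function() {
  fx <- paper_fixture()
  means <- fx$means
  tibble::tibble(
    message_id = means$message_id,
    receptivity = means$receptivity,
    engagement = means$engagement,
    positive_attitude = means$positive_attitude,
    negative_emotion = means$negative_emotion,
    hr_deceleration = means$hr_deceleration,
    recognition_p = means$recognition_accuracy,
    dwell_mean_ms = means$visual_attention
  )
}

#' Configuration for the synthetic two-arm cohort generator
#'
#' Bundles everything the generator needs: arm sizes (defaulting to the
#' study sizes of 713 crowdsourced and 120 lab participants), a root seed,
#' the planted per-message truth, and noise settings. Self-report noise is
#' parameterized by each construct's target internal consistency
#' (Cronbach's alpha) and the between-participant standard deviation of
#' construct scores; the generator converts these into a participant-level
#' latent component and independent item noise via the Spearman-Brown
#' relation, so default cohorts yield alphas near the published values.
#'
#' @param n_selfreport Crowdsourced-arm participants (each rates 1 message).
#' @param n_lab Lab-arm participants (each views all messages).
#' @param seed Root integer seed; each arm derives its own stream from it,
#'   so arms can be regenerated independently and reproducibly.
#' @param truth Planted per-message means, see [fixture_truth()].
#' @param alpha_target Named per-construct target Cronbach's alpha.
#' @param score_sd Named per-construct between-participant SD of construct
#'   scores (set to 0 for noise-free cohorts).
#' @param discretize Round self-report items to integer scale points and
#'   clip to the scale bounds (realistic Likert responses). Disable to
#'   generate continuous items, e.g. for noise-free pipeline checks.
#' @param baseline_mean,baseline_sd Resting-BPM distribution across
#'   participants.
#' @param hr_participant_sd SD of the participant-level deceleration trait
#'   added to every planted deceleration.
#' @param bpm_noise_sd Per-second BPM measurement noise SD.
#' @param exposure_seconds Seconds of message exposure per trace.
#' @param targets_per_message Target fragments drawn from each message
#'   (2 x 12 messages + 24 foils = the 48-fragment task).
#' @param n_foils Foil fragments per participant.
#' @param false_alarm_rate Probability of a "yes" response to a foil.
#' @param deterministic_recognition If `TRUE`, allocate hits so each
#'   message's pooled hit proportion equals the planted probability as
#'   closely as the trial count allows (used for noise-free checks);
#'   otherwise hits are Bernoulli draws.
#' @param dwell_sd Between-record SD of the mean AOI dwell (records are
#'   drawn lognormal, matching the heavy right skew of dwell times; 0 means
#'   every record mean equals the planted value).
#' @param aoi_jitter_sd Within-record SD spreading a record's three AOI
#'   dwells around the record mean.
#' @return A validated `cohort_config` object.
#' @export
cohort_config <- function(n_selfreport = 713,
                          n_lab = 120,
                          seed = 1,
                          truth = fixture_truth(),
                          alpha_target = c(receptivity = 0.92, engagement = 0.94,
                                           positive_attitude = 0.94,
                                           negative_emotion = 0.91),
                          score_sd = c(receptivity = 1.31, engagement = 1.16,
                                       positive_attitude = 1.47,
                                       negative_emotion = 0.89),
                          discretize = TRUE,
                          baseline_mean = 72,
                          baseline_sd = 8,
                          hr_participant_sd = 0.4,
                          bpm_noise_sd = 1,
                          exposure_seconds = 15,
                          targets_per_message = 2,
                          n_foils = 24,
                          false_alarm_rate = 0.2,
                          deterministic_recognition = FALSE,
                          dwell_sd = 770,
                          aoi_jitter_sd = 100) {
  truth <- tibble::as_tibble(truth)
  assert_columns(truth, c("message_id", construct_scales()$construct,
                          "hr_deceleration", "recognition_p", "dwell_mean_ms"),
                 "`truth`")
  if (n_selfreport < 1 || n_lab < 1) {
    stop_madm("Arm sizes must be at least 1.", class = "madmsg_input_error")
  }
  scales <- construct_scales()
  for (i in seq_len(nrow(scales))) {
    v <- truth[[scales$construct[i]]]
    if (any(v < scales$scale_min[i] | v > scales$scale_max[i])) {
      stop_madm(sprintf("Planted '%s' means fall outside the [%g, %g] scale.",
                        scales$construct[i], scales$scale_min[i],
                        scales$scale_max[i]),
                class = "madmsg_input_error")
    }
  }
  if (any(truth$recognition_p < 0 | truth$recognition_p > 1)) {
    stop_madm("Planted recognition probabilities must lie in [0, 1].",
              class = "madmsg_input_error")
  }
  if (any(truth$hr_deceleration < 0) || any(truth$dwell_mean_ms <= 0)) {
    stop_madm("Planted decelerations must be >= 0 and dwell means > 0.",
              class = "madmsg_input_error")
  }
  if (any(alpha_target <= 0 | alpha_target >= 1)) {
    stop_madm("`alpha_target` values must lie strictly in (0, 1).",
              class = "madmsg_input_error")
  }
  if (any(score_sd < 0) || baseline_sd < 0 || hr_participant_sd < 0 ||
      bpm_noise_sd < 0 || dwell_sd < 0 || aoi_jitter_sd < 0) {
    stop_madm("Noise standard deviations must be nonnegative.",
              class = "madmsg_input_error")
  }
  if (false_alarm_rate < 0 || false_alarm_rate > 1) {
    stop_madm("`false_alarm_rate` must lie in [0, 1].",
              class = "madmsg_input_error")
  }
  if (exposure_seconds < 1 || targets_per_message < 1) {
    stop_madm("`exposure_seconds` and `targets_per_message` must be >= 1.",
              class = "madmsg_input_error")
  }
  structure(
    list(
      n_selfreport = as.integer(n_selfreport), n_lab = as.integer(n_lab),
      seed = as.integer(seed), truth = truth,
      alpha_target = alpha_target, score_sd = score_sd,
      discretize = isTRUE(discretize),
      baseline_mean = baseline_mean, baseline_sd = baseline_sd,
      hr_participant_sd = hr_participant_sd, bpm_noise_sd = bpm_noise_sd,
      exposure_seconds = as.integer(exposure_seconds),
      targets_per_message = as.integer(targets_per_message),
      n_foils = as.integer(n_foils), false_alarm_rate = false_alarm_rate,
      deterministic_recognition = isTRUE(deterministic_recognition),
      dwell_sd = dwell_sd, aoi_jitter_sd = aoi_jitter_sd
    ),
    class = "cohort_config"
  )
}

# Split a construct's score variance into a participant latent component
# (variance u^2) and item noise (variance e^2) so that k items with
# inter-item correlation r = alpha / (k - (k - 1) alpha) yield the target
# alpha (Spearman-Brown) and the participant-level k-item mean has the
# target SD: u^2 = s^2 r k / (r k + 1 - r), e^2 = u^2 (1 - r) / r.
latent_components <- function(alpha, k, score_sd) {
  r <- alpha / (k - (k - 1) * alpha)
  u2 <- score_sd^2 * r * k / (r * k + 1 - r)
  e2 <- if (r > 0) u2 * (1 - r) / r else score_sd^2
  list(participant_sd = sqrt(u2), item_sd = sqrt(e2))
}

#' Expected observable construct means under discretization
#'
#' Rounding latent item values to integer scale points and clipping them to
#' the scale bounds shifts the observable mean away from the planted latent
#' mean — the familiar ceiling/floor effect of Likert data, strongest for
#' planted means near a scale bound. This helper returns the exact
#' expectation of a discretized item (hence of the construct score) under
#' the generator: for latent item values \eqn{N(\mu, \sigma)} with
#' \eqn{\sigma^2} the total (participant + item) variance, the probability
#' mass that rounds to each integer scale point is integrated, with the
#' boundary points absorbing the clipped tails. It is the correct recovery
#' target for pipeline estimates on discretized cohorts; with
#' `discretize = FALSE` the planted means themselves are returned.
#'
#' @param config A [cohort_config()].
#' @param construct Construct name.
#' @return Numeric vector of expected observable means, one per message in
#'   `config$truth`.
#' @export
planted_observable_mean <- function(config, construct) {
  stopifnot(inherits(config, "cohort_config"))
  scale <- construct_scale(construct)
  mu <- config$truth[[construct]]
  if (!config$discretize) return(mu)
  lc <- latent_components(config$alpha_target[[construct]], scale$n_items,
                          config$score_sd[[construct]])
  sigma <- sqrt(lc$participant_sd^2 + lc$item_sd^2)
  if (sigma == 0) {
    return(pmin(pmax(round(mu), scale$scale_min), scale$scale_max))
  }
  points <- seq(scale$scale_min, scale$scale_max)
  upper <- c(points[-length(points)] + 0.5, Inf)
  lower <- c(-Inf, points[-1] - 0.5)
  vapply(mu, function(m) {
    sum(points * (stats::pnorm((upper - m) / sigma) -
                    stats::pnorm((lower - m) / sigma)))
  }, numeric(1))
}

#' Generate the crowdsourced self-report arm
#'
#' Each synthetic participant is assigned one message (balanced across
#' messages, emulating the between-subjects design) and answers every item
#' of the four constructs. Item responses are a participant-level latent
#' construct value (planted mean + participant effect) plus independent
#' item noise, optionally rounded to integer scale points and clipped to
#' the scale bounds. Identical config and seed give identical output.
#'
#' @param config A [cohort_config()].
#' @return A long tibble of item responses: `participant_id`, `message_id`,
#'   `construct`, `item_index`, `score`.
#' @export
generate_selfreport_arm <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  scales <- construct_scales()
  n <- config$n_selfreport
  messages <- config$truth$message_id
  assigned <- messages[((seq_len(n) - 1L) %% length(messages)) + 1L]
  pid <- sprintf("S%05d", seq_len(n))
  withr::with_seed(config$seed + 1L, {
    out <- vector("list", nrow(scales))
    for (i in seq_len(nrow(scales))) {
      con <- scales$construct[i]
      k <- scales$n_items[i]
      lc <- latent_components(config$alpha_target[[con]], k,
                              config$score_sd[[con]])
      planted <- config$truth[[con]][match(assigned, messages)]
      latent <- planted + rnorm(n, 0, lc$participant_sd)
      items <- matrix(rep(latent, each = k), nrow = k) +
        matrix(rnorm(n * k, 0, lc$item_sd), nrow = k)
      if (config$discretize) {
        items <- round(items)
      }
      items <- pmin(pmax(items, scales$scale_min[i]), scales$scale_max[i])
      out[[i]] <- tibble::tibble(
        participant_id = rep(pid, each = k),
        message_id = rep(assigned, each = k),
        construct = con,
        item_index = rep(seq_len(k), times = n),
        score = as.numeric(items)
      )
    }
    dplyr::bind_rows(out)
  })
}

#' Generate the lab psychophysiology arm
#'
#' Emulates the within-subjects design: every participant views all
#' messages. Per participant, a resting baseline BPM is drawn once; each
#' message's exposure trace is baseline minus the planted deceleration
#' (plus a participant deceleration trait) with independent per-second
#' noise. The recognition task has `targets_per_message` target fragments
#' per message answered "yes" with the planted hit probability, plus foils
#' answered "yes" at the false-alarm rate. AOI records draw a lognormal
#' record-level dwell mean around the planted value, spread over the three
#' AOIs. Identical config and seed give identical output.
#'
#' @param config A [cohort_config()].
#' @return A list of tibbles: `traces`, `baselines`, `trials`, `aoi`.
#' @export
generate_lab_arm <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_lab
  messages <- config$truth$message_id
  m <- length(messages)
  secs <- config$exposure_seconds
  pid <- sprintf("L%04d", seq_len(n))
  withr::with_seed(config$seed + 2L, {
    baseline <- pmax(rnorm(n, config$baseline_mean, config$baseline_sd), 40)
    hr_trait <- rnorm(n, 0, config$hr_participant_sd)

    # participant x message grid, participant-major
    grid_pid <- rep(pid, each = m)
    grid_msg <- rep(messages, times = n)
    grid_base <- rep(baseline, each = m)
    delta <- rep(config$truth$hr_deceleration, times = n) +
      rep(hr_trait, each = m)

    bpm <- rep(grid_base, each = secs) - rep(delta, each = secs) +
      rnorm(n * m * secs, 0, config$bpm_noise_sd)
    traces <- tibble::tibble(
      participant_id = rep(grid_pid, each = secs),
      message_id = rep(grid_msg, each = secs),
      second_index = rep(seq_len(secs), times = n * m),
      bpm = pmax(bpm, 1)
    )
    baselines <- tibble::tibble(
      participant_id = grid_pid,
      message_id = grid_msg,
      baseline_bpm = grid_base
    )

    tpm <- config$targets_per_message
    target_pid <- rep(pid, each = m * tpm)
    target_msg <- rep(rep(messages, each = tpm), times = n)
    target_frag <- rep(paste0(rep(messages, each = tpm), "_t",
                              rep(seq_len(tpm), times = m)), times = n)
    p_hit <- rep(rep(config$truth$recognition_p, each = tpm), times = n)
    if (config$deterministic_recognition) {
      # allocate round(p * N) hits per message across the participant-major
      # trial order, so the pooled proportion matches the planted value to
      # within 1 / (n * targets_per_message)
      yes <- logical(length(target_msg))
      for (msg in messages) {
        idx <- which(target_msg == msg)
        n_yes <- round(config$truth$recognition_p[messages == msg] * length(idx))
        yes[idx[seq_len(n_yes)]] <- TRUE
      }
    } else {
      yes <- rbinom(length(target_msg), 1, p_hit) == 1
    }
    targets <- tibble::tibble(
      participant_id = target_pid,
      fragment_id = target_frag,
      is_target = TRUE,
      source_message_id = target_msg,
      response_yes = yes
    )
    foils <- tibble::tibble(
      participant_id = rep(pid, each = config$n_foils),
      fragment_id = rep(sprintf("foil_%02d", seq_len(config$n_foils)), times = n),
      is_target = FALSE,
      source_message_id = NA_character_,
      response_yes = rbinom(n * config$n_foils, 1, config$false_alarm_rate) == 1
    )
    trials <- dplyr::bind_rows(targets, foils)

    dwell_mean <- rep(config$truth$dwell_mean_ms, times = n)
    if (config$dwell_sd > 0) {
      # lognormal with mean = planted dwell and sd = dwell_sd: dwell-time
      # distributions are strictly positive and heavily right-skewed
      sdlog <- sqrt(log(1 + (config$dwell_sd / dwell_mean)^2))
      meanlog <- log(dwell_mean) - sdlog^2 / 2
      record_mean <- exp(rnorm(n * m, meanlog, sdlog))
    } else {
      record_mean <- dwell_mean
    }
    jitter <- matrix(rnorm(3 * n * m, 0, config$aoi_jitter_sd), ncol = 3)
    aoi <- tibble::tibble(
      participant_id = grid_pid,
      message_id = grid_msg,
      dwell_s1 = pmax(record_mean + jitter[, 1], 0),
      dwell_s2 = pmax(record_mean + jitter[, 2], 0),
      dwell_hashtag = pmax(record_mean + jitter[, 3], 0)
    )

    list(traces = traces, baselines = baselines, trials = trials, aoi = aoi)
  })
}

#' Generate both arms and assemble the full synthetic pipeline input
#'
#' @param config A [cohort_config()].
#' @return A list with `selfreport` (long item table), `lab` (list of lab
#'   tibbles) and `truth` (the planted per-message means, the manifest for
#'   recovery testing).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  list(
    selfreport = generate_selfreport_arm(config),
    lab = generate_lab_arm(config),
    truth = config$truth
  )
}

#' Run the full estimation pipeline on a synthetic cohort
#'
#' Scores the self-report arm, summarizes the lab arm, and assembles the
#' estimated decision matrix — the estimator side of a parameter-recovery
#' experiment against the cohort's planted truth.
#'
#' @param cohort Output of [generate_cohort()].
#' @param attributes Attribute definitions for the resulting matrix.
#' @return A [decision_matrix()] of estimated per-message attribute means.
#' @export
estimate_decision_matrix <- function(cohort, attributes = default_attributes()) {
  scored <- score_selfreport(cohort$selfreport)
  sr <- summarize_selfreport(scored) |>
    dplyr::select("message_id", "construct", "mean") |>
    tidyr::pivot_wider(names_from = "construct", values_from = "mean")
  lab <- summarize_psychophys(cohort$lab$traces, cohort$lab$baselines,
                              cohort$lab$trials, cohort$lab$aoi)
  means <- dplyr::inner_join(sr, lab, by = "message_id") |>
    dplyr::rename(hr_deceleration = "hr_decel",
                  recognition_accuracy = "recog_acc",
                  visual_attention = "dwell_ms")
  decision_matrix(means, attributes = attributes)
}
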