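test_that("identical config and seed give identical cohorts", {
  c1 <- cohort_config(n_selfreport = 48, n_lab = 10, seed = 31)
  c2 <- cohort_config(n_selfreport = 48, n_lab = 10, seed = 31)
  expect_identical(generate_selfreport_arm(c1), generate_selfreport_arm(c2))
  expect_identical(generate_lab_arm(c1), generate_lab_arm(c2))

  c3 <- cohort_config(n_selfreport = 48, n_lab = 10, seed = 32)
  expect_false(identical(generate_selfreport_arm(c1),
                         generate_selfreport_arm(c3)))
})

test_that("noise-free self-report cohorts return the planted mean exactly", {
  truth <- fixture_truth()
  truth[construct_scales()$construct] <- 5
  truth$negative_emotion <- 3
  config <- cohort_config(n_selfreport = 24, seed = 9, truth = truth,
                          score_sd = c(receptivity = 0, engagement = 0,
                                       positive_attitude = 0,
                                       negative_emotion = 0))
  scored <- score_selfreport(generate_selfreport_arm(config))
  expect_true(all(scored$score[scored$construct != "negative_emotion"] == 5))
  expect_true(all(scored$score[scored$construct == "negative_emotion"] == 3))
})

test_that("noise-free lab cohorts return planted signals exactly", {
  truth <- fixture_truth()
  truth$recognition_p <- 1
  config <- cohort_config(n_lab = 8, seed = 13, truth = truth,
                          baseline_sd = 0, hr_participant_sd = 0,
                          bpm_noise_sd = 0, dwell_sd = 0, aoi_jitter_sd = 0)
  lab <- generate_lab_arm(config)
  got <- summarize_psychophys(lab$traces, lab$baselines, lab$trials, lab$aoi)
  got <- got[match(truth$message_id, got$message_id), ]
  expect_equal(got$hr_decel, truth$hr_deceleration)
  expect_equal(got$recog_acc, rep(1, 12))
  expect_equal(got$dwell_ms, truth$dwell_mean_ms)
})

test_that("default cohorts hit the target internal consistency", {
  config <- cohort_config(n_selfreport = 2000, seed = 55)
  arm <- generate_selfreport_arm(config)
  for (con in construct_scales()$construct) {
    items <- arm[arm$construct == con, ] |>
      tidyr::pivot_wider(id_cols = c("participant_id", "message_id"),
                         names_from = "item_index", values_from = "score")
    alpha <- cronbach_alpha(items[, -(1:2)])
    expect_lt(abs(alpha - config$alpha_target[[con]]), 0.1)
  }
})

test_that("observable means under discretization match a simulation oracle", {
  config <- cohort_config(seed = 1)
  # closed form vs brute-force rounding and clipping of latent normals
  withr::with_seed(808, {
    for (con in c("receptivity", "negative_emotion")) {
      scale <- construct_scales()
      scale <- scale[scale$construct == con, ]
      expected <- planted_observable_mean(config, con)
      mu <- config$truth[[con]][1]
      lc <- madmsg:::latent_components(config$alpha_target[[con]],
                                       scale$n_items, config$score_sd[[con]])
      sims <- rnorm(2e5, mu, sqrt(lc$participant_sd^2 + lc$item_sd^2))
      sims <- pmin(pmax(round(sims), scale$scale_min), scale$scale_max)
      expect_lt(abs(mean(sims) - expected[1]), 0.01)
    }
  })
  # without discretization the planted means are already observable
  cont <- cohort_config(seed = 1, discretize = FALSE)
  expect_identical(planted_observable_mean(cont, "engagement"),
                   cont$truth$engagement)
})

test_that("invalid generator configurations are rejected", {
  truth <- fixture_truth()
  truth$receptivity[1] <- 9  # outside the 7-point scale
  expect_error(cohort_config(truth = truth), class = "madmsg_input_error")

  truth2 <- fixture_truth()
  truth2$recognition_p[3] <- 1.4
  expect_error(cohort_config(truth = truth2), class = "madmsg_input_error")

  expect_error(cohort_config(n_lab = 0), class = "madmsg_input_error")
  expect_error(cohort_config(bpm_noise_sd = -1), class = "madmsg_input_error")
  expect_error(cohort_config(false_alarm_rate = 1.5),
               class = "madmsg_input_error")
})

test_that("a noise-free pipeline reproduces the published ranks end to end", {
  config <- cohort_config(
    n_selfreport = 713, n_lab = 120, seed = 100,
    score_sd = c(receptivity = 0, engagement = 0, positive_attitude = 0,
                 negative_emotion = 0),
    discretize = FALSE,
    baseline_sd = 0, hr_participant_sd = 0, bpm_noise_sd = 0,
    deterministic_recognition = TRUE, dwell_sd = 0, aoi_jitter_sd = 0
  )
  est <- estimate_decision_matrix(generate_cohort(config))
  rm_est <- rank_messages(est)
  rm_fix <- rank_messages(fixture_decision_matrix())
  m <- match(rm_fix$message_id, rm_est$message_id)
  expect_identical(rm_est$ranks[m, colnames(rm_fix$ranks)], rm_fix$ranks)

  # the two recomputed-ranks-only scenarios match the published table
  results <- run_scenarios(est)
  pub <- paper_fixture()$table2
  for (sc in c("equal_attributes", "prefer_lab")) {
    res <- results[[sc]]
    i <- match(pub$message_id, res$message_id)
    expect_equal(res$display_score[i], pub[[paste0(sc, "_score")]])
    expect_identical(res$rank[i], as.integer(pub[[paste0(sc, "_rank")]]))
  }
})

test_that("pipeline recovery error shrinks as the cohort grows", {
  mae <- sapply(c(50, 2000), function(n) {
    config <- cohort_config(n_selfreport = n, n_lab = max(10, n %/% 50),
                            seed = 2026)
    scored <- score_selfreport(generate_selfreport_arm(config))
    got <- summarize_selfreport(scored)
    got <- got[got$construct == "receptivity", ]
    truth <- fixture_truth()
    mean(abs(got$mean[match(truth$message_id, got$message_id)] -
               truth$receptivity))
  })
  expect_lt(mae[2], mae[1])
})
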