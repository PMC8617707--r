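test_that("heart-rate change scores average absolute per-second deviations", {
  expect_identical(hr_deceleration_score(70, c(70, 70, 70)), 0)
  expect_identical(hr_deceleration_score(70, c(68, 66, 64)), 4)

  # order-free: time reversal leaves the score unchanged
  withr::with_seed(5, {
    series <- 70 - runif(15, 0, 6)
    expect_identical(hr_deceleration_score(70, series),
                     hr_deceleration_score(70, rev(series)))
    # deviations scaled by c scale the score by c
    dev <- series - 70
    expect_equal(hr_deceleration_score(70, 70 + 2.5 * dev),
                 2.5 * hr_deceleration_score(70, series))
  })

  expect_error(hr_deceleration_score(70, numeric(0)), class = "madmsg_data_error")
  expect_error(hr_deceleration_score(0, c(70, 70)), class = "madmsg_data_error")
  expect_error(hr_deceleration_score(70, c(70, -1)), class = "madmsg_data_error")
})

test_that("per-message HR summary averages traces unweighted", {
  traces <- dplyr::bind_rows(
    tibble::tibble(participant_id = "P1", message_id = "M1",
                   second_index = 1:3, bpm = c(68, 66, 64)),   # score 4
    tibble::tibble(participant_id = "P2", message_id = "M1",
                   second_index = 1:5, bpm = rep(64, 5))        # score 6
  )
  baselines <- tibble::tibble(participant_id = c("P1", "P2"),
                              message_id = "M1", baseline_bpm = 70)
  s <- summarize_hr(traces, baselines)
  expect_identical(s$hr_decel, 5)  # traces of unequal length count equally
  expect_identical(s$n, 2L)

  expect_error(summarize_hr(traces, baselines[0, ]), class = "madmsg_data_error")
})

test_that("recognition accuracy is the hit rate over target trials only", {
  all_yes <- toy_trials("M1", n_total = 20, n_yes = 20)
  expect_identical(recognition_accuracy(all_yes, "M1")$recog_acc, 1)

  some <- toy_trials("M1", n_total = 20, n_yes = 15)
  expect_identical(recognition_accuracy(some, "M1")$recog_acc, 0.75)

  # correctly rejected foils change nothing
  with_foils <- toy_trials("M1", n_total = 20, n_yes = 15, n_foils = 24)
  expect_identical(recognition_accuracy(with_foils, "M1")$recog_acc, 0.75)

  expect_error(recognition_accuracy(all_yes, "M2"), class = "madmsg_data_error")
})

test_that("recognition pools per-participant hit proportions", {
  # P1 has both targets (1 hit of 2), P2 kept only one trial (1 hit of 1):
  # per-participant averaging gives (0.5 + 1)/2, not the pooled 2/3
  trials <- tibble::tibble(
    participant_id = c("P1", "P1", "P2"),
    fragment_id = c("M1_t1", "M1_t2", "M1_t1"),
    is_target = TRUE,
    source_message_id = "M1",
    response_yes = c(TRUE, FALSE, TRUE)
  )
  expect_identical(recognition_accuracy(trials, "M1")$recog_acc, 0.75)
})

test_that("mean dwell averages the three AOIs then the participants", {
  one <- tibble::tibble(participant_id = "P1", message_id = "M1",
                        dwell_s1 = 1200, dwell_s2 = 1300, dwell_hashtag = 1400)
  expect_identical(mean_dwell(one)$dwell_ms, 1300)

  two <- dplyr::bind_rows(
    one |> dplyr::mutate(dwell_s1 = 0, dwell_s2 = 0, dwell_hashtag = 0),
    one |> dplyr::mutate(dwell_s1 = 600, dwell_s2 = 600, dwell_hashtag = 600)
  )
  expect_identical(mean_dwell(two)$dwell_ms, 300)

  # unfixated AOI counts as zero dwell, with a message
  miss <- one |> dplyr::mutate(dwell_hashtag = NA_real_)
  expect_message(res <- mean_dwell(miss), "1 unfixated")
  expect_equal(res$dwell_ms, (1200 + 1300 + 0) / 3)

  expect_error(mean_dwell(one[0, ]), class = "madmsg_data_error")
  expect_error(mean_dwell(one |> dplyr::mutate(dwell_s1 = -5)),
               class = "madmsg_data_error")
})

test_that("lab summarizers commute with participant reordering", {
  config <- cohort_config(n_lab = 25, seed = 77)
  lab <- generate_lab_arm(config)
  shuffle <- function(df) df[sample(nrow(df)), ]
  withr::with_seed(1, {
    a <- summarize_psychophys(lab$traces, lab$baselines, lab$trials, lab$aoi)
    b <- summarize_psychophys(shuffle(lab$traces), shuffle(lab$baselines),
                              shuffle(lab$trials), shuffle(lab$aoi))
  })
  expect_equal(a, b)
})
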