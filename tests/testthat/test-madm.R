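fx_dm <- fixture_decision_matrix()
fx_rm <- rank_messages(fx_dm)

test_that("study totals sum the study's attribute ranks and rank the sums", {
  sr <- study_totals(fx_rm, "self_report")
  expect_identical(sr$total[sr$message_id == "H1"], 10L)     # 1 + 4 + 3 + 2
  expect_identical(sr$total_rank[sr$message_id == "H1"], 1L)

  lab <- study_totals(fx_rm, "lab")
  expect_identical(lab$total[lab$message_id == "AF1"], 7L)   # 1 + 4 + 2
  expect_identical(lab$total_rank[lab$message_id == "AF1"], 1L)

  expect_error(study_totals(fx_rm, "imaginary"), class = "madmsg_input_error")
})

test_that("a single-attribute study's totals reproduce that attribute's ranks", {
  dm <- decision_matrix(
    tibble::tibble(message_id = c("M1", "M2", "M3"), solo = c(2, 9, 9)),
    attributes = tibble::tibble(name = "solo", study = "self_report",
                                direction = "higher")
  )
  rm <- rank_messages(dm)
  st <- study_totals(rm, "self_report")
  expect_identical(st$total, as.integer(rm$ranks[, "solo"]))
  expect_identical(st$total_rank, as.integer(rm$ranks[, "solo"]))
})

test_that("scenario summary scores are weighted mean ranks", {
  results <- run_scenarios(fx_dm)

  ea <- results$equal_attributes
  # H1: mean of ranks (1, 4, 3, 2, 4, 2, 12) = 4.0, third best overall
  expect_equal(ea$summary_score[ea$message_id == "H1"], 4)
  expect_identical(ea$rank[ea$message_id == "H1"], 3L)

  pl <- results$prefer_lab
  # HS2: mean of self-report total rank 1 and lab attribute ranks 8, 1, 6
  expect_equal(pl$summary_score[pl$message_id == "HS2"], 4)
  expect_identical(pl$rank[pl$message_id == "HS2"], 2L)

  # scores are mean ranks, so they live in [1, n]
  for (res in results) {
    expect_true(all(res$summary_score >= 1 & res$summary_score <= 12))
  }
})

test_that("a single-component scenario reproduces that component's ranking", {
  solo <- weighting_scenario(
    "solo", tibble::tibble(type = "attribute", ref = "receptivity", weight = 2))
  res <- scenario_score(fx_rm, all_study_totals(fx_rm), solo)
  expect_identical(res$rank, as.integer(fx_rm$ranks[, "receptivity"]))
  expect_equal(res$summary_score, as.numeric(fx_rm$ranks[, "receptivity"]))
})

test_that("scenario definitions are validated", {
  expect_error(weighting_scenario("empty", tibble::tibble(type = character(),
                                                          ref = character(),
                                                          weight = numeric())),
               class = "madmsg_input_error")
  expect_error(weighting_scenario("neg", tibble::tibble(type = "attribute",
                                                        ref = "receptivity",
                                                        weight = -1)),
               class = "madmsg_input_error")
  expect_error(weighting_scenario("zero", tibble::tibble(type = "attribute",
                                                         ref = "receptivity",
                                                         weight = 0)),
               class = "madmsg_input_error")
  bad <- weighting_scenario("bad", tibble::tibble(type = "attribute",
                                                  ref = "nope", weight = 1))
  expect_error(scenario_score(fx_rm, all_study_totals(fx_rm), bad),
               class = "madmsg_input_error")
})

test_that("equal-attribute scores are invariant under attribute permutation", {
  fx <- paper_fixture()
  perm <- fx$attributes[c(5, 2, 7, 1, 4, 6, 3), ]
  dm_perm <- decision_matrix(fx$means, attributes = perm)
  base <- run_scenarios(fx_dm)$equal_attributes
  permuted <- run_scenarios(dm_perm)$equal_attributes
  expect_equal(permuted$summary_score, base$summary_score)
  expect_identical(permuted$rank, base$rank)
})

test_that("permuting message order permutes all outputs consistently", {
  fx <- paper_fixture()
  withr::with_seed(21, ord <- sample(12))
  dm_perm <- decision_matrix(fx$means[ord, ], attributes = fx$attributes)
  base <- run_scenarios(fx_dm)$prefer_lab
  permuted <- run_scenarios(dm_perm)$prefer_lab
  m <- match(base$message_id, permuted$message_id)
  expect_equal(permuted$summary_score[m], base$summary_score)
  expect_identical(permuted$rank[m], base$rank)
})

test_that("consensus keeps messages in the top half of every scenario", {
  results <- run_scenarios(fx_dm,
                           published_total_ranks = paper_fixture()$published)
  expect_setequal(consensus_top_half(results),
                  c("HF2", "HS2", "H2", "H1", "A1"))

  # one scenario alone: exactly its top half
  one <- results$equal_attributes
  expect_setequal(consensus_top_half(list(one)),
                  one$message_id[one$rank <= 6])

  # mirror-image rankings share no top-half message
  up <- tibble::tibble(message_id = paste0("M", 1:4),
                       scenario = "up", summary_score = 1:4,
                       rank = 1:4, tie = FALSE)
  down <- up |> dplyr::mutate(scenario = "down",
                              summary_score = rev(summary_score),
                              rank = rev(rank))
  expect_length(consensus_top_half(list(up, down)), 0)

  expect_error(consensus_top_half(list(up, up[1:3, ])),
               class = "madmsg_input_error")
})

test_that("weight sweep finds dominant messages and is seed-deterministic", {
  # a message ranked 1 on every attribute wins every sampled weighting
  dm <- decision_matrix(
    tibble::tibble(message_id = c("M1", "M2", "M3"),
                   a = c(9, 5, 1), b = c(8, 2, 3)),
    attributes = tibble::tibble(name = c("a", "b"), study = "self_report",
                                direction = "higher")
  )
  sweep <- weight_sweep(rank_messages(dm), n_samples = 200, seed = 5)
  expect_identical(sweep$win_freq[sweep$message_id == "M1"], 1)
  expect_identical(sweep$win_freq[sweep$message_id == "M3"], 0)

  two <- weight_sweep(rank_messages(toy_matrix(c(3, 8))), n_samples = 50, seed = 2)
  expect_identical(two$win_freq, c(0, 1))

  expect_identical(weight_sweep(fx_rm, 500, seed = 11),
                   weight_sweep(fx_rm, 500, seed = 11))
  expect_error(weight_sweep(fx_rm, 0), class = "madmsg_input_error")
})

test_that("on the bundled matrix HF2 wins more weightings than dominated AF2", {
  sweep <- weight_sweep(fx_rm, n_samples = 10000, seed = 123)
  hf2 <- sweep$win_freq[sweep$message_id == "HF2"]
  af2 <- sweep$win_freq[sweep$message_id == "AF2"]
  # HF2's rank vector weakly dominates AF2's, so AF2 can never win alone
  expect_true(all(fx_rm$ranks["HF2", ] <= fx_rm$ranks["AF2", ]))
  expect_gt(hf2, af2)
  expect_identical(af2, 0)
})
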