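#' Define a weighting scenario
#'
#' A weighting scenario names the rank components that enter a message's
#' summary score and their weights. A component is either a single
#' attribute's rank column or a study's total rank (the competition rank of
#' that study's rank sum). The summary score for a message is the weighted
#' mean of its component rank values, so it always lies between 1 and the
#' number of messages; smaller is better.
#'
#' @param name Scenario name.
#' @param components A data frame with columns `type` (`"attribute"` or
#'   `"study_total"`), `ref` (attribute name or study label) and `weight`
#'   (nonnegative, at least one positive).
#' @param digits Decimal places used when *displaying* the summary score
#'   (ranking always uses the unrounded score).
#' @return An object of class `weighting_scenario`.
#' @seealso [madm_scenarios()] for the four standard presets.
#' @export
weighting_scenario <- function(name, components, digits = 1) {
  components <- tibble::as_tibble(components)
  assert_columns(components, c("type", "ref", "weight"), "`components`")
  if (nrow(components) == 0) {
    stop_madm("A weighting scenario needs at least one component.",
              class = "madmsg_input_error")
  }
  bad_type <- setdiff(unique(components$type), c("attribute", "study_total"))
  if (length(bad_type) > 0) {
    stop_madm(sprintf("Unknown component type: %s", paste(bad_type, collapse = ", ")),
              class = "madmsg_input_error")
  }
  if (any(components$weight < 0)) {
    stop_madm("Component weights must be nonnegative.",
              class = "madmsg_input_error")
  }
  if (sum(components$weight) <= 0) {
    stop_madm("Component weights must sum to a positive value.",
              class = "madmsg_input_error")
  }
  structure(list(name = name, components = components, digits = digits),
            class = "weighting_scenario")
}

#' The four standard weighting scenarios
#'
#' Builds the four presets used to integrate a self-report arm with a lab
#' arm, all with unit weights:
#' \describe{
#'   \item{equal_attributes}{mean of all attribute ranks (4 self-report +
#'     3 lab in the default configuration) — every measured construct
#'     counts equally.}
#'   \item{equal_studies}{mean of the two study-total ranks — each data
#'     collection method counts equally regardless of how many attributes
#'     it contributed.}
#'   \item{prefer_self_report}{the individual self-report attribute ranks
#'     plus the lab study-total rank (5 components) — self-report detail
#'     dominates.}
#'   \item{prefer_lab}{the self-report study-total rank plus the individual
#'     lab attribute ranks (4 components) — lab detail dominates.}
#' }
#'
#' @param attributes Attribute definitions (see [default_attributes()]);
#'   the presets are derived from their `study` labels.
#' @return Named list of four [weighting_scenario()] objects.
#' @export
madm_scenarios <- function(attributes = default_attributes()) {
  attributes <- as_attribute_defs(attributes)
  sr <- attributes$name[attributes$study == "self_report"]
  lab <- attributes$name[attributes$study == "lab"]
  comp <- function(type, ref) tibble::tibble(type = type, ref = ref, weight = 1)
  list(
    equal_attributes = weighting_scenario(
      "equal_attributes", comp("attribute", attributes$name), digits = 1),
    equal_studies = weighting_scenario(
      "equal_studies", comp("study_total", c("self_report", "lab")), digits = 1),
    prefer_self_report = weighting_scenario(
      "prefer_self_report",
      dplyr::bind_rows(comp("attribute", sr), comp("study_total", "lab")),
      digits = 1),
    prefer_lab = weighting_scenario(
      "prefer_lab",
      dplyr::bind_rows(comp("study_total", "self_report"), comp("attribute", lab)),
      digits = 2)
  )
}

#' Score one weighting scenario
#'
#' Computes each message's summary score (weighted mean of the scenario's
#' component rank values) and ranks the summary scores with competition
#' ranking (smaller score = rank 1 = best; tied scores share the minimum
#' rank and are flagged).
#'
#' @param rm A `rank_matrix` from [rank_messages()].
#' @param totals Study totals as returned by [all_study_totals()]
#'   (optionally with an overridden `total_rank` column, see
#'   [run_scenarios()]).
#' @param scenario A [weighting_scenario()].
#' @return A tibble with columns `message_id`, `scenario`, `summary_score`
#'   (full precision), `display_score` (rounded to the scenario's display
#'   digits), `rank` and `tie`.
#' @export
scenario_score <- function(rm, totals, scenario) {
  stopifnot(inherits(rm, "rank_matrix"), inherits(scenario, "weighting_scenario"))
  comp <- scenario$components
  values <- matrix(NA_real_, length(rm$message_id), nrow(comp))
  for (i in seq_len(nrow(comp))) {
    values[, i] <- component_ranks(rm, totals, comp$type[i], comp$ref[i])
  }
  w <- comp$weight
  summary_score <- as.numeric(values %*% w) / sum(w)
  r <- rank_competition(summary_score, direction = "lower")
  digits <- scenario$digits
  tibble::tibble(
    message_id = rm$message_id,
    scenario = scenario$name,
    summary_score = summary_score,
    display_score = round(summary_score, digits),
    display_digits = digits,
    rank = r$rank,
    tie = r$tie
  )
}

component_ranks <- function(rm, totals, type, ref) {
  if (type == "attribute") {
    if (!ref %in% colnames(rm$ranks)) {
      stop_madm(sprintf("Scenario references unknown attribute '%s'.", ref),
                class = "madmsg_input_error")
    }
    return(as.numeric(rm$ranks[, ref]))
  }
  st <- totals[totals$study == ref, ]
  if (nrow(st) == 0) {
    stop_madm(sprintf("Scenario references unknown study total '%s'.", ref),
              class = "madmsg_input_error")
  }
  idx <- match(rm$message_id, st$message_id)
  if (anyNA(idx)) {
    stop_madm(sprintf("Study totals for '%s' do not cover every message.", ref),
              class = "madmsg_input_error")
  }
  as.numeric(st$total_rank[idx])
}

#' Run a set of weighting scenarios over a decision matrix
#'
#' Convenience wrapper: ranks the matrix, computes study totals, applies an
#' optional published total-rank override, and scores every scenario.
#'
#' @param dm A [decision_matrix()].
#' @param scenarios Named list of [weighting_scenario()] objects; defaults
#'   to the four [madm_scenarios()] presets.
#' @param published_total_ranks Optional reproduction-mode override: a data
#'   frame with a `message_id` column and one `<study>_total_rank` column
#'   per study whose computed total rank should be replaced by a published
#'   column (used when reproducing a printed table whose total-rank column
#'   differs from the rank of the printed rank sums).
#' @return Named list of scenario result tibbles (see [scenario_score()]).
#' @export
run_scenarios <- function(dm, scenarios = NULL,
                          published_total_ranks = NULL) {
  stopifnot(inherits(dm, "decision_matrix"))
  if (is.null(scenarios)) scenarios <- madm_scenarios(dm$attributes)
  rm <- rank_messages(dm)
  totals <- all_study_totals(rm)
  if (!is.null(published_total_ranks)) {
    totals <- override_total_ranks(totals, published_total_ranks)
  }
  lapply(scenarios, function(sc) scenario_score(rm, totals, sc))
}

override_total_ranks <- function(totals, published) {
  published <- tibble::as_tibble(published)
  assert_columns(published, "message_id", "`published_total_ranks`")
  for (study in unique(totals$study)) {
    col <- paste0(study, "_total_rank")
    if (!col %in% names(published)) next
    idx <- totals$study == study
    m <- match(totals$message_id[idx], published$message_id)
    if (anyNA(m)) {
      stop_madm(sprintf("Published total ranks for '%s' do not cover every message.",
                        study), class = "madmsg_input_error")
    }
    new_rank <- as.integer(published[[col]][m])
    totals$total_rank[idx] <- new_rank
    totals$tie[idx] <- vapply(new_rank, function(v) sum(new_rank == v) > 1L,
                              logical(1))
  }
  totals
}

#' Messages ranked in the top half of every scenario
#'
#' The consensus selection rule: keep the messages whose scenario rank is
#' at most `floor(n / 2)` (with `n` messages) in *all* supplied scenario
#' results.
#'
#' @param results A list of scenario result tibbles (e.g., from
#'   [run_scenarios()]).
#' @return Character vector of consensus message ids, in the message order
#'   of the first result.
#' @export
consensus_top_half <- function(results) {
  if (inherits(results, "data.frame")) results <- list(results)
  if (length(results) == 0) {
    stop_madm("Need at least one scenario result.", class = "madmsg_input_error")
  }
  ids <- results[[1]]$message_id
  for (res in results) {
    if (!setequal(res$message_id, ids)) {
      stop_madm("Scenario results cover different message sets.",
                class = "madmsg_input_error")
    }
  }
  cutoff <- floor(length(ids) / 2)
  keep <- rep(TRUE, length(ids))
  for (res in results) {
    rank_for <- res$rank[match(ids, res$message_id)]
    keep <- keep & rank_for <= cutoff
  }
  ids[keep]
}

#' Weight-sensitivity sweep over the attribute simplex
#'
#' Generalizes the fixed weighting scenarios: samples weight vectors
#' uniformly on the simplex over all attribute ranks, scores every message
#' under each sampled weighting, and reports how often each message attains
#' rank 1 (messages tied for the best score all count as winners). A
#' message that wins under most weightings is robustly optimal; a message
#' that never wins is dominated.
#'
#' @param rm A `rank_matrix`.
#' @param n_samples Number of weight vectors to draw (>= 1).
#' @param seed Integer seed; the sweep is deterministic given the seed.
#' @return A tibble with `message_id` and `win_freq` (fraction of sampled
#'   weightings won).
#' @export
weight_sweep <- function(rm, n_samples = 1000, seed = 1) {
  stopifnot(inherits(rm, "rank_matrix"))
  if (!is.numeric(n_samples) || n_samples < 1) {
    stop_madm("`n_samples` must be at least 1.", class = "madmsg_input_error")
  }
  n_samples <- as.integer(n_samples)
  k <- ncol(rm$ranks)
  wins <- withr::with_seed(seed, {
    # Exponential spacings normalised row-wise = uniform Dirichlet(1,...,1)
    w <- matrix(rgamma(n_samples * k, shape = 1), n_samples, k)
    scores <- w %*% t(rm$ranks)  # n_samples x n_messages weighted rank sums
    best <- apply(scores, 1, min)
    colSums(scores == best)
  })
  tibble::tibble(message_id = rm$message_id,
                 win_freq = as.numeric(wins) / n_samples)
}
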