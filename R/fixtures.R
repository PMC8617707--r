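madmsg_extdata <- function(file) {
  path <- system.file("extdata", file, package = "madmsg")
  if (path == "") {
    stop_madm(sprintf("Bundled fixture file '%s' not found.", file))
  }
  path
}

read_fixture_csv <- function(file) {
  readr::read_csv(madmsg_extdata(file), show_col_types = FALSE,
                  progress = FALSE)
}

#' The bundled published decision-matrix fixture
#'
#' Loads the twelve-message waterpipe tobacco study bundled with the
#' package: message metadata (risk content x theme factorial, text and
#' hashtag where published), the per-message attribute means, their printed
#' dispersions (SEs for the self-report arm, SDs for the lab arm), the
#' attribute definitions, the published per-study rank totals and total
#' ranks, and the published weighting-scenario table.
#'
#' On load the fixture is self-checked: the design must contain exactly 12
#' messages, 2 per risk-content x theme cell, and the published
#' self-report totals must equal the rank sums recomputed from the
#' published means (the self-report side of the published table is fully
#' self-consistent). The published lab *total-rank* column is retained
#' verbatim; it is the column reproduction mode feeds to scenarios that
#' consume study-total ranks (see [run_scenarios()]).
#'
#' @return A list with elements `messages`, `means`, `spread`,
#'   `attributes`, `published` and `table2`.
#' @export
paper_fixture <- function() {
  fx <- list(
    messages = read_fixture_csv("messages.csv"),
    means = read_fixture_csv("table1_means.csv"),
    spread = read_fixture_csv("table1_spread.csv"),
    attributes = read_fixture_csv("attributes.csv"),
    published = read_fixture_csv("published_ranks.csv"),
    table2 = read_fixture_csv("table2_published.csv")
  )
  validate_fixture(fx)
  fx
}

validate_fixture <- function(fx) {
  if (nrow(fx$messages) != 12) {
    stop_madm("Fixture must contain exactly 12 messages.")
  }
  cells <- table(fx$messages$risk_content, fx$messages$theme)
  if (!all(dim(cells) == c(2, 3)) || !all(cells == 2)) {
    stop_madm("Fixture messages must fill a 2 x 3 design with 2 messages per cell.")
  }
  dm <- decision_matrix(fx$means, attributes = fx$attributes)
  totals <- study_totals(rank_messages(dm), "self_report")
  pub <- fx$published[match(totals$message_id, fx$published$message_id), ]
  if (!identical(totals$total, as.integer(pub$self_report_total)) ||
      !identical(totals$total_rank, as.integer(pub$self_report_total_rank))) {
    stop_madm(paste(
      "Fixture self-consistency check failed: published self-report totals",
      "do not equal the rank sums recomputed from the published means."
    ))
  }
  invisible(fx)
}

#' The bundled decision matrix as a `decision_matrix` object
#'
#' @return The fixture means and attributes wrapped by [decision_matrix()],
#'   with message metadata attached.
#' @export
fixture_decision_matrix <- function() {
  fx <- paper_fixture()
  decision_matrix(fx$means, attributes = fx$attributes, messages = fx$messages)
}
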