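read_validated_csv <- function(path, cols, what) {
  if (!file.exists(path)) {
    stop_madm(sprintf("File not found: %s", path), class = "madmsg_input_error")
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  assert_columns(df, cols, what)
  df
}

#' Read long-format self-report item responses
#'
#' @param path CSV with columns `participant_id`, `message_id`,
#'   `construct`, `item_index`, `score`.
#' @return A tibble, ready for [score_selfreport()].
#' @export
read_selfreport_csv <- function(path) {
  read_validated_csv(path,
                     c("participant_id", "message_id", "construct",
                       "item_index", "score"),
                     sprintf("'%s'", path))
}

#' Read heart-rate traces and their baseline table
#'
#' @param traces_path CSV with columns `participant_id`, `message_id`,
#'   `second_index`, `bpm`.
#' @param baselines_path CSV with columns `participant_id`, `message_id`,
#'   `baseline_bpm`.
#' @return A list with tibbles `traces` and `baselines`.
#' @export
read_hr_csv <- function(traces_path, baselines_path) {
  list(
    traces = read_validated_csv(
      traces_path, c("participant_id", "message_id", "second_index", "bpm"),
      sprintf("'%s'", traces_path)),
    baselines = read_validated_csv(
      baselines_path, c("participant_id", "message_id", "baseline_bpm"),
      sprintf("'%s'", baselines_path))
  )
}

#' Read recognition-task trials (one row per trial)
#'
#' @param path CSV with columns `participant_id`, `fragment_id`,
#'   `is_target`, `source_message_id`, `response_yes`.
#' @return A tibble, ready for [recognition_accuracy()].
#' @export
read_recognition_csv <- function(path) {
  read_validated_csv(path,
                     c("participant_id", "fragment_id", "is_target",
                       "source_message_id", "response_yes"),
                     sprintf("'%s'", path))
}

#' Read AOI dwell records (one row per participant-message)
#'
#' @param path CSV with columns `participant_id`, `message_id`,
#'   `dwell_s1`, `dwell_s2`, `dwell_hashtag`.
#' @return A tibble, ready for [mean_dwell()].
#' @export
read_aoi_csv <- function(path) {
  read_validated_csv(path,
                     c("participant_id", "message_id", "dwell_s1",
                       "dwell_s2", "dwell_hashtag"),
                     sprintf("'%s'", path))
}

#' Load a decision matrix from CSV (or the bundled fixture)
#'
#' @param path CSV whose first column is `message_id` and remaining columns
#'   are attribute means, or the fixture name `"table1"` for the bundled
#'   published matrix.
#' @param attributes_path Optional CSV of attribute definitions (`name`,
#'   `study`, `direction`); defaults to [default_attributes()] restricted
#'   to the columns present.
#' @return A [decision_matrix()].
#' @export
load_decision_matrix <- function(path, attributes_path = NULL) {
  if (identical(path, "table1")) {
    return(fixture_decision_matrix())
  }
  means <- read_validated_csv(path, "message_id", sprintf("'%s'", path))
  attributes <- if (is.null(attributes_path)) {
    found <- setdiff(names(means), "message_id")
    defaults <- default_attributes()
    known <- defaults[defaults$name %in% found, ]
    extra <- setdiff(found, defaults$name)
    dplyr::bind_rows(known, tibble::tibble(name = extra, study = "unspecified",
                                           direction = "higher"))
  } else {
    read_validated_csv(attributes_path, c("name", "study", "direction"),
                       sprintf("'%s'", attributes_path))
  }
  decision_matrix(means, attributes = attributes)
}

#' Write a decision matrix to CSV
#'
#' @param dm A [decision_matrix()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_decision_matrix <- function(dm, path) {
  stopifnot(inherits(dm, "decision_matrix"))
  df <- tibble::as_tibble(dm$means, rownames = "message_id")
  readr::write_csv(df, path)
  invisible(path)
}

#' Decision-matrix table with ranks and per-study totals
#'
#' Renders the classic decision-matrix presentation: one row per message
#' with every attribute's mean and recomputed competition rank, followed by
#' each study's rank sum and total rank.
#'
#' @param dm A [decision_matrix()].
#' @return A tibble with `message_id`, `<attribute>_mean` and
#'   `<attribute>_rank` columns, and `<study>_total` /
#'   `<study>_total_rank` columns.
#' @export
render_decision_table <- function(dm) {
  stopifnot(inherits(dm, "decision_matrix"))
  rm <- rank_messages(dm)
  out <- tibble::tibble(message_id = dm$message_id)
  for (a in dm$attributes$name) {
    out[[paste0(a, "_mean")]] <- dm$means[, a]
    out[[paste0(a, "_rank")]] <- rm$ranks[, a]
  }
  for (s in unique(dm$attributes$study)) {
    st <- study_totals(rm, s)
    out[[paste0(s, "_total")]] <- st$total[match(out$message_id, st$message_id)]
    out[[paste0(s, "_total_rank")]] <-
      st$total_rank[match(out$message_id, st$message_id)]
  }
  out
}

#' Weighting-scenario table (summary scores and ranks)
#'
#' Renders a set of scenario results side by side, one row per message.
#' With `format = "numeric"` each scenario contributes `_score` (rounded to
#' the scenario's display digits), `_rank` and `_tie` columns. With
#' `format = "display"` scores become fixed-decimal strings and tied ranks
#' carry a trailing `" *"`, matching the conventional footnote
#' "* denotes tied ranking" (returned as the `footnote` attribute).
#'
#' @param results Named list of scenario result tibbles over the same
#'   message set, e.g. from [run_scenarios()].
#' @param format `"numeric"` or `"display"`.
#' @return A tibble, one row per message.
#' @export
render_scenario_table <- function(results, format = c("numeric", "display")) {
  format <- match.arg(format)
  if (inherits(results, "data.frame")) results <- list(results)
  if (length(results) == 0) {
    stop_madm("Need at least one scenario result.", class = "madmsg_input_error")
  }
  ids <- results[[1]]$message_id
  out <- tibble::tibble(message_id = ids)
  for (res in results) {
    if (!setequal(res$message_id, ids)) {
      stop_madm("Scenario results cover different message sets.",
                class = "madmsg_input_error")
    }
    res <- res[match(ids, res$message_id), ]
    name <- res$scenario[1]
    if (format == "numeric") {
      out[[paste0(name, "_score")]] <- res$display_score
      out[[paste0(name, "_rank")]] <- res$rank
      out[[paste0(name, "_tie")]] <- res$tie
    } else {
      decimals <- if ("display_digits" %in% names(res)) {
        res$display_digits[1]
      } else {
        infer_display_digits(res$display_score)
      }
      out[[paste0(name, "_score")]] <- formatC(res$display_score,
                                               format = "f", digits = decimals)
      out[[paste0(name, "_rank")]] <- paste0(res$rank,
                                             ifelse(res$tie, " *", ""))
    }
  }
  if (format == "display") attr(out, "footnote") <- "* denotes tied ranking"
  out
}

infer_display_digits <- function(x) {
  frac <- sub("^[^.]*\\.?", "", format(x, trim = TRUE, scientific = FALSE))
  max(nchar(frac), 1)
}

#' Write per-message construct summaries to CSV
#'
#' @param summary Output of [summarize_selfreport()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_construct_summary_csv <- function(summary, path) {
  assert_columns(summary, c("message_id", "construct", "mean", "se", "n"),
                 "`summary`")
  readr::write_csv(summary, path)
  invisible(path)
}

#' Write the per-message psychophysiological summary to CSV
#'
#' @param summary Output of [summarize_psychophys()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_psychophys_csv <- function(summary, path) {
  assert_columns(summary, c("message_id", "hr_decel", "recog_acc", "dwell_ms"),
                 "`summary`")
  readr::write_csv(summary, path)
  invisible(path)
}

#' Reproduce the published decision-matrix and scenario tables
#'
#' Recomputes, from the bundled per-message means alone, the full
#' decision-matrix table (attribute ranks and per-study totals) and the
#' four weighting scenarios in reproduction mode (study-total rank
#' components use the published total-rank columns). Optionally verifies
#' the recomputation against the bundled published tables.
#'
#' @param check If `TRUE` (default), error unless the recomputed tables
#'   agree with the bundled published tables on every self-report total,
#'   every lab rank sum, and every scenario score, rank and tie flag.
#' @return A list with `table1` (decision table), `table2` (numeric
#'   scenario table), and `consensus` (top-half messages in all scenarios).
#' @export
reproduce_tables <- function(check = TRUE) {
  fx <- paper_fixture()
  dm <- decision_matrix(fx$means, attributes = fx$attributes,
                        messages = fx$messages)
  table1 <- render_decision_table(dm)
  results <- run_scenarios(dm, published_total_ranks = fx$published)
  table2 <- render_scenario_table(results, format = "numeric")
  consensus <- consensus_top_half(results)
  if (check) {
    pub <- fx$published[match(table1$message_id, fx$published$message_id), ]
    ok_tot <-
      identical(as.integer(table1$self_report_total),
                as.integer(pub$self_report_total)) &&
      identical(as.integer(table1$self_report_total_rank),
                as.integer(pub$self_report_total_rank)) &&
      identical(as.integer(table1$lab_total), as.integer(pub$lab_total))
    t2 <- fx$table2[match(table2$message_id, fx$table2$message_id), ]
    shared <- setdiff(intersect(names(table2), names(t2)), "message_id")
    ok_t2 <- all(vapply(shared, function(col) {
      isTRUE(all.equal(as.numeric(table2[[col]]), as.numeric(t2[[col]]),
                       tolerance = 1e-9))
    }, logical(1)))
    if (!ok_tot || !ok_t2) {
      stop_madm("Recomputed tables do not match the bundled published tables.")
    }
  }
  list(table1 = table1, table2 = table2, consensus = consensus)
}
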