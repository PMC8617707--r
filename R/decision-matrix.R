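#' Construct a message-by-attribute decision matrix
#'
#' The decision matrix is the core MADM object: one row per alternative
#' (message), one column per attribute (a measured construct), each cell the
#' attribute's mean score for that message. Attributes carry a study label
#' (`self_report` or `lab`) and a direction, so downstream ranking knows
#' which way "better" points and which attributes belong to which arm.
#'
#' @param means A data frame with a `message_id` column and one numeric
#'   column per attribute, or a numeric matrix with message ids as row
#'   names and attribute names as column names.
#' @param attributes A data frame with columns `name`, `study` and
#'   `direction` (`"higher"` or `"lower"`), one row per attribute. Defaults
#'   to the seven-attribute configuration of the bundled study (four
#'   self-report, three lab, all higher-is-better).
#' @param messages Optional data frame of message metadata with a
#'   `message_id` column (e.g., risk-content and theme factors); retained
#'   for rendering.
#'
#' @return An object of class `decision_matrix`.
#' @seealso [rank_messages()], [study_totals()], [load_decision_matrix()]
#' @export
decision_matrix <- function(means, attributes = default_attributes(),
                            messages = NULL) {
  attributes <- as_attribute_defs(attributes)
  if (is.matrix(means)) {
    if (is.null(rownames(means)) || is.null(colnames(means))) {
      stop_madm("A matrix of means needs message row names and attribute column names.",
                class = "madmsg_input_error")
    }
    mat <- means
  } else {
    means <- tibble::as_tibble(means)
    assert_columns(means, "message_id", "`means`")
    mat <- as.matrix(means[setdiff(names(means), "message_id")])
    rownames(mat) <- as.character(means$message_id)
  }
  storage.mode(mat) <- "double"
  if (anyDuplicated(rownames(mat))) {
    dup <- rownames(mat)[duplicated(rownames(mat))]
    stop_madm(sprintf("Duplicate message_id: %s", paste(unique(dup), collapse = ", ")),
              class = "madmsg_input_error")
  }
  missing_attr <- setdiff(attributes$name, colnames(mat))
  if (length(missing_attr) > 0) {
    stop_madm(sprintf("Attribute column(s) absent from the means table: %s",
                      paste(missing_attr, collapse = ", ")),
              class = "madmsg_input_error")
  }
  mat <- mat[, attributes$name, drop = FALSE]
  if (anyNA(mat)) {
    idx <- which(is.na(mat), arr.ind = TRUE)
    cells <- paste0(rownames(mat)[idx[, 1]], "/", colnames(mat)[idx[, 2]])
    stop_madm(sprintf("Decision matrix has missing cell(s): %s",
                      paste(cells, collapse = ", ")),
              class = "madmsg_input_error")
  }
  if (!is.null(messages)) {
    messages <- tibble::as_tibble(messages)
    assert_columns(messages, "message_id", "`messages`")
    if (!setequal(messages$message_id, rownames(mat))) {
      stop_madm("`messages` metadata does not cover the same message set as `means`.",
                class = "madmsg_input_error")
    }
    messages <- messages[match(rownames(mat), messages$message_id), ]
  }
  structure(
    list(message_id = rownames(mat), attributes = attributes,
         means = mat, messages = messages),
    class = "decision_matrix"
  )
}

as_attribute_defs <- function(attributes) {
  attributes <- tibble::as_tibble(attributes)
  assert_columns(attributes, c("name", "study", "direction"), "`attributes`")
  bad <- setdiff(unique(attributes$direction), c("higher", "lower"))
  if (length(bad) > 0) {
    stop_madm(sprintf("Unknown attribute direction: %s", paste(bad, collapse = ", ")),
              class = "madmsg_input_error")
  }
  if (anyDuplicated(attributes$name)) {
    stop_madm("Attribute names must be unique.", class = "madmsg_input_error")
  }
  attributes
}

#' Default attribute configuration (4 self-report + 3 lab)
#'
#' @return A tibble of attribute definitions: the four crowdsourced
#'   self-report constructs and the three laboratory psychophysiological
#'   measures, all treated as higher-is-better (including negative emotion,
#'   per fear-appeal logic: stronger reported negative emotion ranks the
#'   message as more effective).
#' @export
default_attributes <- function() {
  tibble::tibble(
    name = c("receptivity", "engagement", "positive_attitude",
             "negative_emotion", "hr_deceleration", "recognition_accuracy",
             "visual_attention"),
    study = c(rep("self_report", 4), rep("lab", 3)),
    direction = "higher"
  )
}

#' @export
print.decision_matrix <- function(x, ...) {
  cat(sprintf("<decision_matrix> %d messages x %d attributes\n",
              nrow(x$means), ncol(x$means)))
  cat("attributes:",
      paste0(x$attributes$name, " (", x$attributes$study, ")", collapse = ", "),
      "\n")
  print(round(x$means, 3))
  invisible(x)
}

#' Rank messages within every attribute of a decision matrix
#'
#' Applies competition ranking ([rank_competition()]) to each attribute
#' column: rank 1 is the best score in that attribute's direction, tied
#' scores share the minimum rank.
#'
#' @param dm A [decision_matrix()].
#' @return An object of class `rank_matrix`: integer ranks and tie flags,
#'   both message-by-attribute, plus the attribute definitions.
#' @export
rank_messages <- function(dm) {
  stopifnot(inherits(dm, "decision_matrix"))
  ranks <- matrix(NA_integer_, nrow(dm$means), ncol(dm$means),
                  dimnames = dimnames(dm$means))
  tie <- matrix(NA, nrow(dm$means), ncol(dm$means),
                dimnames = dimnames(dm$means))
  for (j in seq_len(ncol(dm$means))) {
    r <- rank_competition(dm$means[, j], direction = dm$attributes$direction[j])
    ranks[, j] <- r$rank
    tie[, j] <- r$tie
  }
  structure(
    list(message_id = dm$message_id, attributes = dm$attributes,
         ranks = ranks, tie = tie),
    class = "rank_matrix"
  )
}

#' @export
print.rank_matrix <- function(x, ...) {
  cat(sprintf("<rank_matrix> %d messages x %d attributes (ties marked *)\n",
              nrow(x$ranks), ncol(x$ranks)))
  disp <- matrix(paste0(x$ranks, ifelse(x$tie, "*", "")),
                 nrow = nrow(x$ranks), dimnames = dimnames(x$ranks))
  print(disp, quote = FALSE)
  invisible(x)
}

#' Per-study rank totals
#'
#' Sums each message's attribute ranks within one study arm and ranks the
#' totals (competition ranking, lower total = better = rank 1). A message
#' that ranks well across all of a study's attributes gets a small total.
#'
#' @param rm A `rank_matrix` from [rank_messages()].
#' @param study Study label to total over; must appear in the attribute
#'   definitions (`"self_report"` or `"lab"` in the default configuration).
#' @return A tibble with columns `message_id`, `study`, `total`,
#'   `total_rank` and `tie`.
#' @export
study_totals <- function(rm, study) {
  stopifnot(inherits(rm, "rank_matrix"))
  if (!study %in% rm$attributes$study) {
    stop_madm(sprintf("Unknown study label '%s'; available: %s", study,
                      paste(unique(rm$attributes$study), collapse = ", ")),
              class = "madmsg_input_error")
  }
  cols <- rm$attributes$name[rm$attributes$study == study]
  totals <- rowSums(rm$ranks[, cols, drop = FALSE])
  r <- rank_competition(totals, direction = "lower")
  tibble::tibble(
    message_id = rm$message_id,
    study = study,
    total = as.integer(totals),
    total_rank = r$rank,
    tie = r$tie
  )
}

#' Rank totals for every study arm
#'
#' @param rm A `rank_matrix`.
#' @return A tibble stacking [study_totals()] for each distinct study label.
#' @export
all_study_totals <- function(rm) {
  stopifnot(inherits(rm, "rank_matrix"))
  dplyr::bind_rows(lapply(unique(rm$attributes$study),
                          function(s) study_totals(rm, s)))
}
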