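#' Competition ("minimum") ranking
#'
#' Ranks a vector of attribute scores the way sports standings are ranked:
#' tied values share the smallest rank of their group and the next distinct
#' value skips ahead by the size of the tie group (the 1, 2, 2, 4 pattern).
#' This is the tie rule required to reproduce published decision-matrix
#' tables in which, e.g., two messages tied on engagement both hold rank 4
#' and the next message holds rank 6.
#'
#' @param x Numeric vector of scores, no missing values.
#' @param direction `"higher"` if larger scores are better (rank 1 goes to
#'   the maximum, the convention for effectiveness attributes) or `"lower"`
#'   if smaller scores are better (rank 1 goes to the minimum, the
#'   convention for rank totals).
#'
#' @return A list with integer `rank` (same length as `x`, minimum 1) and
#'   logical `tie` flagging every element that shares its value with
#'   another element.
#'
#' @details The rank of an element is one plus the number of elements that
#'   strictly beat it. Values are compared exactly; scores intended to tie
#'   must be numerically identical (as they are when read from a published
#'   table).
#'
#' @examples
#' rank_competition(c(5.94, 5.77, 5.77, 5.74))
#' rank_competition(c(10, 17, 10, 44), direction = "lower")
#' @export
rank_competition <- function(x, direction = c("higher", "lower")) {
  direction <- match.arg(direction)
  if (!is.numeric(x) || length(x) == 0) {
    stop_madm("`x` must be a non-empty numeric vector.",
              class = "madmsg_input_error")
  }
  if (anyNA(x)) {
    stop_madm("`x` contains missing values; ranks are undefined.",
              class = "madmsg_input_error")
  }
  better <- if (direction == "higher") {
    function(v) sum(x > v)
  } else {
    function(v) sum(x < v)
  }
  rank <- unname(vapply(x, function(v) 1L + as.integer(better(v)), integer(1)))
  tie <- unname(vapply(x, function(v) sum(x == v) > 1L, logical(1)))
  list(rank = rank, tie = tie)
}
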