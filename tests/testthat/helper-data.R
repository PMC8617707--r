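# Small in-code builders shared across test files.

# Long-format item rows for one participant-message-construct record.
item_rows <- function(participant_id, message_id, construct, scores) {
  tibble::tibble(
    participant_id = participant_id,
    message_id = message_id,
    construct = construct,
    item_index = seq_along(scores),
    score = scores
  )
}

# A tiny two-message decision matrix with one attribute per study.
toy_matrix <- function(values = c(1, 2), attr_name = "receptivity") {
  decision_matrix(
    tibble::tibble(message_id = c("M1", "M2"), !!attr_name := values),
    attributes = tibble::tibble(name = attr_name, study = "self_report",
                                direction = "higher")
  )
}

# Recognition trials: n_yes hits among n_total target trials for one
# message, one trial per participant (plus optional correctly rejected
# foils).
toy_trials <- function(message_id, n_total, n_yes, n_foils = 0) {
  targets <- tibble::tibble(
    participant_id = sprintf("P%03d", seq_len(n_total)),
    fragment_id = paste0(message_id, "_t1"),
    is_target = TRUE,
    source_message_id = message_id,
    response_yes = seq_len(n_total) <= n_yes
  )
  if (n_foils == 0) return(targets)
  foils <- tibble::tibble(
    participant_id = sprintf("P%03d", seq_len(n_foils)),
    fragment_id = sprintf("foil_%02d", seq_len(n_foils)),
    is_target = FALSE,
    source_message_id = NA_character_,
    response_yes = FALSE
  )
  dplyr::bind_rows(targets, foils)
}

# Independent competition-ranking oracle: base R's min-tie rank.
oracle_competition_rank <- function(x, direction = "higher") {
  if (direction == "higher") rank(-x, ties.method = "min")
  else rank(x, ties.method = "min")
}

# Published per-attribute competition ranks of the bundled decision
# matrix (self-report side as printed; lab side consistent with the
# printed lab rank sums).
fixture_expected_ranks <- function() {
  tibble::tribble(
    ~message_id, ~receptivity, ~engagement, ~positive_attitude,
    ~negative_emotion, ~hr_deceleration, ~recognition_accuracy,
    ~visual_attention,
    "H1",  1,  4,  3,  2,  4,  2, 12,
    "H2",  6,  1,  7,  3,  3, 10,  1,
    "HS1", 2,  6,  4,  3,  6,  9, 10,
    "HS2", 4,  3,  2,  1,  8,  1,  6,
    "HF1", 7,  6,  5,  6,  7,  7,  8,
    "HF2", 3,  4,  1,  5,  5,  4,  3,
    "A1",  5,  2,  6,  8, 10,  6,  4,
    "A2",  8, 10,  9,  6,  9,  3,  9,
    "AS1", 11, 11,  7, 10, 11, 12,  5,
    "AS2", 12,  8, 12, 12,  2, 11,  7,
    "AF1", 10, 12, 11,  9,  1,  4,  2,
    "AF2", 9,  9, 10, 11, 12,  8, 11
  )
}
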