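#' Build a seeded experiment design
#'
#' Lays out the question schedule of the scenario-reading experiment: each
#' subject reads a fixed number of insider-threat scenarios and everyday-
#' conflict scenarios in a random order and answers yes/no to each. Answers
#' are drawn with a configurable per-scenario-type yes-probability; the
#' defaults reproduce the empirical answer rates of the original study
#' (96/242 yes among answered insider questions, 150/248 among conflict
#' questions). A small per-question dropout probability emulates questions
#' lost to response-time limits (default 2%, i.e. 10 of 500 in expectation).
#'
#' @param n_subjects number of subjects (default 25).
#' @param n_insider insider-threat questions per subject (default 10).
#' @param n_conflict everyday-conflict questions per subject (default 10).
#' @param yes_prob_by_type named vector with elements `insider`, `conflict`:
#'   probability of an affirmative answer for each scenario type.
#' @param dropout_prob probability that a question goes unanswered and is
#'   excluded from analysis.
#' @param seed master seed; the design is a pure function of the arguments.
#' @return a tibble with one row per question trial: `subject`, `question`,
#'   `scenario_type` ("insider"/"conflict"), `scenario_index`, `order`
#'   (presentation position), `answer` ("yes"/"no"), `answered` (logical).
#' @export
make_design <- function(n_subjects = 25, n_insider = 10, n_conflict = 10,
                        yes_prob_by_type = c(insider = 96 / 242,
                                             conflict = 150 / 248),
                        dropout_prob = 10 / 500, seed = 1L) {
  stop_if_not_scalar_int(n_subjects, "n_subjects", min = 0)
  stop_if_not_scalar_int(n_insider, "n_insider", min = 0)
  stop_if_not_scalar_int(n_conflict, "n_conflict", min = 0)
  if (!all(c("insider", "conflict") %in% names(yes_prob_by_type)))
    stop("`yes_prob_by_type` needs elements 'insider' and 'conflict'")
  if (any(yes_prob_by_type < 0 | yes_prob_by_type > 1))
    stop("yes-probabilities must lie in [0, 1]")
  if (dropout_prob < 0 || dropout_prob > 1)
    stop("`dropout_prob` must lie in [0, 1]")

  n_q <- n_insider + n_conflict
  rows <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    sub_seed <- derive_seed(seed, s)
    rows[[s]] <- with_seed(sub_seed, {
      type <- c(rep("insider", n_insider), rep("conflict", n_conflict))
      idx <- c(seq_len(n_insider), seq_len(n_conflict))
      p <- yes_prob_by_type[type]
      ans <- ifelse(runif(n_q) < p, "yes", "no")
      answered <- runif(n_q) >= dropout_prob
      ord <- sample.int(n_q)
      tibble::tibble(
        subject = sprintf("S%02d", s),
        question = sprintf("S%02d_Q%02d", s, seq_len(n_q)),
        scenario_type = type,
        scenario_index = idx,
        order = ord,
        answer = unname(ans),
        answered = answered)
    })
  }
  dplyr::bind_rows(rows)
}
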