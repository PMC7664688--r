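# Programmatic fixtures shared across test files.

# Selection benchmark: 5 informative columns (1.5 SD class shift) among 50
# iid noise columns.
make_bench <- function(n = 300, seed = 1, shift = 1.5) {
  set.seed(seed)
  y <- factor(rep(c("a", "b"), length.out = n))
  X <- matrix(rnorm(n * 55), n, 55)
  X[y == "b", 1:5] <- X[y == "b", 1:5] + shift
  colnames(X) <- c(paste0("info", 1:5), paste0("noise", 1:50))
  list(X = X, y = y)
}

# Hand-built feature table for one subject (iid features, optional class
# mean shift on every column) — exercises the evaluation machinery without
# the signal chain.
make_subject_table <- function(subject = "S01", n_ins = 10, n_con = 0,
                               epochs = 5, p = 12, effect = 0, seed = 1,
                               yes_prob = 0.4) {
  set.seed(seed)
  rows <- vector("list", n_ins + n_con)
  for (qi in seq_len(n_ins + n_con)) {
    type <- if (qi <= n_ins) "insider" else "conflict"
    ans <- sample(c("yes", "no"), 1, prob = c(yes_prob, 1 - yes_prob))
    mu <- if (type == "insider" && ans == "yes") effect else 0
    X <- matrix(rnorm(epochs * p, mu), epochs, p)
    colnames(X) <- paste0(rep(c("FP1", "FPz", "FP2"), length.out = p),
                          ".f", seq_len(p))
    rows[[qi]] <- cbind(
      tibble::tibble(subject = subject,
                     question = sprintf("%s_Q%02d", subject, qi),
                     scenario_type = type, answer = ans,
                     start = 0:(epochs - 1), duration = 2),
      tibble::as_tibble(X))
  }
  tibble::as_tibble(do.call(rbind, rows))
}

# Full-chain feature tables at reduced scale: design -> synthesize ->
# artifacts -> preprocess -> epoch -> extract (restricted to `channels` to
# keep the runtime proportionate).
sim_feature_tables <- function(n_subjects, n_insider, n_conflict, duration,
                               intent_effect = 0, scenario_effect = 0,
                               seed = 1,
                               channels = c("FP1", "FPz", "FP2")) {
  design <- make_design(n_subjects, n_insider, n_conflict,
                        dropout_prob = 0, seed = seed)
  effects <- effect_spec(intent_effect, scenario_effect,
                         artifacts = artifact_config(line_amp = 5,
                                                     drift_amp = 10,
                                                     blink_rate = 0.05))
  subjects <- unique(design$subject)
  tables <- list()
  for (si in seq_along(subjects)) {
    base <- subject_baseline(effects, derive_seed(seed, si, 0))
    sub_design <- design[design$subject == subjects[si], ]
    epochs <- list()
    for (qi in seq_len(nrow(sub_design))) {
      rec <- synthesize_question_recording(sub_design[qi, ], effects, base,
                                           seed = derive_seed(seed, si, qi),
                                           duration = duration)
      rec <- inject_artifacts(rec, effects$artifacts,
                              seed = derive_seed(seed, si, qi, 7L))
      clean <- preprocess_recording(rec)
      epochs <- c(epochs, epoch_question(clean))
    }
    tables[[subjects[si]]] <- extract_feature_table(epochs, channels)
  }
  tables
}

# One clean 30 s synthetic question, memoized per session for reuse
local_clean_recording <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      trial <- list(subject = "S01", question = "S01_Q01",
                    scenario_type = "insider", answer = "no")
      raw <- synthesize_question_recording(trial, effect_spec(), seed = 42)
      cache <<- preprocess_recording(raw)
    }
    cache
  }
})
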