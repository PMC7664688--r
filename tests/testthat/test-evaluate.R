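test_that("leave-one-question-out splits are exhaustive and leak-free", {
  tbl <- make_subject_table(n_ins = 10, n_con = 10, epochs = 3, seed = 2)
  sp_int <- make_loqo_splits(tbl, "intent")
  expect_length(sp_int, 10)
  for (s in sp_int) {
    expect_length(s$train_questions, 9)
    expect_false(s$question %in% s$train_questions)
    expect_length(intersect(s$train_idx, s$test_idx), 0)
    # intent universe: insider questions only
    expect_true(all(tbl$scenario_type[c(s$train_idx, s$test_idx)] ==
                      "insider"))
  }
  sp_sc <- make_loqo_splits(tbl, "scenario_type")
  expect_length(sp_sc, 20)
  expect_true(all(vapply(sp_sc, function(s)
    length(s$train_questions), 0L) == 19))
  held <- vapply(sp_sc, function(s) s$question, "")
  expect_setequal(held, unique(tbl$question))
  expect_length(unique(held), 20)
})

test_that("single-class training sides are skipped with a warning", {
  tbl <- make_subject_table(n_ins = 5, epochs = 3, seed = 3, yes_prob = 0)
  tbl$answer[tbl$question == "S01_Q01"] <- "yes"
  expect_warning(sp <- make_loqo_splits(tbl, "intent"), "single-class")
  # only the fold holding out the lone "yes" question loses a class
  expect_equal(sum(vapply(sp, function(s) s$skipped, TRUE)), 1)
  expect_true(sp[[1]]$skipped)
})

test_that("question vote matches the score rule, tie to the negative class", {
  # kNN with k = 1 trained on the test points echoes the assigned epoch
  # votes, so vote patterns can be enumerated exhaustively for 1..29 epochs
  for (n in 1:29) {
    for (k_pos in c(0, 1, floor(n / 2), ceiling(n / 2), n - 1, n)) {
      if (k_pos < 0 || k_pos > n) next
      votes <- c(rep("yes", k_pos), rep("no", n - k_pos))
      X <- matrix(seq_len(n), ncol = 1)
      model <- eegintent:::fit_one_classifier(
        "knn", X, factor(votes, levels = c("no", "yes")),
        list(k = 1), seed = 1)
      pq <- predict_question(model, X)
      expect_equal(pq$score, k_pos / n)
      expect_equal(pq$label, if (k_pos / n > 0.5) "yes" else "no")
    }
  }
  expect_error(predict_question(structure(list(classes = c("no", "yes")),
                                          class = "eeg_classifier"),
                                matrix(nrow = 0, ncol = 1)),
               "no epochs")
})

test_that("classifier tuning is grouped, deterministic, and sane", {
  # linearly separable toy: some SVM grid point fits it perfectly
  set.seed(12)
  X <- rbind(matrix(rnorm(100, -3), 50, 2), matrix(rnorm(100, 3), 50, 2))
  y <- factor(rep(c("no", "yes"), each = 50), levels = c("no", "yes"))
  groups <- rep(sprintf("Q%02d", 1:10), each = 10)
  m <- train_classifier(classifier_spec("svm_rbf"), X, y, groups, seed = 5)
  expect_equal(mean(predict(m, X) == y), 1)
  m2 <- train_classifier(classifier_spec("svm_rbf"), X, y, groups, seed = 5)
  expect_identical(m$tuning$chosen, m2$tuning$chosen)

  # shuffled labels: chosen-model inner accuracy consistent with chance
  accs <- numeric(20)
  for (s in 1:20) {
    set.seed(s)
    ysh <- sample(y)
    mk <- train_classifier(classifier_spec("knn"), X, ysh, groups,
                           seed = s)
    accs[s] <- max(mk$tuning$scores)
  }
  # selecting the max of 5 grid points biases upward; allow that margin
  expect_lt(mean(accs), 0.5 + 2 * sqrt(0.25 / 100) + 0.1)
  expect_gt(mean(accs), 0.5 - 2 * sqrt(0.25 / 100))
  expect_error(classifier_spec("knn", grid = data.frame()), "non-empty")
})

test_that("all four classifier families separate an easy problem", {
  tbl <- make_subject_table(n_ins = 8, epochs = 5, effect = 2.5, seed = 6)
  for (fam in c("knn", "svm_rbf", "gnb", "mlp")) {
    r <- run_subject_cv(tbl, "intent", "none", classifier_spec(fam),
                        seed = 2)
    expect_gte(r$accuracy, 0.75)
  }
})

test_that("zero-effect accuracy sits at the exchangeability chance level", {
  # iid feature tables, gnb: accuracy must match p*q + (1-p)(1-q) within
  # the 95% binomial band, and must not exceed the majority-rate band
  preds <- list()
  for (s in 1:20) {
    tbl <- make_subject_table(n_ins = 10, epochs = 5, effect = 0, seed = s)
    r <- run_subject_cv(tbl, "intent", "none", classifier_spec("gnb"),
                        seed = 100 + s)
    preds[[s]] <- r$per_question
  }
  pq <- dplyr::bind_rows(preds)
  n <- nrow(pq)
  acc <- mean(pq$predicted == pq$truth)
  p <- mean(pq$truth == "yes")
  q <- mean(pq$predicted == "yes")
  e_acc <- p * q + (1 - p) * (1 - q)
  half <- 1.96 * sqrt(e_acc * (1 - e_acc) / n)
  expect_gte(acc, e_acc - half)
  maj <- max(p, 1 - p)
  expect_lte(acc, maj + 1.96 * sqrt(maj * (1 - maj) / n))
})

test_that("ROC points and AUC behave at the extremes and at chance", {
  roc <- roc_points(c(0.9, 0.8, 0.7, 0.3, 0.2),
                    c("yes", "yes", "yes", "no", "no"), "yes")
  expect_equal(roc$auc, 1)
  rev <- roc_points(c(0.1, 0.2, 0.3, 0.8, 0.9),
                    c("yes", "yes", "yes", "no", "no"), "yes")
  expect_equal(rev$auc, 0)
  expect_error(roc_points(c(0.1, 0.9), c("yes", "yes"), "yes"),
               "both classes")
  set.seed(9)
  aucs <- replicate(50, {
    sc <- runif(200)
    lab <- sample(c("yes", "no"), 200, replace = TRUE)
    roc_points(sc, lab, "yes")$auc
  })
  expect_equal(mean(aucs), 0.5, tolerance = 0.05)
})

test_that("aggregation averages subjects and channel subsets validate", {
  tblA <- make_subject_table("S01", n_ins = 6, epochs = 4, effect = 2.5,
                             seed = 7)
  tblB <- make_subject_table("S02", n_ins = 6, epochs = 4, effect = 2.5,
                             seed = 8)
  rA <- run_subject_cv(tblA, "intent", "none", classifier_spec("gnb"),
                       seed = 1)
  rB <- run_subject_cv(tblB, "intent", "none", classifier_spec("gnb"),
                       seed = 1)
  sm <- aggregate_summary(list(rA, rB))
  expect_equal(sm$mean_accuracy, 50 * (rA$accuracy + rB$accuracy))
  expect_true(all(sm$mean_accuracy >= 0 & sm$mean_accuracy <= 100))

  expect_error(run_subject_cv(tblA, "intent", channels = c("FP1", "XX")),
               "unknown channel")
  # full channel set == unrestricted run at the same seed
  full <- run_subject_cv(tblA, "intent", "none", classifier_spec("gnb"),
                         seed = 3, channels = c("FP1", "FPz", "FP2"))
  unres <- run_subject_cv(tblA, "intent", "none", classifier_spec("gnb"),
                          seed = 3)
  expect_identical(full$per_question, unres$per_question)
})
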