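# task -> (label column, positive class, question universe filter)
task_def <- function(task) {
  switch(task,
    intent = list(y_col = "answer", positive = "yes", negative = "no",
                  filter_type = "insider"),
    scenario_type = list(y_col = "scenario_type", positive = "insider",
                         negative = "conflict", filter_type = NULL),
    stop(sprintf("unknown task '%s' (use 'intent' or 'scenario_type')",
                 task)))
}

#' Leave-one-question-out splits for one subject
#'
#' One split per question of the task's question universe: for the intent
#' task the universe is the subject's insider questions (train on the other
#' nine by default); for the scenario-type task it is all questions (train
#' on 19). Folds are exhaustive and pairwise disjoint in their held-out
#' questions. Folds whose training side contains a single class are skipped
#' with a warning rather than silently dropped.
#'
#' @param subject_table feature table of one subject.
#' @param task `"intent"` or `"scenario_type"`.
#' @return list of splits, each with `question`, `train_questions`,
#'   `train_idx`, `test_idx`, `y_col`, `positive`, `negative`, `skipped`.
#' @export
make_loqo_splits <- function(subject_table, task) {
  td <- task_def(task)
  tbl <- subject_table
  if (!is.null(td$filter_type))
    tbl_rows <- which(subject_table$scenario_type == td$filter_type)
  else tbl_rows <- seq_len(nrow(subject_table))
  qs <- unique(subject_table$question[tbl_rows])
  if (length(qs) < 2) stop("need at least 2 questions for cross-validation")
  splits <- lapply(qs, function(q) {
    test_idx <- tbl_rows[subject_table$question[tbl_rows] == q]
    train_idx <- tbl_rows[subject_table$question[tbl_rows] != q]
    y_train <- subject_table[[td$y_col]][train_idx]
    skipped <- length(unique(y_train)) < 2
    if (skipped)
      warning(sprintf("fold %s skipped: single-class training side", q),
              call. = FALSE)
    list(question = q, train_questions = setdiff(qs, q),
         train_idx = train_idx, test_idx = test_idx,
         y_col = td$y_col, positive = td$positive, negative = td$negative,
         skipped = skipped)
  })
  splits
}

#' Question-level decision by epoch majority vote
#'
#' Predicts every epoch of one question and aggregates: the score is the
#' fraction of epochs predicted positive and the label is positive when the
#' score strictly exceeds 0.5 — a tie goes to the negative class (a full
#' 29-epoch question cannot tie; truncated ones can).
#'
#' @param model an `eeg_classifier` (its second class is the positive one).
#' @param epoch_features matrix/table of the question's epoch rows (>= 1).
#' @return list with `label` and `score`.
#' @export
predict_question <- function(model, epoch_features) {
  if (nrow(epoch_features) == 0) stop("question has no epochs")
  pred <- predict(model, epoch_features)
  positive <- model$classes[2]
  score <- mean(as.character(pred) == positive)
  list(label = if (score > 0.5) positive else model$classes[1],
       score = score)
}

#' Subject-wise leave-one-question-out evaluation
#'
#' For every non-skipped fold: fit the z-scaler on training rows, run the
#' feature selector on training rows, tune and fit the classifier with
#' question-grouped internal validation, then majority-vote the held-out
#' question. Nothing fitted ever sees a held-out row; the function asserts
#' after each fold that the scaler's recorded question set excludes the
#' held-out question. Fully deterministic given `seed`.
#'
#' @param subject_table feature table of one subject.
#' @param task `"intent"` or `"scenario_type"`.
#' @param selector `"boruta"`, `"varselrf"` or `"none"`.
#' @param spec a [classifier_spec()].
#' @param seed integer seed.
#' @param sel_config a [selection_config()].
#' @param channels optional channel-name subset restricting the feature
#'   space (unknown names raise an error listing the valid ones).
#' @return object of class `subject_result`: per-question tibble
#'   (`question`, `truth`, `predicted`, `score`, `n_epochs`, `n_selected`),
#'   `accuracy`, counts of skipped folds, and identifiers.
#' @export
run_subject_cv <- function(subject_table, task, selector = "none",
                           spec = classifier_spec("gnb"), seed = 1L,
                           sel_config = selection_config(),
                           channels = NULL) {
  run_subject_cv_multi(subject_table, task, selector, list(spec), seed,
                       sel_config, channels)[[1]]
}

# Shared-fold engine: per fold, the scaler and the feature selection are
# computed once and reused by every classifier spec (selection depends only
# on the training rows and the selector, never on the classifier).
run_subject_cv_multi <- function(subject_table, task, selector, specs,
                                 seed = 1L,
                                 sel_config = selection_config(),
                                 channels = NULL) {
  td <- task_def(task)
  feat_cols <- feature_columns(subject_table)
  if (!is.null(channels)) {
    valid <- unique(sub("\\..*$", "", feat_cols))
    bad <- setdiff(channels, valid)
    if (length(bad) > 0)
      stop(sprintf("unknown channel(s) %s; valid channels: %s",
                   paste(bad, collapse = ", "),
                   paste(valid, collapse = ", ")))
    feat_cols <- feat_cols[sub("\\..*$", "", feat_cols) %in% channels]
  }
  splits <- make_loqo_splits(subject_table, task)
  rows <- lapply(specs, function(s) list())
  n_skipped <- 0L
  for (fi in seq_along(splits)) {
    sp <- splits[[fi]]
    if (sp$skipped) { n_skipped <- n_skipped + 1L; next }
    train <- subject_table[sp$train_idx, ]
    test <- subject_table[sp$test_idx, ]
    stopifnot(length(intersect(train$question, test$question)) == 0)

    scaler <- fit_scaler(train[c(.meta_cols, feat_cols)])
    stopifnot(!(sp$question %in% scaler$questions_seen))
    train_z <- apply_scaler(scaler, train[c(.meta_cols, feat_cols)])
    test_z <- apply_scaler(scaler, test[c(.meta_cols, feat_cols)])

    y_train <- factor(train[[sp$y_col]],
                      levels = c(sp$negative, sp$positive))
    fold_seed <- derive_seed(seed, fi)
    sel <- run_selector(selector, as.matrix(train_z[feat_cols]), y_train,
                        sel_config, fold_seed, groups = train$question)
    if (length(sel) == 0) sel <- feat_cols  # degenerate fallback, logged
    Xtr <- as.matrix(train_z[sel])
    Xte <- as.matrix(test_z[sel])
    for (si in seq_along(specs)) {
      model <- train_classifier(specs[[si]], Xtr, y_train,
                                groups = train$question,
                                seed = derive_seed(fold_seed, si))
      pq <- predict_question(model, Xte)
      rows[[si]][[length(rows[[si]]) + 1]] <- tibble::tibble(
        question = sp$question,
        truth = test[[sp$y_col]][1],
        predicted = pq$label,
        score = pq$score,
        n_epochs = nrow(test),
        n_selected = length(sel))
    }
  }
  lapply(seq_along(specs), function(si) {
    if (length(rows[[si]]) == 0)
      stop(sprintf("subject %s unevaluable: all folds skipped",
                   subject_table$subject[1]))
    per_q <- dplyr::bind_rows(rows[[si]])
    structure(list(subject = subject_table$subject[1], task = task,
                   selector = selector, family = specs[[si]]$family,
                   per_question = per_q,
                   accuracy = mean(per_q$predicted == per_q$truth),
                   n_skipped = n_skipped, seed = seed),
              class = "subject_result")
  })
}

#' @export
print.subject_result <- function(x, ...) {
  cat(sprintf("<subject_result> %s %s %s/%s: accuracy %.1f%% (%d questions, %d skipped)\n",
              x$subject, x$task, x$selector, x$family, 100 * x$accuracy,
              nrow(x$per_question), x$n_skipped))
  invisible(x)
}

#' Mean accuracy per selector x classifier cell
#'
#' @param results list of `subject_result`s (any mix of subjects, selectors
#'   and classifier families).
#' @return tibble with `selector`, `classifier`, `mean_accuracy` (percent),
#'   `n_subjects`; per-subject accuracies are kept in the `per_subject`
#'   attribute for dispersion reporting.
#' @export
aggregate_summary <- function(results) {
  if (length(results) == 0) stop("no subject results to aggregate")
  per <- dplyr::bind_rows(lapply(results, function(r)
    tibble::tibble(subject = r$subject, task = r$task,
                   selector = r$selector, classifier = r$family,
                   accuracy = 100 * r$accuracy)))
  out <- dplyr::summarise(
    dplyr::group_by(per, .data$task, .data$selector, .data$classifier),
    mean_accuracy = mean(.data$accuracy),
    n_subjects = dplyr::n(), .groups = "drop")
  attr(out, "per_subject") <- per
  out
}

#' ROC curve and AUC from question scores
#'
#' Thresholds swept over the distinct observed scores (the positive-epoch
#' fractions); trapezoidal area under the curve.
#'
#' @param scores numeric scores in `[0, 1]`.
#' @param labels true labels. @param positive the positive class.
#' @return list with `points` (tibble `threshold`, `fpr`, `tpr`) and `auc`.
#' @export
roc_points <- function(scores, labels, positive) {
  labels <- as.character(labels)
  pos <- labels == positive
  if (all(pos) || !any(pos))
    stop("ROC needs both classes present")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) mean(scores[pos] >= t), 0.0)
  fpr <- vapply(thr, function(t) mean(scores[!pos] >= t), 0.0)
  ord <- order(fpr, tpr)
  auc <- sum(diff(fpr[ord]) * (head(tpr[ord], -1) + tail(tpr[ord], -1)) / 2)
  list(points = tibble::tibble(threshold = thr, fpr = fpr, tpr = tpr),
       auc = auc)
}

#' Run the full selector x classifier evaluation over subjects
#'
#' Applies [run_subject_cv()] to every subject for every requested selector
#' and classifier family and aggregates the cell means — the engine behind
#' the accuracy summary tables and ROC curves.
#'
#' @param tables named list of per-subject feature tables.
#' @param task `"intent"` or `"scenario_type"`.
#' @param selectors character vector of selectors.
#' @param families character vector of classifier families.
#' @param seed master seed.
#' @param sel_config a [selection_config()].
#' @param channels optional channel subset.
#' @param specs optional named list of [classifier_spec()]s overriding the
#'   default grid per family.
#' @return list: `summary` (tibble), `results` (list of `subject_result`),
#'   `predictions` (bound per-question tibble).
#' @export
run_experiment <- function(tables, task, selectors = c("boruta", "varselrf"),
                           families = c("knn", "svm_rbf", "gnb", "mlp"),
                           seed = 1L, sel_config = selection_config(),
                           channels = NULL, specs = NULL) {
  results <- list()
  spec_list <- lapply(families, function(fam)
    specs[[fam]] %||% classifier_spec(fam))
  for (si in seq_along(tables)) {
    for (sel in selectors) {
      res <- run_subject_cv_multi(tables[[si]], task, selector = sel,
                                  specs = spec_list,
                                  seed = derive_seed(seed, si,
                                                     match(sel, selectors)),
                                  sel_config = sel_config,
                                  channels = channels)
      results <- c(results, res)
    }
  }
  preds <- dplyr::bind_rows(lapply(results, function(r)
    dplyr::mutate(r$per_question, subject = r$subject, task = r$task,
                  selector = r$selector, classifier = r$family)))
  list(summary = aggregate_summary(results), results = results,
       predictions = preds)
}

#' Evaluation restricted to a named channel subset
#'
#' Identical pipeline on the subset's `n x 65` feature columns — e.g.
#' `c("FP1", "FPz", "FP2")` for the frontopolar row or
#' `c("F3", "Fz", "F4")` for the mid-frontal row. With the full montage the
#' result is identical to the unrestricted run at the same seed.
#'
#' @inheritParams run_experiment
#' @param channels channel names to keep (validated).
#' @return as [run_experiment()].
#' @export
channel_subset_run <- function(tables, channels, task,
                               selectors = c("boruta", "varselrf"),
                               families = c("knn", "svm_rbf", "gnb", "mlp"),
                               seed = 1L, sel_config = selection_config(),
                               specs = NULL) {
  run_experiment(tables, task, selectors, families, seed, sel_config,
                 channels = channels, specs = specs)
}
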