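#' Classifier specification with tuning grid
#'
#' Families: `"knn"` (k-nearest neighbors), `"svm_rbf"` (soft-margin SVM
#' with radial kernel trained by SMO), `"gnb"` (Gaussian naive Bayes, no
#' tuning) and `"mlp"` (one-hidden-layer perceptron). Default grids:
#' kNN `k in {1,3,5,7,9}`; SVM `C in 10^(-1..3)`, `gamma in 10^(-4..0)`;
#' MLP hidden width in `{5,10,20}`. Tuning is performed by the evaluation
#' layer on training questions only.
#'
#' @param family one of `"knn"`, `"svm_rbf"`, `"gnb"`, `"mlp"`.
#' @param grid data frame of hyperparameter combinations; `NULL` uses the
#'   family default.
#' @return list of class `classifier_spec`.
#' @export
classifier_spec <- function(family = c("knn", "svm_rbf", "gnb", "mlp"),
                            grid = NULL) {
  family <- match.arg(family)
  if (is.null(grid)) {
    grid <- switch(family,
      knn = data.frame(k = c(1, 3, 5, 7, 9)),
      svm_rbf = expand.grid(C = 10^(-1:3), gamma = 10^(-4:0)),
      gnb = data.frame(dummy = 0),
      mlp = data.frame(hidden = c(5, 10, 20)))
  }
  if (nrow(grid) == 0) stop("tuning grid must be non-empty")
  structure(list(family = family, grid = grid), class = "classifier_spec")
}

# ---- family implementations ------------------------------------------------

fit_one_classifier <- function(family, X, y, params, seed) {
  X <- as.matrix(X)
  if (!is.factor(y)) y <- factor(y)  # keep caller-supplied level order
  model <- switch(family,
    knn = list(X = X, y = y, k = max(1L, min(params$k, nrow(X) - 1L))),
    gnb = fit_gnb(X, y),
    svm_rbf = fit_svm_rbf(X, y, C = params$C, gamma = params$gamma,
                          seed = seed),
    mlp = fit_mlp(X, y, hidden = params$hidden, seed = seed),
    stop(sprintf("unknown classifier family '%s'", family)))
  structure(list(family = family, model = model, params = params,
                 classes = levels(y), seed = seed),
            class = "eeg_classifier")
}

#' @export
predict.eeg_classifier <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  m <- object$model
  lab <- switch(object$family,
    knn = as.character(FNN::knn(m$X, X, m$y, k = m$k)),
    gnb = predict_gnb(m, X),
    svm_rbf = predict_svm_rbf(m, X),
    mlp = predict_mlp(m, X))
  factor(lab, levels = object$classes)
}

# Gaussian naive Bayes with a variance floor
fit_gnb <- function(X, y, var_floor = 1e-9) {
  classes <- levels(y)
  stats_by <- lapply(classes, function(cl) {
    Xi <- X[y == cl, , drop = FALSE]
    list(mu = colMeans(Xi),
         v = pmax(apply(Xi, 2, var), var_floor),
         logprior = log(nrow(Xi) / nrow(X)))
  })
  names(stats_by) <- classes
  list(classes = classes, stats = stats_by)
}

predict_gnb <- function(m, X) {
  ll <- vapply(m$classes, function(cl) {
    s <- m$stats[[cl]]
    apply(X, 1, function(row)
      s$logprior - 0.5 * sum(log(2 * pi * s$v) + (row - s$mu)^2 / s$v))
  }, numeric(nrow(X)))
  if (nrow(X) == 1) ll <- matrix(ll, nrow = 1)
  m$classes[max.col(ll, ties.method = "first")]
}

# RBF SVM via the compiled SMO routine; first factor level maps to -1
fit_svm_rbf <- function(X, y, C, gamma, seed, tol = 1e-3) {
  if (nlevels(y) != 2) stop("svm_rbf is a binary classifier")
  yv <- ifelse(as.integer(y) == 2, 1, -1)
  sm <- svm_smo_cpp(X, yv, C, gamma, tol, max_passes = 3L,
                    max_sweeps = 150L, seed = as.integer(seed))
  list(X = X, yv = yv, alpha = sm$alpha, b = sm$b, gamma = gamma,
       classes = levels(y))
}

predict_svm_rbf <- function(m, X) {
  d <- svm_decision_cpp(m$X, m$yv, m$alpha, m$b, m$gamma, X)
  ifelse(d > 0, m$classes[2], m$classes[1])
}

# One-hidden-layer MLP (tanh hidden, logistic output), full-batch gradient
# descent with momentum, fixed epoch budget, seeded initialization.
fit_mlp <- function(X, y, hidden, seed, epochs = 200, lr = 0.05,
                    momentum = 0.9) {
  if (nlevels(y) != 2) stop("mlp is a binary classifier")
  n <- nrow(X); p <- ncol(X)
  t <- as.numeric(as.integer(y) == 2)
  with_seed(seed, {
    W1 <- matrix(rnorm(p * hidden, 0, 1 / sqrt(p)), p, hidden)
    b1 <- rep(0, hidden)
    W2 <- matrix(rnorm(hidden, 0, 1 / sqrt(hidden)), hidden, 1)
    b2 <- 0
    vW1 <- matrix(0, p, hidden); vb1 <- rep(0, hidden)
    vW2 <- matrix(0, hidden, 1); vb2 <- 0
    for (e in seq_len(epochs)) {
      H <- tanh(sweep(X %*% W1, 2, b1, "+"))
      z <- drop(H %*% W2) + b2
      prob <- 1 / (1 + exp(-z))
      dz <- (prob - t) / n
      gW2 <- crossprod(H, dz); gb2 <- sum(dz)
      dH <- (dz %*% t(W2)) * (1 - H^2)
      gW1 <- crossprod(X, dH); gb1 <- colSums(dH)
      vW2 <- momentum * vW2 - lr * gW2; W2 <- W2 + vW2
      vb2 <- momentum * vb2 - lr * gb2; b2 <- b2 + vb2
      vW1 <- momentum * vW1 - lr * gW1; W1 <- W1 + vW1
      vb1 <- momentum * vb1 - lr * gb1; b1 <- b1 + vb1
    }
    list(W1 = W1, b1 = b1, W2 = W2, b2 = b2, classes = levels(y))
  })
}

predict_mlp <- function(m, X) {
  H <- tanh(sweep(X %*% m$W1, 2, m$b1, "+"))
  z <- drop(H %*% m$W2) + m$b2
  ifelse(z > 0, m$classes[2], m$classes[1])
}

# ---- tuning ----------------------------------------------------------------

#' Tune and fit a classifier on training rows
#'
#' Grid search over the spec's hyperparameter grid using question-grouped
#' internal cross-validation (default 3 folds over the training questions,
#' so epochs of one question never straddle tuning folds). The grid point
#' with the best inner epoch-level accuracy is refitted on all training
#' rows; ties break to the earlier grid row, so the choice is deterministic
#' given the seed.
#'
#' @param spec a [classifier_spec()].
#' @param X_train numeric matrix of (already normalized) training features.
#' @param y_train training labels.
#' @param groups question IDs of the training rows (grouping unit).
#' @param seed integer seed.
#' @param inner_folds number of question-grouped tuning folds.
#' @return an `eeg_classifier` with `tuning` attached (chosen row + scores).
#' @export
train_classifier <- function(spec, X_train, y_train, groups, seed = 1L,
                             inner_folds = 3) {
  stopifnot(inherits(spec, "classifier_spec"))
  X_train <- as.matrix(X_train)
  y_train <- factor(y_train)
  grid <- spec$grid
  scores <- rep(NA_real_, nrow(grid))
  if (nrow(grid) > 1) {
    qs <- unique(groups)
    nf <- min(inner_folds, length(qs))
    fold_of <- with_seed(derive_seed(seed, 11L),
                         sample(rep_len(seq_len(nf), length(qs))))
    names(fold_of) <- qs
    for (g in seq_len(nrow(grid))) {
      acc <- ok <- 0
      for (f in seq_len(nf)) {
        hold <- groups %in% qs[fold_of == f]
        if (all(hold) || !any(hold)) next
        if (nlevels(droplevels(y_train[!hold])) < 2) next
        fit <- fit_one_classifier(spec$family, X_train[!hold, , drop = FALSE],
                                  droplevels(y_train[!hold]),
                                  grid[g, , drop = FALSE],
                                  derive_seed(seed, 20L + g, f))
        pred <- predict(fit, X_train[hold, , drop = FALSE])
        acc <- acc + sum(as.character(pred) == as.character(y_train[hold]))
        ok <- ok + sum(hold)
      }
      scores[g] <- if (ok > 0) acc / ok else -Inf
    }
    best <- which.max(scores)  # first max: deterministic tie-break
  } else best <- 1L
  fit <- fit_one_classifier(spec$family, X_train, y_train,
                            grid[best, , drop = FALSE],
                            derive_seed(seed, 99L))
  fit$tuning <- list(chosen = grid[best, , drop = FALSE], scores = scores)
  fit
}
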