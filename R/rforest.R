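#' Fit the built-in random forest
#'
#' Compact CART-ensemble classifier (gini splits, bootstrap resampling,
#' out-of-bag error, impurity and optional permutation importance) used by
#' the feature-selection wrappers and available as an independent check.
#' Deterministic given `seed`.
#'
#' @param X numeric matrix or data frame (rows = samples).
#' @param y factor (or coercible) class labels, >= 2 classes.
#' @param ntree number of trees.
#' @param mtry features tried per split; default `floor(sqrt(p))`.
#' @param min_node minimum samples per leaf.
#' @param max_depth depth cap.
#' @param permutation_importance also compute OOB permutation importance?
#' @param groups optional grouping vector (one value per row): the bootstrap
#'   resamples whole groups and out-of-bag status is per group, so OOB error
#'   and importance measure across-group generalization (used with question
#'   IDs so epochs of one question never straddle the bag boundary).
#' @param seed integer seed.
#' @return list of class `eeg_rf`: `trees`, `classes`, `oob_error`,
#'   `importance` (gini), `importance_perm` (or NULL), `mtry`, `seed`.
#' @export
rf_fit <- function(X, y, ntree = 100, mtry = NULL, min_node = 1,
                   max_depth = 30, permutation_importance = FALSE,
                   groups = NULL, seed = 1L) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- factor(y)
  if (nlevels(y) < 2) stop("`y` must contain at least 2 classes")
  if (nrow(X) != length(y)) stop("X rows must match length(y)")
  if (nrow(X) < 2 * nlevels(y)) stop("too few rows to grow a forest")
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(X))))
  grp <- if (is.null(groups)) seq_len(nrow(X)) - 1L
         else as.integer(factor(groups)) - 1L
  if (length(grp) != nrow(X)) stop("`groups` must have one value per row")
  fit <- rf_fit_cpp(X, as.integer(y) - 1L, nlevels(y), as.integer(ntree),
                    as.integer(mtry), as.integer(min_node),
                    as.integer(max_depth), isTRUE(permutation_importance),
                    grp, as.integer(seed))
  imp <- fit$importance_gini
  names(imp) <- colnames(X)
  imp_perm <- imp_perm_z <- NULL
  if (permutation_importance) {
    imp_perm <- fit$importance_perm
    imp_perm_z <- fit$importance_perm_z
    names(imp_perm) <- names(imp_perm_z) <- colnames(X)
  }
  structure(list(trees = fit$trees, classes = levels(y),
                 oob_error = fit$oob_error, importance = imp,
                 importance_perm = imp_perm, importance_perm_z = imp_perm_z,
                 mtry = mtry, seed = seed),
            class = "eeg_rf")
}

#' Predict with the built-in random forest
#'
#' @param object an `eeg_rf`. @param newdata matrix/data frame of rows to
#'   classify.
#' @param type `"class"` for labels, `"vote"` for the vote-fraction matrix.
#' @param ... unused.
#' @return factor of predicted classes, or a rows x classes matrix.
#' @export
predict.eeg_rf <- function(object, newdata, type = c("class", "vote"), ...) {
  type <- match.arg(type)
  X <- as.matrix(newdata)
  storage.mode(X) <- "double"
  votes <- rf_predict_cpp(object$trees, X, length(object$classes))
  if (type == "vote") {
    v <- votes / rowSums(votes)
    colnames(v) <- object$classes
    return(v)
  }
  factor(object$classes[max.col(votes, ties.method = "first")],
         levels = object$classes)
}
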