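#' Configuration for the feature selectors
#'
#' Pinned defaults of the two random-forest-based selectors. The Boruta-style
#' wrapper uses `max_iter` shadow rounds, a two-sided binomial test at level
#' `alpha` with Bonferroni correction across columns, and `ntree_boruta`
#' trees per round. The varSelRF-style backward elimination ranks once by
#' permutation importance on an initial forest of `ntree_initial` trees,
#' then repeatedly drops the worst `drop_frac` of the surviving columns,
#' refitting `ntree_iter`-tree forests and recording out-of-bag (OOB) error;
#' the smallest set within one standard error of the minimum OOB error wins
#' (floor of 2 columns). Tree counts are scaled to desk-size data relative
#' to the original implementations' 5000/2000.
#'
#' @param max_iter,alpha,ntree_boruta Boruta wrapper parameters.
#' @param importance importance measure the Boruta forest ranks by:
#'   `"perm_z"` (z-scored out-of-bag permutation importance, the published
#'   default) or `"gini"` (impurity decrease, the fast option).
#' @param drop_frac,ntree_initial,ntree_iter varSelRF parameters.
#' @return list of class `selection_config`.
#' @export
selection_config <- function(max_iter = 100, alpha = 0.01,
                             ntree_boruta = 100,
                             importance = c("perm_z", "gini"),
                             drop_frac = 0.2, ntree_initial = 500,
                             ntree_iter = 200) {
  if (alpha <= 0 || alpha >= 0.5) stop("`alpha` must lie in (0, 0.5)")
  if (drop_frac <= 0 || drop_frac >= 1)
    stop("`drop_frac` must lie in (0, 1)")
  importance <- match.arg(importance)
  structure(list(max_iter = max_iter, alpha = alpha,
                 ntree_boruta = ntree_boruta, importance = importance,
                 drop_frac = drop_frac, ntree_initial = ntree_initial,
                 ntree_iter = ntree_iter),
            class = "selection_config")
}

#' Boruta-style all-relevant feature selection
#'
#' Iteratively appends a shuffled "shadow" copy of every still-active column,
#' fits the built-in random forest, and counts a hit for each column whose
#' importance beats the best shadow. Columns whose hit counts are binomially
#' improbable under chance (two one-sided tests at `alpha`, Bonferroni-
#' corrected across the original columns) are confirmed or rejected;
#' whatever remains at `max_iter` stays tentative. The selected set passed
#' downstream is confirmed plus tentative (inclusive policy, so small folds
#' never end up empty). Deterministic given `seed`.
#'
#' @param X numeric matrix/data frame of features.
#' @param y two-or-more-class labels.
#' @param config a [selection_config()].
#' @param seed integer seed.
#' @param groups optional grouping vector (question IDs): forests bootstrap
#'   whole groups so importance reflects across-question generalization
#'   rather than within-question memorization.
#' @return object of class `feature_decision`: tibble `decisions`
#'   (`feature`, `status`, `median_importance`, `hits`, `n_iter`), the
#'   `selected` character vector, `iterations` used, `seed`.
#' @export
boruta_select <- function(X, y, config = selection_config(), seed = 1L,
                          groups = NULL) {
  X <- as.matrix(X)
  y <- factor(y)
  if (nlevels(y) < 2) stop("`y` must contain at least 2 classes")
  if (nrow(X) < 2 * nlevels(y)) stop("too few rows for selection")
  p <- ncol(X)
  cols <- colnames(X) %||% paste0("V", seq_len(p))
  colnames(X) <- cols

  status <- rep("tentative", p)
  names(status) <- cols
  hits <- integer(p)
  names(hits) <- cols
  n_iter <- integer(p)
  names(n_iter) <- cols
  imp_hist <- matrix(NA_real_, config$max_iter, p,
                     dimnames = list(NULL, cols))
  thr <- config$alpha / p  # Bonferroni per one-sided test family

  iter <- 0L
  while (iter < config$max_iter && any(status == "tentative")) {
    iter <- iter + 1L
    active <- which(status != "rejected")
    Xa <- X[, active, drop = FALSE]
    # Shadows are fresh permutations of every original column, not just the
    # active ones: the max-shadow reference must keep estimating the largest
    # importance obtainable by chance in this dataset, or late iterations
    # would compare survivors against an ever-weaker bar.
    shadows <- with_seed(derive_seed(seed, iter, 1L), apply(X, 2, sample))
    colnames(shadows) <- paste0("shadow_", seq_len(ncol(shadows)))
    fit <- rf_fit(cbind(Xa, shadows), y, ntree = config$ntree_boruta,
                  permutation_importance = config$importance == "perm_z",
                  groups = groups, seed = derive_seed(seed, iter, 2L))
    imp <- if (config$importance == "perm_z") fit$importance_perm_z
           else fit$importance
    shadow_max <- max(imp[grepl("^shadow_", names(imp))])
    real_imp <- imp[seq_along(active)]
    imp_hist[iter, active] <- real_imp
    hit <- real_imp > shadow_max
    hits[active] <- hits[active] + hit
    n_iter[active] <- n_iter[active] + 1L

    und <- which(status == "tentative")
    for (j in und) {
      nj <- n_iter[j]
      if (nj < 5) next  # need a few rounds before testing
      p_up <- pbinom(hits[j] - 1L, nj, 0.5, lower.tail = FALSE)
      p_dn <- pbinom(hits[j], nj, 0.5, lower.tail = TRUE)
      if (p_up < thr) status[j] <- "confirmed"
      else if (p_dn < thr) status[j] <- "rejected"
    }
  }

  med_imp <- apply(imp_hist[seq_len(iter), , drop = FALSE], 2,
                   median, na.rm = TRUE)
  decisions <- tibble::tibble(feature = cols, status = unname(status),
                              median_importance = unname(med_imp),
                              hits = unname(hits), n_iter = unname(n_iter))
  structure(list(decisions = decisions,
                 selected = cols[status != "rejected"],
                 iterations = iter, seed = seed, config = config),
            class = "feature_decision")
}

#' @export
print.feature_decision <- function(x, ...) {
  tab <- table(x$decisions$status)
  cat(sprintf("<feature_decision> %d iterations; %s\n", x$iterations,
              paste(names(tab), tab, sep = ": ", collapse = ", ")))
  invisible(x)
}

#' varSelRF-style backward feature elimination
#'
#' Ranks columns once by OOB permutation importance on an initial forest,
#' then repeatedly drops the configured worst fraction (never below 2
#' columns), refits and records OOB error at each set size. Returns the
#' smallest set whose OOB error is within one standard error of the minimum
#' (`se = sqrt(err * (1 - err) / n)`). Importance is not recomputed during
#' elimination, matching the published default. Deterministic given `seed`.
#'
#' @inheritParams boruta_select
#' @return character vector of selected column names, with attributes
#'   `history` (tibble of set size vs OOB error) and `seed`.
#' @export
varselrf_select <- function(X, y, config = selection_config(), seed = 1L,
                            groups = NULL) {
  X <- as.matrix(X)
  y <- factor(y)
  if (nlevels(y) < 2) stop("`y` must contain at least 2 classes")
  if (nrow(X) < 2 * nlevels(y)) stop("too few rows for selection")
  cols <- colnames(X) %||% paste0("V", seq_len(ncol(X)))
  colnames(X) <- cols

  init <- rf_fit(X, y, ntree = config$ntree_initial,
                 permutation_importance = TRUE, groups = groups,
                 seed = derive_seed(seed, 1L))
  ranking <- names(sort(init$importance_perm, decreasing = TRUE))

  sets <- list()
  current <- ranking
  repeat {
    sets[[length(sets) + 1]] <- current
    if (length(current) <= 2) break
    n_drop <- max(1L, floor(config$drop_frac * length(current)))
    keep <- max(2L, length(current) - n_drop)
    current <- current[seq_len(keep)]
  }

  err <- nvars <- numeric(length(sets))
  for (k in seq_along(sets)) {
    fit <- rf_fit(X[, sets[[k]], drop = FALSE], y,
                  ntree = config$ntree_iter, groups = groups,
                  seed = derive_seed(seed, 100L + k))
    err[k] <- fit$oob_error
    nvars[k] <- length(sets[[k]])
  }
  kmin <- which.min(err)
  se <- sqrt(err[kmin] * (1 - err[kmin]) / nrow(X))
  ok <- which(err <= err[kmin] + se)
  best <- ok[which.min(nvars[ok])]
  structure(sets[[best]],
            history = tibble::tibble(n_vars = nvars, oob_error = err),
            seed = seed)
}

# dispatch used by the evaluation layer; "none" keeps every column
run_selector <- function(selector, X, y, config, seed, groups = NULL) {
  switch(selector,
         boruta = boruta_select(X, y, config, seed, groups)$selected,
         varselrf = as.character(varselrf_select(X, y, config, seed,
                                                 groups)),
         none = colnames(X),
         stop(sprintf("unknown selector '%s'", selector)))
}
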