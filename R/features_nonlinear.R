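#' Nonlinear dynamical features of one channel epoch
#'
#' Four regularity/complexity measures:
#' * approximate entropy and sample entropy with embedding `m = 2` and
#'   tolerance r set to `r_frac * sd(x)` (default 0.2), Chebyshev distance;
#' * permutation entropy of order 3, delay 1, normalized by `log(3!)` to
#'   `[0, 1]`;
#' * correlation dimension by the Grassberger-Procaccia method: time-delay
#'   embedding with delay set to the first zero crossing of the
#'   autocorrelation (capped at 10 samples), embedding dimensions 2..8,
#'   correlation sums over radii spanning the 10th-50th percentile of
#'   pairwise distances, slope by least squares in log-log coordinates, and
#'   the estimate taken as the median slope over the three largest
#'   dimensions. Embedded point clouds are stride-subsampled to at most
#'   `max_points` so the cost stays quadratic in a bounded count.
#'
#' A constant input returns all four values as 0 with a `degenerate`
#' attribute.
#'
#' @param x numeric vector, length >= 100.
#' @param m embedding dimension for ApEn/SampEn.
#' @param r_frac tolerance as a fraction of `sd(x)`.
#' @param max_points cap on embedded points for the correlation dimension.
#' @return named numeric vector: `approx_entropy`, `sample_entropy`,
#'   `permutation_entropy`, `correlation_dimension`.
#' @export
nonlinear_features <- function(x, m = 2, r_frac = 0.2, max_points = 200) {
  if (length(x) < 100) stop("nonlinear_features needs at least 100 samples")
  s <- sd(x)
  if (s < .Machine$double.eps) {
    out <- c(approx_entropy = 0, sample_entropy = 0,
             permutation_entropy = 0, correlation_dimension = 0)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  r <- r_frac * s
  out <- c(approx_entropy = apen_cpp(x, m, r),
           sample_entropy = sampen_cpp(x, m, r),
           permutation_entropy = permutation_entropy(x, order = 3),
           correlation_dimension = correlation_dimension(
             x, max_points = max_points))
  attr(out, "degenerate") <- FALSE
  out
}

#' Permutation entropy of ordinal patterns
#'
#' Shannon entropy of the distribution of ordinal patterns of consecutive
#' `order`-tuples (delay 1), normalized by `log(order!)`. Ties are broken by
#' temporal position (first occurrence ranks lower), the convention that
#' keeps the statistic well defined on quantized signals.
#'
#' @param x numeric vector. @param order pattern length (default 3).
#' @return normalized entropy in `[0, 1]`.
#' @export
permutation_entropy <- function(x, order = 3) {
  n <- length(x) - order + 1
  if (n < 2) return(0)
  idx <- outer(seq_len(n) - 1, seq_len(order), "+")
  w <- matrix(x[idx], nrow = n)
  # lexicographic code of the within-window ranking
  code <- integer(n)
  for (j in seq_len(order)) {
    rank_j <- rowSums(w < w[, j]) +
      rowSums(w[, seq_len(j - 1), drop = FALSE] == w[, j])
    code <- code * order + rank_j
  }
  p <- tabulate(code + 1L)
  p <- p[p > 0] / n
  -sum(p * log(p)) / log(factorial(order))
}

# First zero crossing of the autocorrelation, capped.
.acf_delay <- function(x, cap = 10) {
  a <- acf(x, lag.max = cap, plot = FALSE, demean = TRUE)$acf[-1]
  z <- which(a <= 0)
  if (length(z) == 0) cap else z[1]
}

#' Grassberger-Procaccia correlation dimension
#'
#' See [nonlinear_features()] for the parameter conventions.
#'
#' @param x numeric vector.
#' @param dims embedding dimensions examined.
#' @param n_radii radii per dimension (log-spaced across the 10th-50th
#'   distance percentiles).
#' @param max_points cap on embedded points (stride subsampling).
#' @param delay embedding delay; `NULL` = first ACF zero crossing, capped
#'   at 10.
#' @return estimated correlation dimension (>= 0).
#' @export
correlation_dimension <- function(x, dims = 2:8, n_radii = 8,
                                  max_points = 200, delay = NULL) {
  if (is.null(delay)) delay <- .acf_delay(x)
  slopes <- rep(NA_real_, length(dims))
  for (di in seq_along(dims)) {
    d <- dims[di]
    span <- (d - 1) * delay
    npts <- length(x) - span
    if (npts < 20) next
    starts <- seq_len(npts)
    if (npts > max_points)
      starts <- round(seq(1, npts, length.out = max_points))
    emb <- vapply(seq_len(d) - 1,
                  function(k) x[starts + k * delay], numeric(length(starts)))
    dvec <- as.vector(dist(emb))
    qs <- quantile(dvec[dvec > 0], c(0.1, 0.5), names = FALSE)
    if (!all(is.finite(qs)) || qs[1] <= 0 || qs[2] <= qs[1]) next
    radii <- exp(seq(log(qs[1]), log(qs[2]), length.out = n_radii))
    cs <- corr_sum_cpp(emb, radii, theiler = delay)
    keep <- cs > 0
    if (sum(keep) < 3) next
    lx <- log(radii[keep]); ly <- log(cs[keep])
    slopes[di] <- sum((lx - mean(lx)) * (ly - mean(ly))) /
      sum((lx - mean(lx))^2)
  }
  ok <- which(!is.na(slopes))
  if (length(ok) == 0) return(0)
  top <- tail(ok, 3)
  max(0, median(slopes[top]))
}
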