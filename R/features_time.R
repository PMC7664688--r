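#' Time-domain features of one channel epoch
#'
#' Nine descriptors: mean, mean square, median, peak-to-peak, sample
#' skewness and kurtosis, and the three Hjorth parameters. Moments are
#' bias-uncorrected (`m_k = mean((x - xbar)^k)`); kurtosis is the Pearson
#' (non-excess) form `m4 / m2^2`. Hjorth activity is the variance of the
#' signal; mobility is `sqrt(var(dx) / var(x))` with `dx` the first
#' difference; complexity is `mobility(dx) / mobility(x)`. A constant input
#' returns activity, mobility and complexity (and skewness/kurtosis) as 0 by
#' convention, with a `degenerate` attribute instead of an error.
#'
#' @param x numeric vector, length >= 3.
#' @return named numeric vector of 9 values (attribute `degenerate` is TRUE
#'   for constant input).
#' @export
time_features <- function(x) {
  if (length(x) < 3) stop("time_features needs at least 3 samples")
  m <- mean(x)
  xc <- x - m
  m2 <- mean(xc^2)
  degenerate <- m2 < .Machine$double.eps
  if (degenerate) {
    skw <- krt <- act <- mob <- cpx <- 0
  } else {
    skw <- mean(xc^3) / m2^1.5
    krt <- mean(xc^4) / m2^2
    act <- var(x)
    d1 <- diff(x)
    d2 <- diff(d1)
    v1 <- var(d1)
    mob <- sqrt(v1 / act)
    cpx <- if (v1 < .Machine$double.eps) 0 else sqrt(var(d2) / v1) / mob
  }
  out <- c(mean = m, mean_square = mean(x^2), median = median(x),
           peak_to_peak = max(x) - min(x), skewness = skw, kurtosis = krt,
           hjorth_activity = if (degenerate) 0 else act,
           hjorth_mobility = mob, hjorth_complexity = cpx)
  attr(out, "degenerate") <- degenerate
  out
}
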