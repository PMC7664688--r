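# Daubechies-4 scaling filter (4 vanishing moments, 8 taps, orthonormal;
# coefficients sum to sqrt(2)).
.db4_h <- c(0.2303778133088552, 0.7148465705525415, 0.6308807679295904,
            -0.0279837694169839, -0.1870348117188811, 0.0308413818359870,
            0.0328830116669829, -0.0105974017849973)

# One periodized analysis step: circular correlation with the scaling /
# wavelet filters, downsampled by 2. Requires even length; with an
# orthonormal pair the step conserves energy exactly.
.dwt_step <- function(x) {
  n <- length(x)
  if (n %% 2 != 0) stop("periodized DWT step needs even length")
  h <- .db4_h
  L <- length(h)
  g <- (-1)^(seq_len(L) - 1) * rev(h)
  idx <- outer(seq(0, n - 2, by = 2), seq_len(L) - 1, "+") %% n + 1
  xm <- matrix(x[idx], nrow = n / 2)
  list(a = drop(xm %*% h), d = drop(xm %*% g))
}

#' Multilevel periodized db4 decomposition
#'
#' The input is truncated to the largest multiple of `2^levels` samples so
#' every level has even length and the circular (periodized) transform is
#' exactly orthonormal — total coefficient energy equals signal energy to
#' machine precision. For the default 2 s epochs at 250 Hz this keeps 480 of
#' 500 samples.
#'
#' @param x numeric vector.
#' @param levels decomposition depth (default 5).
#' @return named list of coefficient vectors `D1` ... `D<levels>`,
#'   `A<levels>`.
#' @export
dwt_decompose <- function(x, levels = 5) {
  keep <- (length(x) %/% 2^levels) * 2^levels
  if (keep < 2^levels)
    stop(sprintf("need at least %d samples for %d levels", 2^levels, levels))
  a <- x[seq_len(keep)]
  out <- list()
  for (lev in seq_len(levels)) {
    st <- .dwt_step(a)
    out[[paste0("D", lev)]] <- st$d
    a <- st$a
  }
  out[[paste0("A", levels)]] <- a
  out
}

#' Wavelet subband features of one channel epoch
#'
#' For each of the six subbands (D1..D5, A5 at the default depth):
#' relative energy (subband squared-coefficient sum over the total across
#' subbands), Shannon entropy of the within-subband coefficient energy
#' fractions (natural log), maximum squared coefficient, and the variance of
#' the squared coefficients. Relative energies sum to 1 for any nonzero
#' signal; an all-zero signal returns zeros with a `degenerate` attribute.
#'
#' @param x numeric vector (one channel of one epoch).
#' @param fs sampling rate, recorded for band bookkeeping only.
#' @param levels decomposition depth.
#' @return named numeric vector of `4 * (levels + 1)` values in subband-major
#'   order: `relative_energy_D1`, `shannon_entropy_D1`, `max_energy_D1`,
#'   `variance_D1`, ...
#' @export
dwt_features <- function(x, fs = 250, levels = 5) {
  coefs <- dwt_decompose(x, levels)
  e_sub <- vapply(coefs, function(c) sum(c^2), 0.0)
  tot <- sum(e_sub)
  degenerate <- tot < .Machine$double.eps
  out <- numeric(0)
  for (nm in names(coefs)) {
    c2 <- coefs[[nm]]^2
    if (degenerate || e_sub[[nm]] < .Machine$double.eps) {
      rel <- ent <- 0
    } else {
      rel <- e_sub[[nm]] / tot
      p <- c2 / e_sub[[nm]]
      p <- p[p > 0]
      ent <- -sum(p * log(p))
    }
    v <- c(rel, ent, max(c2), var(c2))
    names(v) <- paste0(c("relative_energy_", "shannon_entropy_",
                         "max_energy_", "variance_"), nm)
    out <- c(out, v)
  }
  attr(out, "degenerate") <- degenerate
  out
}
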