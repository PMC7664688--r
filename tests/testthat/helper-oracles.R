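# Independent oracles used by the tests: deliberately naive implementations
# kept separate from the package's computational path.

# sample entropy by direct O(n^2) template counting (Chebyshev distance)
sampen_brute <- function(x, m = 2, r = 0.2 * sd(x)) {
  n <- length(x)
  A <- B <- 0
  for (i in 1:(n - m - 1)) {
    for (j in (i + 1):(n - m)) {
      if (max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)])) <= r) {
        B <- B + 1
        if (abs(x[i + m] - x[j + m]) <= r) A <- A + 1
      }
    }
  }
  if (B == 0) 0 else -log(A / B)
}

# raw FFT periodogram band power (no window) on one channel
band_power_oracle <- function(x, fs, lo, hi) {
  n <- length(x)
  p <- abs(fft(x - mean(x)))^2 / n
  f <- (seq_len(n) - 1) * fs / n
  keep <- f >= lo & f < hi & f <= fs / 2
  sum(p[keep])
}

# log beta/alpha band-power ratio of a recording's channel
beta_alpha_ratio <- function(rec, ch = 1) {
  log(band_power_oracle(rec$signal[ch, ], rec$fs, 13, 25) /
        band_power_oracle(rec$signal[ch, ], rec$fs, 8, 13))
}

# reference DWT by explicit convolution with periodic extension and
# downsampling (checks the packaged filter-bank implementation)
dwt_step_oracle <- function(x) {
  h <- c(0.2303778133088552, 0.7148465705525415, 0.6308807679295904,
         -0.0279837694169839, -0.1870348117188811, 0.0308413818359870,
         0.0328830116669829, -0.0105974017849973)
  g <- (-1)^(0:7) * rev(h)
  n <- length(x)
  xp <- c(x, x[1:8])  # periodic extension
  a <- d <- numeric(n / 2)
  for (k in seq_len(n / 2)) {
    seg <- xp[(2 * k - 1):(2 * k + 6)]
    a[k] <- sum(h * seg)
    d[k] <- sum(g * seg)
  }
  list(a = a, d = d)
}
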