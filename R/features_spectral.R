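# Hann-windowed one-sided periodogram. Power is scaled so that the sum over
# all bins equals the mean square of the windowed signal (Parseval), which
# makes band "absolute power" the in-band share of signal power.
periodogram <- function(x, fs) {
  n <- length(x)
  w <- 0.5 * (1 - cos(2 * pi * seq_len(n) / (n + 1)))
  xw <- (x - mean(x)) * w
  sp <- abs(fft(xw))^2 / (n * sum(w^2))
  half <- floor(n / 2)
  p <- sp[2:(half + 1)]
  onesided <- 2 * p
  if (n %% 2 == 0) onesided[half] <- p[half]  # Nyquist bin not doubled
  list(freq = (1:half) * fs / n, power = onesided)
}

#' Spectral band features of one channel epoch
#'
#' Windowed-DFT (Hann periodogram) features for the seven canonical bands of
#' [eeg_bands()]: absolute power (sum of spectral power in the band),
#' relative power (absolute power over the sum across the seven bands),
#' maximum in-band spectral value and its frequency (peak frequency, Hz).
#' At the default 2 s epochs the resolution is 0.5 Hz. Relative powers sum
#' to 1 whenever any band power is nonzero.
#'
#' @param x numeric vector, length >= fs (1 s).
#' @param fs sampling rate (Hz).
#' @return named numeric vector of 28 values in band-major order:
#'   `absolute_power_delta`, `relative_power_delta`, `max_power_delta`,
#'   `peak_frequency_delta`, ...
#' @export
spectral_features <- function(x, fs = 250) {
  if (length(x) < fs) stop("spectral_features needs at least 1 s of signal")
  pg <- periodogram(x, fs)
  bands <- eeg_bands()
  absp <- maxp <- pkf <- numeric(nrow(bands))
  for (b in seq_len(nrow(bands))) {
    hi_closed <- b == nrow(bands)
    sel <- pg$freq >= bands$low[b] &
      (if (hi_closed) pg$freq <= bands$high[b] else pg$freq < bands$high[b])
    if (!any(sel)) { absp[b] <- 0; maxp[b] <- 0; pkf[b] <- NA_real_; next }
    absp[b] <- sum(pg$power[sel])
    i <- which.max(pg$power[sel])
    maxp[b] <- pg$power[sel][i]
    pkf[b] <- pg$freq[sel][i]
  }
  tot <- sum(absp)
  relp <- if (tot > 0) absp / tot else rep(0, length(absp))
  pkf[is.na(pkf)] <- 0
  out <- as.vector(rbind(absp, relp, maxp, pkf))
  names(out) <- as.vector(vapply(bands$band, function(bn)
    paste0(c("absolute_power_", "relative_power_", "max_power_",
             "peak_frequency_"), bn), character(4)))
  attr(out, "degenerate") <- tot <= 0
  out
}
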