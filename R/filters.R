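# IIR design + zero-phase filtering. The installed stack has no signal-
# processing package, so Butterworth low/high-pass sections are designed here
# from the analog prototype via bilinear transform, and notches as
# constrained biquads; filtering runs through the compiled SOS kernel.

# Butterworth second-order sections. `type` "low" or "high"; even `order`.
butter_sos <- function(order, cutoff, fs, type = c("low", "high")) {
  type <- match.arg(type)
  if (order %% 2 != 0 || order < 2)
    stop("`order` must be a positive even integer")
  if (cutoff <= 0 || cutoff >= fs / 2)
    stop("`cutoff` must lie in (0, fs/2)")
  warp <- 2 * fs * tan(pi * cutoff / fs)  # prewarped analog cutoff (rad/s)
  k <- seq_len(order / 2)
  theta <- pi * (2 * k + order - 1) / (2 * order)
  poles <- complex(modulus = 1, argument = theta)  # left-half unit circle
  poles <- if (type == "low") poles * warp else warp / poles
  zd <- (2 * fs + poles) / (2 * fs - poles)        # bilinear
  nsec <- length(zd)
  sos <- matrix(0, nsec, 6)
  zero <- if (type == "low") -1 else 1             # digital zeros
  ref <- if (type == "low") 1 else -1              # unit gain at DC / Nyquist
  for (s in seq_len(nsec)) {
    a <- c(1, -2 * Re(zd[s]), Mod(zd[s])^2)
    b <- c(1, -2 * zero, 1)
    hb <- sum(b * ref^(0:2))
    ha <- sum(a * ref^(0:2))
    sos[s, ] <- c(b * abs(ha / hb), 1, a[2], a[3])
  }
  sos
}

# Constrained notch biquad (unit gain away from f0, zero at f0).
notch_sos <- function(f0, fs, bandwidth = 1) {
  if (f0 <= 0 || f0 >= fs / 2) stop("notch frequency must lie in (0, fs/2)")
  w0 <- 2 * pi * f0 / fs
  q <- f0 / bandwidth
  alpha <- sin(w0) / (2 * q)
  a0 <- 1 + alpha
  matrix(c(1 / a0, -2 * cos(w0) / a0, 1 / a0,
           1, -2 * cos(w0) / a0, (1 - alpha) / a0), 1, 6)
}

# Zero-phase (forward-backward) SOS filtering with odd-reflection padding.
sos_filtfilt <- function(x, sos) {
  n <- length(x)
  pad <- min(n - 1, 3 * (2 * nrow(sos) + 1) * 3, 250)
  if (pad > 0) {
    front <- 2 * x[1] - x[(pad + 1):2]
    back <- 2 * x[n] - x[(n - 1):(n - pad)]
    xe <- c(front, x, back)
  } else xe <- x
  y <- sos_filter_cpp(xe, sos)
  y <- rev(sos_filter_cpp(rev(y), sos))
  if (pad > 0) y <- y[(pad + 1):(pad + n)]
  y
}

# Apply a zero-phase SOS filter to every row of a channels x samples matrix.
filt_rows <- function(signal, sos) {
  t(apply(signal, 1, sos_filtfilt, sos = sos))
}

# Integer-factor decimation with an anti-aliasing Butterworth low-pass
# (order 8, cutoff 0.8 x new Nyquist), zero-phase.
resample_signal <- function(signal, fs, target_fs) {
  if (fs == target_fs) return(signal)
  ratio <- fs / target_fs
  if (abs(ratio - round(ratio)) > 1e-9)
    stop("resampling requires an integer fs / target_fs ratio")
  ratio <- round(ratio)
  sos <- butter_sos(8, 0.8 * target_fs / 2, fs, "low")
  low <- filt_rows(signal, sos)
  low[, seq(1, ncol(signal), by = ratio), drop = FALSE]
}
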