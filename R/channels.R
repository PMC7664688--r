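#' The 21-channel 10-20 montage
#'
#' Channel labels and idealized unit-sphere positions for the extended
#' international 10-20 layout used throughout the package (O1, O2, Oz, P3,
#' P4, Pz, C3, C4, Cz, T3, T4, T5, T6, F3, F4, F7, F8, Fz, FP1, FP2, FPz).
#' Positions follow the conventional spherical-head angles and are used for
#' distance-weighted interpolation of rejected channels and for placing
#' spatially localized artifacts (blinks on the frontopolar row).
#'
#' @return a tibble with columns `channel`, `x`, `y`, `z` (unit sphere;
#'   x right, y anterior, z superior).
#' @export
montage_1020 <- function() {
  # (theta, phi) spherical-head angles; theta signed left(-)/right(+)
  ang <- matrix(c(
    -92, -72,   # FP1
     92,  90,   # FPz
     92,  72,   # FP2
    -92, -36,   # F7
    -60, -51,   # F3
     46,  90,   # Fz
     60,  51,   # F4
     92,  36,   # F8
    -92,   0,   # T3
    -45,   0,   # C3
      0,   0,   # Cz
     45,   0,   # C4
     92,   0,   # T4
    -92,  36,   # T5
    -60,  51,   # P3
     46, -90,   # Pz
     60, -51,   # P4
     92, -36,   # T6
    -92,  72,   # O1
     92, -90,   # Oz
     92, -72),  # O2
    ncol = 2, byrow = TRUE)
  labels <- c("FP1", "FPz", "FP2", "F7", "F3", "Fz", "F4", "F8",
              "T3", "C3", "Cz", "C4", "T4", "T5", "P3", "Pz", "P4",
              "T6", "O1", "Oz", "O2")
  inc <- abs(ang[, 1]) * pi / 180
  az <- ifelse(ang[, 1] >= 0, ang[, 2], ang[, 2] + 180) * pi / 180
  tibble::tibble(
    channel = labels,
    x = sin(inc) * cos(az),
    y = sin(inc) * sin(az),
    z = cos(inc))
}

#' Canonical EEG frequency bands
#'
#' The seven analysis bands, half-open `[low, high)` except the last, which
#' closes at 50 Hz: delta 1-4, theta 4-8, alpha 8-13, beta 13-25, high beta
#' 25-30, gamma 30-40, high gamma 40-50 Hz.
#'
#' @return tibble with columns `band`, `low`, `high`.
#' @export
eeg_bands <- function() {
  tibble::tibble(
    band = c("delta", "theta", "alpha", "beta", "high_beta", "gamma",
             "high_gamma"),
    low = c(1, 4, 8, 13, 25, 30, 40),
    high = c(4, 8, 13, 25, 30, 40, 50))
}

#' Dyadic subband edges of a multilevel DWT
#'
#' Frequency bands covered by the detail coefficients D1..Dlevels and the
#' final approximation at a given sampling rate: Dk spans
#' `[fs / 2^(k+1), fs / 2^k)` and the approximation the remainder down to 0.
#' At 250 Hz and 5 levels, D1 covers 62.5-125 Hz and A5 0-3.9 Hz.
#'
#' @param fs sampling rate in Hz.
#' @param levels decomposition depth.
#' @return tibble with columns `subband`, `low`, `high` (Hz).
#' @export
dwt_band_table <- function(fs = 250, levels = 5) {
  k <- seq_len(levels)
  tibble::tibble(
    subband = c(paste0("D", k), paste0("A", levels)),
    low = c(fs / 2^(k + 1), 0),
    high = c(fs / 2^k, fs / 2^(levels + 1)))
}
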