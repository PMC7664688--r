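#' Class-conditional effect specification for the generator
#'
#' The generator plants known ground truth through two dials, both
#' dimensionless shifts of band-limited log power:
#' * `intent_effect`: within insider-threat questions, an affirmative answer
#'   raises beta-band log power and lowers alpha-band log power by half the
#'   effect each, so the nominal beta/alpha log-power-ratio shift equals the
#'   effect (mirroring the reported arousal signature of malicious intent).
#' * `scenario_effect`: insider questions receive the same beta-up/alpha-down
#'   shift relative to conflict questions, plus a matched increase of the
#'   broadband stochastic component, which moves the signal-complexity
#'   (entropy) features the scenario contrast leans on.
#'
#' Setting both effects to zero makes the two classes exchangeable by
#' construction. `subject_variability` is the SD of per-subject random
#' log-amplitude offsets applied to every rhythm, emulating stable
#' between-subject baseline differences.
#'
#' @param intent_effect,scenario_effect non-negative log-power shifts.
#' @param subject_variability SD of per-subject band log-amplitude offsets.
#' @param artifacts an [artifact_config()].
#' @return list of class `effect_spec`.
#' @export
effect_spec <- function(intent_effect = 0, scenario_effect = 0,
                        subject_variability = 0.1,
                        artifacts = artifact_config()) {
  if (intent_effect < 0 || scenario_effect < 0 || subject_variability < 0)
    stop("effect magnitudes must be >= 0")
  structure(list(intent_effect = intent_effect,
                 scenario_effect = scenario_effect,
                 subject_variability = subject_variability,
                 artifacts = artifacts),
            class = "effect_spec")
}

#' Artifact configuration for the generator
#'
#' Amplitudes in microvolts; all zero yields artifact-free recordings and
#' [inject_artifacts()] becomes the identity. The line frequency defaults to
#' 50 Hz (the study's mains frequency).
#'
#' @param line_amp mains sinusoid amplitude (uV).
#' @param line_freq mains frequency (Hz).
#' @param drift_amp low-frequency (< 0.5 Hz) drift amplitude (uV).
#' @param blink_rate expected blink transients per second, concentrated on
#'   the frontopolar row (FP1/FPz/FP2).
#' @param blink_amp blink peak amplitude on the frontopolar channels (uV).
#' @param dead_prob probability that one randomly chosen channel is dead
#'   (flat) for the whole question.
#' @return list of class `artifact_config`.
#' @export
artifact_config <- function(line_amp = 5, line_freq = 50, drift_amp = 20,
                            blink_rate = 0.1, blink_amp = 100,
                            dead_prob = 0) {
  stopifnot(line_amp >= 0, drift_amp >= 0, blink_rate >= 0, blink_amp >= 0,
            dead_prob >= 0, dead_prob <= 1, line_freq > 0)
  structure(list(line_amp = line_amp, line_freq = line_freq,
                 drift_amp = drift_amp, blink_rate = blink_rate,
                 blink_amp = blink_amp, dead_prob = dead_prob),
            class = "artifact_config")
}

#' Construct a raw recording object
#'
#' @param signal channels x samples numeric matrix (microvolts).
#' @param fs sampling rate (Hz).
#' @param channels channel labels; defaults to the 21-channel montage.
#' @param subject,question,scenario_type,answer trial metadata.
#' @return object of class `eeg_recording`.
#' @export
raw_recording <- function(signal, fs, channels = montage_1020()$channel,
                          subject = NA_character_, question = NA_character_,
                          scenario_type = NA_character_,
                          answer = NA_character_) {
  if (!is.matrix(signal) || nrow(signal) != length(channels))
    stop("`signal` must be a channels x samples matrix matching `channels`")
  structure(list(signal = signal, fs = fs, channels = channels,
                 subject = subject, question = question,
                 scenario_type = scenario_type, answer = answer,
                 stage = "raw", interpolated = character(0), log = list()),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording [%s]> %d ch x %d samples @ %g Hz (%s, %s: %s/%s)\n",
              x$stage, nrow(x$signal), ncol(x$signal), x$fs,
              x$subject, x$question, x$scenario_type, x$answer))
  invisible(x)
}

# 1/f^gamma background noise with a given RMS, by spectral shaping of white
# Gaussian noise. The DC bin is zeroed; bins below 0.5 Hz are floored so the
# power does not blow up at the origin.
pink_noise <- function(n, fs, rms, gamma = 1) {
  f <- seq(0, fs - fs / n, length.out = n)
  f <- pmin(f, fs - f) # two-sided frequency magnitude
  shape <- ifelse(f < 1e-9, 0, 1 / pmax(f, 0.5)^(gamma / 2))
  w <- fft(rnorm(n)) * shape
  x <- Re(fft(w, inverse = TRUE)) / n
  s <- sd(x)
  if (s > 0) x <- x * (rms / s)
  x
}

# Band-limited Gaussian oscillation: white noise masked to [lo, hi] Hz with
# 0.5 Hz raised-cosine edges, scaled to the requested RMS.
band_noise <- function(n, fs, lo, hi, rms) {
  f <- seq(0, fs - fs / n, length.out = n)
  f <- pmin(f, fs - f)
  taper <- 0.5
  mask <- rep(0, n)
  core <- f >= lo & f <= hi
  mask[core] <- 1
  ramp_lo <- f >= lo - taper & f < lo
  mask[ramp_lo] <- 0.5 * (1 + cos(pi * (lo - f[ramp_lo]) / taper))
  ramp_hi <- f > hi & f <= hi + taper
  mask[ramp_hi] <- 0.5 * (1 + cos(pi * (f[ramp_hi] - hi) / taper))
  w <- fft(rnorm(n)) * mask
  x <- Re(fft(w, inverse = TRUE)) / n
  s <- sd(x)
  if (s > 0) x <- x * (rms / s)
  x
}

#' Draw a subject's baseline rhythm offsets
#'
#' Per-subject random log-amplitude offsets for the theta, alpha and beta
#' rhythms and the broadband component, N(0, `subject_variability`). Passing
#' the result to [synthesize_question_recording()] for every question of a
#' subject gives that subject a stable individual spectral profile.
#'
#' @param effects an [effect_spec()].
#' @param seed integer seed.
#' @return named list of log-amplitude offsets.
#' @export
subject_baseline <- function(effects = effect_spec(), seed = 1L) {
  with_seed(seed, {
    v <- effects$subject_variability
    list(theta = rnorm(1, 0, v), alpha = rnorm(1, 0, v),
         beta = rnorm(1, 0, v), broadband = rnorm(1, 0, v))
  })
}

# Base RMS amplitudes (uV) of the generative components, split into a
# shared (volume-conducted, spatially smooth) part and a channel-local part
# — scalp rhythms are strongly but not perfectly coherent across channels.
# Totals give a realistic resting-EEG look: ~8 uV 1/f background, a
# prominent alpha rhythm, weaker theta/beta, a small broadband floor.
.base_amps <- list(
  pink_shared = 6.4, pink_local = 3.6,
  theta_shared = 2.0, theta_local = 2.0,
  alpha_shared = 2.5, alpha_local = 3.0,
  beta_shared = 1.4, beta_local = 1.4,
  broadband = 1.5)

# Smooth spatial gain profiles over the montage, emulating volume-conducted
# sources: each rhythm projects to every channel with a gain that varies
# smoothly with electrode position (alpha posterior-dominant, beta/blink
# anterior, theta midline-frontal), so neighboring channels are strongly
# correlated as in real scalp EEG.
.channel_gains <- function() {
  pos <- montage_1020()
  list(pink = exp(0.25 * pos$z),
       theta = exp(0.3 * pos$z + 0.2 * pos$y),
       alpha = exp(-0.5 * pos$y + 0.2 * pos$z),
       beta = exp(0.4 * pos$y))
}

#' Synthesize one question's 21-channel recording
#'
#' Generates the EEG for a single question trial: per channel, a 1/f
#' background plus band-limited theta (4-8 Hz), alpha (8-13 Hz) and beta
#' (13-25 Hz) oscillations and a broadband stochastic component, in
#' microvolts. Class-conditional effects act multiplicatively on the band
#' amplitudes as documented in [effect_spec()]; subject baselines shift all
#' questions of one subject coherently. Purely deterministic given
#' `(trial, effects, subject_baseline, seed)`.
#'
#' @param trial one row of a [make_design()] table (data frame or list with
#'   `subject`, `question`, `scenario_type`, `answer`).
#' @param effects an [effect_spec()].
#' @param subject_baseline result of [subject_baseline()], or `NULL` for a
#'   zero baseline.
#' @param seed integer seed for this question.
#' @param duration trial length in seconds (default 30).
#' @param fs sampling rate in Hz (default 500).
#' @return an `eeg_recording` (21 x `duration * fs`).
#' @export
synthesize_question_recording <- function(trial, effects = effect_spec(),
                                          subject_baseline = NULL,
                                          seed = 1L, duration = 30,
                                          fs = 500) {
  trial <- as.list(trial)
  if (is.null(subject_baseline))
    subject_baseline <- list(theta = 0, alpha = 0, beta = 0, broadband = 0)
  stopifnot(duration > 0, fs > 0)
  n <- round(duration * fs)
  channels <- montage_1020()$channel

  # class-conditional shifts: the total beta-vs-alpha log-power shift
  # delivered in-band equals delta (intent + scenario contributions), and
  # scenario_effect additionally scales the broadband component
  delta <- d_broad <- 0
  if (identical(trial$scenario_type, "insider")) {
    delta <- delta + effects$scenario_effect
    d_broad <- d_broad + effects$scenario_effect / 4
    if (identical(trial$answer, "yes"))
      delta <- delta + effects$intent_effect
  }
  ba <- .base_amps
  sb <- subject_baseline
  amp <- list(
    theta_s = ba$theta_shared * exp(sb$theta),
    theta_l = ba$theta_local * exp(sb$theta),
    alpha_s = ba$alpha_shared * exp(sb$alpha),
    alpha_l = ba$alpha_local * exp(sb$alpha),
    beta_s = ba$beta_shared * exp(sb$beta),
    beta_l = ba$beta_local * exp(sb$beta),
    broad = ba$broadband * exp(sb$broadband + d_broad))

  gains <- .channel_gains()
  nch <- length(channels)
  # The class effect must survive the analysis chain, whose average
  # re-reference removes the across-channel mean of every shared source.
  # A per-band scale factor uniform across channels commutes with the
  # re-reference, so the delivered band log-power shift can be computed in
  # re-referenced terms: shared sources contribute through centered gains,
  # channel-local components through a (1 - 1/n_channels) factor. The scale
  # is solved so the mean in-band log-power shift equals the requested
  # delta, compensating for the in-band 1/f and broadband background.
  ctr <- function(g) g - mean(g)
  pink_tot <- 1 + log(fs / 2 / 0.5)  # flat [0, 0.5] + 1/f [0.5, fs/2]
  loc <- 1 - 1 / nch
  bg_band <- function(lo, hi) {
    frac <- log(hi / lo) / pink_tot
    (ctr(gains$pink) * ba$pink_shared)^2 * frac +
      loc * ba$pink_local^2 * frac +
      loc * amp$broad^2 * (hi - lo) / (fs / 2)
  }
  osc_scale <- function(osc_pow, bg_pow, target) {
    f <- mean(osc_pow / (osc_pow + bg_pow))
    sqrt(max(0, (target - (1 - f)) / f))
  }
  s_alpha <- osc_scale((ctr(gains$alpha) * amp$alpha_s)^2 +
                         loc * amp$alpha_l^2,
                       bg_band(8, 13), exp(-delta / 2))
  s_beta <- osc_scale((ctr(gains$beta) * amp$beta_s)^2 +
                        loc * amp$beta_l^2,
                      bg_band(13, 25), exp(delta / 2))

  signal <- with_seed(seed, {
    # shared (volume-conducted) sources with smooth scalp topographies ...
    src_pink <- pink_noise(n, fs, ba$pink_shared)
    src_theta <- band_noise(n, fs, 4, 8, amp$theta_s)
    src_alpha <- band_noise(n, fs, 8, 13, amp$alpha_s)
    src_beta <- band_noise(n, fs, 13, 25, amp$beta_s)
    m <- gains$pink %o% src_pink + gains$theta %o% src_theta +
      (gains$alpha * s_alpha) %o% src_alpha +
      (gains$beta * s_beta) %o% src_beta
    # ... plus channel-local rhythm parts, background and broadband noise
    for (ch in seq_len(nch)) {
      m[ch, ] <- m[ch, ] + pink_noise(n, fs, ba$pink_local) +
        band_noise(n, fs, 4, 8, amp$theta_l) +
        s_alpha * band_noise(n, fs, 8, 13, amp$alpha_l) +
        s_beta * band_noise(n, fs, 13, 25, amp$beta_l) +
        rnorm(n, 0, amp$broad)
    }
    m
  })
  rownames(signal) <- channels
  raw_recording(signal, fs, channels,
                subject = trial$subject %||% NA_character_,
                question = trial$question %||% NA_character_,
                scenario_type = trial$scenario_type %||% NA_character_,
                answer = trial$answer %||% NA_character_)
}

#' Inject measurement artifacts into a recording
#'
#' Adds, in order: a mains sinusoid on every channel (random per-channel
#' phase), slow sinusoidal drift (0.1-0.3 Hz, random phase/frequency per
#' channel), blink-like raised-cosine transients (~300 ms) concentrated on
#' FP1/FPz/FP2 with 25% amplitude spillover onto F7/F3/Fz/F4/F8, and, with
#' probability `dead_prob`, one randomly chosen flat (dead) channel. A
#' configuration with all amplitudes and rates at zero returns the input
#' unchanged.
#'
#' @param raw an `eeg_recording`.
#' @param config an [artifact_config()].
#' @param seed integer seed.
#' @return the corrupted `eeg_recording`.
#' @export
inject_artifacts <- function(raw, config = artifact_config(), seed = 1L) {
  stopifnot(inherits(raw, "eeg_recording"))
  if (config$line_amp == 0 && config$drift_amp == 0 &&
      config$blink_rate == 0 && config$dead_prob == 0)
    return(raw)
  n <- ncol(raw$signal)
  nc <- nrow(raw$signal)
  t <- seq(0, n - 1) / raw$fs
  sig <- raw$signal
  with_seed(seed, {
    if (config$line_amp > 0)
      for (ch in seq_len(nc))
        sig[ch, ] <- sig[ch, ] +
          config$line_amp * sin(2 * pi * config$line_freq * t +
                                  runif(1, 0, 2 * pi))
    if (config$drift_amp > 0)
      for (ch in seq_len(nc))
        sig[ch, ] <- sig[ch, ] +
          config$drift_amp * sin(2 * pi * runif(1, 0.1, 0.3) * t +
                                   runif(1, 0, 2 * pi))
    if (config$blink_rate > 0) {
      n_blink <- rbinom(1, max(1, round(n / raw$fs)),
                        min(1, config$blink_rate))
      if (n_blink > 0) {
        width <- round(0.3 * raw$fs)
        pulse <- config$blink_amp * 0.5 *
          (1 - cos(2 * pi * seq_len(width) / (width + 1)))
        frontal <- match(c("FP1", "FPz", "FP2"), raw$channels)
        spill <- match(c("F7", "F3", "Fz", "F4", "F8"), raw$channels)
        starts <- sample.int(max(1, n - width), n_blink)
        for (s in starts) {
          span <- s:(s + width - 1)
          for (ch in frontal[!is.na(frontal)])
            sig[ch, span] <- sig[ch, span] + pulse
          for (ch in spill[!is.na(spill)])
            sig[ch, span] <- sig[ch, span] + 0.25 * pulse
        }
      }
    }
    if (config$dead_prob > 0 && runif(1) < config$dead_prob) {
      dead <- sample.int(nc, 1)
      sig[dead, ] <- 0
    }
  })
  out <- raw
  out$signal <- sig
  out
}

#' Simulate all recordings of a design
#'
#' Convenience wrapper: one synthesized (and optionally artifact-corrupted)
#' recording per answered question, each with a seed derived from the master
#' seed and the question's indices so subsets reproduce independently.
#'
#' @param design a [make_design()] table (unanswered questions are skipped).
#' @param effects an [effect_spec()].
#' @param seed master seed.
#' @param duration,fs trial length (s) and sampling rate (Hz).
#' @param with_artifacts add artifacts from `effects$artifacts`?
#' @return named list of `eeg_recording`s, keyed by question ID.
#' @export
simulate_recordings <- function(design, effects = effect_spec(), seed = 1L,
                                duration = 30, fs = 500,
                                with_artifacts = TRUE) {
  design <- design[design$answered, , drop = FALSE]
  subjects <- unique(design$subject)
  out <- list()
  for (si in seq_along(subjects)) {
    base <- subject_baseline(effects, derive_seed(seed, si, 0))
    rows <- which(design$subject == subjects[si])
    for (qi in seq_along(rows)) {
      trial <- design[rows[qi], ]
      rec <- synthesize_question_recording(
        trial, effects, base, seed = derive_seed(seed, si, qi),
        duration = duration, fs = fs)
      if (with_artifacts)
        rec <- inject_artifacts(rec, effects$artifacts,
                                seed = derive_seed(seed, si, qi, 7L))
      out[[trial$question]] <- rec
    }
  }
  out
}
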