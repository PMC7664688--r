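test_that("the cleaning pipeline downsamples, de-means, denoises, rerefs", {
  trial <- list(subject = "S01", question = "Q1",
                scenario_type = "conflict", answer = "no")
  raw <- synthesize_question_recording(trial, seed = 2)
  raw <- inject_artifacts(raw, artifact_config(line_amp = 20,
                                               drift_amp = 30,
                                               blink_rate = 0.1), seed = 3)
  # add a DC offset; the 1 Hz high-pass must remove it
  raw$signal <- raw$signal + 100

  pre_50 <- band_power_oracle(raw$signal[5, ], raw$fs, 49.5, 50.5)
  clean <- preprocess_recording(raw)

  expect_equal(clean$fs, 250)
  expect_equal(ncol(clean$signal), 7500)
  expect_true(all(abs(rowMeans(clean$signal)) < 1))
  # average reference: across-channel mean is 0 at every sample
  expect_lt(max(abs(colMeans(clean$signal))), 1e-9)
  # notch: >= 20 dB reduction at 50 Hz (accounting for the 2x decimation)
  post_50 <- band_power_oracle(clean$signal[5, ], clean$fs, 49.5, 50.5)
  expect_lt(post_50 / (pre_50 / 2), 10^(-20 / 10))
  expect_named(clean$log[c("resample", "highpass", "notch", "bad_channels",
                           "rereference")])
})

test_that("preprocessing rejects unusable inputs", {
  sig <- matrix(rnorm(21 * 400), 21)
  rec <- raw_recording(sig, fs = 500)
  expect_error(preprocess_recording(rec), "at least 2 s")
  rec2 <- raw_recording(matrix(rnorm(21 * 1000), 21), fs = 125)
  expect_error(preprocess_recording(rec2), "below the target")
  # > 50% flat channels -> rejected
  sig3 <- matrix(rnorm(21 * 2000), 21)
  sig3[1:12, ] <- 0
  rec3 <- raw_recording(sig3, fs = 500)
  expect_error(preprocess_recording(rec3), "rejected")
})

test_that("a dead channel is flagged and interpolated from its neighbors", {
  trial <- list(subject = "S01", question = "Q1",
                scenario_type = "insider", answer = "no")
  raw <- synthesize_question_recording(trial, seed = 4, duration = 6)
  raw$signal[7, ] <- 0
  clean <- preprocess_recording(raw)
  expect_identical(clean$interpolated, raw$channels[7])
  expect_gt(var(clean$signal[7, ]), 1e-6)
})

test_that("interpolating an uncorrupted channel reproduces it closely", {
  # smooth topography: shared sources only
  trial <- list(subject = "S01", question = "Q1",
                scenario_type = "insider", answer = "no")
  raw <- synthesize_question_recording(trial, seed = 6, duration = 6)
  ch <- match("Cz", raw$channels)
  est <- eegintent:::interpolate_channels(raw$signal, raw$channels, ch)
  expect_gt(cor(est[ch, ], raw$signal[ch, ]), 0.8)
})

test_that("average re-reference is idempotent", {
  x <- matrix(rnorm(21 * 500), 21)
  once <- sweep(x, 2, colMeans(x))
  twice <- sweep(once, 2, colMeans(once))
  expect_equal(once, twice)
  clean <- local_clean_recording()
  expect_lt(max(abs(colMeans(clean$signal))), 1e-9)
})

test_that("epoching follows the 2 s / 1 s scheme with the short-epoch rule", {
  clean <- local_clean_recording()
  eps <- epoch_question(clean)
  expect_length(eps, 29)
  expect_equal(vapply(eps, function(e) e$start, 0.0), 0:28)
  expect_true(all(vapply(eps, function(e) ncol(e$signal), 0L) == 500))
  # closed form for a duration grid
  for (T in c(2, 3.4, 5, 12, 30)) {
    sub <- clean
    sub$signal <- clean$signal[, seq_len(round(T * 250)), drop = FALSE]
    expect_length(epoch_question(sub), floor(T - 2) + 1)
  }
  # short recordings
  short <- clean
  short$signal <- clean$signal[, 1:375, drop = FALSE]  # 1.5 s
  e1 <- epoch_question(short)
  expect_length(e1, 1)
  expect_equal(e1[[1]]$duration, 1.5)
  tiny <- clean
  tiny$signal <- clean$signal[, 1:225, drop = FALSE]  # 0.9 s
  expect_length(epoch_question(tiny), 0)
  # labels inherited
  expect_equal(eps[[4]]$question, clean$question)
  expect_equal(eps[[4]]$answer, clean$answer)
})
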