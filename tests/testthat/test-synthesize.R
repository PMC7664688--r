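trial_yes <- list(subject = "S01", question = "Q1",
                  scenario_type = "insider", answer = "yes")
trial_no <- list(subject = "S01", question = "Q2",
                 scenario_type = "insider", answer = "no")

test_that("recordings have the stated shape and are seed-deterministic", {
  rec <- synthesize_question_recording(trial_yes, seed = 3)
  expect_equal(dim(rec$signal), c(21, 15000))
  expect_equal(rec$fs, 500)
  expect_identical(rec$signal,
                   synthesize_question_recording(trial_yes, seed = 3)$signal)
  expect_false(identical(
    rec$signal, synthesize_question_recording(trial_yes, seed = 4)$signal))
  # microvolt scale: RMS in a plausible physiological range
  rms <- sqrt(mean(rec$signal^2))
  expect_gt(rms, 3)
  expect_lt(rms, 40)
})

test_that("zero effects make yes/no classes exchangeable (KS at alpha=0.01)", {
  e0 <- effect_spec(0)
  r_yes <- r_no <- numeric(100)
  for (i in 1:100) {
    r_yes[i] <- beta_alpha_ratio(
      synthesize_question_recording(trial_yes, e0, seed = 2 * i,
                                    duration = 10))
    r_no[i] <- beta_alpha_ratio(
      synthesize_question_recording(trial_no, e0, seed = 2 * i + 1,
                                    duration = 10))
  }
  expect_gt(suppressWarnings(ks.test(r_yes, r_no)$p.value), 0.01)
})

test_that("a +0.5 intent effect raises the beta/alpha ratio for yes answers", {
  e5 <- effect_spec(0.5)
  wins <- 0
  for (i in 1:100) {
    ry <- beta_alpha_ratio(
      synthesize_question_recording(trial_yes, e5, seed = 2 * i))
    rn <- beta_alpha_ratio(
      synthesize_question_recording(trial_no, e5, seed = 2 * i + 1))
    if (ry > rn) wins <- wins + 1
  }
  expect_gte(wins, 95)
})

test_that("artifact injection adds what it claims and nothing at zero", {
  rec <- synthesize_question_recording(trial_no, seed = 11, duration = 6)
  none <- artifact_config(line_amp = 0, drift_amp = 0, blink_rate = 0,
                          dead_prob = 0)
  expect_identical(inject_artifacts(rec, none, seed = 1)$signal, rec$signal)

  line <- inject_artifacts(rec, artifact_config(line_amp = 10,
                                                drift_amp = 0,
                                                blink_rate = 0), seed = 1)
  # 50 Hz local maximum exceeding neighbors by >= 10x on every channel
  for (ch in c(1, 11, 21)) {
    p50 <- band_power_oracle(line$signal[ch, ], 500, 49.8, 50.2)
    pnb <- band_power_oracle(line$signal[ch, ], 500, 47, 48)
    expect_gt(p50 / pnb, 10)
  }

  dead <- inject_artifacts(rec, artifact_config(dead_prob = 1), seed = 5)
  expect_equal(sum(apply(dead$signal, 1, var) < 1e-12), 1)

  blink <- inject_artifacts(rec, artifact_config(line_amp = 0,
                                                 drift_amp = 0,
                                                 blink_rate = 0.5,
                                                 blink_amp = 150), seed = 2)
  added <- rowMeans(abs(blink$signal - rec$signal))
  frontal <- match(c("FP1", "FPz", "FP2"), rec$channels)
  occip <- match(c("O1", "Oz", "O2"), rec$channels)
  expect_gt(min(added[frontal]), max(added[occip]))
})

test_that("subject baselines shift a subject's band power coherently", {
  e <- effect_spec(subject_variability = 0.5)
  b1 <- subject_baseline(e, seed = 1)
  b2 <- subject_baseline(e, seed = 2)
  expect_false(identical(b1, b2))
  r1 <- synthesize_question_recording(trial_no, e, b1, seed = 9,
                                      duration = 6)
  r2 <- synthesize_question_recording(trial_no, e, b2, seed = 9,
                                      duration = 6)
  expect_false(identical(r1$signal, r2$signal))
})

test_that("simulate_recordings covers answered questions reproducibly", {
  d <- make_design(2, 2, 2, dropout_prob = 0, seed = 5)
  recs <- simulate_recordings(d, effect_spec(), seed = 5, duration = 4)
  expect_length(recs, 8)
  expect_setequal(names(recs), d$question)
  recs2 <- simulate_recordings(d, effect_spec(), seed = 5, duration = 4)
  expect_identical(recs[[3]]$signal, recs2[[3]]$signal)
})
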