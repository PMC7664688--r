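test_that("time-domain features match arithmetic and closed forms", {
  tf <- time_features(c(1, 2, 3, 4))
  expect_equal(unname(tf[c("mean", "median", "peak_to_peak")]),
               c(2.5, 2.5, 3))
  expect_equal(unname(tf["mean_square"]), mean(c(1, 4, 9, 16)))

  const <- time_features(rep(5, 100))
  expect_equal(unname(const[c("peak_to_peak", "hjorth_activity",
                              "hjorth_mobility", "hjorth_complexity")]),
               rep(0, 4))
  expect_true(attr(const, "degenerate"))

  # sampled sinusoid: mobility = 2 sin(pi f / fs), cross-checked against the
  # differencing definition computed directly
  fs <- 250
  for (f in c(5, 10, 25, 40)) {
    x <- sin(2 * pi * f * seq(0, 2 - 1 / fs, by = 1 / fs))
    tf <- time_features(x)
    expect_equal(unname(tf["hjorth_mobility"]), 2 * sin(pi * f / fs),
                 tolerance = 2e-3)
    expect_equal(unname(tf["hjorth_mobility"]),
                 sqrt(var(diff(x)) / var(x)), tolerance = 1e-12)
  }
})

test_that("DWT features agree with the convolution oracle and band logic", {
  set.seed(3)
  x <- rnorm(64)
  st <- eegintent:::.dwt_step(x)
  orc <- dwt_step_oracle(x)
  expect_equal(st$a, orc$a, tolerance = 1e-12)
  expect_equal(st$d, orc$d, tolerance = 1e-12)

  # 50 Hz sine at fs 250 -> D2 (31.2-62.4 Hz) dominates
  t <- seq(0, 2 - 1 / 250, by = 1 / 250)
  f <- dwt_features(sin(2 * pi * 50 * t), 250)
  rel <- f[grep("^relative_energy_", names(f))]
  expect_equal(names(which.max(rel)), "relative_energy_D2")

  # white noise: D1 holds about half the energy (half the Nyquist band)
  set.seed(11)
  d1 <- replicate(100, dwt_features(rnorm(500))["relative_energy_D1"])
  expect_equal(mean(d1), 0.5, tolerance = 0.02)

  z <- dwt_features(rep(0, 500))
  expect_true(all(z[grep("relative_energy", names(z))] == 0))
  expect_true(attr(z, "degenerate"))
})

test_that("spectral features localize tones and normalize correctly", {
  fs <- 250
  t <- seq(0, 2 - 1 / fs, by = 1 / fs)
  set.seed(4)
  sp <- spectral_features(sin(2 * pi * 10 * t) + rnorm(500, 0, 1e-3), fs)
  expect_gt(sp["relative_power_alpha"], 0.9)
  expect_equal(unname(sp["peak_frequency_alpha"]), 10, tolerance = 0.5)
  expect_equal(sum(sp[grep("^relative_power_", names(sp))]), 1,
               tolerance = 1e-9)

  # white noise: delta's share of the covered 1-50 Hz width is 3/49
  set.seed(5)
  rel_delta <- replicate(200,
    spectral_features(rnorm(500), fs)["relative_power_delta"])
  # small downward bias from Hann-window leakage is expected
  expect_equal(mean(rel_delta), 3 / 49, tolerance = 0.05)
})

test_that("nonlinear features behave on canonical signals", {
  expect_error(nonlinear_features(rnorm(50)), "at least 100")
  const <- nonlinear_features(rep(1, 200))
  expect_true(all(const == 0))
  expect_true(attr(const, "degenerate"))

  # SampEn matches the brute-force oracle exactly for n <= 200
  set.seed(6)
  for (i in 1:5) {
    x <- rnorm(150)
    expect_equal(unname(nonlinear_features(x)["sample_entropy"]),
                 sampen_brute(x), tolerance = 1e-12)
  }

  # iid noise has near-maximal normalized permutation entropy
  set.seed(7)
  pe <- replicate(50, permutation_entropy(runif(500)))
  expect_gte(mean(pe), 0.98)

  # a sine is more regular than its shuffle; its attractor dimension ~ 1
  set.seed(8)
  t <- seq(0, 2 - 1 / 250, by = 1 / 250)
  sine <- sin(2 * pi * 8 * t)
  sampen_of <- function(x) eegintent:::sampen_cpp(x, 2, 0.2 * sd(x))
  wins <- 0
  for (i in 1:50) {
    noisy <- sine + rnorm(500, 0, 0.05)
    if (sampen_of(noisy) < sampen_of(sample(noisy))) wins <- wins + 1
  }
  expect_gte(wins, 48)
  expect_equal(unname(nonlinear_features(sine)["correlation_dimension"]),
               1, tolerance = 0.3)
})

test_that("the feature table has the full catalogue and stable layout", {
  clean <- local_clean_recording()
  eps <- epoch_question(clean)[1:3]
  tbl <- extract_feature_table(eps)
  expect_equal(nrow(tbl), 3)
  expect_length(feature_columns(tbl), 21 * 65)
  expect_false(anyNA(tbl))
  # per-epoch normalization identities over all 21 channels
  relp <- as.matrix(tbl[grep("\\.relative_power_", names(tbl))])
  rele <- as.matrix(tbl[grep("\\.relative_energy_", names(tbl))])
  expect_equal(unname(rowSums(relp)), rep(21, 3), tolerance = 1e-9)
  expect_equal(unname(rowSums(rele)), rep(21, 3), tolerance = 1e-9)

  # empty input keeps the full header; wrong channel set is named
  empty <- extract_feature_table(list())
  expect_equal(nrow(empty), 0)
  expect_length(feature_columns(empty), 1365)
  bad <- eps[[2]]
  bad$channels <- bad$channels[1:20]
  bad$signal <- bad$signal[1:20, ]
  expect_error(extract_feature_table(list(eps[[1]], bad)),
               "epoch 2 lacks channels")

  # channel subsetting yields 65 columns per requested channel
  sub <- extract_feature_table(eps, channels = c("F3", "Fz", "F4"))
  expect_length(feature_columns(sub), 195)
})

test_that("hjorth mobility of a sinusoid increases with frequency", {
  fs <- 250
  grid <- seq(4, 60, by = 8)
  mob <- vapply(grid, function(f) {
    x <- sin(2 * pi * f * seq(0, 2 - 1 / fs, by = 1 / fs))
    unname(time_features(x)["hjorth_mobility"])
  }, 0.0)
  expect_true(all(diff(mob) > 0))
})

test_that("the train-fold scaler normalizes and never touches test rows", {
  tbl <- make_subject_table(epochs = 4, p = 8, seed = 9)
  tr <- tbl[1:24, ]
  te <- tbl[25:40, ]
  sc <- fit_scaler(tr)
  trz <- apply_scaler(sc, tr)
  Z <- as.matrix(trz[feature_columns(trz)])
  expect_lt(max(abs(colMeans(Z))), 1e-9)
  expect_equal(unname(apply(Z, 2, var)), rep(1, 8), tolerance = 1e-9)
  # test rows transformed with train parameters only: non-zero means
  tez <- apply_scaler(sc, te)
  expect_gt(max(abs(colMeans(as.matrix(tez[feature_columns(tez)])))), 1e-6)
  # constant column -> zeros, flagged
  tr2 <- tr
  tr2[[feature_columns(tr2)[1]]] <- 5
  sc2 <- fit_scaler(tr2)
  expect_equal(sc2$zero_var, feature_columns(tr2)[1])
  z2 <- apply_scaler(sc2, tr2)
  expect_true(all(z2[[feature_columns(tr2)[1]]] == 0))
  expect_error(apply_scaler(list(), tr), "not a fitted")
})

test_that("feature tables round-trip bit-exactly through CSV", {
  tbl <- make_subject_table(epochs = 2, p = 6, seed = 10)
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(tbl, path)
  back <- read_feature_table(path)
  for (cl in feature_columns(tbl))
    expect_identical(back[[cl]], tbl[[cl]])
  expect_true(file.exists(paste0(path, ".json")))
})
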