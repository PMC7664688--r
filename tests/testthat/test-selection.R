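test_that("the built-in forest separates a planted signal and reports OOB", {
  b <- make_bench(seed = 2)
  f <- rf_fit(b$X, b$y, ntree = 100, seed = 1)
  expect_lt(f$oob_error, 0.25)
  pred <- predict(f, b$X)
  expect_gt(mean(pred == b$y), 0.9)
  # informative columns dominate the importance ranking
  top5 <- names(sort(f$importance, decreasing = TRUE))[1:5]
  expect_setequal(top5, paste0("info", 1:5))
  # deterministic given seed
  f2 <- rf_fit(b$X, b$y, ntree = 100, seed = 1)
  expect_identical(f$oob_error, f2$oob_error)
  expect_error(rf_fit(b$X, factor(rep("a", 300))), "2 classes")
})

test_that("boruta statuses partition columns; decisions are reproducible", {
  b <- make_bench(seed = 5)
  fd <- boruta_select(b$X, b$y, seed = 9)
  expect_setequal(fd$decisions$feature, colnames(b$X))
  expect_true(all(fd$decisions$status %in%
                    c("confirmed", "rejected", "tentative")))
  expect_setequal(
    fd$selected,
    fd$decisions$feature[fd$decisions$status != "rejected"])
  fd2 <- boruta_select(b$X, b$y, seed = 9)
  expect_identical(fd$decisions, fd2$decisions)
  expect_error(boruta_select(b$X, factor(rep("a", 300))), "2 classes")
})

test_that("boruta confirms nothing when labels are independent of X", {
  nonempty <- 0
  for (s in 1:20) {
    set.seed(100 + s)
    Xn <- matrix(rnorm(300 * 55), 300, 55)
    yn <- factor(rep(c("a", "b"), 150))
    fd <- boruta_select(Xn, yn, seed = s)
    if (any(fd$decisions$status == "confirmed")) nonempty <- nonempty + 1
  }
  expect_lte(nonempty, 1)  # empty confirmed set in >= 95% of 20 runs
})

test_that("varSelRF keeps a floor of two columns and honors contracts", {
  b <- make_bench(seed = 3)
  sel <- varselrf_select(b$X, b$y, seed = 4)
  expect_true(all(sel %in% colnames(b$X)))
  expect_gte(length(sel), 2)
  hist <- attr(sel, "history")
  expect_true(all(diff(hist$n_vars) < 0))
  expect_identical(as.character(varselrf_select(b$X, b$y, seed = 4)),
                   as.character(sel))
  # two informative columns in -> both retained
  X2 <- b$X[, 1:2]
  sel2 <- varselrf_select(X2, b$y, seed = 1)
  expect_setequal(as.character(sel2), colnames(X2))
})
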