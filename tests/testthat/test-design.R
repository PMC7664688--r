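test_that("design lays out the stated experiment and is seed-deterministic", {
  d <- make_design(25, 10, 10, seed = 7)
  expect_equal(nrow(d), 500)
  counts <- dplyr::count(d, subject, scenario_type)
  expect_true(all(counts$n == 10))
  # presentation orders are a permutation of 1..20 within subject
  for (s in unique(d$subject))
    expect_setequal(d$order[d$subject == s], 1:20)
  expect_identical(d, make_design(25, 10, 10, seed = 7))
  expect_false(identical(d$answer, make_design(25, 10, 10, seed = 8)$answer))
})

test_that("degenerate designs and argument errors behave as specified", {
  d1 <- make_design(1, 1, 0, yes_prob_by_type = c(insider = 1, conflict = 0),
                    dropout_prob = 0, seed = 1)
  expect_equal(nrow(d1), 1)
  expect_equal(d1$scenario_type, "insider")
  expect_equal(d1$answer, "yes")
  expect_error(make_design(-1, 10, 10), "integer|>=")
  expect_error(make_design(5, 5, 5, yes_prob_by_type = c(insider = 2,
                                                         conflict = 0.5)),
               "\\[0, 1\\]")
})

test_that("answer rates and dropout follow the configured probabilities", {
  d <- make_design(60, 10, 10, seed = 3)
  ins <- d[d$scenario_type == "insider", ]
  con <- d[d$scenario_type == "conflict", ]
  expect_equal(mean(ins$answer == "yes"), 96 / 242, tolerance = 0.1)
  expect_equal(mean(con$answer == "yes"), 150 / 248, tolerance = 0.1)
  expect_equal(mean(!d$answered), 0.02, tolerance = 0.012)
})

test_that("seed derivation is stable, in range, and sensitive to indices", {
  s1 <- derive_seed(1, 2, 3)
  expect_identical(s1, derive_seed(1, 2, 3))
  expect_true(s1 >= 1 && s1 < 2^31)
  expect_false(derive_seed(1, 2, 3) == derive_seed(1, 3, 2))
  expect_false(derive_seed(1, 2) == derive_seed(2, 2))
})
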