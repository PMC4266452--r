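test_that("Hill fraction remaining obeys its defining identities", {
  # half-maximal at C = IC50, for any potency
  for (p in c(0, 3, 6, 9)) {
    expect_equal(hill_fraction_remaining(pic50_to_ic50(p), p), 0.5)
  }
  # no compound, no block
  expect_identical(hill_fraction_remaining(0, 8), 1)
  # floored pIC50 of 0 produces 0.01% block at the top 100 uM concentration
  block_pct <- 100 * (1 - hill_fraction_remaining(100, 0))
  expect_equal(block_pct, 0.01, tolerance = 1e-3)
  # bounded in [0,1] and strictly decreasing in concentration
  cc <- 10^seq(-4, 3, length.out = 50)
  for (p in c(-2, 0, 4.5, 8)) {
    f <- hill_fraction_remaining(cc, p)
    expect_true(all(f >= 0 & f <= 1))
    expect_true(all(diff(f) < 0))
  }
  expect_error(hill_fraction_remaining(-1, 6), "non-negative")
  expect_error(hill_fraction_remaining(1, 6, n = 0), "positive")
})

test_that("pIC50 to IC50 conversion uses the molar convention", {
  expect_equal(pic50_to_ic50(6), 1)
  expect_equal(pic50_to_ic50(8), 0.01)   # e.g. a potent manual hERG value
  expect_equal(pic50_to_ic50(0), 1e6)    # floored: essentially inactive
  expect_error(pic50_to_ic50(NA), "finite")
  expect_error(pic50_to_ic50(Inf), "finite")
})

test_that("conductance scale factor is the Hill fraction of unblocked channels", {
  set.seed(42)
  cc <- 10^runif(30, -4, 2)
  pp <- runif(30, 0, 9)
  expect_identical(conductance_scale_factor(cc, pp),
                   hill_fraction_remaining(cc, pp))
  expect_identical(conductance_scale_factor(0, 5), 1)
})

test_that("one-parameter Hill fit recovers noise-free pIC50s (grid-search oracle)", {
  cc <- 10^seq(-2, 2, length.out = 8)
  for (true_p in c(3.5, 5, 7.25)) {
    frac <- hill_fraction_remaining(cc, true_p)
    # independent oracle: dense grid search minimising the SSE
    grid <- seq(0, 12, by = 1e-4)
    sse <- vapply(grid, function(p)
      sum((frac - 1 / (1 + cc * 10^(p - 6)))^2), numeric(1))
    oracle <- grid[which.min(sse)]
    fit <- fit_hill(cc, frac)
    expect_equal(fit$pic50, oracle, tolerance = 1e-3)
    expect_equal(fit$pic50, true_p, tolerance = 1e-3)
    expect_false(fit$floored)
    expect_identical(unname(coef(fit)["hill_coefficient"]), 1)
  }
})

test_that("flat or inactive concentration-effect data floor to pIC50 = 0", {
  cc <- 10^seq(-2, 2, length.out = 8)
  flat <- fit_hill(cc, rep(1, 8))
  expect_true(flat$floored)
  expect_identical(flat$pic50, 0)
  # nearly flat (all fractions > 0.95) also floors rather than erroring
  # a screen whose strongest response is under 5% block carries no usable
  # potency signal and is floored too, whatever its trend
  near <- fit_hill(cc, c(1, 1, 0.99, 1, 0.98, 1, 0.97, 0.96))
  expect_true(near$floored)
})

test_that("single-point fits solve the one-parameter curve exactly", {
  fit <- fit_hill(1, 0.5)       # C = IC50 forces pIC50 = 6
  expect_equal(fit$pic50, 6, tolerance = 1e-6)
  expect_true(fit$low_confidence)
})

test_that("Hill fit is scale-consistent in concentration units", {
  cc <- 10^seq(-1.5, 1.5, length.out = 7)
  frac <- hill_fraction_remaining(cc, 5.3)
  f1 <- fit_hill(cc, frac)
  f2 <- fit_hill(10 * cc, frac)
  expect_equal(f2$pic50, f1$pic50 - 1, tolerance = 1e-6)
})

test_that("Hill fit validates its inputs and clips raw fractions", {
  expect_error(fit_hill(numeric(0), numeric(0)), "no concentration")
  expect_error(fit_hill(c(1, 2), 0.5), "lengths differ")
  expect_error(fit_hill(c(0, 1), c(0.5, 0.5)), "strictly positive")
  # fractions outside [0,1] are clipped, not rejected
  fit <- fit_hill(c(0.1, 1, 10), c(1.08, 0.5, -0.02))
  expect_true(all(fit$data$fraction_remaining >= 0 &
                  fit$data$fraction_remaining <= 1))
  expect_equal(fit$pic50, 6, tolerance = 0.15)
})

test_that("hill_fit methods are coherent", {
  cc <- 10^seq(-2, 2, length.out = 8)
  frac <- hill_fraction_remaining(cc, 5)
  fit <- fit_hill(cc, frac)
  expect_equal(predict(fit, 10^(6 - fit$pic50)), 0.5, tolerance = 1e-6)
  expect_equal(sum(residuals(fit)^2), fit$residual_sse, tolerance = 1e-12)
  expect_output(print(fit), "pIC50")
})
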