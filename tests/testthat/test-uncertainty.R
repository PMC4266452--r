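test_that("pIC50 resampling is seeded, centred and floored", {
  pic <- c(IKr = 6, ICaL = 4, INa = 0)

  # degenerate distribution: zero variability reproduces the input
  d0 <- sample_pic50s(pic, assay_variability(0), n_samples = 5, seed = 7)
  expect_true(all(d0 == matrix(pic, 5, 3, byrow = TRUE)))

  # determinism
  d1 <- sample_pic50s(pic, assay_variability(0.2), 100, seed = 11)
  d2 <- sample_pic50s(pic, assay_variability(0.2), 100, seed = 11)
  expect_identical(d1, d2)

  # normal-sampling oracle: sample mean within 3 standard errors
  dd <- sample_pic50s(c(IKr = 6), assay_variability(0.2), 10000, seed = 3)
  expect_lt(abs(mean(dd) - 6), 3 * 0.2 / sqrt(10000))

  # floored affinities are perturbed around 0 and re-floored
  df <- sample_pic50s(c(Ito = 0), assay_variability(0.3), 2000, seed = 5)
  expect_true(all(df >= 0))
  expect_gt(mean(df == 0), 0.4)  # about half the mass refloors
  expect_gt(mean(df > 0), 0.4)

  expect_error(sample_pic50s(pic, assay_variability(-0.1), 10),
               "non-negative")
})

test_that("the percentile estimator matches a sort-based oracle", {
  set.seed(99)
  for (n in c(1, 2, 7, 40)) {
    x <- rnorm(n)
    for (p in c(0, 0.025, 0.5, 0.975, 1)) {
      s <- sort(x)
      h <- (n - 1) * p
      oracle <- if (n == 1) s[1] else {
        lo <- floor(h)
        if (lo + 1 >= n) s[n] else s[lo + 1] * (1 - (h - lo)) +
          s[lo + 2] * (h - lo)
      }
      expect_equal(percentile(x, p), oracle)
    }
  }
  # order statistics exactly at their ranks
  expect_identical(percentile(c(3, 1, 2), 0), 1)
  expect_identical(percentile(c(3, 1, 2), 0.5), 2)
  expect_identical(percentile(c(3, 1, 2), 1), 3)
})

test_that("zero assay variability collapses the credible band onto the curve", {
  grid <- c(0.1, 1)
  ctrl <- cached_control("tentusscher2006")
  bd <- credible_band("x", "tentusscher2006", grid = grid,
                      variability = assay_variability(0), n_samples = 3,
                      seed = 1, control = ctrl, convergence_tol = 1e-3,
                      max_paces_per_conc = 15,
                      pic50_override = c(IKr = 6.5))
  expect_equal(bd$band$delta_lower_ms, bd$curve$points$delta_apd90_ms)
  expect_equal(bd$band$delta_upper_ms, bd$curve$points$delta_apd90_ms)
  expect_true(all(bd$band$fraction_failed == 0))
})

test_that("the band brackets the point estimate and is seeded deterministically", {
  grid <- c(0.1, 1)
  ctrl <- cached_control("tentusscher2006")
  args <- list("x", "tentusscher2006", grid = grid,
               variability = assay_variability(c(IKr = 0.25)),
               n_samples = 40, seed = 21, control = ctrl,
               convergence_tol = 1e-3, max_paces_per_conc = 15,
               pic50_override = c(IKr = 6.5))
  bd <- do.call(credible_band, args)
  pts <- bd$curve$points$delta_apd90_ms
  expect_true(all(bd$band$delta_lower_ms <= pts + 1e-9))
  expect_true(all(bd$band$delta_upper_ms >= pts - 1e-9))
  bd2 <- do.call(credible_band, args)
  expect_identical(bd$band, bd2$band)
})

test_that("band width grows with assay variability", {
  # same seed: draws are mean + sigma * z with identical z, so widths are
  # exactly ordered provided no draw hits the floor at 0
  grid <- c(0.3, 3)
  ctrl <- cached_control("tentusscher2006")
  width_at <- function(sig) {
    bd <- credible_band("x", "tentusscher2006", grid = grid,
                        variability = assay_variability(c(IKr = sig)),
                        n_samples = 30, seed = 8, control = ctrl,
                        convergence_tol = 1e-3, max_paces_per_conc = 12,
                        pic50_override = c(IKr = 6))
    bd$band$delta_upper_ms - bd$band$delta_lower_ms
  }
  w_small <- width_at(0.1)
  w_large <- width_at(0.3)
  expect_true(all(w_large >= w_small - 0.01))
})
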