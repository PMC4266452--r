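test_that("free plasma concentration follows the unit algebra", {
  # cmax numerically equal to MW, fully unbound: exactly 1 uM
  expect_equal(free_plasma_concentration(250, 0, 250), 1)
  # fully bound: nothing free
  expect_identical(free_plasma_concentration(1000, 100, 300), 0)
  # hand arithmetic: (500 / 250) * 0.5 = 1 uM
  expect_equal(free_plasma_concentration(500, 50, 250), 1)
  # linear in cmax and in fraction unbound
  expect_equal(free_plasma_concentration(1000, 50, 250),
               2 * free_plasma_concentration(500, 50, 250))
  expect_equal(free_plasma_concentration(500, 75, 250),
               0.5 * free_plasma_concentration(500, 50, 250))
  expect_error(free_plasma_concentration(500, 50, 0), "positive")
  expect_error(free_plasma_concentration(500, 150, 250), "0, 100")
  expect_error(free_plasma_concentration(-1, 50, 250), "non-negative")
})

test_that("classification honours the fold-change evaluation window", {
  # a curve crossing 5 ms at 1 uM
  cv <- fake_curve(10^seq(-3, 2, length.out = 11),
                   c(0, 0, 0, 0, 0, 1, 3, 10, 20, 30, 40))
  expect_false(classify(cv, tqt_conc = 0.05, fold_window = 1))
  expect_true(classify(cv, tqt_conc = 0.05, fold_window = 100))

  # flat zero curve is negative whatever the window
  flat <- fake_curve(10^seq(-3, 2, length.out = 5), rep(0, 5))
  for (w in c(1, 10, 100, 1e6))
    expect_false(classify(flat, 0.1, fold_window = w))

  # the threshold is inclusive
  at5 <- fake_curve(c(0.01, 1, 100), c(5, 5, 5))
  expect_true(classify(at5, 1, fold_window = 1))

  # repolarisation failure inside the window counts as positive
  rf <- fake_curve(c(0.01, 1, 100), c(0, NA, 0),
                   flag = c(NA, "repolarisation_failure", NA))
  expect_true(classify(rf, 1, fold_window = 1))
  expect_true(classify(rf, 0.1, fold_window = 100))
  # between a numeric point and a failed one the curve is not evaluable
  expect_true(is.na(classify(rf, 0.011, fold_window = 1)))

  # a window entirely off the grid clamps with a warning
  expect_warning(out <- classify(flat, 1e8, fold_window = 1),
                 "outside the concentration grid")
  expect_false(out)
})

test_that("point classification equals thresholded interpolation", {
  set.seed(4)
  for (r in 1:20) {
    delta <- cumsum(runif(8, -2, 6))
    cv <- fake_curve(10^seq(-3, 2, length.out = 8), delta)
    conc <- 10^runif(1, -3, 2)
    expect_identical(classify(cv, conc, fold_window = 1),
                     interpolate_delta(cv, conc) >= 5)
  }
})

test_that("predictions are monotone in the fold window", {
  set.seed(5)
  folds <- c(1, 3, 10, 30, 100)
  for (r in 1:30) {
    delta <- cumsum(runif(10, -3, 5))
    cv <- fake_curve(10^seq(-3, 2, length.out = 10), delta)
    conc <- 10^runif(1, -4, 3)
    pred <- vapply(folds, function(w)
      suppressWarnings(classify(cv, conc, fold_window = w)), logical(1))
    expect_true(all(diff(as.integer(pred)) >= 0))
  }
})

test_that("contingency metrics follow their definitions exactly", {
  # TP=2, FN=1, FP=0, TN=3
  ct <- build_contingency(predicted = c(TRUE, TRUE, FALSE, FALSE, FALSE,
                                        FALSE),
                          delta_qtc = c(10, 6, 8, 2, -1, 0))
  expect_identical(c(ct$tp, ct$fp, ct$tn, ct$fn), c(2L, 0L, 3L, 1L))
  expect_equal(ct$sensitivity, 100 * 2 / 3)
  expect_equal(ct$specificity, 100)
  expect_equal(ct$accuracy, 100 * 5 / 6)
  expect_output(print(ct), "sensitivity 67%")

  # all correct
  perfect <- build_contingency(c(TRUE, FALSE, TRUE), c(6, 1, 12))
  expect_equal(c(perfect$sensitivity, perfect$specificity,
                 perfect$accuracy), c(100, 100, 100))

  # no observed positives: sensitivity undefined, not zero
  none <- build_contingency(c(FALSE, TRUE), c(0, 1))
  expect_true(is.na(none$sensitivity))
  expect_output(print(none), "undefined")

  # the observation threshold is inclusive at exactly 5 ms
  edge <- build_contingency(c(TRUE), c(5))
  expect_identical(edge$tp, 1L)

  # identities on random tables
  set.seed(6)
  for (r in 1:10) {
    n <- 20
    pred <- runif(n) > 0.5
    dq <- runif(n, -5, 15)
    ct <- build_contingency(pred, dq)
    expect_identical(ct$tp + ct$fn, sum(dq >= 5))
    expect_equal(ct$accuracy,
                 (ct$sensitivity * (ct$tp + ct$fn) +
                  ct$specificity * (ct$tn + ct$fp)) / ct$n,
                 tolerance = 1e-12)
  }
})

test_that("the performance summary scores every model/dataset/window cell", {
  grid <- 10^seq(-3, 2, length.out = 8)
  # three synthetic compounds: a strong prolonger (crosses 5 ms well below
  # its TQT concentration), a mild one crossing inside a 10x window, and a
  # clean negative
  curves <- list(
    fake_curve(grid, c(0, 2, 8, 15, 25, 30, 35, 40)),
    fake_curve(grid, c(0, 0, 0, 2, 8, 15, 25, 40)),
    fake_curve(grid, rep(0, 8)))
  curves[[1]]$compound_id <- "a"
  curves[[2]]$compound_id <- "b"
  curves[[3]]$compound_id <- "c"
  tqt <- data.frame(compound_id = c("a", "b", "c"),
                    free_conc_uM = c(1, 0.1, 1),
                    delta_qtc_ms = c(12, 9, 0))

  tab <- summary_table(curves, tqt, fold_windows = c(1, 10, 100))
  expect_identical(nrow(tab), 3L)
  # single model/dataset row equals the direct contingency computation
  direct <- build_contingency(
    vapply(curves, function(cv)
      classify(cv, tqt$free_conc_uM[match(cv$compound_id,
                                          tqt$compound_id)],
               fold_window = 10), logical(1)),
    tqt$delta_qtc_ms)
  row10 <- tab[tab$fold_window == 10, ]
  expect_identical(c(row10$tp, row10$fp, row10$tn, row10$fn),
                   c(direct$tp, direct$fp, direct$tn, direct$fn))
  # widening the window never decreases sensitivity
  expect_true(all(diff(tab$sensitivity[order(tab$fold_window)]) >= 0))
  # every true crossing lies inside the 10x window here: full sensitivity
  expect_equal(row10$sensitivity, 100)
  expect_equal(row10$specificity, 100)
})
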