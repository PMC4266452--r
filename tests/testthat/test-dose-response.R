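test_that("the default concentration grid spans 1 nM to 100 uM in 20 log steps", {
  g <- make_grid()
  expect_length(g, 20)
  expect_equal(g[1], 1e-3)
  expect_equal(g[20], 100)
  steps <- diff(log10(g))
  expect_equal(steps, rep(5 / 19, 19))

  expect_identical(make_grid(n = 2), c(1e-3, 100))
  expect_error(make_grid(c_min = 1, c_max = 0.1), "c_max > c_min")
  expect_error(make_grid(n = 1), "at least 2")
})

test_that("dataset definitions pick the right screening source per channel", {
  panel <- load_pic50_table()
  dof <- panel[panel$compound_id == "dofetilide", ]

  # zero concentration: control conditions whatever the dataset
  expect_equal(assemble_scale_factors(dof, "Q", 0),
               setNames(rep(1, 6), channel_handles()))

  # manual hERG pIC50 8.0 => IC50 = 0.01 uM, so factor 0.5 at 0.01 uM
  mq <- assemble_scale_factors(dof, "MQ", 0.01)
  expect_equal(unname(mq["IKr"]), 0.5)
  # under Q the hERG value is 6.9, much weaker block at the same conc
  q <- assemble_scale_factors(dof, "Q", 0.01)
  expect_gt(q["IKr"], 0.9)
  # MQ differs from Q only through IKr
  expect_equal(mq[setdiff(channel_handles(), "IKr")],
               q[setdiff(channel_handles(), "IKr")])

  # B&Q2 has no Kv4.3 screen: Ito unblocked at every concentration
  for (conc in c(0.01, 1, 100))
    expect_identical(unname(
      assemble_scale_factors(dof, "BQ2", conc)["Ito"]), 1)
  # IK1 is never screened
  expect_identical(unname(q["IK1"]), 1)

  # a compound without Barracuda data cannot be evaluated under B&Q2
  alv <- panel[panel$compound_id == "alvimopan", ]
  expect_error(assemble_scale_factors(alv, "BQ2", 1), "alvimopan")
  expect_error(assemble_scale_factors(dof, "XX", 1), "unknown dataset")
})

test_that("log-linear interpolation reads curves exactly and clamps", {
  cv <- fake_curve(c(0.01, 0.1, 1, 10), c(0, 10, 20, 40))
  # interpolation identity at grid points
  expect_equal(interpolate_delta(cv, 0.1), 10)
  expect_equal(interpolate_delta(cv, 10), 40)
  # linear in log10-concentration halfway between grid points
  expect_equal(interpolate_delta(cv, 10^mean(log10(c(0.01, 0.1)))), 5)
  # clamped outside the grid
  expect_equal(interpolate_delta(cv, 1e-5), 0)
  expect_equal(interpolate_delta(cv, 1e4), 40)
  expect_error(interpolate_delta(cv, -1), "concentration > 0")

  # flagged bracketing points propagate the flag
  fl <- fake_curve(c(0.01, 0.1, 1), c(0, NA, 20),
                   flag = c(NA, "repolarisation_failure", NA))
  d <- interpolate_delta(fl, 0.05)
  expect_true(is.na(d))
  expect_identical(attr(d, "flag"), "repolarisation_failure")
})

test_that("an inactive compound produces a flat dose-response curve", {
  grid <- c(1e-3, 0.1, 10, 100)
  ctrl <- cached_control("tentusscher2006")
  inert <- setNames(rep(0, 5), c("IKr", "IKs", "INa", "ICaL", "Ito"))
  cv <- run_sweep("inert", "tentusscher2006", grid = grid, control = ctrl,
                  convergence_tol = 1e-3, max_paces_per_conc = 30,
                  pic50_override = inert)
  expect_identical(nrow(cv$points), length(grid))
  expect_true(all(is.na(cv$points$flag)))
  expect_true(all(abs(cv$points$delta_apd90_ms) < 0.5))
  expect_true(!is.unsorted(cv$points$concentration_uM))
})

test_that("identical pIC50 inputs give identical curves (MQ vs Q equivalence)", {
  panel <- load_pic50_table()
  dof <- panel[panel$compound_id == "dofetilide", ]
  # force the manual hERG value equal to the Quattro one; the MQ and Q
  # datasets then resolve to the same pIC50 vector and must give the same
  # curve (the protocol is deterministic)
  dof$pic50[dof$channel == "IKr" & dof$source == "M"] <-
    dof$pic50[dof$channel == "IKr" & dof$source == "Q"]
  grid <- c(1e-3, 0.1, 10)
  ctrl <- cached_control("tentusscher2006")
  a <- run_sweep("dofetilide", "tentusscher2006", "Q", panel = dof,
                 grid = grid, control = ctrl, convergence_tol = 1e-3,
                 max_paces_per_conc = 20)
  b <- run_sweep("dofetilide", "tentusscher2006", "MQ", panel = dof,
                 grid = grid, control = ctrl, convergence_tol = 1e-3,
                 max_paces_per_conc = 20)
  expect_identical(a$points$apd90_ms, b$points$apd90_ms)
})

test_that("warm-started and cold-started sweeps agree (no hysteresis)", {
  grid <- c(0.03, 0.3, 3)
  ctrl <- cached_control("tentusscher2006")
  pic <- c(IKr = 6)  # moderate pure hERG blocker
  warm <- run_sweep("x", "tentusscher2006", grid = grid, control = ctrl,
                    convergence_tol = 1e-4, max_paces_per_conc = 80,
                    pic50_override = pic, warm_start = TRUE)
  cold <- run_sweep("x", "tentusscher2006", grid = grid, control = ctrl,
                    convergence_tol = 1e-4, max_paces_per_conc = 80,
                    pic50_override = pic, warm_start = FALSE)
  expect_true(all(abs(warm$points$apd90_ms - cold$points$apd90_ms) < 1))
})

test_that("curve serialisation round-trips through CSV", {
  cv <- fake_curve(c(0.01, 0.1, 1), c(0, 5, NA),
                   flag = c(NA, NA, "repolarisation_failure"))
  path <- tempfile(fileext = ".csv")
  write_dose_response(cv, path)
  back <- read.csv(path)
  expect_equal(back$delta_apd90_ms[1:2], c(0, 5))
  expect_identical(back$flag[3], "repolarisation_failure")
  unlink(path)
})
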