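test_that("the bundled screening panel matches its printed source values", {
  panel <- load_pic50_table()
  expect_identical(length(unique(panel$compound_id)), 34L)
  expect_true(all(panel$pic50 >= 0))

  pick <- function(id, ch, src)
    panel$pic50[panel$compound_id == id & panel$channel == ch &
                panel$source == src]
  # spot values
  expect_identical(pick("dofetilide", "IKr", "Q"), 6.9)
  expect_identical(pick("dofetilide", "IKr", "B"), 6.2)
  expect_identical(pick("dofetilide", "IKr", "M"), 8.0)
  expect_identical(pick("paliperidone", "IKr", "M"), 5.9)
  expect_identical(pick("alvimopan", "Ito", "Q"), 0)
  # a compound outside the 26-compound Barracuda screen has no B rows
  expect_identical(length(pick("alvimopan", "IKr", "B")), 0L)
  # the manual hERG column is complete
  herg_m <- panel[panel$channel == "IKr" & panel$source == "M", ]
  expect_identical(nrow(herg_m), 34L)
  # the Barracuda screen covers 26 compounds
  expect_identical(length(unique(panel$compound_id[panel$source == "B"])),
                   26L)
  # compound ids are normalised, display names preserved
  expect_true(all(panel$compound_id == tolower(panel$display_name)))
})

test_that("the panel round-trips through CSV bit-identically", {
  panel <- load_pic50_table()
  path <- tempfile(fileext = ".csv")
  write_pic50_table(panel, path)
  again <- load_pic50_table(path)
  rownames(panel) <- rownames(again) <- NULL
  expect_identical(again, panel)
  unlink(path)
})

test_that("the concentration-effect generator is exact and seeded", {
  pts <- generate_concentration_effect(6, noise_sd = 0, n_points = 8,
                                       seed = 1)
  expect_equal(pts$fraction_remaining,
               hill_fraction_remaining(pts$concentration_uM, 6))
  a <- generate_concentration_effect(5, noise_sd = 0.05, seed = 42)
  b <- generate_concentration_effect(5, noise_sd = 0.05, seed = 42)
  expect_identical(a, b)
  expect_true(all(a$fraction_remaining >= 0 & a$fraction_remaining <= 1))
})

test_that("fitting generator output recovers the generating pIC50", {
  pts <- generate_concentration_effect(5.5, noise_sd = 0.02, n_points = 8,
                                       seed = 9)
  fit <- fit_hill(pts$concentration_uM, pts$fraction_remaining)
  expect_lt(abs(fit$pic50 - 5.5), 0.2)
})

test_that("the synthetic TQT cohort is schema-valid with usable truth labels", {
  one <- generate_synthetic_tqt(1, seed = 2)
  expect_identical(nrow(one), 1L)
  expect_true(all(c("compound_id", "cmax_ng_per_ml", "percent_bound",
                    "molecular_weight", "delta_qtc_ms", "true_positive",
                    "free_conc_uM") %in% names(one)))
  expect_identical(generate_synthetic_tqt(10, seed = 3),
                   generate_synthetic_tqt(10, seed = 3))

  co <- generate_synthetic_tqt(200, effect_model = "mixed",
                               prop_positive = 0.4, seed = 4)
  expect_true(all(co$molecular_weight >= 200 & co$molecular_weight <= 700))
  expect_true(all(co$percent_bound >= 0 & co$percent_bound <= 100))
  expect_equal(co$free_conc_uM,
               free_plasma_concentration(co$cmax_ng_per_ml,
                                         co$percent_bound,
                                         co$molecular_weight))
  expect_identical(sum(co$true_positive), 80L)

  # under the null effect model the observed-positive rate matches the
  # closed-form normal tail P(N(0,2) >= 5) ~ 0.62%
  nul <- generate_synthetic_tqt(3000, effect_model = "null", seed = 5)
  rate <- mean(nul$delta_qtc_ms >= 5)
  p <- pnorm(5, 0, 2, lower.tail = FALSE)
  expect_lt(abs(rate - p), 3 * sqrt(p * (1 - p) / 3000) + 1e-3)
})

test_that("the command-line front end wires the package end to end", {
  cli <- system.file("cli", "qtsim", package = "qtsim", mustWork = TRUE)
  rscript <- file.path(R.home("bin"), "Rscript")
  tmp <- tempfile("cli")
  dir.create(tmp)

  run_cli <- function(...) {
    res <- suppressWarnings(
      system2(rscript, c(cli, ...), stdout = TRUE, stderr = TRUE))
    status <- attr(res, "status")
    if (is.null(status)) status <- 0L
    list(status = status, output = res)
  }

  # synth -> fit round trip
  pfile <- file.path(tmp, "points.csv")
  r <- run_cli("synth", "--what", "points", "--pic50", "6", "--n", "8",
               "--seed", "3", "--output", pfile)
  expect_identical(r$status, 0L)
  ffile <- file.path(tmp, "fits.csv")
  r <- run_cli("fit", "--input", pfile, "--output", ffile)
  expect_identical(r$status, 0L)
  fits <- read.csv(ffile)
  expect_lt(abs(fits$pic50[1] - 6), 0.2)

  # a small sweep
  cfile <- file.path(tmp, "curve.csv")
  r <- run_cli("sweep", "--model", "tentusscher2006", "--dataset", "MQ",
               "--compound", "dofetilide", "--n-grid", "3",
               "--max-paces", "40", "--max-paces-per-conc", "10",
               "--convergence-tol", "1e-2", "--output", cfile)
  expect_identical(r$status, 0L)
  curve <- read.csv(cfile)
  expect_identical(nrow(curve), 3L)
  expect_identical(curve$dataset[1], "MQ")

  # evaluate the curve against a tiny hand-written TQT table
  tfile <- file.path(tmp, "tqt.csv")
  write.csv(data.frame(compound_id = "dofetilide", free_conc_uM = 0.01,
                       delta_qtc_ms = 20),
            tfile, row.names = FALSE)
  sfile <- file.path(tmp, "summary.csv")
  r <- run_cli("evaluate", "--curves", cfile, "--tqt", tfile,
               "--window", "100", "--output", sfile)
  expect_identical(r$status, 0L)
  expect_true(file.exists(sfile))

  # unknown subcommands exit 2 with usage
  r <- run_cli("frobnicate")
  expect_identical(r$status, 2L)

  unlink(tmp, recursive = TRUE)
})
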