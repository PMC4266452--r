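test_that("the registry instantiates the three published models", {
  tt <- ap_model("tentusscher2006")
  expect_identical(tt$variant, "epicardial")
  expect_identical(tt$n_state, 19L)
  expect_identical(length(tt$state), 19L)

  gr <- ap_model("grandi2010")
  expect_identical(gr$variant, "epicardial")
  expect_identical(gr$n_state, 39L)

  oh <- ap_model("ohara2011")
  expect_identical(oh$variant, "endocardial")
  expect_identical(oh$n_state, 41L)

  expect_error(ap_model("noble1962"), "registered models")
  expect_setequal(list_models(),
                  c("tentusscher2006", "grandi2010", "ohara2011"))
})

test_that("models are quiescent at their published resting state without stimulus", {
  for (nm in list_models()) {
    mdl <- ap_model(nm)
    d <- evaluate_derivatives(mdl, mdl$state, t = 500)  # stimulus off
    expect_lt(abs(d[["V"]]), 0.1)
  }
})

test_that("conductance block scales each current linearly", {
  # I = g * (driving terms) implies the derivative vector is affine in each
  # scale factor: f(1) - 2 f(0.5) + f(0) == 0 componentwise.
  for (nm in list_models()) {
    base <- ap_model(nm)
    # probe during the plateau of a pace so every current is active
    tr <- reference_rk4(base, t_end = 120, dt = 0.002, sample_dt = 10)
    state <- tr[nrow(tr), -1]
    for (ch in channel_handles()) {
      d1 <- evaluate_derivatives(base, state, t = 500)
      dh <- evaluate_derivatives(apply_block(base, setNames(0.5, ch)),
                                 state, t = 500)
      d0 <- evaluate_derivatives(apply_block(base, setNames(0, ch)),
                                 state, t = 500)
      expect_equal(d1 - 2 * dh + d0, d1 * 0, tolerance = 1e-10)
      # a 0.5 factor changes the model unless the current is truly zero here
      if (ch %in% c("IKr", "ICaL"))
        expect_false(isTRUE(all.equal(d1, dh)))
    }
  }
})

test_that("apply_block validates factors and restores control exactly", {
  mdl <- ap_model("ohara2011")
  expect_error(apply_block(mdl, c(IKr = 1.5)), "\\[0, 1\\]")
  expect_error(apply_block(mdl, c(IKx = 0.5)), "unknown channel")
  expect_error(apply_block(mdl, 0.5), "named")

  blocked <- apply_block(mdl, c(IKr = 0.3, ICaL = 0.7))
  restored <- apply_block(blocked, setNames(rep(1, 6), channel_handles()))
  expect_identical(restored$scale, mdl$scale)
  st <- mdl$state
  expect_identical(evaluate_derivatives(restored, st),
                   evaluate_derivatives(mdl, st))
})

test_that("gate variables cannot leave [0, 1]", {
  for (nm in list_models()) {
    mdl <- ap_model(nm)
    for (V in c(-90, -40, 0, 30)) {
      st <- mdl$state
      st[1] <- V
      st0 <- st; st0[mdl$gate_index] <- 0
      d0 <- evaluate_derivatives(mdl, st0, t = 500)
      expect_true(all(d0[mdl$gate_index] >= -1e-12))
      st1 <- st; st1[mdl$gate_index] <- 1
      d1 <- evaluate_derivatives(mdl, st1, t = 500)
      expect_true(all(d1[mdl$gate_index] <= 1e-12))
    }
  }
})

test_that("evaluate_derivatives reports the offending state variable on NaN", {
  mdl <- ap_model("tentusscher2006")
  st <- mdl$state
  st[4] <- NaN
  expect_error(evaluate_derivatives(mdl, st), "Cai")
})

test_that("the Ito handle scales only the fast component in grandi2010", {
  mdl <- ap_model("grandi2010")
  st <- mdl$state
  st[1] <- 20  # depolarised so Ito would conduct if open
  # fast Ito gates shut, slow Ito open: the Kv4.3 block handle must not act
  st[mdl$state_names == "xtof"] <- 0
  st[mdl$state_names == "ytof"] <- 0
  st[mdl$state_names == "xtos"] <- 0.5
  st[mdl$state_names == "ytos"] <- 0.5
  d_ctrl <- evaluate_derivatives(mdl, st, t = 500)
  d_blk <- evaluate_derivatives(apply_block(mdl, c(Ito = 0.2)), st, t = 500)
  expect_identical(d_ctrl, d_blk)
  # fast Ito open: the handle must act
  st[mdl$state_names == "xtof"] <- 0.5
  st[mdl$state_names == "ytof"] <- 0.5
  d_ctrl2 <- evaluate_derivatives(mdl, st, t = 500)
  d_blk2 <- evaluate_derivatives(apply_block(mdl, c(Ito = 0.2)), st, t = 500)
  expect_false(isTRUE(all.equal(d_ctrl2[["V"]], d_blk2[["V"]])))
  # in the single-Ito models the same manoeuvre on the whole current acts
  tt <- ap_model("tentusscher2006")
  stt <- tt$state
  stt[1] <- 20
  stt[tt$state_names == "r"] <- 0.5
  stt[tt$state_names == "s"] <- 0.5
  expect_false(isTRUE(all.equal(
    evaluate_derivatives(tt, stt, t = 500)[["V"]],
    evaluate_derivatives(apply_block(tt, c(Ito = 0.2)), stt,
                         t = 500)[["V"]])))
})
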