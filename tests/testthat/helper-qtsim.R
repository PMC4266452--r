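# Shared fixtures for the test suite.
#
# Control steady-state solves are cached per (model, tolerance) so that the
# dose-response, uncertainty and acceptance tests reuse them.  Tests run the
# pacing protocol at reduced problem sizes (moderate pace caps and a looser
# steady-state tolerance) to keep the suite quick; the protocol itself is
# identical to the full-rigour defaults.

.qtsim_cache <- new.env(parent = emptyenv())

cached_control <- function(model_name, convergence_tol = 2e-6,
                           max_paces = 600) {
  key <- sprintf("%s_%g_%d", model_name, convergence_tol, max_paces)
  if (is.null(.qtsim_cache[[key]])) {
    .qtsim_cache[[key]] <- pace_to_steady_state(
      ap_model(model_name), convergence_tol = convergence_tol,
      max_paces = max_paces)
  }
  .qtsim_cache[[key]]
}

control_apd90 <- function(model_name, ...) {
  res <- cached_control(model_name, ...)
  compute_apd(res$trace, pacing_period = res$period_ms)$apd90
}

# APD90 after applying a block to a model, starting from the cached control
# state.  Returns the compute_apd() result (so flags are visible).
blocked_apd <- function(model_name, factors, max_paces = 40,
                        convergence_tol = 1e-3) {
  ctrl <- cached_control(model_name)
  mdl <- apply_block(ap_model(model_name), factors)
  res <- pace_to_steady_state(mdl, initial_state = ctrl$final_state,
                              convergence_tol = convergence_tol,
                              max_paces = max_paces)
  compute_apd(res$trace, pacing_period = res$period_ms)
}

# A hand-built dose-response object with prescribed delta values, for
# interpolation/classification tests that need exact curves.
fake_curve <- function(conc, delta, flag = rep(NA_character_, length(conc)),
                       control = 300) {
  structure(list(
    compound_id = "synthetic", model_name = "none", dataset = "Q",
    control_apd90 = control, pic50s = c(IKr = NA_real_),
    points = data.frame(concentration_uM = conc,
                        apd90_ms = control + delta,
                        delta_apd90_ms = delta, flag = flag,
                        stringsAsFactors = FALSE)),
    class = "dose_response")
}
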