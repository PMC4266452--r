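#' Adaptive solver settings
#'
#' Settings for the stiff adaptive integrator used to pace the models:
#' relative tolerance 1e-6, absolute tolerance 1e-8, and a maximum time step
#' smaller than the stimulus duration (so the square stimulus pulse is never
#' stepped over).
#'
#' @param rel_tol relative tolerance.
#' @param abs_tol absolute tolerance.
#' @param max_step maximum internal step in ms, or NULL to use half the
#'   stimulus duration of the model being paced.
#' @return a list of class \code{"solver_settings"}.
#' @export
solver_settings <- function(rel_tol = 1e-6, abs_tol = 1e-8, max_step = NULL) {
  stopifnot(rel_tol > 0, abs_tol > 0, is.null(max_step) || max_step > 0)
  structure(list(rel_tol = rel_tol, abs_tol = abs_tol, max_step = max_step),
            class = "solver_settings")
}

# One pace of the compiled model through deSolve's stiff adaptive solver.
# `times` must start at 0 (pace onset).  Returns the deSolve output matrix.
.integrate_pace <- function(model, state, times, solver) {
  hmax <- solver$max_step
  if (is.null(hmax)) hmax <- model$stimulus$duration / 2
  if (hmax >= model$stimulus$duration)
    stop("max_step must be smaller than the stimulus duration", call. = FALSE)
  fns <- list(
    c("qtsim_deriv_tt06", "qtsim_init_tt06"),
    c("qtsim_deriv_grandi", "qtsim_init_grandi"),
    c("qtsim_deriv_ohara", "qtsim_init_ohara"))[[model$model_id]]
  out <- deSolve::lsoda(
    y = as.numeric(state), times = times, func = fns[1],
    parms = as.numeric(.model_parms(model)), dllname = "qtsim",
    initfunc = fns[2], rtol = solver$rel_tol, atol = solver$abs_tol,
    hmax = hmax, maxsteps = 50000)
  if (attr(out, "istate")[1] < 0)
    stop(sprintf("integration failure near t = %.3f ms",
                 attr(out, "rstate")[1]), call. = FALSE)
  out
}

#' Pace a model at a fixed rate to pseudo-steady state
#'
#' Paces the model pace by pace with the adaptive stiff solver and declares
#' pseudo-steady state when the relative 2-norm of the change in the full
#' state vector between successive pace onsets drops below
#' \code{convergence_tol}.  The final pace is re-integrated with dense output
#' to produce a sampled voltage trace for APD measurement.
#'
#' @param model an [ap_model()] object (with any block factors applied).
#' @param initial_state optional starting state; defaults to the model's
#'   published initial conditions, or to the model's current \code{$state}
#'   if it has been updated by a previous call.
#' @param rate pacing rate in Hz (period = 1000/rate ms).
#' @param solver a [solver_settings()] object.
#' @param convergence_tol relative state-change tolerance between pace
#'   onsets (default 1e-6).
#' @param max_paces upper bound on the number of paces (default 10000).
#' @param sample_dt trace sampling interval in ms for the final pace.
#' @return an object of class \code{"pacing_result"}: \code{final_state}
#'   (state at the onset of the final pace), \code{n_paces},
#'   \code{converged}, and \code{trace}, a data.frame with columns
#'   \code{time_ms} and \code{V_mV} covering the final pace.
#' @export
pace_to_steady_state <- function(model, initial_state = NULL, rate = 1,
                                 solver = solver_settings(),
                                 convergence_tol = 1e-6, max_paces = 10000,
                                 sample_dt = 0.1) {
  stopifnot(inherits(model, "ap_model"), rate > 0, max_paces >= 1)
  period <- 1000 / rate
  if (abs(period - model$stimulus$period) > 1e-9) {
    model$stimulus$period <- period
  }
  state <- if (is.null(initial_state)) model$state else as.numeric(initial_state)
  if (length(state) != model$n_state)
    stop("initial state must have length ", model$n_state, call. = FALSE)

  converged <- FALSE
  n_paces <- 0L
  for (k in seq_len(max_paces)) {
    out <- .integrate_pace(model, state, c(0, period), solver)
    new_state <- as.numeric(out[nrow(out), -1])
    n_paces <- k
    delta <- sqrt(sum((new_state - state)^2)) / max(sqrt(sum(state^2)), 1e-12)
    state <- new_state
    if (delta < convergence_tol) {
      converged <- TRUE
      break
    }
  }

  times <- seq(0, period, by = sample_dt)
  if (times[length(times)] < period) times <- c(times, period)
  dense <- .integrate_pace(model, state, times, solver)
  vi <- model$v_index + 1L  # first column of deSolve output is time
  trace <- data.frame(time_ms = dense[, 1], V_mV = dense[, vi])

  structure(list(final_state = setNames(state, model$state_names),
                 n_paces = n_paces, converged = converged,
                 period_ms = period, trace = trace,
                 model_name = model$name),
            class = "pacing_result")
}

#' @export
print.pacing_result <- function(x, ...) {
  apd <- compute_apd(x$trace, pacing_period = x$period_ms)
  cat(sprintf("Pacing result for %s: %d pace(s), %s\n", x$model_name,
              x$n_paces,
              if (x$converged) "converged" else "NOT converged (max paces)"))
  if (!is.na(apd$apd90))
    cat(sprintf("  APD90 of final pace: %.2f ms\n", apd$apd90))
  else
    cat(sprintf("  final pace flagged: %s\n",
                if (apd$repolarisation_failure) "repolarisation failure"
                else "no depolarisation"))
  invisible(x)
}

#' Action potential duration at a given repolarisation percentage
#'
#' Measures APD from a sampled single-pace voltage trace.  The baseline is
#' the voltage at pace onset (pre-stimulus), the amplitude is peak minus
#' baseline, and the threshold is \code{peak - percent/100 * amplitude}.
#' APD is the time from the point of maximum upstroke velocity to the first
#' downward crossing of the threshold, with linear interpolation between
#' samples.  An amplitude below 10 mV is flagged as no depolarisation; a
#' missing downward crossing within the pace is flagged as repolarisation
#' failure (the cell remains at depolarised potentials).
#'
#' @param trace data.frame with columns \code{time_ms} and \code{V_mV}
#'   covering one full pace, sorted by time.
#' @param repolarisation_percent percentage of repolarisation (default 90).
#' @param pacing_period pace length in ms.
#' @return a list with \code{apd90} (ms, NA when undefined) and logical
#'   flags \code{repolarisation_failure} and \code{no_depolarisation}.
#' @export
compute_apd <- function(trace, repolarisation_percent = 90,
                        pacing_period = 1000) {
  if (is.matrix(trace)) trace <- data.frame(time_ms = trace[, 1],
                                            V_mV = trace[, 2])
  if (!all(c("time_ms", "V_mV") %in% names(trace)))
    stop("trace needs columns 'time_ms' and 'V_mV'", call. = FALSE)
  tt <- trace$time_ms
  vv <- trace$V_mV
  if (length(tt) < 3L) stop("trace too short", call. = FALSE)
  if (is.unsorted(tt, strictly = FALSE))
    stop("trace times must be sorted", call. = FALSE)

  res <- list(apd90 = NA_real_, repolarisation_failure = FALSE,
              no_depolarisation = FALSE)

  baseline <- vv[1]
  ipeak <- which.max(vv)
  peak <- vv[ipeak]
  amplitude <- peak - baseline
  if (amplitude < 10) {
    res$no_depolarisation <- TRUE
    return(res)
  }
  threshold <- peak - repolarisation_percent / 100 * amplitude

  dv <- diff(vv) / pmax(diff(tt), 1e-12)
  iup <- which.max(dv)
  t_up <- tt[iup]

  # first downward crossing of the threshold after the peak
  after <- seq(max(ipeak, iup), length(vv) - 1L)
  cross <- after[vv[after] > threshold & vv[after + 1L] <= threshold]
  if (length(cross) == 0L) {
    res$repolarisation_failure <- TRUE
    return(res)
  }
  i <- cross[1L]
  frac <- (vv[i] - threshold) / (vv[i] - vv[i + 1L])
  t_cross <- tt[i] + frac * (tt[i + 1L] - tt[i])
  res$apd90 <- t_cross - t_up
  res
}

#' Change in APD90 between drug and control
#'
#' @param apd_drug APD90 under compound (ms), or the result of
#'   [compute_apd()].
#' @param apd_control control APD90 (ms), or a [compute_apd()] result.
#' @return the prolongation in ms (positive = prolongation), or \code{NA}
#'   carrying a \code{"flag"} attribute when either input is flagged.
#' @export
delta_apd90 <- function(apd_drug, apd_control) {
  flag_of <- function(x) {
    if (is.list(x)) {
      if (isTRUE(x$repolarisation_failure)) return("repolarisation_failure")
      if (isTRUE(x$no_depolarisation)) return("no_depolarisation")
      if (is.na(x$apd90)) return("undefined")
    } else if (is.na(x)) return("undefined")
    NULL
  }
  val_of <- function(x) if (is.list(x)) x$apd90 else x
  fl <- c(flag_of(apd_drug), flag_of(apd_control))
  if (length(fl))
    return(structure(NA_real_, flag = fl[1]))
  val_of(apd_drug) - val_of(apd_control)
}
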