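#' Logarithmic concentration grid
#'
#' The default sweep covers 1 nM to 100 uM in 20 points equally spaced on a
#' log10 scale (endpoints included).
#'
#' @param c_min lowest concentration (micromolar).
#' @param c_max highest concentration (micromolar).
#' @param n number of grid points (>= 2).
#' @return numeric vector of concentrations in micromolar, increasing.
#' @examples
#' make_grid()          # 20 points, 1e-3 .. 1e2 uM
#' make_grid(n = 2)     # just the endpoints
#' @export
make_grid <- function(c_min = 1e-3, c_max = 100, n = 20) {
  if (!(c_max > c_min && c_min > 0)) stop("need c_max > c_min > 0",
                                          call. = FALSE)
  if (n < 2) stop("need at least 2 grid points", call. = FALSE)
  10^seq(log10(c_min), log10(c_max), length.out = n)
}

# Which screening source supplies each channel's pIC50, per dataset.
# B&Q2 has no Kv4.3 screen, so Ito stays unblocked there (absent data is
# not a zero pIC50).
.dataset_sources <- function(dataset) {
  switch(dataset,
    Q   = c(IKr = "Q", ICaL = "Q", INa = "Q", IKs = "Q", Ito = "Q"),
    MQ  = c(IKr = "M", ICaL = "Q", INa = "Q", IKs = "Q", Ito = "Q"),
    BQ2 = c(IKr = "B", ICaL = "B", INa = "Q2", IKs = "Q2"),
    stop("unknown dataset '", dataset, "'; use Q, BQ2 or MQ", call. = FALSE))
}

# pIC50 per channel for one compound under a dataset; NA entries never arise
# (missing required data errors), channels not in the map are unblocked.
.dataset_pic50s <- function(affinities, dataset, compound_id = "<compound>") {
  src <- .dataset_sources(dataset)
  out <- numeric(0)
  for (ch in names(src)) {
    v <- affinities$pic50[affinities$channel == ch &
                          affinities$source == src[ch]]
    if (length(v) == 0L || is.na(v[1]))
      stop(sprintf("missing %s pIC50 (source %s, dataset %s) for %s",
                   ch, src[ch], dataset, compound_id), call. = FALSE)
    out[ch] <- v[1]
  }
  out
}

#' Conductance scale factors for a compound at one concentration
#'
#' Maps a compound's screened affinities onto the five blockable channels
#' for a given dataset, and converts each pIC50 into the Hill conductance
#' scale factor at the requested concentration.  The dataset determines the
#' screening source per channel: \code{Q} uses the Quattro screen for all
#' five channels; \code{MQ} replaces only the hERG (IKr) value with the
#' manual patch clamp value; \code{BQ2} uses Barracuda for IKr and ICaL and
#' the second Quattro screen for INa and IKs, leaving Ito unblocked (that
#' platform has no Kv4.3 screen).
#'
#' @param affinities long-format channel-affinity rows for one compound
#'   (columns \code{channel}, \code{source}, \code{pic50}).
#' @param dataset one of \code{"Q"}, \code{"BQ2"}, \code{"MQ"}.
#' @param concentration concentration in micromolar (>= 0).
#' @return named numeric vector of factors in [0, 1] over
#'   [channel_handles()]; IK1 is always 1 (never screened).
#' @export
assemble_scale_factors <- function(affinities, dataset, concentration) {
  stopifnot(length(concentration) == 1L, concentration >= 0)
  cid <- if ("compound_id" %in% names(affinities) && nrow(affinities))
    affinities$compound_id[1] else "<compound>"
  pic <- .dataset_pic50s(affinities, dataset, cid)
  factors <- setNames(rep(1, 6), channel_handles())
  factors[names(pic)] <- conductance_scale_factor(concentration, pic)
  factors
}

#' Concentration sweep: change in APD90 across a concentration grid
#'
#' Runs the full conductance-block protocol for one compound, model and
#' dataset: the model is paced at 1 Hz to pseudo-steady state in control
#' conditions, then the concentration is increased along the grid, the
#' scaled conductances are imposed at each step, and pacing continues until
#' a new steady state from which APD90 is measured.  Each concentration is
#' warm-started from the previous concentration's steady state (the
#' sequential ramp protocol); set \code{warm_start = FALSE} to re-equilibrate
#' from control at every concentration instead.
#'
#' Integration failure or repolarisation failure at a concentration flags
#' that point and the sweep continues.
#'
#' @param compound compound identifier present in \code{panel}.
#' @param model model name (see [list_models()]) or an [ap_model()] object.
#' @param dataset screening dataset: \code{"Q"}, \code{"BQ2"} or \code{"MQ"}.
#' @param panel long-format affinity table (default: the bundled panel).
#' @param grid concentration grid in micromolar (default [make_grid()]).
#' @param solver [solver_settings()].
#' @param convergence_tol steady-state tolerance (see
#'   [pace_to_steady_state()]).
#' @param max_paces pace cap for the control solve.
#' @param max_paces_per_conc pace cap per concentration step (warm-started
#'   steps re-equilibrate quickly; default 500).
#' @param warm_start logical; ramp sequentially (default) or restart from
#'   control at each concentration.
#' @param rate pacing rate in Hz.
#' @param control optional precomputed control [pace_to_steady_state()]
#'   result to reuse across sweeps.
#' @param pic50_override optional named numeric vector of pIC50s per channel
#'   (IKr, IKs, INa, ICaL, Ito) that bypasses \code{panel}/\code{dataset}
#'   lookup; used by the uncertainty resampler.
#' @return an object of class \code{"dose_response"} with fields
#'   \code{compound_id}, \code{model_name}, \code{dataset},
#'   \code{control_apd90}, \code{pic50s} and \code{points} (a data.frame
#'   with \code{concentration_uM}, \code{apd90_ms}, \code{delta_apd90_ms},
#'   \code{flag}).
#' @export
run_sweep <- function(compound, model, dataset = "Q",
                      panel = load_pic50_table(), grid = make_grid(),
                      solver = solver_settings(), convergence_tol = 1e-6,
                      max_paces = 10000, max_paces_per_conc = 500,
                      warm_start = TRUE, rate = 1, control = NULL,
                      pic50_override = NULL) {
  if (is.character(model)) model <- ap_model(model)
  stopifnot(inherits(model, "ap_model"))
  if (is.unsorted(grid, strictly = TRUE))
    stop("grid must be strictly increasing", call. = FALSE)

  if (is.null(pic50_override)) {
    aff <- panel[panel$compound_id == compound, , drop = FALSE]
    if (nrow(aff) == 0L)
      stop("compound '", compound, "' not found in panel", call. = FALSE)
    pic <- .dataset_pic50s(aff, dataset, compound)
  } else {
    pic <- pic50_override
    bad <- setdiff(names(pic), channel_handles())
    if (length(bad)) stop("unknown channel in pic50_override: ",
                          paste(bad, collapse = ", "), call. = FALSE)
  }

  if (is.null(control))
    control <- pace_to_steady_state(model, rate = rate, solver = solver,
                                    convergence_tol = convergence_tol,
                                    max_paces = max_paces)
  control_apd <- compute_apd(control$trace,
                             pacing_period = control$period_ms)
  if (is.na(control_apd$apd90))
    stop("control simulation has no measurable APD90", call. = FALSE)

  n <- length(grid)
  apd90 <- rep(NA_real_, n)
  flag <- rep(NA_character_, n)
  state <- control$final_state

  for (i in seq_len(n)) {
    factors <- setNames(rep(1, 6), channel_handles())
    factors[names(pic)] <- conductance_scale_factor(grid[i], pic)
    blocked <- apply_block(model, factors)
    start <- if (warm_start) state else control$final_state
    res <- tryCatch(
      pace_to_steady_state(blocked, initial_state = start, rate = rate,
                           solver = solver,
                           convergence_tol = convergence_tol,
                           max_paces = max_paces_per_conc),
      error = function(e) e)
    if (inherits(res, "error")) {
      flag[i] <- "integration_failure"
      next
    }
    if (warm_start) state <- res$final_state
    apd <- compute_apd(res$trace, pacing_period = res$period_ms)
    if (!is.na(apd$apd90)) {
      apd90[i] <- apd$apd90
    } else if (apd$repolarisation_failure) {
      flag[i] <- "repolarisation_failure"
    } else {
      flag[i] <- "no_depolarisation"
    }
  }

  structure(list(
    compound_id = compound, model_name = model$name, dataset = dataset,
    control_apd90 = control_apd$apd90, pic50s = pic,
    points = data.frame(concentration_uM = grid, apd90_ms = apd90,
                        delta_apd90_ms = apd90 - control_apd$apd90,
                        flag = flag, stringsAsFactors = FALSE)),
    class = "dose_response")
}

#' @export
print.dose_response <- function(x, ...) {
  cat(sprintf("Dose-response curve: %s | %s | dataset %s\n",
              x$compound_id, x$model_name, x$dataset))
  cat(sprintf("  control APD90 %.2f ms; %d concentrations %.3g-%.3g uM\n",
              x$control_apd90, nrow(x$points),
              min(x$points$concentration_uM), max(x$points$concentration_uM)))
  ok <- !is.na(x$points$delta_apd90_ms)
  if (any(ok))
    cat(sprintf("  dAPD90 range: %+.2f to %+.2f ms\n",
                min(x$points$delta_apd90_ms[ok]),
                max(x$points$delta_apd90_ms[ok])))
  if (any(!ok))
    cat("  flagged points:", sum(!ok), "\n")
  invisible(x)
}

#' @export
plot.dose_response <- function(x, band = NULL, threshold = 5, ...) {
  pts <- x$points
  ok <- !is.na(pts$delta_apd90_ms)
  ylim <- range(c(pts$delta_apd90_ms[ok], threshold,
                  if (!is.null(band)) c(band$band$delta_lower_ms,
                                        band$band$delta_upper_ms)),
                na.rm = TRUE)
  plot(pts$concentration_uM[ok], pts$delta_apd90_ms[ok], log = "x",
       type = "b", pch = 16, xlab = "concentration (uM)",
       ylab = expression(Delta * "APD90 (ms)"), ylim = ylim,
       main = sprintf("%s | %s | %s", x$compound_id, x$model_name,
                      x$dataset), ...)
  if (!is.null(band)) {
    bb <- band$band
    okb <- !is.na(bb$delta_lower_ms)
    polygon(c(bb$concentration_uM[okb], rev(bb$concentration_uM[okb])),
            c(bb$delta_lower_ms[okb], rev(bb$delta_upper_ms[okb])),
            col = grDevices::adjustcolor("steelblue", 0.3), border = NA)
  }
  abline(h = threshold, lty = 3, col = "blue")
  if (any(!ok))
    points(pts$concentration_uM[!ok], rep(max(ylim), sum(!ok)), pch = 4,
           col = "red")
  invisible(x)
}

#' Read a dose-response curve at an arbitrary concentration
#'
#' Linear interpolation of the change in APD90 in log10-concentration
#' between the bracketing grid points.  Concentrations below (above) the
#' grid return the first (last) point's value; a flagged bracketing point
#' propagates its flag instead of a number.
#'
#' @param curve a [run_sweep()] result.
#' @param concentration concentration in micromolar (> 0).
#' @return interpolated change in APD90 (ms), or \code{NA} with a
#'   \code{"flag"} attribute.
#' @export
interpolate_delta <- function(curve, concentration) {
  stopifnot(inherits(curve, "dose_response"),
            length(concentration) == 1L, concentration > 0)
  pts <- curve$points
  if (nrow(pts) == 0L) stop("empty curve", call. = FALSE)
  lc <- log10(concentration)
  lg <- log10(pts$concentration_uM)

  pick <- function(i) {
    if (!is.na(pts$flag[i]))
      structure(NA_real_, flag = pts$flag[i])
    else pts$delta_apd90_ms[i]
  }
  if (lc <= lg[1]) return(pick(1L))
  if (lc >= lg[length(lg)]) return(pick(length(lg)))
  hi <- which(lg >= lc)[1]
  lo <- hi - 1L
  if (abs(lg[hi] - lc) < 1e-12) return(pick(hi))
  if (abs(lg[lo] - lc) < 1e-12) return(pick(lo))
  if (!is.na(pts$flag[lo])) return(structure(NA_real_, flag = pts$flag[lo]))
  if (!is.na(pts$flag[hi])) return(structure(NA_real_, flag = pts$flag[hi]))
  w <- (lc - lg[lo]) / (lg[hi] - lg[lo])
  (1 - w) * pts$delta_apd90_ms[lo] + w * pts$delta_apd90_ms[hi]
}

#' Serialise a dose-response curve to CSV
#'
#' @param curve a [run_sweep()] result.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_dose_response <- function(curve, path) {
  out <- cbind(compound = curve$compound_id, model = curve$model_name,
               dataset = curve$dataset, curve$points)
  write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}
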