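#' Assay-variability specification
#'
#' Standard deviations of pIC50 (log10-molar units) describing screen-to-
#' screen variability, per channel.  Used to resample pIC50s when building
#' credible bands.  A scalar recycles over the five screened channels.
#'
#' @param sigma scalar, named numeric vector over channels (IKr, IKs, INa,
#'   ICaL, Ito), or a data.frame with columns \code{channel},
#'   \code{source}, \code{sigma}.
#' @param dataset dataset used to resolve a (channel, source) table.
#' @return named numeric vector of sigmas over the five screened channels.
#' @export
assay_variability <- function(sigma = 0.2, dataset = "Q") {
  channels <- c("IKr", "IKs", "INa", "ICaL", "Ito")
  if (is.data.frame(sigma)) {
    stopifnot(all(c("channel", "source", "sigma") %in% names(sigma)))
    src <- .dataset_sources(dataset)
    out <- setNames(rep(0, length(channels)), channels)
    for (ch in intersect(channels, names(src))) {
      v <- sigma$sigma[sigma$channel == ch & sigma$source == src[ch]]
      if (length(v)) out[ch] <- v[1]
    }
  } else if (!is.null(names(sigma))) {
    out <- setNames(rep(0, length(channels)), channels)
    bad <- setdiff(names(sigma), channels)
    if (length(bad)) stop("unknown channel(s) in sigma: ",
                          paste(bad, collapse = ", "), call. = FALSE)
    out[names(sigma)] <- sigma
  } else {
    stopifnot(length(sigma) == 1L)
    out <- setNames(rep(sigma, length(channels)), channels)
  }
  if (any(out < 0)) stop("sigma must be non-negative", call. = FALSE)
  out
}

#' Sample perturbed pIC50 sets from assay variability
#'
#' Each draw perturbs every channel's pIC50 independently as
#' Normal(observed, sigma(channel)); draws below 0 are re-floored to exactly
#' 0, consistent with the flooring convention for the observed values.
#' Deterministic given the seed.
#'
#' @param pic50s named numeric vector of observed pIC50s per channel.
#' @param variability named sigma vector (see [assay_variability()]) or a
#'   scalar.
#' @param n_samples number of draws (>= 1).
#' @param seed integer seed.
#' @return numeric matrix, \code{n_samples} rows, one column per channel.
#' @export
sample_pic50s <- function(pic50s, variability = assay_variability(),
                          n_samples, seed = 1) {
  stopifnot(n_samples >= 1, !is.null(names(pic50s)))
  if (length(variability) == 1L && is.null(names(variability)))
    variability <- setNames(rep(variability, length(pic50s)), names(pic50s))
  if (any(variability < 0)) stop("sigma must be non-negative", call. = FALSE)
  sig <- variability[names(pic50s)]
  if (any(is.na(sig)))
    stop("no sigma supplied for channel(s): ",
         paste(names(pic50s)[is.na(sig)], collapse = ", "), call. = FALSE)
  draws <- withr_seed(seed, {
    m <- matrix(rnorm(n_samples * length(pic50s), mean = rep(pic50s,
                each = n_samples), sd = rep(sig, each = n_samples)),
                nrow = n_samples)
    m
  })
  draws[draws < 0] <- 0
  colnames(draws) <- names(pic50s)
  draws
}

#' Empirical percentile (order statistics with linear interpolation)
#'
#' The percentile estimator used for the credible-band bounds: the sorted
#' sample is read at rank \code{1 + (n-1)p}, interpolating linearly between
#' the neighbouring order statistics.
#'
#' @param x numeric sample (no NAs).
#' @param p probability in [0, 1].
#' @return the percentile estimate.
#' @export
percentile <- function(x, p) {
  stopifnot(length(x) >= 1, !anyNA(x), p >= 0, p <= 1)
  s <- sort(x)
  h <- (length(s) - 1) * p
  lo <- floor(h)
  if (lo + 1 >= length(s)) return(s[length(s)])
  s[lo + 1] + (h - lo) * (s[lo + 2] - s[lo + 1])
}

#' Credible band for a dose-response curve under assay variability
#'
#' Propagates per-channel pIC50 assay variability into a 95 percent
#' credible band around the change-in-APD90 curve: pIC50 sets are sampled
#' from the assay-variability distribution, the concentration sweep is
#' re-run for each draw, and the empirical 2.5th/97.5th percentiles of the
#' sampled dAPD90 are taken at every grid concentration.  Draws that show
#' repolarisation failure at a concentration are excluded from the
#' percentiles there and reported via \code{fraction_failed}.
#'
#' @inheritParams run_sweep
#' @param variability sigma specification (see [assay_variability()]).
#' @param n_samples number of resampled sweeps (>= 2; default 500).
#' @param seed integer seed (fixed for reproducibility).
#' @param level credible level (default 0.95).
#' @return an object of class \code{"credible_band"}: the unperturbed point
#'   curve (\code{$curve}), the band data.frame (\code{$band}: columns
#'   \code{concentration_uM}, \code{delta_lower_ms}, \code{delta_upper_ms},
#'   \code{fraction_failed}), \code{n_samples}, \code{seed}, \code{level}.
#' @export
credible_band <- function(compound, model, dataset = "Q",
                          panel = load_pic50_table(), grid = make_grid(),
                          variability = assay_variability(),
                          n_samples = 500, seed = 1, level = 0.95,
                          solver = solver_settings(), convergence_tol = 1e-6,
                          max_paces = 10000, max_paces_per_conc = 500,
                          control = NULL, pic50_override = NULL) {
  stopifnot(n_samples >= 2)
  if (is.character(model)) model <- ap_model(model)

  if (is.null(control))
    control <- pace_to_steady_state(model, solver = solver,
                                    convergence_tol = convergence_tol,
                                    max_paces = max_paces)
  if (is.null(pic50_override)) {
    aff <- panel[panel$compound_id == compound, , drop = FALSE]
    if (nrow(aff) == 0L)
      stop("compound '", compound, "' not found in panel", call. = FALSE)
    pic <- .dataset_pic50s(aff, dataset, compound)
  } else pic <- pic50_override

  sig <- assay_variability(variability, dataset)[names(pic)]
  draws <- sample_pic50s(pic, sig, n_samples, seed)

  point <- run_sweep(compound, model, dataset, panel = panel, grid = grid,
                     solver = solver, convergence_tol = convergence_tol,
                     max_paces = max_paces,
                     max_paces_per_conc = max_paces_per_conc,
                     control = control, pic50_override = pic)

  deltas <- matrix(NA_real_, n_samples, length(grid))
  failed <- matrix(FALSE, n_samples, length(grid))
  for (s in seq_len(n_samples)) {
    sw <- run_sweep(compound, model, dataset, panel = panel, grid = grid,
                    solver = solver, convergence_tol = convergence_tol,
                    max_paces = max_paces,
                    max_paces_per_conc = max_paces_per_conc,
                    control = control,
                    pic50_override = draws[s, ])
    deltas[s, ] <- sw$points$delta_apd90_ms
    failed[s, ] <- !is.na(sw$points$flag) &
                   sw$points$flag == "repolarisation_failure"
  }

  a <- (1 - level) / 2
  lower <- upper <- rep(NA_real_, length(grid))
  fraction_failed <- colMeans(failed)
  for (i in seq_along(grid)) {
    v <- deltas[!is.na(deltas[, i]), i]
    if (length(v)) {
      lower[i] <- percentile(v, a)
      upper[i] <- percentile(v, 1 - a)
    }
  }

  structure(list(
    curve = point,
    band = data.frame(concentration_uM = grid, delta_lower_ms = lower,
                      delta_upper_ms = upper,
                      fraction_failed = fraction_failed),
    n_samples = n_samples, seed = seed, level = level, sigma = sig),
    class = "credible_band")
}

#' @export
print.credible_band <- function(x, ...) {
  cat(sprintf("%.0f%% credible band (%d samples, seed %d) around:\n",
              100 * x$level, x$n_samples, x$seed))
  print(x$curve)
  w <- x$band$delta_upper_ms - x$band$delta_lower_ms
  ok <- !is.na(w)
  if (any(ok))
    cat(sprintf("  band width: %.2f to %.2f ms\n", min(w[ok]), max(w[ok])))
  if (any(x$band$fraction_failed > 0))
    cat(sprintf("  repolarisation failure in up to %.0f%% of draws\n",
                100 * max(x$band$fraction_failed)))
  invisible(x)
}
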