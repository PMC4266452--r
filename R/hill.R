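#' Fraction of current remaining under Hill-type conductance block
#'
#' Evaluates the Hill function \deqn{R([C]) = \left(1 + ([C]/IC_{50})^n\right)^{-1}}
#' giving the proportion of peak ionic current that remains in the presence of
#' a compound at concentration \code{concentration}.  Potency is supplied as a
#' pIC50 (-log10 of the IC50 in molar, as reported by ion channel screens);
#' concentrations are in micromolar throughout the package.
#'
#' @param concentration numeric vector of concentrations (micromolar, >= 0).
#' @param pic50 numeric vector of pIC50 values (-log10 molar).
#' @param n Hill coefficient (> 0).  The screening analysis in this package
#'   fixes \code{n = 1}; the parameter is exposed for exploratory use.
#' @return numeric vector of fractions in [0, 1]; 1 at zero concentration.
#' @examples
#' hill_fraction_remaining(1, pic50 = 6)   # C == IC50 -> 0.5
#' hill_fraction_remaining(0, pic50 = 8)   # no compound -> 1
#' @seealso [conductance_scale_factor()], [fit_hill()]
#' @export
hill_fraction_remaining <- function(concentration, pic50, n = 1) {
  if (!is.numeric(concentration) || any(!is.finite(concentration)))
    stop("'concentration' must be finite numeric", call. = FALSE)
  if (any(concentration < 0))
    stop("'concentration' must be non-negative (micromolar)", call. = FALSE)
  if (!is.numeric(pic50) || any(!is.finite(pic50)))
    stop("'pic50' must be finite numeric", call. = FALSE)
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n <= 0)
    stop("Hill coefficient 'n' must be a single positive number", call. = FALSE)
  ic50 <- pic50_to_ic50(pic50)
  1 / (1 + (concentration / ic50)^n)
}

#' Convert a pIC50 (molar scale) to an IC50 in micromolar
#'
#' pIC50 values are -log10 of the IC50 in molar, so the IC50 in micromolar is
#' \code{10^(6 - pIC50)}.  A floored pIC50 of 0 corresponds to an IC50 of
#' 1e6 micromolar, i.e. essentially no block over the screened range.
#'
#' @param pic50 numeric vector, finite.
#' @return IC50 values in micromolar.
#' @examples
#' pic50_to_ic50(6)  # 1 uM
#' pic50_to_ic50(8)  # 0.01 uM
#' @export
pic50_to_ic50 <- function(pic50) {
  if (!is.numeric(pic50) || any(!is.finite(pic50)))
    stop("'pic50' must be finite numeric", call. = FALSE)
  10^(6 - pic50)
}

#' Conductance scale factor for a blocked channel
#'
#' The conductance-block model makes a quasi-steady-state approximation for
#' compound binding: the maximal conductance of channel j in the presence of
#' the compound is \eqn{g_j = R([C]) \bar{g}_j}, where R is the Hill fraction
#' of unblocked channels.  This function is therefore numerically identical to
#' [hill_fraction_remaining()]; it exists so that code applying block to a
#' model reads as what it does.
#'
#' @inheritParams hill_fraction_remaining
#' @return scale factor(s) in [0, 1] multiplying the control conductance.
#' @export
conductance_scale_factor <- function(concentration, pic50, n = 1) {
  hill_fraction_remaining(concentration, pic50, n)
}

# Sum-of-squares objective for the one-parameter (pIC50) Hill fit.
hill_sse <- function(pic50, concentration, fraction) {
  sum((fraction - 1 / (1 + concentration * 10^(pic50 - 6)))^2)
}

#' Fit a one-parameter Hill curve (pIC50 only) to concentration-effect data
#'
#' Fits \eqn{R([C]) = (1 + [C]/IC_{50})^{-1}} to observed (concentration,
#' fraction-of-current-remaining) points by ordinary least squares, with the
#' Hill coefficient fixed at 1.  Raw fractions outside [0, 1] are clipped
#' before fitting.  The optimisation is a deterministic multi-start: Brent
#' searches seeded from a fixed grid of 13 initial pIC50s (0, 1, ..., 12);
#' the best SSE wins and ties are broken towards the smaller pIC50.
#'
#' Fitted pIC50s at or below 0 (IC50 above 1e6 micromolar, i.e. no
#' discernible activity) are floored to exactly 0 and flagged; floored fits
#' are still usable in simulation, where they produce at most 0.01 percent
#' block at 100 micromolar.
#'
#' @param concentration numeric vector of concentrations (micromolar, > 0),
#'   or a data.frame with columns \code{concentration_uM} and
#'   \code{fraction_remaining}.
#' @param fraction_remaining numeric vector of observed fractions; ignored
#'   when \code{concentration} is a data.frame.
#' @return an object of class \code{"hill_fit"} with components
#'   \item{pic50}{fitted pIC50 (-log10 molar; 0 if floored)}
#'   \item{hill_coefficient}{always 1}
#'   \item{floored}{TRUE if the unconstrained optimum was at or below 0}
#'   \item{residual_sse}{sum of squared residuals at the returned pIC50}
#'   \item{low_confidence}{TRUE for fits on fewer than 2 distinct concentrations}
#' @examples
#' cc <- 10^seq(-2, 2, length.out = 8)
#' fit <- fit_hill(cc, hill_fraction_remaining(cc, pic50 = 5))
#' coef(fit)
#' @export
fit_hill <- function(concentration, fraction_remaining = NULL) {
  if (is.data.frame(concentration)) {
    df <- concentration
    if (!all(c("concentration_uM", "fraction_remaining") %in% names(df)))
      stop("data.frame input needs columns 'concentration_uM' and 'fraction_remaining'",
           call. = FALSE)
    concentration <- df$concentration_uM
    fraction_remaining <- df$fraction_remaining
  }
  if (length(concentration) == 0L)
    stop("no concentration-effect points supplied", call. = FALSE)
  if (length(concentration) != length(fraction_remaining))
    stop("'concentration' and 'fraction_remaining' lengths differ", call. = FALSE)
  if (any(!is.finite(concentration)) || any(concentration <= 0))
    stop("concentrations must be finite and strictly positive", call. = FALSE)
  if (any(!is.finite(fraction_remaining)))
    stop("fractions must be finite", call. = FALSE)

  fraction <- pmin(pmax(fraction_remaining, 0), 1)
  low_confidence <- length(unique(concentration)) < 2L

  # essentially flat screens (no fraction below 0.95) are reported as
  # floored fits outright rather than chasing a marginal optimum
  if (all(fraction > 0.95)) {
    return(structure(
      list(pic50 = 0, hill_coefficient = 1, floored = TRUE,
           residual_sse = hill_sse(0, concentration, fraction),
           low_confidence = low_confidence,
           n_points = length(concentration),
           data = data.frame(concentration_uM = concentration,
                             fraction_remaining = fraction)),
      class = "hill_fit"))
  }

  # Deterministic multi-start Brent search; each start searches +/- 1.5 log
  # units so the windows tile the whole 0-12 range with overlap.
  starts <- 0:12
  best <- NULL
  for (s in starts) {
    opt <- stats::optimize(hill_sse, interval = c(s - 1.5, s + 1.5),
                           concentration = concentration, fraction = fraction,
                           tol = 1e-10)
    if (is.null(best) || opt$objective < best$objective - 1e-15 ||
        (abs(opt$objective - best$objective) <= 1e-15 &&
         opt$minimum < best$minimum)) {
      best <- opt
    }
  }
  pic50 <- best$minimum
  floored <- pic50 <= 0
  if (floored) pic50 <- 0
  sse <- hill_sse(pic50, concentration, fraction)

  structure(
    list(pic50 = pic50, hill_coefficient = 1, floored = floored,
         residual_sse = sse, low_confidence = low_confidence,
         n_points = length(concentration),
         data = data.frame(concentration_uM = concentration,
                           fraction_remaining = fraction)),
    class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, digits = 4, ...) {
  cat("One-parameter Hill fit (n fixed at 1)\n")
  cat(sprintf("  pIC50: %s%s\n", format(x$pic50, digits = digits),
              if (x$floored) "  [floored: fitted pIC50 <= 0]" else ""))
  cat(sprintf("  IC50 : %s uM\n", format(pic50_to_ic50(x$pic50), digits = digits)))
  cat(sprintf("  SSE  : %s on %d points%s\n",
              format(x$residual_sse, digits = digits), x$n_points,
              if (x$low_confidence) "  [single-concentration fit]" else ""))
  invisible(x)
}

#' @export
coef.hill_fit <- function(object, ...) {
  c(pic50 = object$pic50, hill_coefficient = object$hill_coefficient)
}

#' @export
predict.hill_fit <- function(object, concentration = NULL, ...) {
  if (is.null(concentration)) concentration <- object$data$concentration_uM
  hill_fraction_remaining(concentration, object$pic50, object$hill_coefficient)
}

#' @export
residuals.hill_fit <- function(object, ...) {
  object$data$fraction_remaining - predict(object)
}
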