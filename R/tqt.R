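#' Free plasma concentration from Cmax, protein binding and molecular weight
#'
#' Converts a peak total plasma concentration in ng/mL into the free (unbound)
#' molar concentration: since 1 ng/mL = 1 ug/L, dividing by the molecular
#' weight in g/mol yields umol/L directly, and multiplying by the unbound
#' fraction gives the free concentration:
#' \deqn{C_{free} = \frac{C_{max}}{MW} \left(1 - \frac{PB}{100}\right) \; \mu M}
#'
#' @param cmax peak plasma concentration, ng/mL (>= 0).
#' @param percent_bound percent plasma protein binding, in [0, 100].
#' @param molecular_weight molecular weight, g/mol (> 0).
#' @return free plasma concentration in micromolar.
#' @examples
#' free_plasma_concentration(500, 50, 250)   # 1 uM
#' @export
free_plasma_concentration <- function(cmax, percent_bound, molecular_weight) {
  if (any(molecular_weight <= 0)) stop("molecular weight must be positive",
                                       call. = FALSE)
  if (any(cmax < 0)) stop("cmax must be non-negative", call. = FALSE)
  if (any(percent_bound < 0 | percent_bound > 100))
    stop("percent_bound must be in [0, 100]", call. = FALSE)
  (cmax / molecular_weight) * (1 - percent_bound / 100)
}

#' Classify a dose-response curve against the 5 ms prolongation criterion
#'
#' Predicts whether a compound prolongs repolarisation by at least
#' \code{threshold} ms, evaluated over a fold-change window around the
#' estimated clinical (TQT) free plasma concentration: the evaluation window
#' is \code{[tqt_conc/fold_window, tqt_conc*fold_window]} intersected with
#' the sweep grid, and the prediction is positive when the maximum
#' interpolated change in APD90 over the window reaches the threshold.
#' \code{fold_window = 1} reduces to the point evaluation at
#' \code{tqt_conc}.  Repolarisation-failure points inside the window count
#' as positive (failure to repolarise is the extreme prolongation).
#'
#' @param curve a [run_sweep()] result.
#' @param tqt_conc estimated free plasma concentration, micromolar (> 0).
#' @param fold_window symmetric concentration window factor (>= 1).
#' @param threshold prolongation criterion in ms (>= is positive).
#' @return logical: predicted positive.
#' @export
classify <- function(curve, tqt_conc, fold_window = 1, threshold = 5) {
  stopifnot(inherits(curve, "dose_response"), tqt_conc > 0, fold_window >= 1)
  pts <- curve$points
  grid <- pts$concentration_uM
  lo <- tqt_conc / fold_window
  hi <- tqt_conc * fold_window

  if (hi < min(grid) || lo > max(grid)) {
    warning("evaluation window lies outside the concentration grid; ",
            "classifying at the nearest grid endpoint")
    at <- if (hi < min(grid)) min(grid) else max(grid)
    lo <- hi <- at
  }
  lo <- max(lo, min(grid))
  hi <- min(hi, max(grid))

  # candidate evaluation points: window endpoints plus grid points inside
  inside <- grid[grid >= lo & grid <= hi]
  cand <- unique(c(lo, inside, hi))

  # repolarisation failure at a grid point inside the window is the extreme
  # prolongation: positive regardless of the numeric points
  flagged <- !is.na(pts$flag) & pts$flag == "repolarisation_failure" &
             grid >= lo & grid <= hi
  if (any(flagged)) return(TRUE)

  any_positive <- FALSE
  any_numeric <- FALSE
  for (cc in cand) {
    d <- interpolate_delta(curve, cc)
    if (!is.null(attr(d, "flag"))) next  # flagged: not evaluable here
    any_numeric <- TRUE
    if (d >= threshold) any_positive <- TRUE
  }
  if (!any_numeric) return(NA)
  any_positive
}

#' Build a 2x2 contingency table of predicted vs observed QT prolongation
#'
#' Observed positive means a mean QTc change of at least \code{threshold} ms
#' in the clinical study; predicted positive comes from [classify()].
#' Sensitivity, specificity and accuracy are computed from exact integer
#' counts (and rendered to whole percent in the print method).
#'
#' @param predicted logical vector of model predictions (NA allowed;
#'   NA records are dropped as non-evaluable).
#' @param delta_qtc observed mean change in QTc (ms) per compound.
#' @param threshold observation threshold in ms (inclusive).
#' @return an object of class \code{"contingency_table"} with counts
#'   \code{tp}, \code{fp}, \code{tn}, \code{fn} and derived percentages
#'   \code{sensitivity}, \code{specificity}, \code{accuracy} (NA when
#'   undefined).
#' @examples
#' build_contingency(c(TRUE, TRUE, FALSE, FALSE, FALSE, TRUE),
#'                   c(10, 8, 6, -1, 0, 2))
#' @export
build_contingency <- function(predicted, delta_qtc, threshold = 5) {
  stopifnot(length(predicted) == length(delta_qtc), length(predicted) >= 1)
  keep <- !is.na(predicted)
  predicted <- predicted[keep]
  delta_qtc <- delta_qtc[keep]
  observed <- delta_qtc >= threshold
  tp <- sum(predicted & observed)
  fp <- sum(predicted & !observed)
  tn <- sum(!predicted & !observed)
  fn <- sum(!predicted & observed)
  structure(list(
    tp = tp, fp = fp, tn = tn, fn = fn, n = tp + fp + tn + fn,
    sensitivity = if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_,
    accuracy = if (tp + fp + tn + fn > 0)
      100 * (tp + tn) / (tp + fp + tn + fn) else NA_real_),
    class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat("            observed >=5ms   observed <5ms\n")
  cat(sprintf("pred. pos.  %14d  %14d\n", x$tp, x$fp))
  cat(sprintf("pred. neg.  %14d  %14d\n", x$fn, x$tn))
  fmt <- function(v) if (is.na(v)) "undefined" else sprintf("%.0f%%", v)
  cat(sprintf("sensitivity %s  specificity %s  accuracy %s  (n = %d)\n",
              fmt(x$sensitivity), fmt(x$specificity), fmt(x$accuracy), x$n))
  invisible(x)
}

#' Performance summary over models, datasets and concentration windows
#'
#' Scores a collection of dose-response curves against TQT records for every
#' (model, dataset) combination present and every requested fold window,
#' producing a long-format table of contingency metrics mirroring a
#' models-by-datasets-by-windows performance summary.
#'
#' @param curves list of [run_sweep()] results (any mix of compounds,
#'   models, datasets).
#' @param tqt data.frame with columns \code{compound_id},
#'   \code{delta_qtc_ms} and either \code{free_conc_uM} or the raw exposure
#'   columns (\code{cmax_ng_per_ml}, \code{percent_bound},
#'   \code{molecular_weight}).
#' @param fold_windows numeric vector of fold windows (default 1, 10, 100).
#' @param threshold prolongation criterion in ms.
#' @return data.frame with one row per model x dataset x window: counts and
#'   metric percentages; combinations with no curve are omitted.
#' @export
summary_table <- function(curves, tqt, fold_windows = c(1, 10, 100),
                          threshold = 5) {
  stopifnot(length(curves) >= 1, all(fold_windows >= 1))
  if (!("free_conc_uM" %in% names(tqt))) {
    tqt$free_conc_uM <- free_plasma_concentration(
      tqt$cmax_ng_per_ml, tqt$percent_bound, tqt$molecular_weight)
  }
  meta <- data.frame(
    i = seq_along(curves),
    compound = vapply(curves, function(x) x$compound_id, character(1)),
    model = vapply(curves, function(x) x$model_name, character(1)),
    dataset = vapply(curves, function(x) x$dataset, character(1)),
    stringsAsFactors = FALSE)

  combos <- unique(meta[c("model", "dataset")])
  out <- NULL
  for (r in seq_len(nrow(combos))) {
    sel <- meta[meta$model == combos$model[r] &
                meta$dataset == combos$dataset[r], ]
    sel <- sel[sel$compound %in% tqt$compound_id, ]
    if (nrow(sel) == 0L) next
    idx <- match(sel$compound, tqt$compound_id)
    for (w in fold_windows) {
      pred <- vapply(seq_len(nrow(sel)), function(k)
        classify(curves[[sel$i[k]]], tqt$free_conc_uM[idx[k]],
                 fold_window = w, threshold = threshold), logical(1))
      ct <- build_contingency(pred, tqt$delta_qtc_ms[idx],
                              threshold = threshold)
      out <- rbind(out, data.frame(
        model = combos$model[r], dataset = combos$dataset[r],
        fold_window = w, tp = ct$tp, fp = ct$fp, tn = ct$tn, fn = ct$fn,
        sensitivity = ct$sensitivity, specificity = ct$specificity,
        accuracy = ct$accuracy, n = ct$n, stringsAsFactors = FALSE))
    }
  }
  rownames(out) <- NULL
  out
}
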