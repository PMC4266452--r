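#' Load the bundled multi-channel screening pIC50 panel
#'
#' Reads the packaged CSV of per-compound, per-channel, per-source pIC50
#' values (34 marketed compounds, channels hERG/CaV1.2/NaV1.5/KCNQ1/Kv4.3,
#' sources Q/B/Q2/M) and returns it in long "channel affinity" form.  Zero
#' entries are kept as exact 0 (floored fits, still used in simulation);
#' empty cells (compounds not screened on a platform) become absent rows.
#'
#' @param path path to a CSV with the panel schema; defaults to the bundled
#'   dataset.
#' @return a data.frame with columns \code{compound_id} (lower-case
#'   identifier), \code{display_name}, \code{channel} (IKr, ICaL, INa, IKs,
#'   Ito), \code{source} (Q, B, Q2, M) and \code{pic50}.
#' @examples
#' panel <- load_pic50_table()
#' subset(panel, compound_id == "dofetilide" & channel == "IKr")
#' @export
load_pic50_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "pic50_panel.csv", package = "qtsim",
                        mustWork = TRUE)
  wide <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                   colClasses = c(display_name = "character"))
  expected <- c("display_name", "herg_q", "herg_b", "herg_m", "cav12_q",
                "cav12_b", "nav15_q", "nav15_q2", "kcnq1_q", "kcnq1_q2",
                "kv43_q")
  if (!identical(names(wide), expected))
    stop("pIC50 panel has unexpected columns: ",
         paste(names(wide), collapse = ", "), call. = FALSE)

  colmap <- list(
    herg_q = c("IKr", "Q"), herg_b = c("IKr", "B"), herg_m = c("IKr", "M"),
    cav12_q = c("ICaL", "Q"), cav12_b = c("ICaL", "B"),
    nav15_q = c("INa", "Q"), nav15_q2 = c("INa", "Q2"),
    kcnq1_q = c("IKs", "Q"), kcnq1_q2 = c("IKs", "Q2"),
    kv43_q = c("Ito", "Q"))

  out <- do.call(rbind, lapply(names(colmap), function(cn) {
    vals <- wide[[cn]]
    keep <- !is.na(vals)
    if (any(vals[keep] < 0))
      stop("negative pIC50 in column ", cn,
           " (flooring convention violated) at row ",
           which(keep & vals < 0)[1], call. = FALSE)
    data.frame(compound_id = tolower(wide$display_name[keep]),
               display_name = wide$display_name[keep],
               channel = colmap[[cn]][1], source = colmap[[cn]][2],
               pic50 = vals[keep], stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$compound_id, out$channel, out$source), , drop = FALSE]
}

#' Write a channel-affinity table back to the wide panel CSV layout
#'
#' Inverse of [load_pic50_table()]; used for round-trip serialisation.
#'
#' @param panel long-format data.frame as returned by [load_pic50_table()].
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_pic50_table <- function(panel, path) {
  key <- list(c("IKr", "Q"), c("IKr", "B"), c("IKr", "M"),
              c("ICaL", "Q"), c("ICaL", "B"),
              c("INa", "Q"), c("INa", "Q2"),
              c("IKs", "Q"), c("IKs", "Q2"), c("Ito", "Q"))
  cols <- c("herg_q", "herg_b", "herg_m", "cav12_q", "cav12_b",
            "nav15_q", "nav15_q2", "kcnq1_q", "kcnq1_q2", "kv43_q")
  ids <- sort(unique(panel$compound_id))
  wide <- data.frame(display_name = vapply(ids, function(id)
    panel$display_name[panel$compound_id == id][1], character(1)))
  for (k in seq_along(key)) {
    wide[[cols[k]]] <- vapply(ids, function(id) {
      v <- panel$pic50[panel$compound_id == id &
                       panel$channel == key[[k]][1] &
                       panel$source == key[[k]][2]]
      if (length(v)) v[1] else NA_real_
    }, numeric(1))
  }
  write.csv(wide, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Synthesise screening-style concentration-effect points
#'
#' Generates (concentration, fraction-remaining) points on a log-spaced
#' concentration grid from a one-parameter Hill curve with additive Gaussian
#' measurement noise, clipped to [0, 1] — emulating the per-well output of an
#' automated planar patch screen.
#'
#' @param pic50 generating pIC50 (-log10 molar).
#' @param n Hill coefficient of the generating curve.
#' @param noise_sd standard deviation of the additive noise on the fraction
#'   scale (typical screen repeatability is around 0.02-0.05).
#' @param n_points number of concentrations.
#' @param c_range concentration range in micromolar (log-spaced inclusive
#'   endpoints); the default matches a 1 nM - 100 uM screen.
#' @param seed integer seed; the generator is deterministic given the seed.
#' @return data.frame with columns \code{concentration_uM} and
#'   \code{fraction_remaining}.
#' @export
generate_concentration_effect <- function(pic50, n = 1, noise_sd = 0.02,
                                          n_points = 8,
                                          c_range = c(1e-3, 100),
                                          seed = 1) {
  stopifnot(n_points >= 1, noise_sd >= 0, length(c_range) == 2,
            all(c_range > 0), c_range[2] > c_range[1])
  conc <- 10^seq(log10(c_range[1]), log10(c_range[2]),
                 length.out = n_points)
  frac <- hill_fraction_remaining(conc, pic50, n)
  if (noise_sd > 0) {
    frac <- withr_seed(seed, frac + rnorm(n_points, 0, noise_sd))
    frac <- pmin(pmax(frac, 0), 1)
  }
  data.frame(concentration_uM = conc, fraction_remaining = frac)
}

# Evaluate `expr` under a local RNG seed without touching the caller's RNG
# stream.
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Generate a synthetic Thorough QT exposure cohort
#'
#' Emulates the schema of a clinical TQT exposure spreadsheet: per compound,
#' the peak plasma concentration at the highest dose tested (Cmax, ng/mL),
#' percent plasma protein binding, molecular weight (g/mol) and the mean
#' change in QTc at that dose (ms).  The generating truth (whether the
#' compound is a "true" QT-prolonger and the underlying free concentration)
#' is retained so that expected contingency counts can be recomputed exactly.
#' This cohort is synthetic: it stands in for clinical exposure data, which
#' is not bundled.
#'
#' @param n_compounds number of records.
#' @param effect_model \code{"null"} (no true effect: dQTc ~ Normal(0, 2)) or
#'   \code{"mixed"} (a proportion of true prolongers with dQTc ~
#'   Normal(12, 3), the rest null).
#' @param prop_positive proportion of true prolongers under "mixed".
#' @param compound_ids optional character vector of compound identifiers to
#'   use (e.g. the bundled panel's); defaults to synthetic ids.
#' @param seed integer seed.
#' @return data.frame with columns \code{compound_id},
#'   \code{cmax_ng_per_ml}, \code{percent_bound}, \code{molecular_weight},
#'   \code{delta_qtc_ms}, plus truth columns \code{true_positive} and
#'   \code{free_conc_uM}.
#' @export
generate_synthetic_tqt <- function(n_compounds, effect_model = c("mixed", "null"),
                                   prop_positive = 0.4,
                                   compound_ids = NULL, seed = 1) {
  effect_model <- match.arg(effect_model)
  stopifnot(n_compounds >= 1, prop_positive >= 0, prop_positive <= 1)
  if (is.null(compound_ids))
    compound_ids <- sprintf("compound_%02d", seq_len(n_compounds))
  stopifnot(length(compound_ids) == n_compounds)
  withr_seed(seed, {
    mw <- runif(n_compounds, 200, 700)
    cmax <- 10^runif(n_compounds, 1, 3.5)        # 10 ng/mL - ~3.2 ug/mL
    pb <- runif(n_compounds, 20, 99.5)           # % plasma protein binding
    truth <- switch(effect_model,
      null = rep(FALSE, n_compounds),
      mixed = seq_len(n_compounds) <= round(prop_positive * n_compounds))
    dqtc <- ifelse(truth, rnorm(n_compounds, 12, 3), rnorm(n_compounds, 0, 2))
    data.frame(compound_id = compound_ids,
               cmax_ng_per_ml = cmax, percent_bound = pb,
               molecular_weight = mw, delta_qtc_ms = dqtc,
               true_positive = truth,
               free_conc_uM = free_plasma_concentration(cmax, pb, mw),
               stringsAsFactors = FALSE)
  })
}
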