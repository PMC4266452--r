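#' @useDynLib qtsim, .registration = TRUE
#' @importFrom stats optimize rnorm runif setNames
#' @importFrom utils read.csv write.csv
NULL

# Internal registry of the three human ventricular AP models.  Each entry
# carries the published initial conditions, the CellML-style square-pulse
# stimulus definition, and the mapping from channel labels to the scalable
# maximal-conductance handles compiled into the C right-hand sides.
.qtsim_registry <- function() {
  list(
    tentusscher2006 = list(
      model_id = 1L,
      label = "ten Tusscher & Panfilov 2006",
      variant = "epicardial",
      n_state = 19L,
      v_index = 1L,
      state_names = c("V", "Ki", "Nai", "Cai", "CaSS", "CaSR", "Rprime",
                      "xr1", "xr2", "xs", "m", "h", "j", "d", "f", "f2",
                      "fCass", "s", "r"),
      gate_index = 7:19,
      init = c(V = -85.23, Ki = 136.89, Nai = 8.604, Cai = 0.000126,
               CaSS = 0.00036, CaSR = 3.64, Rprime = 0.9073,
               xr1 = 0.00621, xr2 = 0.4712, xs = 0.0095, m = 0.00172,
               h = 0.7444, j = 0.7045, d = 3.373e-5, f = 0.7888,
               f2 = 0.9755, fCass = 0.9953, s = 0.999998, r = 2.42e-8),
      stimulus = list(amplitude = -52, duration = 1, period = 1000,
                      offset = 0),
      ito_note = "single transient-outward current; block scales the whole conductance",
      citation = "ten Tusscher KHWJ, Panfilov AV (2006) Am J Physiol Heart Circ Physiol 291:H1088-H1100"
    ),
    grandi2010 = list(
      model_id = 2L,
      label = "Grandi, Pasqualini & Bers 2010",
      variant = "epicardial",
      n_state = 39L,
      v_index = 1L,
      state_names = c("V", "m", "h", "j", "d", "f", "fcaBj", "fcaBsl",
                      "xtos", "ytos", "xtof", "ytof", "xkr", "xks",
                      "RyRr", "RyRo", "RyRi", "NaBj", "NaBsl", "TnCL",
                      "TnCHc", "TnCHm", "CaM", "Myoc", "Myom", "SRB",
                      "SLLj", "SLLsl", "SLHj", "SLHsl", "Csqnb", "Casr",
                      "Naj", "Nasl", "Nai", "Ki", "Caj", "Casl", "Cai"),
      gate_index = c(2:6, 9:14),
      init = c(V = -81.4552, m = 1.405627e-3, h = 9.867005e-1,
               j = 9.915620e-1, d = 7.175662e-6, f = 1.000681 - 7e-4,
               fcaBj = 2.421991e-2, fcaBsl = 1.452605e-2,
               xtos = 4.051574e-3, ytos = 9.945511e-1,
               xtof = 4.051574e-3, ytof = 9.945511e-1,
               xkr = 8.641386e-3, xks = 5.412034e-3,
               RyRr = 8.884332e-1, RyRo = 8.156628e-7, RyRi = 1.024274e-7,
               NaBj = 3.539892, NaBsl = 7.720854e-1,
               TnCL = 8.773191e-3, TnCHc = 1.078283e-1, TnCHm = 1.524002e-2,
               CaM = 2.911916e-4, Myoc = 1.298754e-3, Myom = 1.381982e-1,
               SRB = 2.143165e-3, SLLj = 9.566355e-3, SLLsl = 1.110363e-1,
               SLHj = 7.347888e-3, SLHsl = 7.297378e-2, Csqnb = 1.242988,
               Casr = 0.554514, Naj = 8.80329, Nasl = 8.80733,
               Nai = 8.80853, Ki = 120, Caj = 1.737475e-4,
               Casl = 1.031812e-4, Cai = 8.597401e-5),
      stimulus = list(amplitude = -9.5, duration = 5, period = 1000,
                      offset = 0),
      ito_note = "distinct fast and slow Ito; block scales the fast component only",
      citation = "Grandi E, Pasqualini FS, Bers DM (2010) J Mol Cell Cardiol 48:112-121"
    ),
    ohara2011 = list(
      model_id = 3L,
      label = "O'Hara, Virag, Varro & Rudy 2011",
      variant = "endocardial",
      n_state = 41L,
      v_index = 1L,
      state_names = c("V", "Nai", "Nass", "Ki", "Kss", "Cai", "Cass",
                      "Cansr", "Cajsr", "m", "hf", "hs", "j", "hsp", "jp",
                      "mL", "hL", "hLp", "a", "iF", "iS", "ap", "iFp",
                      "iSp", "d", "ff", "fs", "fcaf", "fcas", "jca", "nca",
                      "ffp", "fcafp", "xrf", "xrs", "xs1", "xs2", "xk1",
                      "Jrelnp", "Jrelp", "CaMKt"),
      gate_index = c(10:30, 32:38),
      init = c(V = -87.5, Nai = 7.268, Nass = 7.268, Ki = 144.65,
               Kss = 144.65, Cai = 8.6e-5, Cass = 8.49e-5, Cansr = 1.61,
               Cajsr = 1.56, m = 0.0074621, hf = 0.692591, hs = 0.692574,
               j = 0.692477, hsp = 0.448501, jp = 0.692413,
               mL = 0.000194015, hL = 0.496116, hLp = 0.265885,
               a = 0.00101185, iF = 0.999542, iS = 0.589579,
               ap = 0.000515567, iFp = 0.999542, iSp = 0.641861,
               d = 2.43015e-9, ff = 0.999999, fs = 0.910671,
               fcaf = 0.999999, fcas = 0.99982, jca = 0.999977,
               nca = 0.00267171, ffp = 0.999999, fcafp = 0.999999,
               xrf = 8.26608e-6, xrs = 0.453268, xs1 = 0.270492,
               xs2 = 0.0001963, xk1 = 0.996801, Jrelnp = 2.53943e-5,
               Jrelp = 3.17262e-7, CaMKt = 0.0124065),
      stimulus = list(amplitude = -80, duration = 0.5, period = 1000,
                      offset = 0),
      ito_note = "single transient-outward current; block scales the whole conductance",
      citation = "O'Hara T, Virag L, Varro A, Rudy Y (2011) PLoS Comput Biol 7:e1002061"
    )
  )
}

#' Names of the channels with scalable maximal conductances
#'
#' @return character vector of the six block handles, in the canonical order
#'   used by the compiled models.
#' @export
channel_handles <- function() c("IKr", "IKs", "INa", "ICaL", "Ito", "IK1")

#' List the registered action potential models
#'
#' @return character vector of model names accepted by [ap_model()].
#' @export
list_models <- function() names(.qtsim_registry())

#' Instantiate a human ventricular action potential model
#'
#' Returns one of the three registered human ventricular myocyte ODE systems
#' with its published parameterisation, published initial conditions, and the
#' square-pulse stimulus as defined in the model's CellML implementation.
#' All six scalable conductances (IKr, IKs, INa, ICaL, Ito, IK1) start at
#' their control values (scale factor 1).
#'
#' @param name one of \code{"tentusscher2006"} (epicardial, 19 states),
#'   \code{"grandi2010"} (epicardial, 39 states) or \code{"ohara2011"}
#'   (endocardial, 41 states).
#' @return an object of class \code{"ap_model"}.
#' @examples
#' mdl <- ap_model("ohara2011")
#' mdl$n_state
#' @export
ap_model <- function(name) {
  reg <- .qtsim_registry()
  if (length(name) != 1L || !is.character(name) || !(name %in% names(reg)))
    stop("unknown model '", paste(name, collapse = ","),
         "'; registered models: ", paste(names(reg), collapse = ", "),
         call. = FALSE)
  spec <- reg[[name]]
  spec$name <- name
  spec$scale <- setNames(rep(1, 6), channel_handles())
  spec$state <- spec$init
  class(spec) <- "ap_model"
  spec
}

#' @export
print.ap_model <- function(x, ...) {
  cat(sprintf("%s (%s variant), %d state variables\n",
              x$label, x$variant, x$n_state))
  cat("  ", x$citation, "\n", sep = "")
  cat(sprintf("  stimulus: %g (%g ms pulse every %g ms)\n",
              x$stimulus$amplitude, x$stimulus$duration, x$stimulus$period))
  blocked <- x$scale[x$scale != 1]
  if (length(blocked))
    cat("  conductance scaling: ",
        paste(sprintf("%s=%.4g", names(blocked), blocked), collapse = ", "),
        "\n", sep = "")
  else cat("  conductance scaling: control (all 1)\n")
  invisible(x)
}

# Parameter vector handed to the compiled right-hand side.
.model_parms <- function(model) {
  stim <- model$stimulus
  c(model$scale[channel_handles()],
    stim$amplitude, stim$duration, stim$period, stim$offset)
}

#' Apply conductance-block scale factors to a model
#'
#' Multiplies the maximal conductance of each named channel by the supplied
#' factor (Hill fraction of unblocked channels).  The control conductances
#' are compiled constants, so re-applying factors of 1 restores control
#' exactly.  In \code{grandi2010} the \code{Ito} factor scales only the fast
#' transient-outward component (the Kv4.3-like current); in the other two
#' models it scales the whole Ito conductance.
#'
#' @param model an [ap_model()] object.
#' @param factors named numeric vector or list, names drawn from
#'   [channel_handles()], values in [0, 1].
#' @return the model with updated scale factors.
#' @examples
#' mdl <- apply_block(ap_model("ohara2011"), c(IKr = 0.5))
#' @export
apply_block <- function(model, factors) {
  stopifnot(inherits(model, "ap_model"))
  factors <- unlist(factors)
  if (length(factors) == 0L) return(model)
  if (is.null(names(factors)) || any(!nzchar(names(factors))))
    stop("'factors' must be named by channel", call. = FALSE)
  bad <- setdiff(names(factors), channel_handles())
  if (length(bad))
    stop("unknown channel label(s): ", paste(bad, collapse = ", "),
         "; valid labels: ", paste(channel_handles(), collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(factors)) || any(factors < 0) || any(factors > 1))
    stop("block scale factors must be in [0, 1]", call. = FALSE)
  model$scale[names(factors)] <- factors
  model
}

#' Evaluate the model right-hand side at a given state and time
#'
#' Computes the time derivative of every state variable of the published ODE
#' system at \code{(state, t)}, including the stimulus current when \code{t}
#' falls inside the stimulus pulse.
#'
#' @param model an [ap_model()] object (block factors are honoured).
#' @param state numeric state vector of length \code{model$n_state}.
#' @param t time in ms (default 0; relevant only through the stimulus).
#' @return named numeric vector of derivatives (per ms).
#' @export
evaluate_derivatives <- function(model, state, t = 0) {
  stopifnot(inherits(model, "ap_model"))
  state <- as.numeric(state)
  if (length(state) != model$n_state)
    stop("state must have length ", model$n_state, call. = FALSE)
  if (any(!is.finite(state))) {
    bad <- which(!is.finite(state))
    stop("non-finite state variable(s): ",
         paste(model$state_names[bad], collapse = ", "), call. = FALSE)
  }
  dy <- .Call(qtsim_c_rhs, model$model_id, as.numeric(t), state,
              as.numeric(.model_parms(model)))
  setNames(dy, model$state_names)
}

# Fixed-step RK4 reference integration of the same equations; used as the
# independent oracle against the adaptive solver.  Returns a matrix with a
# time column followed by the state columns.
reference_rk4 <- function(model, state = NULL, t0 = 0, t_end = 1000,
                          dt = 0.001, sample_dt = 0.1) {
  stopifnot(inherits(model, "ap_model"))
  if (is.null(state)) state <- model$state
  sample <- max(1L, as.integer(round(sample_dt / dt)))
  out <- .Call(qtsim_c_rk4, model$model_id, as.numeric(state),
               as.numeric(.model_parms(model)), as.numeric(t0),
               as.numeric(t_end), as.numeric(dt), sample)
  colnames(out) <- c("time", model$state_names)
  out
}
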