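#' Names of the 16 model input parameters
#'
#' Canonical ordering of the inputs of the symmetric two-mass vocal-fold
#' model, in the g-cm-ms unit system: subglottal pressure `P`
#' (g cm^-1 ms^-2), masses `m1`, `m2` (g), spring constants `k1`, `k2` and
#' coupling `kc` (g ms^-2), damping constants `r1`, `r2` (g ms^-1), mass
#' thicknesses `d1`, `d2` and vocal-fold length `L` (cm), collision spring
#' constants `c1`, `c2` (g ms^-2), rest glottal areas `a01`, `a02`, and the
#' smoothed-step reference scale `x0` (cm).
#'
#' @return Character vector of length 16.
#' @export
param_names <- function() {
  c("P", "m1", "m2", "k1", "k2", "kc", "r1", "r2",
    "d1", "d2", "L", "c1", "c2", "a01", "a02", "x0")
}

#' Model parameter set
#'
#' Construct the 16-parameter input vector of the symmetric two-mass
#' vocal-fold model. Called with no arguments it returns the nominal
#' parameter set of Steinecke and Herzel; any parameter can be overridden
#' by name.
#'
#' @param ... Named overrides, e.g. `sh_params(P = 0.009)`. Names must be a
#'   subset of [param_names()].
#' @return Named numeric vector of length 16 in canonical order.
#' @examples
#' p <- sh_params()
#' p["P"]
#' sh_params(L = 1.5)["L"]
#' @export
sh_params <- function(...) {
  nominal <- c(
    P = 0.008, m1 = 0.125, m2 = 0.025,
    k1 = 0.08, k2 = 0.008, kc = 0.025,
    r1 = 0.02, r2 = 0.02,
    d1 = 0.25, d2 = 0.05, L = 1.4,
    c1 = 0.24, c2 = 0.024,
    a01 = 0.05, a02 = 0.05, x0 = 0.05
  )
  dots <- list(...)
  if (length(dots)) {
    nm <- names(dots)
    if (is.null(nm) || any(nm == "") || !all(nm %in% param_names()))
      stop("unknown parameter name(s): ",
           paste(setdiff(nm, param_names()), collapse = ", "))
    nominal[nm] <- vapply(dots, as.numeric, numeric(1))
  }
  validate_params(nominal)
  nominal
}

validate_params <- function(p) {
  if (!is.numeric(p) || length(p) != 16L ||
      !identical(names(p), param_names()))
    stop("parameter set must be a named numeric vector in param_names() order")
  if (!all(is.finite(p)) || any(p <= 0))
    stop("all 16 parameters must be strictly positive and finite")
  invisible(p)
}

#' Simulation configuration
#'
#' Time-stepping settings for the fixed-step integrator, plus the air
#' density used by the Bernoulli flow law (a physical constant, not one of
#' the 16 model parameters).
#'
#' @param dt Time step in ms.
#' @param duration Total simulated time in ms.
#' @param transient Initial span in ms discarded before any analysis.
#' @param x_init Initial displacement of both masses in cm.
#' @param v_init Initial velocity of both masses in cm/ms.
#' @param rho Air density in g cm^-3.
#' @return A list with class `"sim_config"`.
#' @export
sim_config <- function(dt = 0.01, duration = 1500, transient = 500,
                       x_init = 0.01, v_init = 0, rho = 0.00113) {
  stopifnot(is.numeric(dt), dt > 0, is.finite(dt),
            is.numeric(duration), is.numeric(transient),
            duration > transient, transient >= 0,
            is.numeric(rho), rho > 0)
  structure(
    list(dt = dt, duration = duration, transient = transient,
         x_init = x_init, v_init = v_init, rho = rho),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> dt =", x$dt, "ms, duration =", x$duration,
      "ms, transient =", x$transient, "ms, rho =", x$rho, "g/cm^3\n")
  invisible(x)
}
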