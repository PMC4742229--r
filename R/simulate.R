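#' Smoothed step function
#'
#' The smoothed Heaviside step used throughout the model: 0 for `y <= 0`
#' and `tanh(50 * y / x0)` for `y > 0`. Continuous at 0 and monotone
#' non-decreasing; `x0` sets the softening length scale.
#'
#' @param y Numeric vector.
#' @param x0 Positive length scale (cm).
#' @return Numeric vector of values in `[0, 1)`.
#' @examples
#' smoothed_step(c(-1, 0, 0.05), x0 = 0.05)
#' @export
smoothed_step <- function(y, x0) {
  if (!is.numeric(y) || any(!is.finite(y))) stop("y must be finite numeric")
  if (!is.numeric(x0) || length(x0) != 1L || !is.finite(x0) || x0 <= 0)
    stop("x0 must be a single positive finite number")
  ifelse(y > 0, tanh(50 * y / x0), 0)
}

#' Time derivatives of the two-mass system state
#'
#' Right-hand side of the 4-state symmetric model ODE. State order is
#' `(x1, v1, x2, v2)` (displacements in cm, velocities in cm/ms). Each mass
#' feels its restoring spring, damping, coupling to the other mass, and a
#' collision spring engaged when its glottal area `a_i = a0i + 2 L x_i`
#' becomes negative; the lower mass additionally carries the aerodynamic
#' driving force `L d1 P [1 - Theta(a_min) (a_min/a1)^2] Theta(a1)`.
#'
#' @param state Numeric 4-vector `(x1, v1, x2, v2)`.
#' @param params Parameter set from [sh_params()].
#' @param config Simulation configuration (unused by the dynamics; accepted
#'   for interface symmetry).
#' @return Numeric 4-vector of time derivatives.
#' @export
sh_derivatives <- function(state, params, config = sim_config()) {
  if (!is.numeric(state) || length(state) != 4L || any(!is.finite(state)))
    stop("state must be a finite numeric 4-vector")
  validate_params(params)
  x1 <- state[1]; v1 <- state[2]; x2 <- state[3]; v2 <- state[4]
  a1 <- params[["a01"]] + 2 * params[["L"]] * x1
  a2 <- params[["a02"]] + 2 * params[["L"]] * x2
  amin <- min(a1, a2)
  x0 <- params[["x0"]]

  f_aero <- 0
  if (a1 > 0) {
    f_aero <- params[["L"]] * params[["d1"]] * params[["P"]] *
      (1 - smoothed_step(amin, x0) * (amin / a1)^2) * smoothed_step(a1, x0)
  }
  f1 <- f_aero - params[["r1"]] * v1 - params[["k1"]] * x1 -
    params[["kc"]] * (x1 - x2) -
    smoothed_step(-a1, x0) * params[["c1"]] * a1 / (2 * params[["L"]])
  f2 <- -params[["r2"]] * v2 - params[["k2"]] * x2 -
    params[["kc"]] * (x2 - x1) -
    smoothed_step(-a2, x0) * params[["c2"]] * a2 / (2 * params[["L"]])
  c(v1, f1 / params[["m1"]], v2, f2 / params[["m2"]])
}

#' Bernoulli glottal flow
#'
#' Glottal volume velocity through the minimum glottal area:
#' `U = sqrt(2 P / rho) * a_min * Theta(a_min)`, zero when the glottis is
#' closed.
#'
#' @param a_min Minimum glottal area (model area units), may be a vector.
#' @param P Subglottal pressure (g cm^-1 ms^-2), non-negative.
#' @param rho Air density (g cm^-3).
#' @param x0 Smoothed-step length scale (cm).
#' @return Flow in cm^3/ms, same length as `a_min`.
#' @export
glottal_flow <- function(a_min, P, rho = 0.00113, x0 = 0.05) {
  if (!is.numeric(P) || length(P) != 1L || !is.finite(P) || P < 0)
    stop("P must be a single non-negative finite pressure")
  if (rho <= 0) stop("rho must be positive")
  sqrt(2 * P / rho) * a_min * smoothed_step(a_min, x0)
}

#' Simulate the two-mass vocal-fold model
#'
#' Integrates the 4-state symmetric system with classical fixed-step
#' Runge-Kutta (RK4) and returns the glottal-flow waveform with the initial
#' transient removed, plus (optionally) the full state trajectory.
#' Deterministic: identical inputs give bit-identical output.
#'
#' @param params Parameter set from [sh_params()].
#' @param config Simulation configuration from [sim_config()].
#' @param keep_trajectory If `TRUE`, also return the full state trajectory
#'   (including the transient span).
#' @param engine `"cpp"` (default, compiled) or `"r"` (reference
#'   implementation in pure R; slow, used for cross-checking).
#' @return A list of class `"sh_sim"` with elements
#'   \item{flow}{tibble with columns `time_ms`, `u` (cm^3/ms), transient
#'     removed}
#'   \item{diverged}{logical; `TRUE` if the state became non-finite (the
#'     run is then unusable but no error is thrown)}
#'   \item{trajectory}{(optional) tibble with `time_ms`, `x1`, `v1`, `x2`,
#'     `v2`, `a1`, `a2`, `a_min` over the full duration}
#'   \item{config}{the configuration used}
#' @examples
#' sim <- simulate_fold(sh_params(), sim_config(duration = 300, transient = 100))
#' head(sim$flow)
#' @export
simulate_fold <- function(params, config = sim_config(),
                          keep_trajectory = FALSE,
                          engine = c("cpp", "r")) {
  validate_params(params)
  stopifnot(inherits(config, "sim_config"))
  engine <- match.arg(engine)

  if (engine == "cpp") {
    raw <- cpp_simulate(unname(params[param_names()]), config$dt,
                        config$duration, config$transient,
                        config$x_init, config$v_init, config$rho,
                        keep_trajectory)
  } else {
    raw <- simulate_fold_r(params, config, keep_trajectory)
  }

  n <- length(raw$u)
  flow <- tibble::tibble(
    time_ms = raw$t_start + raw$dt * (seq_len(n) - 1),
    u = as.numeric(raw$u)
  )
  out <- list(flow = flow, diverged = isTRUE(raw$diverged), config = config)
  if (keep_trajectory) {
    nt <- length(raw$x1)
    out$trajectory <- tibble::tibble(
      time_ms = config$dt * (seq_len(nt) - 1),
      x1 = as.numeric(raw$x1), v1 = as.numeric(raw$v1),
      x2 = as.numeric(raw$x2), v2 = as.numeric(raw$v2),
      a1 = as.numeric(raw$a1), a2 = as.numeric(raw$a2),
      a_min = as.numeric(raw$a_min)
    )
  }
  class(out) <- "sh_sim"
  out
}

# Pure-R RK4 reference integrator (same contract as the compiled path).
simulate_fold_r <- function(params, config, keep_trajectory) {
  n_steps <- round(config$duration / config$dt)
  n_skip <- round(config$transient / config$dt)
  dt <- config$dt
  s <- c(config$x_init, config$v_init, config$x_init, config$v_init)
  u <- numeric(n_steps - n_skip + 1)
  L <- params[["L"]]; a01 <- params[["a01"]]; a02 <- params[["a02"]]
  flow_coef <- sqrt(2 * params[["P"]] / config$rho)
  traj <- if (keep_trajectory)
    matrix(NA_real_, n_steps + 1, 7) else NULL
  diverged <- FALSE

  for (step in 0:n_steps) {
    a1 <- a01 + 2 * L * s[1]; a2 <- a02 + 2 * L * s[3]
    amin <- min(a1, a2)
    if (keep_trajectory)
      traj[step + 1, ] <- c(s, a1, a2, amin)
    if (step >= n_skip)
      u[step - n_skip + 1] <-
        if (amin > 0) flow_coef * amin * smoothed_step(amin, params[["x0"]]) else 0
    if (any(!is.finite(s)) || max(abs(s[c(1, 3)])) > 1e6) {
      diverged <- TRUE
      break
    }
    if (step == n_steps) break
    k1 <- sh_derivatives(s, params, config)
    k2 <- sh_derivatives(s + dt / 2 * k1, params, config)
    k3 <- sh_derivatives(s + dt / 2 * k2, params, config)
    k4 <- sh_derivatives(s + dt * k3, params, config)
    s <- s + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  out <- list(u = u, dt = dt, t_start = n_skip * dt, diverged = diverged)
  if (keep_trajectory) {
    out$x1 <- traj[, 1]; out$v1 <- traj[, 2]
    out$x2 <- traj[, 3]; out$v2 <- traj[, 4]
    out$a1 <- traj[, 5]; out$a2 <- traj[, 6]; out$a_min <- traj[, 7]
  }
  out
}

#' @export
print.sh_sim <- function(x, ...) {
  cat("<sh_sim>", nrow(x$flow), "flow samples, dt =", x$config$dt, "ms",
      if (x$diverged) "(DIVERGED)" else "", "\n")
  invisible(x)
}

#' Export a glottal-flow waveform to CSV
#'
#' Writes a two-column CSV (`time_ms`, `U_cm3_per_ms`) with a header row
#' and '.' decimal separator.
#'
#' @param sim An `"sh_sim"` object (or a tibble with `time_ms` and `u`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_waveform_csv <- function(sim, path) {
  flow <- if (inherits(sim, "sh_sim")) sim$flow else sim
  stopifnot(all(c("time_ms", "u") %in% names(flow)))
  df <- data.frame(time_ms = flow$time_ms, U_cm3_per_ms = flow$u)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
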