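# Synthetic waveforms and stub measure functions shared across test files.

# Flow tibble for an arbitrary waveform function of time (ms).
synthetic_flow <- function(f, duration_ms = 1000, dt = 0.01) {
  t <- seq(0, duration_ms, by = dt)
  tibble::tibble(time_ms = t, u = f(t))
}

# Half-wave rectified sine at f0 (Hz), amplitude 1 cm^3/ms.
half_wave_flow <- function(f0_hz = 125, duration_ms = 1000, dt = 0.01) {
  synthetic_flow(function(t) pmax(0, sin(2 * pi * f0_hz / 1000 * t)),
                 duration_ms, dt)
}

# Periodic triangular pulses: rise_ms up, fall_ms down, closed the rest.
triangle_flow <- function(rise_ms = 2, fall_ms = 1, period_ms = 8,
                          duration_ms = 1000, dt = 0.01) {
  synthetic_flow(function(t) {
    ph <- t %% period_ms
    ifelse(ph < rise_ms, ph / rise_ms,
           ifelse(ph < rise_ms + fall_ms, 1 - (ph - rise_ms) / fall_ms, 0))
  }, duration_ms, dt)
}

# Harmonic-series waveform sum(a_n * cos(2 pi n f0 t)), offset to be >= 0.
harmonic_flow <- function(amps, f0_hz = 125, duration_ms = 1000, dt = 0.01) {
  synthetic_flow(function(t) {
    u <- rep(1.05 * sum(abs(amps)), length(t))
    for (n in seq_along(amps))
      u <- u + amps[n] * cos(2 * pi * n * f0_hz / 1000 * t)
    u
  }, duration_ms, dt)
}

# Stub measure function: deterministic smooth functions of the parameters,
# always "oscillating". Output y = (P / P_nominal)^2 exercises the
# power-law elasticity; others are constants or linear.
stub_power_measures <- function(params) {
  p0 <- sh_params()
  tibble::tibble(
    y = (params[["P"]] / p0[["P"]])^2,
    lin = 3 * (params[["L"]] / p0[["L"]]),
    const = 7,
    oscillating = TRUE
  )
}

# Stub producing the full standard measure set with values mid-range of
# every normal-phonation bound (always passes the filter).
stub_normal_measures <- function(params) {
  tibble::tibble(
    f0_hz = 150, mean_flow_cm3s = 200, ac_flow_cm3s = 300,
    max_flow_cm3s = 400, mfdr_ls2 = 500, oq = 0.6, sq = 1.3,
    period_cov = 0.001, oscillating = TRUE,
    hrf_db = -10, h1h2_db = 5, spectral_flagged = FALSE
  )
}
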