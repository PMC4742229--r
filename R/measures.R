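#' Unit conversions between model and clinical units
#'
#' The model works in the g-cm-ms unit system while normal-phonation bounds
#' are stated in clinical units. Supported conversion ids:
#' \describe{
#'   \item{`cm3_ms_to_cm3_s` / `cm3_s_to_cm3_ms`}{flow, factor 1000}
#'   \item{`cm3_ms2_to_l_s2` / `l_s2_to_cm3_ms2`}{flow declination rate,
#'     factor 1000}
#'   \item{`g_cm_ms2_to_cmh2o` / `cmh2o_to_g_cm_ms2`}{pressure, factor
#'     `1e6 / 980.665`}
#' }
#'
#' @param value Numeric vector.
#' @param kind Conversion id (see above).
#' @return Converted numeric vector.
#' @examples
#' convert_units(0.2, "cm3_ms_to_cm3_s")  # 200 cm^3/s
#' convert_units(0.008, "g_cm_ms2_to_cmh2o")  # ~8.16 cm H2O
#' @export
convert_units <- function(value, kind) {
  factors <- c(
    cm3_ms_to_cm3_s = 1000,
    cm3_s_to_cm3_ms = 1 / 1000,
    cm3_ms2_to_l_s2 = 1000,
    l_s2_to_cm3_ms2 = 1 / 1000,
    g_cm_ms2_to_cmh2o = 1e6 / 980.665,
    cmh2o_to_g_cm_ms2 = 980.665 / 1e6
  )
  if (!is.character(kind) || length(kind) != 1L || !kind %in% names(factors))
    stop("unknown conversion id: ", kind)
  value * factors[[kind]]
}

as_flow_tibble <- function(flow) {
  if (inherits(flow, "sh_sim")) flow <- flow$flow
  stopifnot(is.data.frame(flow), all(c("time_ms", "u") %in% names(flow)))
  flow
}

#' Detect glottal-flow cycles
#'
#' Cycle boundaries are the upward crossings of the threshold
#' `min(U) + eps * (max(U) - min(U))`; for waveforms with full glottal
#' closure (`min(U) = 0`) this reduces to `eps * max(U)`, while
#' oscillation with incomplete closure (flow never near zero) is still
#' detected. A crossing only counts as a boundary once the waveform also
#' reaches mid-level (hysteresis), so secondary ripples near the trough
#' are not mistaken for pulse onsets. Returns an integer vector of
#' boundary sample indices
#' (first sample at or above threshold), with an attribute `"time_ms"`
#' holding linearly interpolated crossing times for sub-sample period
#' estimation. An empty vector encodes absent oscillation.
#'
#' @param flow An `"sh_sim"` object or a tibble with `time_ms`, `u`.
#' @param eps Relative open/closed threshold (fraction of peak flow).
#' @return Integer vector of boundary indices (possibly empty).
#' @export
detect_cycles <- function(flow, eps = 0.01) {
  flow <- as_flow_tibble(flow)
  det <- cpp_detect_cycles(flow$u, eps)
  idx <- det$idx
  if (!length(idx)) return(integer(0))
  dt <- flow$time_ms[2] - flow$time_ms[1]
  structure(idx, time_ms = flow$time_ms[idx - 1L] + det$frac * dt)
}

#' Time-domain voice-source measures
#'
#' Extracts the cycle-based measures from a glottal-flow waveform:
#' fundamental frequency (reciprocal mean period), mean flow (time average
#' over complete cycles), AC flow (mean per-cycle peak-to-trough
#' amplitude), maximum flow, maximum flow declination rate (peak of
#' `-dU/dt` by centered differences), open quotient (mean fraction of the
#' cycle with flow above threshold) and speed quotient (mean ratio of rise
#' to fall duration within the open phase). At least 20 complete cycles are
#' required; otherwise the waveform is classified as non-oscillating and
#' all measures are `NA`.
#'
#' @param flow An `"sh_sim"` object or tibble with `time_ms`, `u`.
#' @param cycles Cycle boundaries from [detect_cycles()]; computed if `NULL`.
#' @param eps Relative open/closed threshold.
#' @param min_cycles Minimum number of complete cycles for validity.
#' @return One-row tibble with columns `f0_hz`, `mean_flow_cm3s`,
#'   `ac_flow_cm3s`, `max_flow_cm3s`, `mfdr_ls2`, `oq`, `sq`,
#'   `period_cov`, `oscillating`.
#' @export
time_domain_measures <- function(flow, cycles = NULL, eps = 0.01,
                                 min_cycles = 20L) {
  flow <- as_flow_tibble(flow)
  if (is.null(cycles)) cycles <- detect_cycles(flow, eps)
  nb <- length(cycles)
  if (nb < min_cycles + 1L) return(invalid_time_measures())
  dt <- flow$time_ms[2] - flow$time_ms[1]
  vals <- td_values(flow$u, cycles, attr(cycles, "time_ms"), dt, eps)
  tibble::as_tibble_row(c(as.list(vals), oscillating = TRUE))
}

# shared numeric core of the time-domain measures (no tibbles)
td_values <- function(u, idx, t_cross, dt, eps) {
  nb <- length(idx)
  periods <- diff(t_cross)
  mp <- mean(periods)
  span <- cpp_span_stats(u, idx[1], idx[nb] - 1L, dt)
  thr <- min(u) + eps * (max(u) - min(u))
  cs <- cpp_cycle_stats(u, idx[-nb], idx[-1], thr)
  cyc_len <- diff(idx)
  ok_sq <- cs[, 4] > 0 & cs[, 5] > 0
  c(f0_hz = 1000 / mp,
    mean_flow_cm3s = span[1] * 1000,
    ac_flow_cm3s = mean(cs[, 1] - cs[, 2]) * 1000,
    max_flow_cm3s = span[2] * 1000,
    mfdr_ls2 = span[3] * 1000,
    oq = mean(cs[, 3] / cyc_len),
    sq = if (any(ok_sq)) mean(cs[ok_sq, 4] / cs[ok_sq, 5]) else NA_real_,
    period_cov = stats::sd(periods) / mp)
}

invalid_time_measures <- function() {
  tibble::tibble(
    f0_hz = NA_real_, mean_flow_cm3s = NA_real_, ac_flow_cm3s = NA_real_,
    max_flow_cm3s = NA_real_, mfdr_ls2 = NA_real_, oq = NA_real_,
    sq = NA_real_, period_cov = NA_real_, oscillating = FALSE
  )
}

#' Spectral voice-source measures
#'
#' Computes the harmonic richness factor and H1-H2 from the discrete
#' spectrum of the waveform trimmed to an integer number of cycles
#' (rectangular window, so harmonic frequencies fall on exact bins).
#' Harmonic amplitudes `A_n` of the flow are evaluated at `n * f0` by the
#' Goertzel recursion. The harmonic richness factor is a source-spectrum
#' measure, `HRF = 10 log10(sum_{n>=2} A_n^2 / A_1^2)`. H1-H2 is an
#' acoustic spectral-tilt measure: the radiated pressure is proportional
#' to the flow derivative (monopole radiation), whose n-th harmonic
#' amplitude is `n * omega0 * A_n`, so
#' `H1-H2 = 20 log10(A_1 / (2 A_2))`. Degenerate spectra (vanishing `A_1`
#' or `A_2`) are floored at -100 dB / ceilinged at +100 dB and flagged.
#'
#' @param flow An `"sh_sim"` object or tibble with `time_ms`, `u`.
#' @param f0 Fundamental frequency in Hz (accepted for interface
#'   compatibility; harmonic frequencies are derived from the detected
#'   cycle boundaries, which is equivalent for a steady waveform).
#' @param cycles Optional precomputed boundaries from [detect_cycles()].
#' @param eps Relative threshold for the internal cycle trim.
#' @param max_harmonics Highest harmonic summed into the HRF (capped at
#'   the Nyquist frequency).
#' @param max_cycles Analysis segment length in cycles (the last
#'   `max_cycles` complete cycles are used; the window stays an integer
#'   number of periods either way).
#' @return One-row tibble with `hrf_db`, `h1h2_db`, `spectral_flagged`.
#' @export
spectral_measures <- function(flow, f0 = NULL, cycles = NULL, eps = 0.01,
                              max_harmonics = 64L, max_cycles = 64L) {
  flow <- as_flow_tibble(flow)
  if (is.null(cycles)) cycles <- detect_cycles(flow, eps)
  if (length(cycles) < 2L)
    return(tibble::tibble(hrf_db = NA_real_, h1h2_db = NA_real_,
                          spectral_flagged = TRUE))
  vals <- spectral_values(flow$u, cycles, max_harmonics, max_cycles)
  tibble::tibble(hrf_db = vals[["hrf_db"]], h1h2_db = vals[["h1h2_db"]],
                 spectral_flagged = as.logical(vals[["spectral_flagged"]]))
}

# shared numeric core of the spectral measures
spectral_values <- function(u, idx, max_harmonics, max_cycles) {
  nb <- length(idx)
  first <- max(1L, nb - max_cycles)
  n_cyc <- nb - first
  a <- idx[first]; b <- idx[nb] - 1L
  n <- b - a + 1L
  n_harm <- min(max_harmonics, floor(n / n_cyc / 2))
  omegas <- 2 * pi * (1:n_harm) * n_cyc / n
  amps <- 2 / n * cpp_goertzel(u, omegas, a, b)

  a1 <- amps[1]; a2 <- amps[2]
  tiny <- 1e-12 * max(amps, 0)
  flagged <- FALSE
  if (a1 <= tiny) {
    hrf <- -100; h1h2 <- 100; flagged <- TRUE
  } else {
    rest <- sum(amps[-1]^2)
    if (rest <= tiny^2) {
      hrf <- -100; flagged <- TRUE
    } else hrf <- 10 * log10(rest / a1^2)
    if (a2 <= tiny) {
      h1h2 <- 100; flagged <- TRUE
    } else h1h2 <- 20 * log10(a1 / (2 * a2))
  }
  c(hrf_db = hrf, h1h2_db = h1h2, spectral_flagged = flagged)
}

#' Extract all voice-source measures from a simulation
#'
#' Runs cycle detection, the time-domain measures and (optionally) the
#' spectral measures, returning one tidy row. Diverged or non-oscillating
#' simulations yield `oscillating = FALSE` with `NA` measures.
#'
#' @param sim An `"sh_sim"` object or tibble with `time_ms`, `u`.
#' @param eps Relative open/closed threshold.
#' @param max_harmonics Harmonic cap for the HRF sum.
#' @param spectral If `FALSE`, skip HRF/H1-H2 (used for sensitivity
#'   re-simulations where only the six core outputs are needed).
#' @return One-row tibble of measures.
#' @export
extract_measures <- function(sim, eps = 0.01, max_harmonics = 64L,
                             spectral = TRUE) {
  if (inherits(sim, "sh_sim") && sim$diverged) {
    out <- invalid_time_measures()
    if (spectral)
      out <- dplyr::bind_cols(out, tibble::tibble(
        hrf_db = NA_real_, h1h2_db = NA_real_, spectral_flagged = TRUE))
    return(out)
  }
  flow <- as_flow_tibble(sim)
  cycles <- detect_cycles(flow, eps)
  td <- time_domain_measures(flow, cycles, eps)
  if (!spectral) return(td)
  sp <- if (td$oscillating)
    spectral_measures(flow, td$f0_hz, cycles, eps, max_harmonics)
  else
    tibble::tibble(hrf_db = NA_real_, h1h2_db = NA_real_,
                   spectral_flagged = TRUE)
  dplyr::bind_cols(td, sp)
}

#' Normal-phonation acceptance bounds
#'
#' The six output ranges within which model behaviour is considered
#' representative of normal human phonation: fundamental frequency 88-263
#' Hz, mean flow 50-420 cm^3/s, AC flow 40-800 cm^3/s, MFDR 100-1150
#' L/s^2, HRF -19-2.1 dB, H1-H2 -24-11 dB.
#'
#' @return Tibble with columns `measure`, `low`, `high`.
#' @export
normal_criteria <- function() {
  tibble::tibble(
    measure = c("f0_hz", "mean_flow_cm3s", "ac_flow_cm3s",
                "mfdr_ls2", "hrf_db", "h1h2_db"),
    low = c(88, 50, 40, 100, -19, -24),
    high = c(263, 420, 800, 1150, 2.1, 11)
  )
}

#' Classify normal phonation
#'
#' Applies the six acceptance bounds (inclusively) plus a steadiness gate
#' (period coefficient of variation below `steady_cov`) to a tibble of
#' measures. Non-oscillating rows fail regardless of the bounds.
#'
#' @param measures Tibble with the measure columns of
#'   [extract_measures()]; may have several rows.
#' @param criteria Bounds tibble as from [normal_criteria()].
#' @param steady_cov Maximum period coefficient of variation for "steady"
#'   phonation.
#' @return `measures` with logical columns `pass_<measure>` per criterion,
#'   `pass_steady`, and the overall `pass_normal`.
#' @export
classify_normal <- function(measures, criteria = normal_criteria(),
                            steady_cov = 0.05) {
  stopifnot(all(criteria$low < criteria$high))
  out <- measures
  flag_cols <- character(0)
  for (i in seq_len(nrow(criteria))) {
    m <- criteria$measure[i]
    col <- paste0("pass_", m)
    v <- measures[[m]]
    out[[col]] <- !is.na(v) & v >= criteria$low[i] & v <= criteria$high[i]
    flag_cols <- c(flag_cols, col)
  }
  out$pass_steady <- !is.na(measures$period_cov) &
    measures$period_cov < steady_cov
  all_flags <- c(flag_cols, "pass_steady")
  out$pass_normal <- measures$oscillating &
    Reduce(`&`, lapply(all_flags, function(cl) out[[cl]]))
  out
}

# ---- internal fast path -----------------------------------------------------
# Simulate one parameter set and classify it without building any tibbles.
# Spectral measures are only computed once the cheap time-domain bounds
# already pass (lazy evaluation of the same filter). Returns a list:
# pass, oscillating, measures (named numeric incl. NA hrf/h1h2 when the
# subject was rejected before the spectral stage).
fast_attempt <- function(params, config, crit_lo, crit_hi, eps = 0.01,
                         steady_cov = 0.05, max_harmonics = 64L,
                         need_spectral = TRUE) {
  raw <- cpp_simulate(unname(params[param_names()]), config$dt,
                      config$duration, config$transient,
                      config$x_init, config$v_init, config$rho, FALSE)
  fail <- list(pass = FALSE, oscillating = FALSE, measures = NULL)
  if (isTRUE(raw$diverged)) return(fail)
  det <- cpp_detect_cycles(raw$u, eps)
  nb <- length(det$idx)
  if (nb < 21L) return(fail)
  t_cross <- (det$idx + det$frac) * raw$dt
  td <- td_values(raw$u, det$idx, t_cross, raw$dt, eps)

  td_ok <- td[["period_cov"]] < steady_cov &&
    td[["f0_hz"]] >= crit_lo[["f0_hz"]] && td[["f0_hz"]] <= crit_hi[["f0_hz"]] &&
    td[["mean_flow_cm3s"]] >= crit_lo[["mean_flow_cm3s"]] &&
    td[["mean_flow_cm3s"]] <= crit_hi[["mean_flow_cm3s"]] &&
    td[["ac_flow_cm3s"]] >= crit_lo[["ac_flow_cm3s"]] &&
    td[["ac_flow_cm3s"]] <= crit_hi[["ac_flow_cm3s"]] &&
    td[["mfdr_ls2"]] >= crit_lo[["mfdr_ls2"]] && td[["mfdr_ls2"]] <= crit_hi[["mfdr_ls2"]]

  if (!td_ok) {
    return(list(pass = FALSE, oscillating = TRUE,
                measures = c(td, hrf_db = NA_real_, h1h2_db = NA_real_)))
  }
  if (!need_spectral) {
    return(list(pass = TRUE, oscillating = TRUE,
                measures = c(td, hrf_db = NA_real_, h1h2_db = NA_real_)))
  }
  sp <- spectral_values(raw$u, det$idx, max_harmonics, 64L)
  pass <- !sp[["spectral_flagged"]] &&
    sp[["hrf_db"]] >= crit_lo[["hrf_db"]] && sp[["hrf_db"]] <= crit_hi[["hrf_db"]] &&
    sp[["h1h2_db"]] >= crit_lo[["h1h2_db"]] && sp[["h1h2_db"]] <= crit_hi[["h1h2_db"]]
  list(pass = pass, oscillating = TRUE,
       measures = c(td, hrf_db = sp[["hrf_db"]], h1h2_db = sp[["h1h2_db"]]))
}

# Fast extraction of the six sensitivity outputs (plus the rest of the
# time-domain set); no spectral stage, no tibbles. Returns named numeric
# or NULL when the run is unusable.
fast_outputs <- function(params, config, eps = 0.01) {
  raw <- cpp_simulate(unname(params[param_names()]), config$dt,
                      config$duration, config$transient,
                      config$x_init, config$v_init, config$rho, FALSE)
  if (isTRUE(raw$diverged)) return(NULL)
  det <- cpp_detect_cycles(raw$u, eps)
  if (length(det$idx) < 21L) return(NULL)
  t_cross <- (det$idx + det$frac) * raw$dt
  td_values(raw$u, det$idx, t_cross, raw$dt, eps)
}

criteria_bounds <- function(criteria) {
  list(lo = setNames(criteria$low, criteria$measure),
       hi = setNames(criteria$high, criteria$measure))
}
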