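#' The six model outputs used in sensitivity analyses
#'
#' Fundamental frequency, mean flow, maximum flow, maximum flow
#' declination rate, open quotient and speed quotient, named by their
#' measure-table columns.
#'
#' @return Named character vector: display names keyed by column name.
#' @export
sensitivity_outputs <- function() {
  c(f0_hz = "Frequency", mean_flow_cm3s = "Mean Flow",
    max_flow_cm3s = "Max Flow", mfdr_ls2 = "MFDR",
    oq = "OQ", sq = "SQ")
}

measures_for_sensitivity <- function(params, config, measure_fn) {
  if (is.null(measure_fn)) {
    fast_outputs(params, config)  # named numeric, or NULL when unusable
  } else {
    measure_fn(params)
  }
}

row_oscillating <- function(m) {
  if (is.null(m)) return(FALSE)
  !("oscillating" %in% names(m)) || isTRUE(m[["oscillating"]])
}

#' Non-dimensional local sensitivities of one subject
#'
#' For each input parameter, re-simulates with that parameter scaled by
#' `(1 + delta)` (all others fixed) and forms the forward-difference
#' elasticity `S* = ((F_perturbed - F_base) / F_base) / delta` for each
#' output. `S*` reads as percent output change per percent input change.
#' Records are flagged invalid when the perturbed run fails to oscillate,
#' an output is missing, or the base output is zero.
#'
#' @param params The subject's parameter set (should pass the
#'   normal-phonation filter for meaningful results).
#' @param delta Relative perturbation (default 0.01, i.e. +1%).
#' @param outputs Character vector of output columns (default the six of
#'   [sensitivity_outputs()]).
#' @param inputs Parameters to perturb (default all 16).
#' @param base Optional one-row tibble of base measures (avoids one
#'   simulation when already available).
#' @param config Simulation configuration.
#' @param measure_fn Optional stub replacing simulate-and-measure
#'   (testing hook), a function of a parameter vector returning a one-row
#'   tibble containing the `outputs` columns.
#' @return Tibble with columns `input`, `output`, `s_star`, `valid`.
#' @export
local_sensitivity <- function(params, delta = 0.01,
                              outputs = names(sensitivity_outputs()),
                              inputs = param_names(), base = NULL,
                              config = sim_config(), measure_fn = NULL) {
  stopifnot(delta > 0, all(inputs %in% names(params)))
  if (is.null(base))
    base <- measures_for_sensitivity(params, config, measure_fn)
  base_ok <- row_oscillating(base)
  f_base <- if (is.null(base)) rep(NA_real_, length(outputs)) else
    vapply(outputs, function(o) as.numeric(base[[o]][1]), numeric(1))

  purrr::map_dfr(inputs, function(inp) {
    pert <- params
    pert[[inp]] <- pert[[inp]] * (1 + delta)
    m <- measures_for_sensitivity(pert, config, measure_fn)
    ok <- base_ok && row_oscillating(m)
    f_pert <- if (is.null(m)) rep(NA_real_, length(outputs)) else
      vapply(outputs, function(o) as.numeric(m[[o]][1]), numeric(1))
    s <- unname((f_pert - f_base) / f_base / delta)
    valid <- unname(ok & is.finite(s) & is.finite(f_base) & f_base != 0)
    tibble::tibble(input = inp, output = outputs,
                   s_star = ifelse(valid, s, NA_real_), valid = valid)
  })
}

#' Sensitivity tensor over a population
#'
#' Applies [local_sensitivity()] to every accepted subject of a
#' population, reusing each subject's stored measures as the unperturbed
#' base (16 re-simulations per subject).
#'
#' @param pop A `"vp_population"` from [generate_population()].
#' @param delta Relative perturbation.
#' @param outputs Output columns.
#' @param config Simulation configuration.
#' @param measure_fn Optional stub, as in [local_sensitivity()].
#' @param verbose Print progress every 50 subjects.
#' @return Tibble (class `"vp_tensor"`): `rmax`, `subject`, `input`,
#'   `output`, `s_star`, `valid` -- 96 records per subject.
#' @export
population_sensitivity <- function(pop, delta = 0.01,
                                   outputs = names(sensitivity_outputs()),
                                   config = sim_config(), measure_fn = NULL,
                                   verbose = FALSE) {
  stopifnot(nrow(pop) >= 1)
  rmax <- attr(pop, "rmax")
  pcols <- param_names()
  res <- purrr::map_dfr(seq_len(nrow(pop)), function(i) {
    params <- setNames(as.numeric(pop[i, pcols][1, ]), pcols)
    base <- pop[i, , drop = FALSE]
    if (verbose && i %% 50L == 0L) message("subject ", i, "/", nrow(pop))
    local_sensitivity(params, delta, outputs, base = base,
                      config = config, measure_fn = measure_fn) |>
      dplyr::mutate(subject = pop$subject[i], .before = 1)
  })
  res <- dplyr::mutate(res, rmax = rmax, .before = 1)
  class(res) <- c("vp_tensor", class(res))
  res
}

classify_consistency <- function(mean, sd) {
  dplyr::case_when(
    abs(mean) >= 2 * sd ~ "consistent",
    abs(mean) >= sd ~ "within-2sd",
    TRUE ~ "within-1sd"
  )
}

#' Summarize the sensitivity tensor per input-output pair
#'
#' With `by_range = TRUE`, returns one row per (`rmax`, `input`,
#' `output`): the median, 5th and 95th percentile, mean and standard
#' deviation of valid `S*` records, exclusion counts, and the consistency
#' class (`consistent` when `|mean| >= 2 sd`, `within-2sd` when
#' `sd <= |mean| < 2 sd`, else `within-1sd`). The default view computes
#' those statistics within each range and then averages the
#' median/percentiles across ranges, matching how multi-range results are
#' tabulated.
#'
#' @param tensor A `"vp_tensor"` (possibly several `rmax` values bound
#'   together with `dplyr::bind_rows()`).
#' @param by_range Return the per-range table instead of the
#'   range-averaged one.
#' @return A tibble (see above).
#' @export
summarize_pairs <- function(tensor, by_range = FALSE) {
  per_range <- tensor |>
    dplyr::group_by(.data$rmax, .data$input, .data$output) |>
    dplyr::summarise(
      n_valid = sum(.data$valid),
      n_invalid = sum(!.data$valid),
      median = if (sum(.data$valid)) median(.data$s_star[.data$valid]) else NA_real_,
      p5 = if (sum(.data$valid)) quantile(.data$s_star[.data$valid], 0.05, names = FALSE) else NA_real_,
      p95 = if (sum(.data$valid)) quantile(.data$s_star[.data$valid], 0.95, names = FALSE) else NA_real_,
      mean = if (sum(.data$valid)) mean(.data$s_star[.data$valid]) else NA_real_,
      sd = if (sum(.data$valid) > 1) sd(.data$s_star[.data$valid]) else 0,
      .groups = "drop"
    ) |>
    dplyr::mutate(class = classify_consistency(.data$mean, .data$sd))
  if (by_range) return(per_range)
  per_range |>
    dplyr::group_by(.data$input, .data$output) |>
    dplyr::summarise(
      p5 = mean(.data$p5, na.rm = TRUE),
      median = mean(.data$median, na.rm = TRUE),
      p95 = mean(.data$p95, na.rm = TRUE),
      n_valid = sum(.data$n_valid),
      n_invalid = sum(.data$n_invalid),
      n_ranges = dplyr::n(),
      .groups = "drop"
    )
}

#' Rank inputs by overall influence
#'
#' Orders the input parameters by the mean absolute (range-averaged)
#' median sensitivity across outputs, most influential first. Ties break
#' lexicographically by input name.
#'
#' @param summaries Range-averaged summary from [summarize_pairs()].
#' @return Tibble `input`, `influence`, `rank`.
#' @export
rank_inputs <- function(summaries) {
  summaries |>
    dplyr::group_by(.data$input) |>
    dplyr::summarise(influence = mean(abs(.data$median), na.rm = TRUE),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$influence), .data$input) |>
    dplyr::mutate(rank = dplyr::row_number())
}

# ---- designed-experiment methods -------------------------------------------

#' One-at-a-time (OAT) sensitivity analysis
#'
#' Varies each parameter to `nominal * (1 - p)` and `nominal * (1 + p)`
#' in turn, all others held nominal (2 levels x 16 parameters = 32 runs),
#' and reports the normalized central-difference elasticity
#' `S* = (F_high - F_low) / F_mid / (2 p)` with `F_mid` the mean of the
#' two endpoint values. A pair is marked unavailable when either endpoint
#' fails the normal-phonation filter. By construction the method cannot
#' see interactions between parameters.
#'
#' @param nominal Nominal parameter set.
#' @param percent_range Half-range `p` as a fraction (e.g. 0.07 for ±7%).
#' @param outputs Output columns.
#' @param criteria Normal-phonation bounds for the endpoint filter (set
#'   `NULL` to skip filtering, e.g. with stubs).
#' @param config Simulation configuration.
#' @param measure_fn Optional stub, as in [local_sensitivity()].
#' @return List with `design` (32-row tibble: `run`, `input`, `level`,
#'   normalized settings `z_*`, `pass`) and `sensitivities`
#'   (`input`, `output`, `s_star`, `valid`).
#' @export
oat_analysis <- function(nominal = sh_params(), percent_range,
                         outputs = names(sensitivity_outputs()),
                         criteria = normal_criteria(),
                         config = sim_config(), measure_fn = NULL) {
  stopifnot(percent_range > 0)
  inputs <- names(nominal)
  runs <- tidyr::expand_grid(input = inputs, level = c(-1, 1))
  results <- purrr::pmap(runs, function(input, level) {
    params <- nominal
    params[[input]] <- params[[input]] * (1 + level * percent_range)
    m <- if (is.null(measure_fn))
      extract_measures(simulate_fold(params, config))
    else measure_fn(params)
    pass <- if (is.null(criteria)) row_oscillating(m)
    else isTRUE(classify_normal(m, criteria)$pass_normal)
    list(m = m, pass = pass)
  })
  zmat <- matrix(0, nrow(runs), length(inputs),
                 dimnames = list(NULL, paste0("z_", inputs)))
  for (i in seq_len(nrow(runs)))
    zmat[i, paste0("z_", runs$input[i])] <- runs$level[i]
  design <- dplyr::bind_cols(
    tibble::tibble(run = seq_len(nrow(runs))), runs,
    tibble::as_tibble(zmat),
    tibble::tibble(pass = vapply(results, `[[`, logical(1), "pass"))
  )

  sens <- purrr::map_dfr(inputs, function(inp) {
    i_lo <- which(runs$input == inp & runs$level == -1)
    i_hi <- which(runs$input == inp & runs$level == 1)
    ok <- results[[i_lo]]$pass && results[[i_hi]]$pass
    purrr::map_dfr(outputs, function(o) {
      f_lo <- as.numeric(results[[i_lo]]$m[[o]][1])
      f_hi <- as.numeric(results[[i_hi]]$m[[o]][1])
      f_mid <- (f_lo + f_hi) / 2
      s <- (f_hi - f_lo) / f_mid / (2 * percent_range)
      valid <- ok && is.finite(s) && f_mid != 0
      tibble::tibble(input = inp, output = o,
                     s_star = ifelse(valid, s, NA_real_), valid = valid)
    })
  })
  list(design = design, sensitivities = sens)
}

#' Cotter systematic fractional factorial design
#'
#' The 2n+2-run screening design: run 0 with every parameter at its low
#' extreme, runs 1..n flipping one parameter high with the rest low, runs
#' n+1..2n flipping one parameter low with the rest high, and run 2n+1
#' with every parameter high.
#'
#' @param n_params Number of parameters `n`.
#' @param low,high Low/high levels, scalars or length-`n` vectors.
#' @param names Optional parameter names (default `x1..xn`, or
#'   [param_names()] when `n_params == 16`).
#' @return Tibble with `run` (0-based), `role` (one of `all_low`,
#'   `one_high`, `one_low`, `all_high`), `flip` (flipped parameter or
#'   `NA`), and one settings column per parameter.
#' @export
cotter_design <- function(n_params = 16L, low = -1, high = 1, names = NULL) {
  low <- rep_len(low, n_params)
  high <- rep_len(high, n_params)
  stopifnot(all(low < high))
  if (is.null(names))
    names <- if (n_params == 16L) param_names() else paste0("x", seq_len(n_params))
  n <- n_params
  m <- matrix(rep(low, each = 2 * n + 2), nrow = 2 * n + 2)
  colnames(m) <- names
  for (j in seq_len(n)) m[1 + j, j] <- high[j]            # one high, rest low
  for (j in seq_len(n)) m[1 + n + j, ] <- high            # rest high...
  for (j in seq_len(n)) m[1 + n + j, j] <- low[j]         # ...one low
  m[2 * n + 2, ] <- high
  tibble::tibble(
    run = 0:(2 * n + 1),
    role = c("all_low", rep("one_high", n), rep("one_low", n), "all_high"),
    flip = c(NA, names, names, NA)
  ) |>
    dplyr::bind_cols(tibble::as_tibble(m))
}

#' Cotter odd/even effect indices
#'
#' From the `2n+2` responses of a [cotter_design()] run (in design order),
#' computes per parameter `j` the odd-order effect
#' `C_odd = ((y_allhigh - y_onelow_j) + (y_onehigh_j - y_alllow)) / 4`,
#' the even-order effect
#' `C_even = ((y_allhigh - y_onelow_j) - (y_onehigh_j - y_alllow)) / 4`,
#' and the influence measure `|C_odd| + |C_even|`. For an additive linear
#' response the odd index recovers the main-effect coefficient and the
#' even index vanishes; a pure two-way interaction shows up only in the
#' even index. If any response is missing the whole analysis is
#' unavailable (all-`NA` result with a warning), the documented failure
#' mode of the method.
#'
#' @param responses Numeric vector of length `2n+2`.
#' @param names Optional parameter names.
#' @return Tibble `input`, `c_odd`, `c_even`, `total`, `valid`.
#' @export
cotter_indices <- function(responses, names = NULL) {
  len <- length(responses)
  stopifnot(len >= 4, len %% 2 == 0)
  n <- (len - 2L) / 2L
  if (is.null(names))
    names <- if (n == 16L) param_names() else paste0("x", seq_len(n))
  if (any(!is.finite(responses))) {
    warning("failed run(s) in Cotter design: analysis unavailable",
            call. = FALSE)
    return(tibble::tibble(input = names, c_odd = NA_real_,
                          c_even = NA_real_, total = NA_real_,
                          valid = FALSE))
  }
  y0 <- responses[1]
  y_hi_j <- responses[1 + seq_len(n)]
  y_lo_j <- responses[1 + n + seq_len(n)]
  yn <- responses[2 * n + 2]
  c_odd <- ((yn - y_lo_j) + (y_hi_j - y0)) / 4
  c_even <- ((yn - y_lo_j) - (y_hi_j - y0)) / 4
  tibble::tibble(input = names, c_odd = c_odd, c_even = c_even,
                 total = abs(c_odd) + abs(c_even), valid = TRUE)
}

#' Run Cotter's method on the vocal-fold model
#'
#' Builds the 34-run design at `nominal * (1 ± percent_range)`, simulates
#' every run, and computes the Cotter indices per output. If any run
#' fails the normal-phonation filter the analysis is unavailable.
#'
#' @inheritParams oat_analysis
#' @return List with `design`, `responses` (34 x outputs tibble), and
#'   `indices` (per output, bound rows of [cotter_indices()]).
#' @export
cotter_analysis <- function(nominal = sh_params(), percent_range,
                            outputs = names(sensitivity_outputs()),
                            criteria = normal_criteria(),
                            config = sim_config(), measure_fn = NULL) {
  des <- cotter_design(length(nominal),
                       low = nominal * (1 - percent_range),
                       high = nominal * (1 + percent_range),
                       names = names(nominal))
  pmat <- as.matrix(des[, names(nominal)])
  rows <- purrr::map(seq_len(nrow(pmat)), function(i) {
    params <- setNames(pmat[i, ], names(nominal))
    m <- if (is.null(measure_fn))
      extract_measures(simulate_fold(params, config))
    else measure_fn(params)
    pass <- if (is.null(criteria)) row_oscillating(m)
    else isTRUE(classify_normal(m, criteria)$pass_normal)
    list(m = m, pass = pass)
  })
  resp <- purrr::map_dfc(outputs, function(o) {
    v <- vapply(rows, function(r)
      if (r$pass) as.numeric(r$m[[o]][1]) else NA_real_, numeric(1))
    tibble::tibble(!!o := v)
  })
  idx <- purrr::map_dfr(outputs, function(o) {
    cotter_indices(resp[[o]], names = names(nominal)) |>
      dplyr::mutate(output = o, .before = 1)
  })
  list(design = des, responses = resp, indices = idx)
}

# ---- D-optimal quadratic response surface ----------------------------------

#' Full quadratic model matrix
#'
#' Expands an `n x p` matrix of normalized settings into the
#' `1 + p + p + p(p-1)/2` columns of the full second-order model:
#' intercept, linear, pure quadratic and pairwise interaction terms
#' (153 terms for p = 16).
#'
#' @param z Matrix or data frame of normalized coordinates.
#' @return Numeric model matrix with named columns.
#' @export
quad_model_matrix <- function(z) {
  z <- as.matrix(z)
  p <- ncol(z)
  nm <- colnames(z)
  if (is.null(nm)) nm <- paste0("x", seq_len(p))
  cols <- list(`(Intercept)` = rep(1, nrow(z)))
  for (j in seq_len(p)) cols[[nm[j]]] <- z[, j]
  for (j in seq_len(p)) cols[[paste0(nm[j], "^2")]] <- z[, j]^2
  for (j in seq_len(p - 1)) for (k in (j + 1):p)
    cols[[paste0(nm[j], ":", nm[k])]] <- z[, j] * z[, k]
  do.call(cbind, cols)
}

#' D-optimal design for the full quadratic model
#'
#' Selects `n_points` rows from a candidate set on the normalized
#' hypercube `[-1, 1]^p` to maximize the log-determinant of the
#' information matrix `X'X` of the full quadratic model: a seeded random
#' start refined by Fedorov exchange passes (each swap's determinant
#' ratio evaluated exactly via the leverage identities). The default candidate
#' set is a seeded Latin hypercube of `n_candidates` points plus the
#' centre and the axial (one-coordinate ±1) points. Deterministic given
#' `seed`.
#'
#' @param n_points Number of design points (>= number of model terms for
#'   a subsequent fit).
#' @param n_params Dimension of the design space.
#' @param n_candidates Size of the Latin-hypercube candidate set.
#' @param seed Optional integer seed for candidate generation.
#' @param candidates Optional explicit candidate matrix (overrides the
#'   generated set). If `n_points` equals the candidate count the full
#'   candidate set is returned.
#' @param exchange_passes Number of Fedorov exchange sweeps.
#' @return Tibble of class `"vp_design"` with `run` and `z_*` columns;
#'   attribute `log_det` holds the achieved log-determinant.
#' @export
d_optimal_design <- function(n_points = 231L, n_params = 16L,
                             n_candidates = 5000L, seed = NULL,
                             candidates = NULL, exchange_passes = 3L) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(candidates)) {
    lh <- lhs::randomLHS(n_candidates, n_params) * 2 - 1
    axial <- matrix(0, 2 * n_params + 1, n_params)
    for (j in seq_len(n_params)) {
      axial[2 * j - 1, j] <- -1
      axial[2 * j, j] <- 1
    }
    candidates <- rbind(lh, axial)
  }
  candidates <- as.matrix(candidates)
  if (is.null(colnames(candidates)))
    colnames(candidates) <- if (ncol(candidates) == 16L) param_names()
      else paste0("x", seq_len(ncol(candidates)))
  nc <- nrow(candidates)
  stopifnot(n_points <= nc)

  X <- quad_model_matrix(candidates)
  q <- ncol(X)

  if (n_points == nc) {
    sel <- seq_len(nc)
  } else {
    # seeded random start, then Fedorov exchange with rank-one
    # Sherman-Morrison updates of the inverse information matrix; the
    # leverage identities give the exact determinant-ratio of each
    # candidate swap without refactorizing
    sel <- sample.int(nc, n_points)
    refresh <- function(sel) {
      Minv <- solve(crossprod(X[sel, , drop = FALSE]) + diag(1e-10, q))
      V <- X %*% Minv
      list(Minv = Minv, V = V, d = rowSums(V * X))
    }
    st <- refresh(sel)
    for (pass in seq_len(exchange_passes)) {
      improved <- FALSE
      for (i in seq_len(n_points)) {
        xi <- X[sel[i], ]
        di <- st$d[sel[i]]
        dij <- as.numeric(st$V %*% xi)
        delta <- st$d - di - (di * st$d - dij^2)
        jbest <- which.max(delta)
        if (delta[jbest] > 1e-9 && (1 - di) > 1e-10) {
          # remove x_i (negative-rank update) ...
          w <- as.numeric(st$Minv %*% xi)
          st$Minv <- st$Minv + tcrossprod(w) / (1 - di)
          st$d <- st$d + dij^2 / (1 - di)
          st$V <- st$V + tcrossprod(dij, w) / (1 - di)
          # ... then add x_j
          xj <- X[jbest, ]
          w2 <- as.numeric(st$Minv %*% xj)
          dj <- sum(xj * w2)
          vj <- as.numeric(X %*% w2)
          st$Minv <- st$Minv - tcrossprod(w2) / (1 + dj)
          st$d <- st$d - vj^2 / (1 + dj)
          st$V <- st$V - tcrossprod(vj, w2) / (1 + dj)
          sel[i] <- jbest
          improved <- TRUE
        }
      }
      st <- refresh(sel)  # clear accumulated update drift
      if (!improved) break
    }
  }

  Z <- candidates[sel, , drop = FALSE]
  ld <- determinant(crossprod(quad_model_matrix(Z)), logarithm = TRUE)$modulus
  out <- dplyr::bind_cols(
    tibble::tibble(run = seq_len(nrow(Z))),
    tibble::as_tibble(Z, .name_repair = ~ paste0("z_", colnames(Z)))
  )
  structure(out, class = c("vp_design", class(out)), log_det = as.numeric(ld))
}

#' Map normalized design coordinates to parameter sets
#'
#' Coordinate `z` in `[-1, 1]` maps multiplicatively to
#' `nominal * rmax^z`, so the design spans the same
#' `[nominal/rmax, nominal*rmax]` box as the population sampling scheme.
#'
#' @param z Numeric vector (length 16) or matrix of normalized
#'   coordinates.
#' @param nominal Nominal parameter set.
#' @param rmax Range bound.
#' @return Parameter vector, or a list of parameter vectors for a matrix.
#' @export
design_to_params <- function(z, nominal = sh_params(), rmax) {
  stopifnot(rmax > 1)
  if (is.matrix(z) || is.data.frame(z)) {
    z <- as.matrix(z)
    return(lapply(seq_len(nrow(z)),
                  function(i) nominal * rmax^as.numeric(z[i, ])))
  }
  nominal * rmax^as.numeric(z)
}

#' Fit a quadratic response surface
#'
#' Least-squares fit of the full second-order model (intercept, linear,
#' pure quadratic, pairwise interactions) to one or more responses over a
#' design of normalized coordinates.
#'
#' @param design A `"vp_design"`, or a matrix/tibble of normalized
#'   coordinates (columns `z_*` are used if present).
#' @param responses Matrix or data frame of responses, one column per
#'   output, rows matching the design.
#' @return Object of class `"vp_rsm"`: coefficients (terms x outputs),
#'   term names, fitted values, residuals. Supports [tidy()], [glance()]
#'   and [predict()].
#' @export
fit_rsm <- function(design, responses) {
  Z <- design_coords(design)
  responses <- as.matrix(responses)
  keep <- stats::complete.cases(responses) & stats::complete.cases(Z)
  Z <- Z[keep, , drop = FALSE]
  Y <- responses[keep, , drop = FALSE]
  X <- quad_model_matrix(Z)
  if (nrow(X) < ncol(X))
    stop("need at least ", ncol(X), " valid responses, got ", nrow(X))
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X))
    stop("rank-deficient design: rank ", qr_x$rank, " < ", ncol(X),
         " terms (condition problem)")
  coef <- qr.coef(qr_x, Y)
  fitted <- X %*% coef
  structure(
    list(coef = coef, terms = colnames(X), params = colnames(Z),
         fitted = fitted, residuals = Y - fitted,
         outputs = colnames(Y), n = nrow(X)),
    class = "vp_rsm")
}

design_coords <- function(design) {
  if (is.matrix(design)) return(design)
  df <- as.data.frame(design)
  zc <- grep("^z_", names(df), value = TRUE)
  if (length(zc)) {
    m <- as.matrix(df[zc])
    colnames(m) <- sub("^z_", "", zc)
    m
  } else {
    as.matrix(df[vapply(df, is.numeric, logical(1)) &
                   !(names(df) %in% "run")])
  }
}

#' @export
predict.vp_rsm <- function(object, newdata, ...) {
  Z <- design_coords(newdata)
  quad_model_matrix(Z) %*% object$coef
}

#' @export
print.vp_rsm <- function(x, ...) {
  cat("<vp_rsm>", length(x$terms), "terms,", length(x$outputs),
      "output(s),", x$n, "fitting points\n")
  invisible(x)
}

#' @rdname fit_rsm
#' @param x A `"vp_rsm"` object.
#' @param ... Unused.
#' @export
tidy.vp_rsm <- function(x, ...) {
  tibble::as_tibble(x$coef, rownames = NULL) |>
    dplyr::mutate(term = x$terms, .before = 1) |>
    tidyr::pivot_longer(-"term", names_to = "output",
                        values_to = "estimate")
}

#' @rdname fit_rsm
#' @export
glance.vp_rsm <- function(x, ...) {
  purrr::map_dfr(seq_along(x$outputs), function(j) {
    y <- x$fitted[, j] + x$residuals[, j]
    rss <- sum(x$residuals[, j]^2)
    tss <- sum((y - mean(y))^2)
    tibble::tibble(
      output = x$outputs[j],
      r.squared = if (tss > 0) 1 - rss / tss else NA_real_,
      sigma = sqrt(rss / max(1, x$n - length(x$terms))),
      nobs = x$n)
  })
}

#' Non-dimensional sensitivities from a response surface
#'
#' Evaluates the analytic gradient of the fitted quadratic at a point of
#' the normalized design space and converts it to the elasticity scale:
#' with the multiplicative coordinate map `x = nominal * rmax^z`,
#' `S* = dF/dz / (F * log(rmax))`.
#'
#' @param surface A `"vp_rsm"` fit.
#' @param at Normalized evaluation point (default the centre, i.e. the
#'   nominal parameter set).
#' @param rmax Range bound used for the coordinate map.
#' @return Tibble `input`, `output`, `s_star` (NA where the surface value
#'   is zero).
#' @export
rsm_sensitivity <- function(surface, at = NULL, rmax) {
  p <- length(surface$params)
  if (is.null(at)) at <- rep(0, p)
  stopifnot(length(at) == p, rmax > 1)
  zm <- matrix(at, 1, p, dimnames = list(NULL, surface$params))
  f <- as.numeric(predict(surface, zm))
  nm <- surface$params
  purrr::map_dfr(seq_along(surface$outputs), function(q) {
    b <- surface$coef[, q]
    g <- vapply(seq_len(p), function(j) {
      gj <- b[[nm[j]]] + 2 * b[[paste0(nm[j], "^2")]] * at[j]
      for (k in seq_len(p)) {
        if (k == j) next
        term <- if (j < k) paste0(nm[j], ":", nm[k]) else paste0(nm[k], ":", nm[j])
        gj <- gj + b[[term]] * at[k]
      }
      gj
    }, numeric(1))
    s <- if (f[q] == 0) rep(NA_real_, p) else g / (f[q] * log(rmax))
    tibble::tibble(input = nm, output = surface$outputs[q], s_star = s)
  })
}

#' Validate a response surface against fresh simulations
#'
#' Simulates the model at `n_points` random in-range points and compares
#' the surface predictions with the simulated outputs. Reports the mean
#' over points of the maximum across outputs of the relative error (the
#' "average maximum error"), per-output mean errors, and the count of
#' failed (excluded) simulations.
#'
#' @param surface A `"vp_rsm"` fitted on the same coordinate map.
#' @param nominal Nominal parameter set.
#' @param rmax Range bound of the coordinate map.
#' @param n_points Number of random validation points.
#' @param seed Optional integer seed.
#' @param config Simulation configuration.
#' @param simulate_fn Optional stub: function of a normalized coordinate
#'   vector returning a named vector/one-row tibble of outputs (testing
#'   hook).
#' @return List: `avg_max_error_pct`, `per_output` (tibble of mean
#'   relative errors in %), `n_used`, `n_failed`, `errors` (per-point
#'   tibble).
#' @export
validate_rsm <- function(surface, nominal = sh_params(), rmax,
                         n_points = 100L, seed = NULL,
                         config = sim_config(), simulate_fn = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- length(surface$params)
  outputs <- surface$outputs
  Z <- matrix(runif(n_points * p, -1, 1), n_points, p,
              dimnames = list(NULL, surface$params))
  pred <- predict(surface, Z)
  rows <- purrr::map(seq_len(n_points), function(i) {
    if (is.null(simulate_fn)) {
      params <- design_to_params(as.numeric(Z[i, ]), nominal, rmax)
      m <- extract_measures(simulate_fold(params, config), spectral = FALSE)
      if (!isTRUE(m$oscillating)) return(NULL)
      vapply(outputs, function(o) as.numeric(m[[o]][1]), numeric(1))
    } else {
      m <- simulate_fn(as.numeric(Z[i, ]))
      vapply(outputs, function(o) as.numeric(m[[o]][1]), numeric(1))
    }
  })
  used <- !vapply(rows, is.null, logical(1))
  if (!any(used)) stop("all validation simulations failed")
  actual <- do.call(rbind, rows[used])
  rel <- abs(pred[used, , drop = FALSE] - actual) / abs(actual)
  per_point_max <- apply(rel, 1, max)
  list(
    avg_max_error_pct = 100 * mean(per_point_max),
    per_output = tibble::tibble(output = outputs,
                                mean_rel_error_pct = 100 * colMeans(rel)),
    n_used = sum(used),
    n_failed = sum(!used),
    errors = tibble::as_tibble(rel) |>
      dplyr::mutate(point = which(used), .before = 1)
  )
}

#' Export a sensitivity tensor to CSV
#'
#' Columns: `rmax`, `subject_id`, `input`, `output`, `s_star`, `valid`.
#'
#' @param tensor A `"vp_tensor"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tensor_csv <- function(tensor, path) {
  df <- as.data.frame(tensor)
  names(df)[names(df) == "subject"] <- "subject_id"
  write.csv(df[c("rmax", "subject_id", "input", "output", "s_star", "valid")],
            path, row.names = FALSE)
  invisible(path)
}
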