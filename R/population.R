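#' The five population sampling ranges
#'
#' The grid of multiplicative range bounds used in the study design.
#'
#' @return Numeric vector `c(1.10, 1.20, 1.50, 2.00, 5.00)`.
#' @export
rmax_grid <- function() c(1.10, 1.20, 1.50, 2.00, 5.00)

#' Draw multiplicative sampling factors
#'
#' Each factor is `r^a` with `r ~ U(1, rmax)` and the sign exponent `a`
#' equal to -1 or +1 with equal probability, so factors land in
#' `[1/rmax, rmax]` with (on average) half above and half below 1. Uses
#' the current RNG state.
#'
#' @param n Number of factors to draw.
#' @param rmax Upper bound of the uniform range variable, `>= 1`.
#' @return Numeric vector of length `n`.
#' @examples
#' set.seed(1)
#' draw_factor(5, rmax = 5)
#' @export
draw_factor <- function(n, rmax) {
  if (!is.numeric(rmax) || length(rmax) != 1L || !is.finite(rmax) || rmax < 1)
    stop("rmax must be a single number >= 1")
  r <- runif(n, 1, rmax)
  a <- ifelse(runif(n) < 0.5, -1, 1)
  r^a
}

#' Sample one virtual subject's parameter set
#'
#' Scales every one of the 16 nominal parameters by an independent draw
#' from [draw_factor()].
#'
#' @param nominal Nominal parameter set, see [sh_params()].
#' @param rmax Sampling range bound.
#' @return Named numeric parameter vector.
#' @export
sample_subject <- function(nominal = sh_params(), rmax = 1.5) {
  validate_params(nominal)
  nominal * draw_factor(length(nominal), rmax)
}

# Shared worker: simulate one parameter set and return its classified
# measures row. measure_fn(params) (if given) bypasses the simulator and
# must return a one-row measures tibble -- used for stubbed tests.
subject_measures <- function(params, config, criteria, measure_fn = NULL,
                             eps = 0.01, steady_cov = 0.05) {
  m <- if (is.null(measure_fn)) {
    extract_measures(simulate_fold(params, config), eps = eps)
  } else {
    measure_fn(params)
  }
  classify_normal(m, criteria, steady_cov = steady_cov)
}

#' Generate a virtual population by rejection sampling
#'
#' Repeatedly samples parameter sets with the multiplicative uniform
#' scheme, simulates each candidate, extracts its voice measures, and
#' keeps subjects that pass the normal-phonation filter, until `n_target`
#' accepted subjects are collected or `max_attempts` candidates have been
#' tried. The attempted count supports success-rate estimation.
#'
#' @param nominal Nominal parameter set.
#' @param rmax Sampling range bound.
#' @param n_target Number of accepted subjects wanted.
#' @param criteria Normal-phonation bounds, see [normal_criteria()].
#' @param seed Integer seed; if non-`NULL`, `set.seed(seed)` is called so
#'   the run is reproducible.
#' @param max_attempts Cap on candidate simulations (default
#'   `200 * n_target`).
#' @param config Simulation configuration.
#' @param measure_fn Optional stub replacing the simulate-and-measure step
#'   (testing hook): a function of a parameter vector returning a one-row
#'   measures tibble.
#' @param factor_fn Optional override for the factor sampler: a function
#'   `(n)` returning `n` multiplicative factors. Defaults to the uniform
#'   scheme; used by adaptive resampling.
#' @param verbose Print a progress line every 1000 attempts.
#' @return Tibble of accepted subjects (class `"vp_population"`):
#'   `subject` id, 16 parameter columns, 16 `factor_*` columns, the
#'   measure columns and pass flags. Attributes: `rmax`, `seed`,
#'   `attempted`, `accepted`, `exhausted` (logical). Use
#'   [glance.vp_population()] for the accounting summary.
#' @export
generate_population <- function(nominal = sh_params(), rmax, n_target,
                                criteria = normal_criteria(), seed = NULL,
                                max_attempts = 200L * n_target,
                                config = sim_config(), measure_fn = NULL,
                                factor_fn = NULL, verbose = FALSE) {
  validate_params(nominal)
  stopifnot(n_target >= 1, max_attempts >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(factor_fn))
    factor_fn <- function(n) draw_factor(n, rmax)
  use_fast <- is.null(measure_fn) &&
    setequal(criteria$measure, normal_criteria()$measure)
  cb <- criteria_bounds(criteria)

  rows <- vector("list", n_target)
  accepted <- 0L
  attempted <- 0L
  npar <- length(nominal)

  while (accepted < n_target && attempted < max_attempts) {
    attempted <- attempted + 1L
    factors <- factor_fn(npar)
    params <- nominal * factors
    if (use_fast) {
      att <- fast_attempt(params, config, cb$lo, cb$hi)
      if (att$pass) {
        accepted <- accepted + 1L
        rows[[accepted]] <- c(params,
                              setNames(factors, paste0("factor_", names(nominal))),
                              att$measures)
      }
    } else {
      row <- subject_measures(params, config, criteria, measure_fn)
      if (isTRUE(row$pass_normal)) {
        accepted <- accepted + 1L
        rows[[accepted]] <- dplyr::bind_cols(
          tibble::as_tibble_row(params),
          tibble::as_tibble_row(setNames(factors, paste0("factor_", names(nominal)))),
          row
        )
      }
    }
    if (verbose && attempted %% 1000L == 0L)
      message("attempted ", attempted, ", accepted ", accepted)
  }

  out <- if (accepted == 0L) {
    tibble::tibble(subject = integer(0))
  } else if (use_fast) {
    m <- do.call(rbind, rows[seq_len(accepted)])
    dplyr::bind_cols(
      tibble::tibble(subject = seq_len(accepted)),
      tibble::as_tibble(m),
      tibble::tibble(oscillating = TRUE, pass_normal = TRUE)
    )
  } else {
    dplyr::bind_cols(
      tibble::tibble(subject = seq_len(accepted)),
      dplyr::bind_rows(rows[seq_len(accepted)])
    )
  }
  exhausted <- accepted < n_target
  if (exhausted)
    warning("max_attempts exhausted: ", accepted, "/", n_target,
            " subjects accepted", call. = FALSE)
  structure(out,
            class = c("vp_population", class(out)),
            rmax = rmax, seed = seed,
            attempted = attempted, accepted = accepted,
            exhausted = exhausted)
}

#' @rdname generate_population
#' @param x A `"vp_population"` object.
#' @param ... Unused.
#' @export
glance.vp_population <- function(x, ...) {
  tibble::tibble(
    rmax = attr(x, "rmax"),
    seed = if (is.null(attr(x, "seed"))) NA_integer_ else attr(x, "seed"),
    attempted = attr(x, "attempted"),
    accepted = attr(x, "accepted"),
    success_rate = attr(x, "accepted") / attr(x, "attempted"),
    exhausted = attr(x, "exhausted")
  )
}

#' Per-parameter success histograms
#'
#' For each of the 16 input parameters, histograms the accepted subjects'
#' multiplicative factors on the log-factor axis spanning
#' `[-log(rmax), +log(rmax)]`. A uniform row indicates a parameter whose
#' value barely affects the chance of normal phonation; a skewed row marks
#' a parameter that gates success.
#'
#' @param pop A `"vp_population"` from [generate_population()].
#' @param n_bins Number of equal-width bins on the log-factor axis.
#' @return Tibble with columns `parameter`, `bin`, `log_lo`, `log_hi`,
#'   `count`, `mass` (masses sum to 1 within each parameter).
#' @export
success_histograms <- function(pop, n_bins = 25L) {
  stopifnot(nrow(pop) >= 1)
  rmax <- attr(pop, "rmax")
  lim <- log(rmax)
  edges <- seq(-lim, lim, length.out = n_bins + 1L)
  purrr::map_dfr(param_names(), function(p) {
    lf <- log(pop[[paste0("factor_", p)]])
    lf <- pmin(pmax(lf, -lim), lim)
    counts <- graphics::hist(lf, breaks = edges, plot = FALSE)$counts
    tibble::tibble(
      parameter = p, bin = seq_len(n_bins),
      log_lo = edges[-(n_bins + 1L)], log_hi = edges[-1],
      count = counts, mass = counts / sum(counts)
    )
  })
}

#' Fit sampleable densities to success histograms
#'
#' Smooths each parameter's histogram masses with a centered moving
#' average (window 3, truncated at the edges), renormalizes, and builds a
#' monotone piecewise-linear CDF over the log-factor support, from which
#' new factors can be drawn by inverse-CDF sampling.
#'
#' @param hists Histogram tibble from [success_histograms()].
#' @return Tibble of class `"vp_density"`, one row per parameter, with
#'   list-columns `knots` (log-factor CDF knots) and `cdf`.
#' @export
fit_density <- function(hists) {
  stopifnot(all(c("parameter", "log_lo", "log_hi", "mass") %in% names(hists)))
  out <- hists |>
    dplyr::group_by(.data$parameter) |>
    dplyr::group_modify(function(df, key) {
      if (sum(df$mass) <= 0) stop("empty histogram for ", key$parameter)
      m <- df$mass
      n <- length(m)
      sm <- vapply(seq_len(n), function(i) {
        w <- max(1, i - 1):min(n, i + 1)
        mean(m[w])
      }, numeric(1))
      sm <- sm / sum(sm)
      knots <- c(df$log_lo[1], df$log_hi)
      cdf <- c(0, cumsum(sm))
      tibble::tibble(knots = list(knots), cdf = list(cdf))
    }) |>
    dplyr::ungroup()
  structure(out, class = c("vp_density", class(out)))
}

#' Sample factors from fitted densities
#'
#' Inverse-CDF sampling of per-parameter multiplicative factors from a
#' [fit_density()] object. Uses the current RNG state.
#'
#' @param density A `"vp_density"` object.
#' @param n Number of subjects to draw.
#' @return Matrix `n x 16` of factors, columns named by parameter.
#' @export
sample_density <- function(density, n) {
  stopifnot(inherits(density, "vp_density"), n >= 1)
  cols <- lapply(seq_len(nrow(density)), function(i) {
    u <- runif(n)
    exp(approx(density$cdf[[i]], density$knots[[i]], xout = u,
               ties = "ordered", rule = 2)$y)
  })
  m <- do.call(cbind, cols)
  colnames(m) <- density$parameter
  m[, param_names(), drop = FALSE]
}

#' Success rate under adaptive (density-based) sampling
#'
#' Re-runs the sample-simulate-classify pipeline with parameters drawn
#' from densities fitted to a prior accepted population instead of the
#' uniform scheme, and returns the resulting acceptance accounting.
#'
#' @param nominal Nominal parameter set.
#' @param density `"vp_density"` fitted at the same `rmax`.
#' @param rmax Sampling range bound (used only for bookkeeping).
#' @param criteria Normal-phonation bounds.
#' @param n_samples Number of candidates to simulate.
#' @param seed Optional integer seed.
#' @param config Simulation configuration.
#' @param measure_fn Optional stub, as in [generate_population()].
#' @return Tibble row: `rmax`, `attempted`, `accepted`, `success_rate`.
#' @export
adaptive_success_rate <- function(nominal = sh_params(), density, rmax,
                                  criteria = normal_criteria(),
                                  n_samples = 1000L, seed = NULL,
                                  config = sim_config(), measure_fn = NULL) {
  stopifnot(inherits(density, "vp_density"))
  if (!is.null(seed)) set.seed(seed)
  factors <- sample_density(density, n_samples)
  use_fast <- is.null(measure_fn) &&
    setequal(criteria$measure, normal_criteria()$measure)
  cb <- criteria_bounds(criteria)
  accepted <- 0L
  for (i in seq_len(n_samples)) {
    params <- nominal * factors[i, ]
    pass <- if (use_fast) {
      fast_attempt(params, config, cb$lo, cb$hi)$pass
    } else {
      isTRUE(subject_measures(params, config, criteria, measure_fn)$pass_normal)
    }
    if (pass) accepted <- accepted + 1L
  }
  tibble::tibble(rmax = rmax, attempted = n_samples, accepted = accepted,
                 success_rate = accepted / n_samples)
}

#' Convergence of sensitivity summaries with population size
#'
#' Generates one population at the largest requested size and reports, for
#' each size in `n_grid`, the per-pair median sensitivity over the first
#' `n` subjects. Convergence is flagged when the top-ranked pairs' medians
#' change by less than `tol` (relative) between successive sizes.
#'
#' @param nominal Nominal parameter set.
#' @param rmax Sampling range bound.
#' @param n_grid Increasing integer vector of population sizes.
#' @param criteria Normal-phonation bounds.
#' @param seed Optional integer seed.
#' @param config Simulation configuration.
#' @param measure_fn Optional stub, as in [generate_population()].
#' @param delta Relative perturbation for the local sensitivities.
#' @param outputs Output columns for the sensitivities (default the six
#'   of [sensitivity_outputs()]).
#' @param tol Relative tolerance on successive medians.
#' @param top_k Number of top pairs (by final |median|) checked.
#' @return List with `table` (tibble: `n`, `input`, `output`, `median`)
#'   and `converged` (logical).
#' @export
convergence_check <- function(nominal = sh_params(), rmax, n_grid,
                              criteria = normal_criteria(), seed = NULL,
                              config = sim_config(), measure_fn = NULL,
                              delta = 0.01,
                              outputs = names(sensitivity_outputs()),
                              tol = 0.05, top_k = 5L) {
  stopifnot(length(n_grid) >= 2, all(diff(n_grid) > 0))
  n_max <- max(n_grid)
  pop <- generate_population(nominal, rmax, n_max, criteria, seed = seed,
                             config = config, measure_fn = measure_fn)
  tensor <- population_sensitivity(pop, delta = delta, outputs = outputs,
                                   config = config, measure_fn = measure_fn)
  tab <- purrr::map_dfr(n_grid, function(n) {
    tensor |>
      dplyr::filter(.data$subject <= n, .data$valid) |>
      dplyr::group_by(.data$input, .data$output) |>
      dplyr::summarise(median = median(.data$s_star), .groups = "drop") |>
      dplyr::mutate(n = n, .before = 1)
  })
  final <- tab |>
    dplyr::filter(.data$n == n_max) |>
    dplyr::arrange(dplyr::desc(abs(.data$median))) |>
    head(top_k)
  wide <- tab |>
    dplyr::semi_join(final, by = c("input", "output")) |>
    dplyr::arrange(.data$input, .data$output, .data$n)
  converged <- wide |>
    dplyr::group_by(.data$input, .data$output) |>
    dplyr::summarise(
      ok = all(abs(diff(.data$median)) <=
                 tol * pmax(abs(head(.data$median, -1)), 1e-12)),
      .groups = "drop") |>
    dplyr::pull(.data$ok) |>
    all()
  list(table = tab, converged = converged)
}

#' Write a population archive
#'
#' Writes the accepted-subject table to CSV together with a JSON sidecar
#' recording `rmax`, `seed`, `attempted` and `accepted`.
#'
#' @param pop A `"vp_population"`.
#' @param path CSV output path; the sidecar gets extension `.json`.
#' @return `path`, invisibly.
#' @export
write_population_csv <- function(pop, path) {
  write.csv(as.data.frame(pop), path, row.names = FALSE)
  side <- sub("\\.csv$", ".json", path)
  jsonlite::write_json(
    list(rmax = attr(pop, "rmax"),
         seed = attr(pop, "seed"),
         attempted = attr(pop, "attempted"),
         accepted = attr(pop, "accepted")),
    side, auto_unbox = TRUE, null = "null")
  invisible(path)
}
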