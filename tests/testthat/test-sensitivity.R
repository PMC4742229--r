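test_that("forward-difference elasticity matches the power-law closed form", {
  # output = (P/P0)^2: S* at +1% is ((1.01^2 - 1)/1)/0.01 = 2.01 exactly
  sens <- local_sensitivity(sh_params(), delta = 0.01,
                            outputs = c("y", "lin", "const"),
                            inputs = c("P", "L", "m2"),
                            measure_fn = stub_power_measures)
  s_p_y <- dplyr::filter(sens, input == "P", output == "y")$s_star
  expect_equal(s_p_y, 2.01, tolerance = 1e-10)
  # linear output in L: S* = ((1.01 - 1)/1)/0.01 = 1
  s_l <- dplyr::filter(sens, input == "L", output == "lin")$s_star
  expect_equal(s_l, 1, tolerance = 1e-10)
  # outputs independent of the input give exactly 0
  expect_equal(dplyr::filter(sens, input == "m2")$s_star, c(0, 0, 0))
  expect_equal(dplyr::filter(sens, input == "P", output == "const")$s_star, 0)
})

test_that("elasticity converges to the analytic log-derivative as delta shrinks", {
  errs <- vapply(c(0.04, 0.02, 0.01, 0.005), function(d) {
    s <- local_sensitivity(sh_params(), delta = d, outputs = "y",
                           inputs = "P", measure_fn = stub_power_measures)
    abs(s$s_star - 2)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))           # monotone improvement
  expect_gt(errs[1] / errs[4], 6)            # observed order >= 1
})

test_that("d2 has exactly zero sensitivity under the model dynamics", {
  base <- vocalpop:::fast_outputs(sh_params(), sim_config())
  sens <- local_sensitivity(sh_params(), base = tibble::as_tibble_row(as.list(base)),
                            inputs = "d2")
  expect_true(all(sens$valid))
  expect_equal(sens$s_star, rep(0, 6))
})

test_that("population tensor has 96 records per subject with a validity mask", {
  pop <- generate_population(rmax = 1.5, n_target = 3, seed = 20,
                             measure_fn = stub_power_measures |>
                               (\(f) function(p) {
                                 dplyr::mutate(stub_normal_measures(p),
                                               y = f(p)$y)
                               })())
  tensor <- population_sensitivity(pop, measure_fn = function(p)
    dplyr::mutate(stub_normal_measures(p), y = (p[["P"]] / 0.008)^2))
  expect_equal(nrow(tensor), 3 * 96)
  expect_true(all(c("rmax", "subject", "input", "output", "s_star", "valid")
                  %in% names(tensor)))
  expect_equal(sum(tensor$valid) + sum(!tensor$valid), 3 * 96)
  # medians invariant to subject order
  perm <- tensor[sample.int(nrow(tensor)), ]
  expect_equal(summarize_pairs(perm), summarize_pairs(tensor))
})

test_that("pair summaries average percentiles across ranges and classify consistency", {
  # two ranges with known constant sensitivities
  mk <- function(rmax, value) tibble::tibble(
    rmax = rmax, subject = rep(1:50, each = 1), input = "P", output = "y",
    s_star = value, valid = TRUE)
  t1 <- mk(1.1, rep(1, 50))
  t2 <- mk(1.5, rep(3, 50))
  avg <- summarize_pairs(dplyr::bind_rows(t1, t2))
  expect_equal(avg$median, 2)   # mean of per-range medians 1 and 3
  expect_equal(avg$p5, 2)
  expect_equal(avg$n_ranges, 2L)

  per <- summarize_pairs(dplyr::bind_rows(t1, t2), by_range = TRUE)
  expect_equal(per$sd, c(0, 0))
  expect_equal(per$class, c("consistent", "consistent"))

  # classification partition and sign-flip invariance
  set.seed(30)
  noisy <- tibble::tibble(
    rmax = 1.5, subject = 1:200, input = "kc", output = "sq",
    s_star = rnorm(200, mean = 0.1, sd = 1), valid = TRUE)
  cls <- summarize_pairs(noisy, by_range = TRUE)$class
  expect_true(cls %in% c("consistent", "within-1sd", "within-2sd"))
  flipped <- dplyr::mutate(noisy, s_star = -s_star)
  expect_equal(summarize_pairs(flipped, by_range = TRUE)$class, cls)

  # invalid records are excluded and counted
  part <- dplyr::mutate(noisy, valid = subject <= 150,
                        s_star = ifelse(valid, s_star, NA_real_))
  ps <- summarize_pairs(part, by_range = TRUE)
  expect_equal(ps$n_valid, 150L)
  expect_equal(ps$n_invalid, 50L)
})

test_that("input ranking orders by influence with lexicographic ties", {
  summaries <- tibble::tibble(
    input = rep(c("b", "a", "c"), each = 2),
    output = rep(c("y1", "y2"), 3),
    median = c(2, 2, 2, 2, 5, 5))
  rk <- rank_inputs(summaries)
  expect_equal(rk$input, c("c", "a", "b"))  # tie between a and b -> a first
  expect_equal(rk$rank, 1:3)
})

test_that("OAT recovers linear slopes and is blind to pure interactions", {
  p0 <- sh_params()
  lin_stub <- function(params) tibble::tibble(
    y = 1 + 2 * (params[["P"]] / p0[["P"]] - 1) - 0.5 * (params[["L"]] / p0[["L"]] - 1),
    oscillating = TRUE)
  oat <- oat_analysis(percent_range = 0.02, outputs = "y",
                      criteria = NULL, measure_fn = lin_stub)
  expect_equal(nrow(oat$design), 32)
  s <- oat$sensitivities
  expect_equal(dplyr::filter(s, input == "P")$s_star, 2, tolerance = 1e-9)
  expect_equal(dplyr::filter(s, input == "L")$s_star, -0.5, tolerance = 1e-9)
  expect_equal(dplyr::filter(s, input == "m1")$s_star, 0)

  # pure two-way interaction: OAT reports 0 for both involved inputs
  int_stub <- function(params) tibble::tibble(
    y = 5 + (params[["P"]] / p0[["P"]] - 1) * (params[["L"]] / p0[["L"]] - 1),
    oscillating = TRUE)
  oat2 <- oat_analysis(percent_range = 0.02, outputs = "y",
                       criteria = NULL, measure_fn = int_stub)
  expect_equal(dplyr::filter(oat2$sensitivities, input %in% c("P", "L"))$s_star,
               c(0, 0), tolerance = 1e-9)
})

test_that("OAT marks pairs unavailable when an endpoint fails the filter", {
  flaky <- function(params) {
    m <- stub_normal_measures(params)
    if (params[["P"]] > sh_params()[["P"]]) m$f0_hz <- 500  # high endpoint fails
    m
  }
  oat <- oat_analysis(percent_range = 0.05, outputs = "f0_hz",
                      measure_fn = flaky)
  sp <- dplyr::filter(oat$sensitivities, input == "P")
  expect_false(sp$valid)
  expect_true(is.na(sp$s_star))
})

test_that("the Cotter design has the documented 2n+2 structure", {
  des <- cotter_design(16)
  expect_equal(nrow(des), 34)
  m <- as.matrix(des[, param_names()])
  expect_true(all(m[1, ] == -1))                  # run 0: all low
  expect_true(all(m[34, ] == 1))                  # run 2n+1: all high
  for (j in 1:16) {
    expect_equal(sum(m[1 + j, ] == 1), 1)         # one high, rest low
    expect_equal(which(m[1 + j, ] == 1), j, ignore_attr = TRUE)
    expect_equal(sum(m[17 + j, ] == -1), 1)       # one low, rest high
    expect_equal(which(m[17 + j, ] == -1), j, ignore_attr = TRUE)
  }
  # each intermediate row differs from its base corner in exactly one spot
  expect_true(all(rowSums(m[2:17, ] != matrix(-1, 16, 16)) == 1))
  expect_true(all(rowSums(m[18:33, ] != matrix(1, 16, 16)) == 1))
})

test_that("Cotter indices recover additive effects and flag interactions", {
  n <- 16
  des <- cotter_design(n)
  m <- as.matrix(des[, param_names()])
  b <- seq(-1, 1, length.out = n)
  y_add <- as.numeric(m %*% b)
  idx <- cotter_indices(y_add)
  expect_equal(idx$c_odd, b, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(idx$c_even, rep(0, n), tolerance = 1e-12)

  y_int <- m[, 1] * m[, 2]
  idx2 <- cotter_indices(y_int)
  expect_equal(idx2$c_odd, rep(0, n), tolerance = 1e-12)
  expect_equal(idx2$c_even[1:2], c(1, 1), tolerance = 1e-12)
  expect_equal(idx2$c_even[3:n], rep(0, n - 2), tolerance = 1e-12)

  expect_equal(cotter_indices(rep(4, 34))$total, rep(0, n))
  expect_warning(bad <- cotter_indices(c(NA, y_add[-1])), "unavailable")
  expect_true(all(is.na(bad$total)))
  expect_false(any(bad$valid))
})

test_that("quadratic model matrix spans the full second-order basis", {
  z <- matrix(runif(30, -1, 1), 10, 3, dimnames = list(NULL, c("a", "b", "c")))
  X <- quad_model_matrix(z)
  expect_equal(ncol(X), 1 + 3 + 3 + 3)
  expect_equal(X[, "a:b"], z[, "a"] * z[, "b"])
  expect_equal(X[, "b^2"], z[, "b"]^2)
  z16 <- matrix(0.5, 2, 16)
  expect_equal(ncol(quad_model_matrix(z16)), 153)
})

test_that("D-optimal selection beats random subsets and degenerates gracefully", {
  set.seed(40)
  cands <- matrix(runif(80 * 3, -1, 1), 80, 3)
  des <- d_optimal_design(n_points = 15, n_params = 3, candidates = cands)
  expect_equal(nrow(des), 15)
  ld <- attr(des, "log_det")
  X <- quad_model_matrix(cands)
  rand_ld <- replicate(100, {
    s <- sample.int(80, 15)
    determinant(crossprod(X[s, ]), logarithm = TRUE)$modulus
  })
  expect_gte(ld, max(rand_ld) - 1e-9)

  # n_points == candidate count returns the full candidate set
  all_des <- d_optimal_design(n_points = 80, n_params = 3, candidates = cands)
  expect_equal(nrow(all_des), 80)

  # deterministic given seed
  d1 <- d_optimal_design(n_points = 40, n_params = 4, n_candidates = 300,
                         seed = 41)
  d2 <- d_optimal_design(n_points = 40, n_params = 4, n_candidates = 300,
                         seed = 41)
  expect_equal(as.data.frame(d1), as.data.frame(d2))
})

test_that("response-surface fit recovers a known quadratic exactly", {
  set.seed(42)
  z <- matrix(runif(60 * 4, -1, 1), 60, 4,
              dimnames = list(NULL, c("a", "b", "c", "d")))
  X <- quad_model_matrix(z)
  beta <- rnorm(ncol(X))
  y <- as.numeric(X %*% beta)
  fit <- fit_rsm(z, cbind(out = y))
  expect_equal(as.numeric(fit$coef), beta, tolerance = 1e-8)
  expect_equal(as.numeric(predict(fit, z)), y, tolerance = 1e-8)

  # constant response: intercept only
  fit0 <- fit_rsm(z, cbind(out = rep(3, 60)))
  expect_equal(fit0$coef[1], 3, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(max(abs(fit0$coef[-1])), 0, tolerance = 1e-10)

  expect_error(fit_rsm(z[1:10, ], cbind(out = y[1:10])), "at least")
  zdup <- z
  zdup[, 2] <- zdup[, 1]  # collinear inputs: rank-deficient basis
  expect_error(fit_rsm(zdup, cbind(out = y)), "rank")

  g <- glance(fit)
  expect_equal(g$r.squared, 1, tolerance = 1e-10)
  td <- tidy(fit)
  expect_equal(nrow(td), ncol(X))
})

test_that("surface gradient converts to elasticities at the centre point", {
  rmax <- 1.1
  # response exp(2 z log rmax) = (x/x0)^2 has elasticity exactly 2
  set.seed(43)
  z <- matrix(runif(40 * 2, -1, 1), 40, 2, dimnames = list(NULL, c("a", "b")))
  y <- exp(2 * log(rmax) * z[, "a"])
  fit <- fit_rsm(z, cbind(out = y))
  # quadratic truncation of the exponential leaves a ~0.4% bias
  s <- rsm_sensitivity(fit, rmax = rmax)
  expect_equal(dplyr::filter(s, input == "a")$s_star, 2, tolerance = 0.01)
  expect_equal(dplyr::filter(s, input == "b")$s_star, 0, tolerance = 0.01)

  # zero-gradient surface: all elasticities 0
  fit0 <- fit_rsm(z, cbind(out = rep(2, 40)))
  expect_equal(rsm_sensitivity(fit0, rmax = rmax)$s_star, c(0, 0),
               tolerance = 1e-10)
})

test_that("surface validation is exact when the simulator is the surface", {
  set.seed(44)
  z <- matrix(runif(60 * 3, -1, 1), 60, 3,
              dimnames = list(NULL, c("a", "b", "c")))
  X <- quad_model_matrix(z)
  beta <- cbind(y1 = rnorm(ncol(X)), y2 = rnorm(ncol(X)))
  fit <- fit_rsm(z, X %*% beta + 5)  # offset keeps responses away from 0
  val <- validate_rsm(fit, rmax = 1.1, n_points = 50, seed = 45,
                      simulate_fn = function(zv) {
                        zm <- matrix(zv, 1, dimnames = list(NULL, c("a", "b", "c")))
                        y <- predict(fit, zm)
                        setNames(as.numeric(y), colnames(y))
                      })
  expect_lt(val$avg_max_error_pct, 1e-8)
  expect_equal(val$n_failed, 0)
})

test_that("design coordinates map multiplicatively onto parameter space", {
  p <- design_to_params(rep(1, 16), sh_params(), rmax = 2)
  expect_equal(p, sh_params() * 2)
  p2 <- design_to_params(rep(-1, 16), sh_params(), rmax = 2)
  expect_equal(p2, sh_params() / 2)
  ps <- design_to_params(matrix(0, 2, 16), sh_params(), rmax = 1.5)
  expect_equal(ps[[2]], sh_params())
})

test_that("narrow-range designed experiments run clean on the real model", {
  # every OAT endpoint at ±7% phonates normally
  oat <- oat_analysis(percent_range = 0.07, outputs = c("f0_hz", "mfdr_ls2"))
  expect_true(all(oat$design$pass))
  expect_true(all(oat$sensitivities$valid))

  # Cotter at ±2%: all 34 corner runs pass, and the leading effects agree
  # in sign with the population-level medians
  cot <- cotter_analysis(percent_range = 0.02)
  expect_equal(nrow(cot$design), 34)
  expect_false(any(is.na(cot$responses)))
  idx <- cot$indices
  expect_true(all(idx$valid))
  l_mfdr <- dplyr::filter(idx, output == "mfdr_ls2", input == "L")
  expect_gt(l_mfdr$c_odd, 0)         # longer folds -> steeper closure
  k1_mean <- dplyr::filter(idx, output == "mean_flow_cm3s", input == "k1")
  expect_lt(k1_mean$c_odd, 0)        # stiffer lower mass -> less flow
  # OAT agrees in sign with Cotter on the same pairs
  oat_l <- dplyr::filter(oat$sensitivities, input == "L", output == "mfdr_ls2")
  expect_gt(oat_l$s_star, 0)
})
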