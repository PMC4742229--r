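test_that("multiplicative factors respect range bounds and symmetry", {
  expect_equal(draw_factor(5, rmax = 1), rep(1, 5))
  expect_error(draw_factor(1, rmax = 0.5), "rmax")
  set.seed(1)
  f <- draw_factor(1e5, rmax = 5)
  expect_true(all(f >= 1 / 5 & f <= 5))
  # P(factor > 1) = 1/2 within 3 binomial standard errors
  phat <- mean(f > 1)
  se <- sqrt(0.25 / 1e5)
  expect_lt(abs(phat - 0.5), 3 * se)
  # log factors symmetric about 0 (sign test via mean of signs)
  expect_lt(abs(mean(sign(log(f)))), 3 * se * 2)
})

test_that("subject sampling scales every parameter independently", {
  expect_equal(sample_subject(sh_params(), rmax = 1), sh_params())
  set.seed(2)
  for (i in 1:20) {
    p <- sample_subject(sh_params(), rmax = 3)
    fac <- p / sh_params()
    expect_true(all(fac >= 1 / 3 & fac <= 3))
    expect_true(all(p > 0))
  }
  # per-parameter log factors symmetric about 0 at rmax = 5 (sign test)
  set.seed(3)
  lf <- log(t(replicate(4000, sample_subject(sh_params(), 5) / sh_params())))
  signs <- colMeans(lf > 0)
  se <- sqrt(0.25 / 4000)
  expect_true(all(abs(signs - 0.5) < 4 * se))
})

test_that("rejection sampling accounts for every attempt and honors the seed", {
  # stub that always passes: attempted == accepted == n_target
  pop <- generate_population(rmax = 1.5, n_target = 25, seed = 9,
                             measure_fn = stub_normal_measures)
  g <- glance(pop)
  expect_equal(g$accepted, 25L)
  expect_equal(g$attempted, 25L)
  expect_equal(g$success_rate, 1)
  expect_equal(nrow(pop), 25L)
  # factor columns reproduce params / nominal
  p0 <- sh_params()
  for (nm in c("P", "m2", "x0"))
    expect_equal(pop[[paste0("factor_", nm)]], pop[[nm]] / p0[[nm]],
                 tolerance = 1e-12)

  # identical seeds give identical populations, including accounting
  pop2 <- generate_population(rmax = 1.5, n_target = 25, seed = 9,
                              measure_fn = stub_normal_measures)
  expect_equal(as.data.frame(pop), as.data.frame(pop2))
  expect_identical(attr(pop, "attempted"), attr(pop2, "attempted"))
})

test_that("filter disabled by infinite bounds accepts every oscillating subject", {
  wide <- dplyr::mutate(normal_criteria(), low = -Inf, high = Inf)
  pop <- generate_population(rmax = 5, n_target = 30, seed = 4,
                             criteria = wide,
                             measure_fn = stub_normal_measures)
  expect_equal(glance(pop)$success_rate, 1)
})

test_that("a rejecting filter triggers the max_attempts guard", {
  never <- dplyr::mutate(normal_criteria(),
                         low = dplyr::if_else(measure == "f0_hz", 1e5, low),
                         high = dplyr::if_else(measure == "f0_hz", 2e5, high))
  expect_warning(
    pop <- generate_population(rmax = 1.5, n_target = 5, seed = 5,
                               max_attempts = 40, criteria = never,
                               measure_fn = stub_normal_measures),
    "exhausted")
  expect_equal(glance(pop)$accepted, 0L)
  expect_equal(glance(pop)$attempted, 40L)
  expect_true(glance(pop)$exhausted)
})

test_that("real-model population generation is reproducible and bounded", {
  pop <- suppressWarnings(
    generate_population(rmax = 1.2, n_target = 8, seed = 11,
                        max_attempts = 60))
  pop2 <- suppressWarnings(
    generate_population(rmax = 1.2, n_target = 8, seed = 11,
                        max_attempts = 60))
  expect_equal(as.data.frame(pop), as.data.frame(pop2))
  expect_gte(attr(pop, "attempted"), attr(pop, "accepted"))
  if (nrow(pop)) {
    expect_true(all(pop$pass_normal))
    expect_true(all(pop$f0_hz >= 88 & pop$f0_hz <= 263))
  }
})

test_that("success histograms conserve counts over the log-factor support", {
  pop <- generate_population(rmax = 2, n_target = 40, seed = 6,
                             measure_fn = stub_normal_measures)
  hists <- success_histograms(pop, n_bins = 25)
  expect_equal(nrow(hists), 16 * 25)
  sums <- hists |>
    dplyr::group_by(parameter) |>
    dplyr::summarise(n = sum(count), m = sum(mass))
  expect_true(all(sums$n == 40))
  expect_equal(sums$m, rep(1, 16))
  expect_true(all(hists$log_lo >= -log(2) - 1e-12))
  expect_true(all(hists$log_hi <= log(2) + 1e-12))
})

test_that("fitted densities reproduce a uniform histogram as a linear CDF", {
  # exactly uniform bin masses: the fitted CDF must be linear to within 2%
  hists <- success_histograms(
    generate_population(rmax = 2, n_target = 25, seed = 7,
                        measure_fn = stub_normal_measures))
  uniform <- dplyr::mutate(hists, count = 4L, mass = 1 / 25)
  dens <- fit_density(uniform)
  for (i in seq_len(nrow(dens))) {
    knots <- dens$knots[[i]]
    cdf <- dens$cdf[[i]]
    lin <- (knots - knots[1]) / (knots[length(knots)] - knots[1])
    expect_lt(max(abs(cdf - lin)), 0.02)
  }
})

test_that("density sampling is self-consistent and respects support", {
  # single-bin spike: all mass in one bin
  hists <- success_histograms(
    generate_population(rmax = 2, n_target = 30, seed = 8,
                        measure_fn = stub_normal_measures))
  spike <- hists |>
    dplyr::group_by(parameter) |>
    dplyr::mutate(mass = as.numeric(bin == 13), count = 30 * (bin == 13)) |>
    dplyr::ungroup()
  dens <- fit_density(spike)
  set.seed(10)
  draws <- sample_density(dens, 500)
  lo <- spike$log_lo[spike$bin == 12][1]  # smoothing spreads to adjacent bins
  hi <- spike$log_hi[spike$bin == 14][1]
  expect_true(all(log(draws) >= lo - 1e-9 & log(draws) <= hi + 1e-9))

  # goodness of fit of samples against the fitted CDF itself (KS test)
  skew <- hists |>
    dplyr::group_by(parameter) |>
    dplyr::mutate(mass = bin / sum(bin), count = bin) |>
    dplyr::ungroup()
  dens2 <- fit_density(skew)
  set.seed(11)
  draws2 <- log(sample_density(dens2, 20000)[, "P"])
  i <- which(dens2$parameter == "P")
  cdf_fun <- stats::approxfun(dens2$knots[[i]], dens2$cdf[[i]], rule = 2)
  ks <- suppressWarnings(stats::ks.test(draws2, cdf_fun))
  expect_gt(ks$p.value, 0.001)
})

test_that("adaptive sampling from structureless densities matches uniform", {
  # densities fitted from uniform noise carry no information: acceptance
  # of a stub filter is unchanged
  pop <- generate_population(rmax = 2, n_target = 300, seed = 12,
                             measure_fn = stub_normal_measures)
  dens <- fit_density(success_histograms(pop))
  coin <- function(params) {
    m <- stub_normal_measures(params)
    m$f0_hz <- if (runif(1) < 0.5) 150 else 500  # 50% acceptance, iid
    m
  }
  ar <- adaptive_success_rate(density = dens, rmax = 2, n_samples = 400,
                              seed = 13, measure_fn = coin)
  se <- sqrt(0.25 / 400)
  expect_lt(abs(ar$success_rate - 0.5), 4 * se)
  # standard error shrinks as 1/sqrt(n): rate estimates concentrate
  ar2 <- adaptive_success_rate(density = dens, rmax = 2, n_samples = 1600,
                               seed = 14, measure_fn = coin)
  expect_lt(abs(ar2$success_rate - 0.5), 2 * se)
})

test_that("convergence check reports stable medians for a stable stub", {
  # passes the filter via mid-range measures, adds a power-law output
  stub <- function(params) {
    dplyr::mutate(stub_normal_measures(params),
                  y = (params[["P"]] / 0.008)^2)
  }
  cc <- convergence_check(rmax = 1.5, n_grid = c(40, 80), seed = 15,
                          measure_fn = stub, delta = 0.01,
                          outputs = c("y", "oq"), top_k = 2)
  expect_true(cc$converged)
  meds <- cc$table |>
    dplyr::filter(input == "P", output == "y") |>
    dplyr::pull(median)
  # output = (P/P0)^2 has constant elasticity 2.01 at +1% forward difference
  expect_equal(meds, rep(2.01, 2), tolerance = 1e-6)
})

test_that("population archive round-trips through CSV + JSON sidecar", {
  pop <- generate_population(rmax = 1.5, n_target = 10, seed = 16,
                             measure_fn = stub_normal_measures)
  path <- withr::local_tempfile(fileext = ".csv")
  write_population_csv(pop, path)
  df <- read.csv(path)
  expect_equal(nrow(df), 10)
  side <- jsonlite::read_json(sub("\\.csv$", ".json", path))
  expect_equal(side$rmax, 1.5)
  expect_equal(side$accepted, 10L)
  expect_equal(side$attempted, attr(pop, "attempted"))
})
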