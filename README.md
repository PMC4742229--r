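# vocalpop

Population-based sensitivity analysis of the symmetric Steinecke–Herzel
two-mass vocal-fold model, in R.

Lumped-element vocal-fold models are the workhorses of computational voice
science, but most studies probe them one configuration at a time — in
effect, one virtual patient. `vocalpop` takes the population view: it
samples thousands of virtual subjects by multiplicative perturbation of
the 16 model parameters, keeps the ones whose glottal-flow waveform looks
like normal human phonation, and characterizes how every model output
responds to every input *across the accepted population*, as distributions
rather than single numbers. It is aimed at voice scientists and modelers
who need to know which parameters of a reduced-order phonation model have
consistent, negligible, or erratic effects before trusting an optimization
or an inverse analysis built on it.

## What is inside

* **Simulator** — the symmetric two-mass model (masses `m1`, `m2`, springs
  `k1`, `k2`, `kc`, dampers `r1`, `r2`, collision springs `c1`, `c2`,
  geometry `d1`, `d2`, `L`, rest areas `a01`, `a02`, smoothed-step scale
  `x0`, subglottal pressure `P`), integrated with fixed-step RK4 in
  compiled code; Bernoulli glottal flow
  `U = sqrt(2P/ρ) · a_min · Θ(a_min)`.
* **Voice measures** — F0, mean/AC/peak flow, maximum flow declination
  rate, harmonic richness factor, H1–H2, open and speed quotients, plus
  the six-bound normal-phonation filter (88–263 Hz, 50–420 cm³/s, 40–800
  cm³/s, 100–1150 L/s², −19–2.1 dB, −24–11 dB).
* **Population sampling** — factors `r^a` with `r ~ U(1, Rmax)`,
  `a = ±1`, rejection on the filter; per-parameter success histograms,
  fitted sampleable densities, and adaptive (density-guided) resampling.
* **Sensitivities** — per-subject non-dimensional elasticities
  `S* = (ΔF/F)/(Δx/x)` at +1% for all 16 × 6 input–output pairs;
  range-wise medians/percentiles and mean-vs-SD consistency classes; MDSD
  (multi-dimensional sensitivity distribution) plots.
* **Designed experiments** — one-at-a-time (32 runs), Cotter screening
  (34 runs), and a 231-point D-optimal quadratic response surface with
  independent validation, for comparison against the Monte Carlo answer.

## Worked example

```r
library(vocalpop)
library(dplyr)

# one subject: the nominal configuration
m <- extract_measures(simulate_fold(sh_params()))
round(as.data.frame(m[, c("f0_hz", "mean_flow_cm3s", "mfdr_ls2",
                          "hrf_db", "h1h2_db", "oq")]), 2)
#>    f0_hz mean_flow_cm3s mfdr_ls2 hrf_db h1h2_db   oq
#> 1 135.8          249.89   362.26 -11.31    5.44 0.65
classify_normal(m)$pass_normal
#> [1] TRUE

# a virtual population at Rmax = 1.5 and its sensitivity tensor
pop <- generate_population(rmax = 1.5, n_target = 100, seed = 1)
glance(pop)
#> # A tibble: 1 × 6
#>    rmax  seed attempted accepted success_rate exhausted
#>   <dbl> <int>     <int>    <int>        <dbl> <lgl>
#> 1   1.5     1       309      100        0.324 FALSE

tensor <- population_sensitivity(pop)
summarize_pairs(tensor) |>
  arrange(desc(abs(median))) |>
  head(3)
#> # A tibble: 3 × 8
#>   input output           p5 median   p95 n_valid n_invalid n_ranges
#>   <chr> <chr>         <dbl>  <dbl> <dbl>   <int>     <int>    <int>
#> 1 L     mfdr_ls2       1.71   2.00  3.48     100         0        1
#> 2 P     mfdr_ls2       1.35   1.50  2.25     100         0        1
#> 3 L     max_flow_cm3s  1.12   1.44  1.86     100         0        1
```

The F0 of the nominal model sits at 135.8 Hz between the coupled
eigenfrequencies of the linearized system; a 1% increase in vocal-fold
length `L` raises the maximum flow declination rate by about 2% (`S*` ≈
2.0), the single strongest input–output coupling in the model, with
subglottal pressure close behind. `plot_mdsd(tensor)` draws the full
grayscale distribution grid; `plot_mean_sd(summarize_pairs(tensor,
by_range = TRUE))` separates the few consistent pairs from the erratic
majority.

`run_pipeline(run_config(), "results/")` executes the whole study
(populations → tensors → summaries → figures, all seeded) and archives
CSVs, a JSON manifest and PNG figures; a thin CLI wrapper lives at
`inst/cli/vocalpop.R`.

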