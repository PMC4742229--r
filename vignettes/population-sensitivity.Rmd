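---
title: "Population-based sensitivity analysis of a two-mass vocal-fold model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population-based sensitivity analysis of a two-mass vocal-fold model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vocalpop)
library(dplyr)
```

## The model

`vocalpop` simulates the symmetric Steinecke–Herzel (S&H) two-mass
vocal-fold model: each fold is lumped into a lower mass `m1` (the main
vibrating body, driven by subglottal pressure) and an upper mass `m2`,
coupled by a spring `kc`, each with its own restoring spring (`k1`, `k2`),
damper (`r1`, `r2`) and a collision spring (`c1`, `c2`) that engages when a
mass crosses the glottal midline. The glottal areas at the two mass levels
are `a_i = a0i + 2 L x_i`, where `L` is the vocal-fold length and `a0i` the
rest areas. The lower mass carries the aerodynamic driving force

    F_aero = L d1 P [1 - Θ(a_min) (a_min / a1)^2] Θ(a1),

a jet-pressure profile that delivers the full subglottal pressure `P` when
the glottis is closed downstream and Bernoulli recovery when open. `Θ` is a
smoothed step, `Θ(y) = tanh(50 y / x0)` for `y > 0` and zero otherwise,
with `x0` the reference length scale; it keeps the vector field continuous
at closure. Glottal volume velocity follows the Bernoulli law
`U = sqrt(2 P / ρ) a_min Θ(a_min)` with air density `ρ = 0.00113 g/cm³`
(a physical constant, deliberately not one of the 16 sampled parameters).
All quantities live in the g–cm–ms unit system. The model is symmetric
(one fold simulated and mirrored — a 4-state system), has no Coanda
switching, no turbulence and no vocal-tract coupling; those are properties
of the chosen source model, not omissions. The upper-mass thickness `d2`
enters no force or flow term, so every one of its sensitivities is exactly
zero — a useful built-in null check.

Sixteen parameters define an instance: `P, m1, m2, k1, k2, kc, r1, r2, d1,
d2, L, c1, c2, a01, a02, x0`, with the nominal values returned by
`sh_params()`.

## Numerical choices

* **Integration**: classical fixed-step RK4 with `dt = 0.01 ms`, 1500 ms of
  simulated time, the first 500 ms discarded as transient. Fixed-step keeps
  runs bit-reproducible; halving `dt` changes the nominal fundamental
  frequency by well under 0.5% (asserted in the test suite). Initial
  conditions `x1 = x2 = 0.01 cm`, zero velocity — steady-state measures do
  not depend on them, only the discarded transient does.
* **Divergence**: a non-finite state flags the run as failed instead of
  raising an error, so one absurd parameter draw cannot abort a population
  run.
* **Fixed-point early exit**: the system is autonomous, so a state that
  has reached numerical equilibrium (velocities and accelerations below
  10⁻¹⁰ for both masses) can never re-oscillate; the integrator then fills
  the remaining flow with the constant equilibrium value and stops. This
  leaves every classification outcome unchanged while cutting the cost of
  broad-range rejection sampling roughly threefold, since most rejected
  candidates are decays to a fixed point. Trajectory-keeping runs always
  integrate the full duration.
* **Cycle detection**: upward crossings of
  `min(U) + 0.01 (max(U) - min(U))`, with a mid-level hysteresis gate so
  trough ripples are not mistaken for pulse onsets. The range-relative
  threshold matters: at broad sampling ranges many subjects phonate
  *without* full glottal closure, and a threshold pinned near zero flow
  would misclassify them as silent. At least 20 complete cycles and a
  period coefficient of variation below 5% are required before a waveform
  counts as steady phonation.
* **Spectra**: the waveform is trimmed to an integer number of cycles
  (rectangular window, harmonics on exact DFT bins, evaluated by the
  Goertzel recursion over the last up-to-64 cycles). The harmonic richness
  factor `HRF = 10 log10(Σ_{n≥2} A_n² / A_1²)` is a source-spectrum
  measure computed on the flow harmonics `A_n`. H1–H2 is an acoustic
  spectral-tilt measure: radiated pressure is proportional to the flow
  derivative under monopole radiation, whose harmonics are `n ω0 A_n`, so
  `H1-H2 = 20 log10(A_1 / (2 A_2))`. Two observations support this split:
  the accepted H1–H2 range extends to −24 dB, which flow spectra
  essentially never reach (flow H1–H2 is almost always positive), and with
  a flow-based H1–H2 the nominal parameter set itself would fail the
  filter by a fraction of a dB, contradicting the fact that phonation is
  normal in the vicinity of the nominal configuration. The HRF sum is
  capped at 64 harmonics: flow harmonics decay like `n^-2`, so the
  neglected tail changes HRF by under 0.01 dB while quartering the
  per-subject cost.
* **MFDR** uses centred finite differences of `U` at full resolution with
  no smoothing — the waveform is smooth and smoothing would bias the peak.

## The virtual population

A virtual subject multiplies every nominal parameter by an independent
factor `r^a`, `r ~ U(1, Rmax)`, `a = ±1` with equal probability, so factors
span `[1/Rmax, Rmax]` with half above and half below 1 on average. The
study grid is `Rmax ∈ {1.10, 1.20, 1.50, 2.00, 5.00}`. Subjects are
rejected unless all six normal-phonation bounds hold (f0 88–263 Hz, mean
flow 50–420 cm³/s, AC flow 40–800 cm³/s, MFDR 100–1150 L/s², HRF −19–2.1
dB, H1–H2 −24–11 dB) together with the steadiness gate. Populations are
generated sequentially from one seeded stream (`set.seed(seed)` at run
start), which makes a run — including its attempted/accepted accounting —
exactly reproducible.

```{r population, eval = FALSE}
pop <- generate_population(rmax = 1.5, n_target = 300, seed = 1)
glance(pop)
```

The generator is first-class, tested code: what it emulates is the
sampling law and rejection filter of the study design. What it does *not*
emulate is real physiological covariance — parameters are drawn
independently, whereas in humans length, stiffness and mass co-vary
through muscle activation. Passing tests therefore validate the
computational pipeline on the stated sampling assumptions, not the
physiological realism of any individual virtual subject.

Success histograms of the accepted subjects' factors (25 equal-width bins
on the log-factor axis) show which parameters gate normal phonation.
`fit_density()` smooths the bin masses with a width-3 moving average and
builds a monotone piecewise-linear CDF per parameter; resampling from
those CDFs instead of the uniform scheme (`adaptive_success_rate()`)
raises the acceptance rate at `Rmax = 5` several-fold. All 16 parameters
are resampled from their fitted marginals (resampling only the skewed
ones was the other defensible reading; resampling all is simpler and the
near-uniform marginals are nearly neutral anyway).

## Sensitivities

For each accepted subject, each parameter in turn is scaled by 1.01 (a +1%
forward perturbation — the direction is a convention; `delta` is an
argument) and the model re-simulated. The non-dimensional sensitivity is
the elasticity

    S* = ((F_perturbed - F_base) / F_base) / 0.01,

read as percent output change per percent input change, computed for six
outputs: fundamental frequency, mean flow, maximum flow, MFDR, open
quotient and speed quotient. Per subject that is 16 × 6 = 96 records, with
a validity mask for perturbed runs that fail to phonate (excluded from
summaries, with exclusion counts reported). Per input–output pair the
median and the 5th/95th percentiles are computed within each range and
averaged across ranges; medians are used because the sensitivity
distributions are strongly non-normal. The consistency classes at a single
range compare `|mean|` with one and two standard deviations of the
per-subject sensitivities.

Three designed-experiment methods are implemented for comparison, and all
three need every design point to phonate normally — their documented
failure mode at broad ranges:

* `oat_analysis()`: one-at-a-time ± variation, 32 runs, normalized central
  differences (the midpoint of the two endpoint responses is the
  normalizer, so no 33rd run is needed); structurally blind to
  interactions.
* `cotter_analysis()`: the 2n+2 = 34-run systematic fractional factorial,
  with odd/even effect indices; an additive response puts everything in
  the odd index, a pure two-way interaction everything in the even index.
* `d_optimal_design()` + `fit_rsm()`: a 231-point D-optimal design for the
  full 153-term quadratic surface on the `[-1, 1]^16` hypercube (seeded
  Latin-hypercube candidates plus axial points, Fedorov exchange with
  rank-one determinant updates), least-squares fit per output, analytic
  gradient converted to elasticities at the centre. Design coordinates map
  multiplicatively, `x = nominal · Rmax^z`, so the design box coincides
  with the population sampling box. 231 points against 153 terms leaves
  honest lack-of-fit degrees of freedom. `validate_rsm()` re-simulates at
  fresh random points and reports the mean over points of the
  maximum-across-outputs relative error ("average maximum error" — the
  per-output means are also returned so other readings of that phrase can
  be checked).

## Problem sizes and what the checks compute

The full study design (1000 subjects per range, five ranges, 17 runs per
subject) is ~85,000 simulations. The package's automated checks reproduce
the headline numbers at reduced scale — 200–500 accepted subjects per
range, chosen so the whole pipeline (population, tensors, response
surface, resampling) reruns from scratch in minutes on one core while
keeping the binomial/bootstrap error of each reproduced quantity a small
fraction of its published value. `convergence_check()` exposes the
stability of the medians against population size directly.

## Known limitations

* Independent parameter sampling (above) — by design, to keep individual
  sensitivities identifiable.
* The local sensitivities are forward differences at +1%; they quantify
  local slopes, not variance decomposition (no Sobol-type indices).
* The measure set is the study's six outputs; jitter, shimmer and
  noise-to-harmonic ratios are out of scope.
* Cycle-based measures assume near-periodic waveforms; strongly aperiodic
  (chaotic) regimes are rejected by the steadiness gate rather than
  characterized.
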