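Package: vocalpop
Title: Population-Based Sensitivity Analysis of a Two-Mass Vocal-Fold Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates the symmetric Steinecke-Herzel two-mass vocal-fold
    model and analyses its behaviour across virtual populations of phonating
    subjects. Provides a fast fixed-step Runge-Kutta simulator of the coupled
    mass-spring-damper system with Bernoulli glottal flow, extraction of
    clinical voice-source measures (fundamental frequency, mean/AC/peak flow,
    maximum flow declination rate, harmonic richness factor, H1-H2, open and
    speed quotients), a normal-phonation rejection filter, multiplicative
    uniform population sampling with adaptive density-based resampling,
    per-subject non-dimensional local sensitivities aggregated into
    multi-dimensional sensitivity distributions, and three designed-experiment
    sensitivity methods (one-at-a-time, Cotter screening, and a D-optimal
    quadratic response surface) for comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    graphics,
    utils,
    lhs
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
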