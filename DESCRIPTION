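Package: macrores
Title: Macroecological Baselines, Stochastic Community Dynamics and
    Resilience Metrics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies ecological resilience as the displacement of, and
    return to, macroecological baseline distributions. Provides the beta
    stationary species proportional-abundance distribution of neutral
    birth-death-immigration dynamics with a maximum-likelihood fitter; Pareto
    and truncated-Pareto individual size spectra with exponent estimation and
    bootstrap confidence intervals; density-mass scaling fits; an exact
    (Gillespie) birth-death-immigration community simulator and a pure-birth
    master-equation solver; a one-dimensional forward Kolmogorov
    (Fokker-Planck) finite-volume solver with stationary-density quadrature;
    a size-structured demographic engine built on metabolic-scaling growth
    and mortality, including the steady-state size distribution with log-log
    slope -2 and an individual-based forest simulator; pulse and press
    perturbation operators with baseline-deviation metrics and recovery-time
    estimation; and a random community-matrix stability scanner for the
    complexity-stability transition under sparse connectance scaling.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    deSolve,
    fitdistrplus,
    jsonlite,
    Rcpp,
    vegan
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
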