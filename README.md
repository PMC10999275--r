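# macrores

Quantitative resilience analysis for ecological communities, built on
macroecological baselines.

Ecological assemblages of many individuals settle into characteristic
statistical distributions — the species proportional-abundance distribution,
the individual size spectrum, density–mass scaling — that emerge from
stochastic birth–death dynamics under weak symmetry (neutrality, shared
allometric scaling, zero-sum resource use) assumptions. `macrores` treats
those distributions as measurable attractors: a disturbance displaces a
community from its baseline distribution, and resilience becomes the size of
the displacement and the time course of the return. The package is aimed at
quantitative ecologists who want to move beyond ball-and-cup metaphors to
fitted parameters, calibrated tolerances and recovery times.

## What is inside

**Baseline distributions.** The stationary beta species
proportional-abundance density
ρ<sub>∞</sub>(x) = Γ(α+β)/(Γ(α)Γ(β)) · x<sup>α−1</sup>(1−x)<sup>β−1</sup>
of neutral birth–death–immigration dynamics, with an MLE fitter
(`fit_beta_sad`) and a diagnostic for its exact power-law special cases at
α = 1 or β = 1 (`beta_sad_loglinearity`). Pareto and truncated Pareto size
spectra f(m) = (λ+1)/(m<sub>max</sub><sup>λ+1</sup> −
m<sub>0</sub><sup>λ+1</sup>) · m<sup>λ</sup> with maximum-likelihood exponent
estimation and bootstrap confidence intervals (`fit_trunc_pareto`,
`fit_loglog_slope`). Density–mass scaling N = aM<sup>−b</sup>
(`fit_density_mass_scaling`).

**Dynamics.** An exact Gillespie birth–death simulator
(`gillespie_simulate`), a compiled neutral zero-sum community with
immigration (`simulate_neutral_community`) with a KS stationarity test
against the beta baseline (`stationary_abundance_test`), a pure-birth
master-equation solver (`solve_master_equation`), a conservative
finite-volume forward Kolmogorov (Fokker–Planck) solver
(`fokker_planck_solve`, `fokker_planck_stationary`), and a size-structured
demographic engine: the steady-state size distribution of the balance
equation ½(VN)″ − (GN)′ − MN = 0 (`solve_steady_state_size_distribution`)
and an individual-based forest simulator (`ibm_forest_simulate`). Under
metabolic-scaling growth G = g₀D<sup>θ</sup> and the steady-state
growth–mortality symmetry D·M/G = 2 − ∂lnG/∂lnD
(`steady_state_mortality`), the size distribution's log–log slope is exactly
−2 — de Liocourt's inverse-J forest structure — for every θ < 2.

**Resilience.** Pulse and press perturbation operators (`perturbation`,
`apply_perturbation`), baseline-deviation metrics (KS, Hellinger, parameter
distance; `baseline_deviation`, `bray_curtis`), recovery trajectories with
refitted baselines (`track_recovery`), null-calibrated tolerances
(`calibrate_recovery_tolerance`) and recovery times (`recovery_time`). A
random community-matrix stability scanner for the complexity transition at
α√(SC) = 1 and its disappearance under sparse connectance C ∝ 1/S
(`stability_probability`, `sparse_scaling_scan`).

## Worked example: perturb a steady-state forest and time its recovery

```r
library(macrores)

g   <- mst_growth()                      # G(D) = D^(1/3)
M   <- steady_state_mortality(g)         # balancing mortality, slope -2
sim <- ibm_forest_simulate(growth = g, mortality = M,
                           n_init = 5000, t_max = 3, seed = 1)
sim
#> Individual-based forest: 5000 stems at t = 3 (dt = 0.000278)
#>   diameter range [0.01, 2.8]

fit <- fit_trunc_pareto(sim$sizes, n_boot = 200, seed = 2)
fit
#> Truncated Pareto size spectrum (MLE, plug-in endpoints)
#>   lambda = -2.0194 (se 0.0153), m0 = 0.01, mmax = 2.79968, n = 5000
#>   95% bootstrap CI for lambda: [-2.0527, -1.9900]
```

The equilibrated forest sits on the −2 baseline (the CI covers −2). Now
remove every stem above the 90th diameter percentile — a disturbance that
hits the largest individuals — and track the return:

```r
spec <- perturbation("remove_large", intensity = 1,
                     threshold = quantile(sim$sizes, 0.9))
tr   <- track_recovery(sim$sizes, g, M, fit, spec,
                       horizon = 2.5, interval = 0.25, seed = 3)
tr
#> Recovery trajectory (ks deviation): 10 samples on (0, 2.5]
#>   final lambda = -1.9794, final deviation = 0.0197

tol <- calibrate_recovery_tolerance(sim$sizes, g, M, fit,
                                    horizon = 2.5, interval = 0.25,
                                    seeds = 11:13)
recovery_time(tr, tol)   # tolerance 0.0218, persistence 3
#> [1] 0.5
```

The deviation re-enters the forest's own null fluctuation band (95th
percentile 0.022) within half a time unit, and the final fitted exponent is
back on the baseline: the assemblage recovered. Running the same pipeline
with `perturbation("rate_shift", intensity = 2, threshold = median(sim$sizes))`
— a sustained doubling of small-tree mortality — produces a deviation series
that plateaus an order of magnitude above tolerance and a final λ̂ near
−2.4: a shifted baseline, `recovery_time()` = `Inf`.

A thin command-line interface over the same functions is installed at
`inst/cli/macrores.R` (subcommands `simulate-forest`, `simulate-community`,
`fit-sad`, `fit-sizedist`, `perturb`, `stability-scan`, `make-fixtures`).

See `vignettes/macroecological-resilience.Rmd` for the models, assumptions,
numerical choices and limitations.

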