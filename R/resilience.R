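#' Specify a perturbation
#'
#' Disturbance operators acting on a size-structured assemblage, following
#' the three canonical post-perturbation scenarios for a size-spectrum
#' baseline: (b) removal of smaller individuals (pulse; the refitted
#' exponent shallows, then recovers as individuals grow and recruit),
#' (d) removal of the largest individuals (pulse; `mmax` collapses, then
#' recovers as survivors grow), and (c) a sustained (press) shift of a
#' demographic rate after which the assemblage equilibrates to a different
#' baseline rather than returning.
#'
#' @param kind one of `"remove_small"`, `"remove_large"`,
#'   `"proportional_thinning"`, `"rate_shift"`.
#' @param intensity for removals: per-individual removal probability in
#'   `[0, 1]` (applied below/above `threshold` for the size-selective
#'   kinds, everywhere for proportional thinning). For `rate_shift`: the
#'   multiplier applied to mortality.
#' @param threshold size cutoff for `remove_small` / `remove_large` /
#'   `rate_shift` (for the latter: mortality is multiplied below the
#'   threshold; use `side = "above"` to shift large-tree mortality).
#' @param side for `rate_shift`: `"below"` or `"above"` the threshold.
#' @param interval for `rate_shift`: press duration `c(start, end)` in
#'   model time relative to the perturbation instant; default the whole
#'   horizon.
#' @return object of class `"perturbation"`.
#' @export
perturbation <- function(kind = c("remove_small", "remove_large",
                                  "proportional_thinning", "rate_shift"),
                         intensity, threshold = NULL,
                         side = c("below", "above"), interval = NULL) {
  kind <- match.arg(kind)
  side <- match.arg(side)
  if (kind != "rate_shift") {
    if (intensity < 0 || intensity > 1)
      stop("removal `intensity` must be in [0, 1]", call. = FALSE)
    if (kind != "proportional_thinning" && is.null(threshold))
      stop("size-selective removal needs a `threshold`", call. = FALSE)
  } else {
    if (intensity <= 0) stop("rate multiplier must be positive", call. = FALSE)
    if (is.null(threshold))
      stop("`rate_shift` needs a size `threshold`", call. = FALSE)
  }
  structure(list(kind = kind, intensity = intensity, threshold = threshold,
                 side = side, interval = interval),
            class = "perturbation")
}

#' Apply a perturbation
#'
#' For pulse kinds (`remove_small`, `remove_large`,
#' `proportional_thinning`) acting on a vector of individual sizes, each
#' individual in the targeted size range is removed independently with
#' probability `intensity`. Removing the entire population is an error
#' (the framework assumes non-total mortality: a new demographic
#' equilibrium requires survivors). For `rate_shift` acting on a
#' [demographic_rates()] object, a new rates object is returned whose
#' mortality is multiplied by `intensity` on the targeted side of the
#' threshold (a press disturbance).
#'
#' @param population numeric vector of individual sizes, or a
#'   [demographic_rates()] object for `rate_shift`.
#' @param spec a [perturbation()].
#' @param seed integer seed for the removal draws.
#' @return perturbed sizes (numeric) or modified `demographic_rates`.
#' @export
apply_perturbation <- function(population, spec, seed = NULL) {
  stopifnot(inherits(spec, "perturbation"))
  if (spec$kind == "rate_shift") {
    if (!inherits(population, "demographic_rates"))
      stop("`rate_shift` applies to a `demographic_rates` object",
           call. = FALSE)
    M0 <- population$M
    thr <- spec$threshold
    mult <- spec$intensity
    M1 <- if (spec$side == "below") {
      function(D) M0(D) * ifelse(D < thr, mult, 1)
    } else {
      function(D) M0(D) * ifelse(D >= thr, mult, 1)
    }
    out <- population
    out$M <- M1
    return(out)
  }
  sizes <- as.numeric(population)
  if (length(sizes) == 0L) stop("population is empty", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  at_risk <- switch(spec$kind,
                    remove_small = sizes < spec$threshold,
                    remove_large = sizes > spec$threshold,
                    proportional_thinning = rep(TRUE, length(sizes)))
  kill <- at_risk & stats::runif(length(sizes)) < spec$intensity
  out <- sizes[!kill]
  if (length(out) == 0L)
    stop("perturbation would remove the entire population; total ",
         "mortality is outside the recovery framework", call. = FALSE)
  out
}

#' Deviation of a distribution from its macroecological baseline
#'
#' Distance between a current state (an empirical size sample or a fitted
#' baseline-family object) and a fitted baseline, used as the resilience
#' metric: deviations from the macroecological baseline quantify the
#' displacement a perturbation caused and the return path.
#'
#' Metrics: `"ks"` is the Kolmogorov-Smirnov sup-distance between the two
#' distribution functions (empirical vs parametric, or parametric vs
#' parametric on a fine grid); `"hellinger"` is the Hellinger distance
#' between densities (in `[0, 1]`); `"param"` is the Euclidean distance
#' between parameter vectors standardized by the baseline's absolute
#' parameter values (requires both objects to be fits of the same family).
#'
#' @param current numeric sample, or `trunc_pareto_fit` / `beta_sad_fit`.
#' @param baseline a `trunc_pareto_fit` or `beta_sad_fit`.
#' @param metric `"ks"`, `"hellinger"`, or `"param"`.
#' @return non-negative scalar; 0 on identical inputs.
#' @export
baseline_deviation <- function(current, baseline,
                               metric = c("ks", "hellinger", "param")) {
  metric <- match.arg(metric)
  if (metric == "param") {
    if (!identical(class(current), class(baseline)))
      stop("`param` distance requires fits of the same family", call. = FALSE)
    p1 <- stats::coef(current); p2 <- stats::coef(baseline)
    scale <- pmax(abs(p2), .Machine$double.eps)
    return(sqrt(sum(((p1 - p2) / scale)^2)))
  }
  bf <- dist_funs(baseline)
  if (is.numeric(current)) {
    if (metric == "hellinger")
      stop("`hellinger` needs two densities; fit the current sample first",
           call. = FALSE)
    x <- sort(current)
    return(ks_statistic(x, bf$cdf(x)))
  }
  cf <- dist_funs(current)
  lo <- max(bf$support[1], cf$support[1])
  hi <- min(bf$support[2], cf$support[2])
  if (!(lo < hi)) stop("supports do not overlap", call. = FALSE)
  if (metric == "ks") {
    g <- grid_for(bf, cf, lo, hi)
    max(abs(cf$cdf(g) - bf$cdf(g)))
  } else {
    # Hellinger via Bhattacharyya coefficient on a log-ish grid
    g <- grid_for(bf, cf, lo, hi)
    f <- sqrt(cf$pdf(g) * bf$pdf(g))
    bc <- trapz(g, f)
    sqrt(max(0, 1 - min(bc, 1)))
  }
}

# cdf/pdf accessors for the supported baseline families
dist_funs <- function(obj) {
  if (inherits(obj, "trunc_pareto_fit")) {
    list(cdf = function(q) ptrunc_pareto(q, obj$lambda, obj$m0, obj$mmax),
         pdf = function(m) dtrunc_pareto(m, obj$lambda, obj$m0, obj$mmax),
         support = c(obj$m0, obj$mmax), log_grid = TRUE)
  } else if (inherits(obj, "beta_sad_fit")) {
    list(cdf = function(q) stats::pbeta(q, obj$alpha, obj$beta_shape),
         pdf = function(x) stats::dbeta(x, obj$alpha, obj$beta_shape),
         support = c(0, 1), log_grid = FALSE)
  } else {
    stop("unsupported baseline family: ", paste(class(obj), collapse = "/"),
         call. = FALSE)
  }
}

grid_for <- function(bf, cf, lo, hi, n = 20001) {
  if (isTRUE(bf$log_grid) && lo > 0) exp(seq(log(lo), log(hi), length.out = n))
  else seq(lo, hi, length.out = n)
}

#' Track recovery of the size-spectrum baseline after a perturbation
#'
#' Applies a perturbation to an equilibrated individual-based forest state,
#' continues the simulation, and at every sampling time refits the
#' truncated-Pareto baseline family and computes the deviation from the
#' pre-perturbation baseline. The trajectory of fitted parameters and
#' deviations is the operational resilience measure: the rate and shape of
#' the return (or the failure to return) to the baseline.
#'
#' Pulse perturbations (`remove_*`, `proportional_thinning`) are applied
#' instantaneously to the standing sizes before the simulation resumes.
#' Press perturbations (`rate_shift`) leave the sizes untouched but run the
#' simulation under the shifted mortality for the spec's `interval`
#' (default: the whole horizon).
#'
#' @param sizes equilibrated individual diameters (the simulator state at
#'   the end of a baseline run).
#' @param growth an [mst_growth()] object.
#' @param mortality baseline mortality function `M(D)`.
#' @param baseline a `trunc_pareto_fit` of the equilibrated state.
#' @param spec a [perturbation()]; `NULL` runs the unperturbed null
#'   trajectory (used to calibrate the recovery tolerance).
#' @param horizon post-perturbation time to simulate.
#' @param interval sampling interval (must not exceed `horizon`).
#' @param D_min recruitment diameter.
#' @param metric deviation metric passed to [baseline_deviation()]
#'   (sample-vs-baseline; default `"ks"`).
#' @param n_boot bootstrap replicates for each refit's CI (0 for none;
#'   the final sample's fit always gets a CI when `n_boot > 0`).
#' @param seed integer seed.
#' @return object of class `"recovery_trajectory"`: list with `series` (data
#'   frame `t`, `lambda`, `m0`, `mmax`, `deviation`), `final_fit` (the
#'   last refit, with bootstrap CI), `baseline`, `spec`.
#' @export
track_recovery <- function(sizes, growth, mortality, baseline, spec,
                           horizon, interval, D_min = 0.01,
                           metric = "ks", n_boot = 200, seed = NULL) {
  stopifnot(inherits(baseline, "trunc_pareto_fit"))
  if (horizon < interval)
    stop("`horizon` must cover at least one sampling interval", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  M <- mortality
  if (!is.null(spec)) {
    stopifnot(inherits(spec, "perturbation"))
    if (spec$kind == "rate_shift") {
      rates <- demographic_rates(growth, mortality, recruitment = 0)
      M <- apply_perturbation(rates, spec)$M
    } else {
      sizes <- apply_perturbation(sizes, spec)
    }
  }
  press_window <- if (!is.null(spec) && spec$kind == "rate_shift") {
    if (is.null(spec$interval)) c(0, horizon) else spec$interval
  } else NULL
  times <- seq(interval, horizon, by = interval)
  k <- length(times)
  lam <- m0 <- mm <- dev <- numeric(k)
  final_fit <- NULL
  cur <- sizes
  for (i in seq_len(k)) {
    mid <- times[i] - interval / 2
    Mi <- if (!is.null(press_window) &&
              mid >= press_window[1] && mid <= press_window[2]) M else mortality
    sim <- ibm_forest_simulate(growth = growth, mortality = Mi,
                               recruitment = "zero_sum",
                               D_min = D_min, n_init = length(cur),
                               init_sizes = cur, t_max = interval)
    cur <- sim$sizes
    fit <- fit_trunc_pareto(cur, n_boot = if (i == k) n_boot else 0)
    lam[i] <- fit$lambda; m0[i] <- fit$m0; mm[i] <- fit$mmax
    dev[i] <- baseline_deviation(cur, baseline, metric = metric)
    if (i == k) final_fit <- fit
  }
  structure(list(series = data.frame(t = times, lambda = lam, m0 = m0,
                                     mmax = mm, deviation = dev),
                 final_fit = final_fit, baseline = baseline, spec = spec,
                 metric = metric),
            class = "recovery_trajectory")
}

#' @export
print.recovery_trajectory <- function(x, ...) {
  s <- x$series
  cat(sprintf(
    "Recovery trajectory (%s deviation): %d samples on (0, %.3g]\n",
    x$metric, nrow(s), max(s$t)))
  cat(sprintf("  final lambda = %.4f, final deviation = %.4f\n",
              s$lambda[nrow(s)], s$deviation[nrow(s)]))
  invisible(x)
}

#' Calibrate the recovery tolerance from the baseline's own fluctuations
#'
#' The recovery criterion needs a tolerance below which the deviation
#' series counts as "back at baseline". Because an equilibrated finite
#' assemblage fluctuates, the tolerance is calibrated as a quantile
#' (default 95%) of the deviations observed along unperturbed null
#' trajectories started from the same state.
#'
#' @inheritParams track_recovery
#' @param seeds integer vector of seeds, one null trajectory each.
#' @param prob quantile of the pooled null deviations.
#' @return scalar tolerance.
#' @export
calibrate_recovery_tolerance <- function(sizes, growth, mortality, baseline,
                                         horizon, interval, D_min = 0.01,
                                         metric = "ks", seeds = 1:5,
                                         prob = 0.95) {
  devs <- unlist(lapply(seeds, function(s) {
    track_recovery(sizes, growth, mortality, baseline, spec = NULL,
                   horizon = horizon, interval = interval, D_min = D_min,
                   metric = metric, n_boot = 0, seed = s)$series$deviation
  }))
  unname(stats::quantile(devs, prob))
}

#' Recovery time of a trajectory
#'
#' First sampling time after the perturbation at which the deviation stays
#' below `tolerance` for `persistence` consecutive samples (the time
#' reported is the first sample of the qualifying run). Requiring several
#' consecutive sub-tolerance samples guards against single-sample flukes.
#' Returns `Inf` if the trajectory never qualifies ("not recovered").
#'
#' @param traj a `"recovery_trajectory"` or a data frame with columns `t`
#'   and `deviation`.
#' @param tolerance positive deviation tolerance (see
#'   [calibrate_recovery_tolerance()]).
#' @param persistence number of consecutive sub-tolerance samples required
#'   (`>= 1`).
#' @return recovery time (model time units), or `Inf` if not recovered.
#' @export
recovery_time <- function(traj, tolerance, persistence = 3) {
  if (inherits(traj, "recovery_trajectory")) traj <- traj$series
  if (tolerance <= 0) stop("`tolerance` must be positive", call. = FALSE)
  persistence <- as.integer(persistence)
  if (persistence < 1L) stop("`persistence` must be >= 1", call. = FALSE)
  below <- traj$deviation < tolerance
  n <- length(below)
  if (n >= persistence) {
    run <- 0L
    for (i in seq_len(n)) {
      run <- if (below[i]) run + 1L else 0L
      if (run >= persistence) return(traj$t[i - persistence + 1L])
    }
  }
  Inf
}
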