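#' Metabolic-scaling growth parameters
#'
#' Diameter growth under metabolic scaling theory: `G(D) = g0 * D^theta`,
#' with the default exponent `theta = 1/3` (diameter growth implied by the
#' 3/4-power scaling of whole-plant metabolism). `g0` carries units
#' diameter^(1-theta)/time.
#'
#' @param g0 growth normalization, `> 0`.
#' @param theta dimensionless growth exponent.
#' @return object of class `"mst_growth"`: list with `g0`, `theta`, and the
#'   growth function `G(D)`.
#' @export
mst_growth <- function(g0 = 1, theta = 1 / 3) {
  if (g0 <= 0) stop("`g0` must be positive", call. = FALSE)
  structure(list(g0 = g0, theta = theta,
                 G = function(D) g0 * D^theta),
            class = "mst_growth")
}

#' Mortality schedule balancing growth at resource steady state
#'
#' At resource (demographic) steady state, growth and mortality must
#' balance so that the steady-state size distribution has log-log slope -2
#' (de Liocourt's law under metabolic scaling). The balance condition is
#' \deqn{D\,\frac{M(D)}{G(D)} = 2 - \frac{\partial \ln G}{\partial \ln D},}
#' i.e. `M(D) = G(D) (2 - theta) / D` for power-law growth
#' `G = g0 D^theta`, which gives `M(D) = g0 (2 - theta) D^(theta - 1)`.
#' For `theta >= 2` the balancing mortality would be non-positive, which is
#' demographically impossible, so an error is raised.
#'
#' @param growth an [mst_growth()] object.
#' @return the mortality rate function `M(D)` (units 1/time), with the
#'   parameters attached as attributes `mu0` (`= g0 (2 - theta)`) and
#'   `theta_m` (`= theta - 1`).
#' @examples
#' M <- steady_state_mortality(mst_growth(g0 = 1, theta = 1 / 3))
#' M(1)   # 5/3
#' @export
steady_state_mortality <- function(growth) {
  stopifnot(inherits(growth, "mst_growth"))
  if (growth$theta >= 2)
    stop("`theta` >= 2 would require non-positive mortality to balance ",
         "growth; the steady-state symmetry holds only for theta < 2",
         call. = FALSE)
  mu0 <- growth$g0 * (2 - growth$theta)
  te <- growth$theta - 1
  M <- function(D) mu0 * D^te
  attr(M, "mu0") <- mu0
  attr(M, "theta_m") <- te
  M
}

#' Bundle size-dependent demographic rates
#'
#' @param growth growth function `G(D) > 0` (diameter/time) or an
#'   [mst_growth()] object.
#' @param mortality mortality function `M(D) >= 0` (1/time).
#' @param growth_variance optional variance-in-growth function
#'   `V(D) >= 0` (diameter^2/time); `NULL` means deterministic growth.
#' @param recruitment recruitment rate `R >= 0` (individuals/time entering
#'   at the smallest size).
#' @return object of class `"demographic_rates"`.
#' @export
demographic_rates <- function(growth, mortality, growth_variance = NULL,
                              recruitment = 1) {
  G <- if (inherits(growth, "mst_growth")) growth$G else growth
  stopifnot(is.function(G), is.function(mortality))
  if (recruitment < 0) stop("`recruitment` must be >= 0", call. = FALSE)
  structure(list(G = G, M = mortality, V = growth_variance,
                 R = recruitment, growth = growth),
            class = "demographic_rates")
}

#' Steady-state size distribution of the demographic balance equation
#'
#' Solves the steady state of the size-structured balance
#' \deqn{\tfrac12 (V N)'' - (G N)' - M N + \text{recruitment at } D_{min} = 0.}
#' With deterministic growth (`V` absent) the first-order balance
#' `(G N)' = -M N` integrates in closed form,
#' `N(D) = C/G(D) * exp(-int M/G dD)`; the quadrature is performed in
#' log-diameter (integrand `D M/G`), which is exact for the
#' metabolic-scaling power-law family and accurate on log grids. With
#' `V > 0` the full second-order steady state is solved as a linear system
#' on a finite-volume discretization with recruitment entering as an influx
#' at the smallest cell and free outflow at the largest.
#'
#' For growth `G = g0 D^theta` and mortality `M = mu0 D^(theta-1)` the
#' log-log slope is exactly `-(mu0/g0) - theta`; with the steady-state
#' mortality schedule of [steady_state_mortality()] this is -2 for every
#' `theta < 2`.
#'
#' @param rates a [demographic_rates()] object.
#' @param grid strictly increasing diameter grid (default 400 log-spaced
#'   nodes on `[0.01, 1]`).
#' @param total total stem count to normalize the distribution to.
#' @return object of class `"size_distribution"`: list with `grid`,
#'   `density` (stems per unit diameter), `slope` (OLS slope of `log N` on
#'   `log D`), `slope_se`, `total`, `method`.
#' @export
solve_steady_state_size_distribution <- function(rates,
                                                 grid = exp(seq(log(0.01), log(1), length.out = 400)),
                                                 total = 1) {
  stopifnot(inherits(rates, "demographic_rates"))
  if (is.unsorted(grid, strictly = TRUE))
    stop("`grid` must be strictly increasing", call. = FALSE)
  G <- rates$G(grid)
  if (any(G <= 0)) stop("growth must be positive on the grid", call. = FALSE)
  M <- rates$M(grid)
  if (is.null(rates$V)) {
    # first-order balance, integrated in log-diameter
    integrand <- grid * M / G          # = D M(D) / G(D)
    lD <- log(grid)
    n <- length(grid)
    cumint <- c(0, cumsum((integrand[-1] + integrand[-n]) / 2 * diff(lD)))
    lN <- -log(G) - cumint
    lN <- lN - max(lN)
    N <- exp(lN)
    method <- "analytic"
  } else {
    V <- rates$V(grid)
    if (any(V < 0)) stop("growth variance must be non-negative", call. = FALSE)
    N <- ssd_linear_solve(grid, G, M, V, rates$R)
    method <- "finite-volume"
  }
  Z <- trapz(grid, N)
  N <- N * total / Z
  fit <- stats::lm(log(N) ~ log(grid))
  sm <- suppressWarnings(summary(fit))  # exact power laws fit perfectly
  structure(list(grid = grid, density = N,
                 slope = unname(stats::coef(fit)[2L]),
                 slope_se = sm$coefficients[2L, 2L],
                 total = total, method = method),
            class = "size_distribution")
}

trapz <- function(x, y) sum((y[-1] + y[-length(y)]) / 2 * diff(x))

# steady-state linear solve of 0 = -(GN)' + (1/2)(VN)'' - MN + R at D_min,
# on a (possibly non-uniform) cell-centred grid; upwind advection (G > 0),
# free outflow at the top edge.
ssd_linear_solve <- function(grid, G, M, V, R) {
  n <- length(grid)
  faces <- (grid[-n] + grid[-1]) / 2
  w <- diff(c(grid[1] - (faces[1] - grid[1]), faces,
              grid[n] + (grid[n] - faces[n - 1])))
  L <- matrix(0, n, n)
  Gf <- (G[-n] + G[-1]) / 2
  dxc <- diff(grid)
  for (j in seq_len(n - 1L)) {
    cc <- Gf[j] + V[j] / (2 * dxc[j])        # from cell j through face j
    dd <- V[j + 1L] / (2 * dxc[j])           # from cell j+1 back through face j
    L[j, j] <- L[j, j] - cc / w[j]
    L[j + 1L, j] <- L[j + 1L, j] + cc / w[j + 1L]
    L[j, j + 1L] <- L[j, j + 1L] + dd / w[j]
    L[j + 1L, j + 1L] <- L[j + 1L, j + 1L] - dd / w[j + 1L]
  }
  L[n, n] <- L[n, n] - (G[n] + V[n] / (2 * w[n])) / w[n]   # outflow at top
  diag(L) <- diag(L) - M
  b <- numeric(n)
  b[1] <- -R / w[1]
  N <- solve(L, b)
  pmax(N, 0)
}

#' @export
print.size_distribution <- function(x, ...) {
  cat(sprintf(paste0("Steady-state size distribution (%s): %d nodes on ",
                     "[%.3g, %.3g]\n  log-log slope = %.6f (se %.2g)\n"),
              x$method, length(x$grid), min(x$grid), max(x$grid),
              x$slope, x$slope_se))
  invisible(x)
}

#' Individual-based forest simulator
#'
#' Discrete-time individual-based model of a size-structured assemblage:
#' the size of each tree is a particle drifting to larger diameters at rate
#' `G(D)` (with optional Gaussian growth noise of variance `V(D) dt`),
#' removed by death with probability `1 - exp(-M(D) dt)` per step, and
#' replaced by recruits entering at `D_min`. Within a step, death is applied
#' before growth; recruits enter after growth and start growing the next
#' step.
#'
#' Recruitment policies: `"zero_sum"` replaces every death with one recruit
#' at `D_min` in the same step, so the population fills all available space
#' and the count is constant; `"open"` recruits a Poisson number of
#' individuals per step at rate `recruit_rate`; `"none"` disables
#' recruitment. If the population goes extinct before `t_max` the series is
#' truncated and flagged.
#'
#' @param growth an [mst_growth()] object (or any list with a growth
#'   function `G`).
#' @param mortality mortality function `M(D)`; default is the steady-state
#'   balance schedule of [steady_state_mortality()].
#' @param recruitment one of `"zero_sum"`, `"open"`, `"none"`.
#' @param recruit_rate recruits per unit time for the `"open"` policy.
#' @param growth_variance optional `V(D)` for stochastic growth.
#' @param D_min recruitment diameter (lower size bound).
#' @param n_init initial number of individuals.
#' @param init_sizes optional initial diameters (length `n_init`); default
#'   starts everyone at `D_min`.
#' @param t_max simulation horizon.
#' @param dt time step; default `0.01 / M(D_min)` so the largest per-step
#'   death probability is about 1%.
#' @param record_times times at which to store full diameter snapshots
#'   (default: `t_max` only).
#' @param seed integer seed.
#' @return object of class `"forest_sim"`: list with `sizes` (final
#'   diameters), `snapshots` (list of diameter vectors), `snapshot_times`,
#'   `t_end`, `extinct`, `dt`, `params`.
#' @export
ibm_forest_simulate <- function(growth = mst_growth(),
                                mortality = steady_state_mortality(growth),
                                recruitment = c("zero_sum", "open", "none"),
                                recruit_rate = NULL,
                                growth_variance = NULL,
                                D_min = 0.01, n_init = 5000,
                                init_sizes = NULL,
                                t_max = 3, dt = NULL,
                                record_times = NULL, seed = NULL) {
  recruitment <- match.arg(recruitment)
  if (n_init < 1) stop("`n_init` must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  G <- growth$G
  M <- mortality
  if (is.null(dt)) dt <- 0.01 / M(D_min)
  if (recruitment == "open" && is.null(recruit_rate))
    stop("`recruit_rate` is required for open recruitment", call. = FALSE)

  D <- if (is.null(init_sizes)) rep(D_min, n_init) else as.numeric(init_sizes)
  if (length(D) != n_init)
    stop("`init_sizes` must have length `n_init`", call. = FALSE)
  n_steps <- ceiling(t_max / dt)
  rec_t <- if (is.null(record_times)) t_max else sort(record_times)
  rec_step <- pmin(pmax(round(rec_t / dt), 1L), n_steps)
  snapshots <- vector("list", length(rec_t))
  extinct <- FALSE
  t_end <- t_max

  for (k in seq_len(n_steps)) {
    # death before growth
    dead <- stats::runif(length(D)) < -expm1(-M(D) * dt)
    n_dead <- sum(dead)
    D <- D[!dead]
    if (length(D)) {
      D <- D + G(D) * dt
      if (!is.null(growth_variance))
        D <- pmax(D + stats::rnorm(length(D),
                                   sd = sqrt(growth_variance(D) * dt)),
                  D_min)
    }
    n_rec <- switch(recruitment,
                    zero_sum = n_dead,
                    open = stats::rpois(1, recruit_rate * dt),
                    none = 0L)
    if (n_rec > 0) D <- c(D, rep(D_min, n_rec))
    if (length(D) == 0L) {
      extinct <- TRUE
      t_end <- k * dt
      break
    }
    hit <- which(rec_step == k)
    for (w in hit) snapshots[[w]] <- D
  }
  for (w in which(vapply(snapshots, is.null, logical(1))))
    snapshots[[w]] <- numeric(0)
  structure(list(sizes = D, snapshots = snapshots, snapshot_times = rec_t,
                 t_end = t_end, extinct = extinct, dt = dt,
                 params = list(growth = growth, recruitment = recruitment,
                               D_min = D_min, n_init = n_init,
                               t_max = t_max, seed = seed)),
            class = "forest_sim")
}

#' @export
print.forest_sim <- function(x, ...) {
  cat(sprintf(
    "Individual-based forest: %d stems at t = %.3g (dt = %.3g)%s\n",
    length(x$sizes), x$t_end, x$dt, if (x$extinct) " [extinct]" else ""))
  if (length(x$sizes))
    cat(sprintf("  diameter range [%.4g, %.4g]\n", min(x$sizes), max(x$sizes)))
  invisible(x)
}

#' Log-log slope of a size distribution
#'
#' Estimates the size-spectrum log-log slope either by maximum likelihood
#' (`"mle"`: the truncated-Pareto density exponent of [fit_trunc_pareto()],
#' which equals the log-log slope of the size density) or by ordinary least
#' squares on a log-binned histogram (`"ols"`: logarithmically spaced bins,
#' bins with fewer than `min_count` individuals dropped, regression of log
#' bin density on log bin centre).
#'
#' @param sizes individual sizes (`>= 30` for MLE, enough for `>= 5`
#'   retained bins for OLS), or a `"size_distribution"` object, in which
#'   case the attached OLS slope of the solved density is returned.
#' @param method `"mle"` or `"ols"`.
#' @param n_bins number of log bins for the OLS path.
#' @param min_count minimum individuals for a bin to be retained.
#' @param n_boot,seed bootstrap controls for the MLE confidence interval.
#' @return object of class `"loglog_slope"`: list with `slope`, `ci`
#'   (95%), `method`, `n`.
#' @export
fit_loglog_slope <- function(sizes, method = c("mle", "ols"), n_bins = 12,
                             min_count = 5, n_boot = 200, seed = NULL) {
  if (inherits(sizes, "size_distribution")) {
    return(structure(list(slope = sizes$slope,
                          ci = sizes$slope + c(-2, 2) * sizes$slope_se,
                          method = "solved-density", n = length(sizes$grid)),
                     class = "loglog_slope"))
  }
  method <- match.arg(method)
  sizes <- sizes[!is.na(sizes)]
  if (method == "mle") {
    if (length(sizes) < 30L)
      stop("need at least 30 sizes for the MLE slope", call. = FALSE)
    fit <- fit_trunc_pareto(sizes, n_boot = n_boot, seed = seed)
    ci <- if (!is.null(fit$ci)) fit$ci else fit$lambda + c(-2, 2) * fit$se
    out <- list(slope = fit$lambda, ci = ci, method = "mle",
                n = length(sizes))
  } else {
    breaks <- exp(seq(log(min(sizes)), log(max(sizes)), length.out = n_bins + 1))
    breaks[1] <- breaks[1] * (1 - 1e-12)
    breaks[length(breaks)] <- breaks[length(breaks)] * (1 + 1e-12)
    cnt <- tabulate(findInterval(sizes, breaks, rightmost.closed = TRUE),
                    nbins = n_bins)
    ctr <- sqrt(breaks[-1] * breaks[-(n_bins + 1)])
    dens <- cnt / diff(breaks)
    keep <- cnt >= min_count
    if (sum(keep) < 5L)
      stop("fewer than 5 bins with >= `min_count` individuals; the ",
           "log-binned OLS slope is not identifiable", call. = FALSE)
    fit <- stats::lm(log(dens[keep]) ~ log(ctr[keep]))
    ci <- suppressMessages(stats::confint(fit)[2L, ])
    out <- list(slope = unname(stats::coef(fit)[2L]), ci = unname(ci),
                method = "ols", n = length(sizes))
  }
  structure(out, class = "loglog_slope")
}

#' @export
print.loglog_slope <- function(x, ...) {
  cat(sprintf("Size-spectrum log-log slope (%s): %.4f  [%.4f, %.4f], n = %d\n",
              x$method, x$slope, x$ci[1], x$ci[2], x$n))
  invisible(x)
}
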