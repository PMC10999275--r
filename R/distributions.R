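#' Stationary beta species proportional-abundance density
#'
#' Density of the stationary species proportional-abundance distribution
#' (SAD) arising from symmetric (neutral) birth-death-immigration dynamics
#' in the diffusion limit. For proportional abundance `x = n/J` the
#' stationary density is
#' \deqn{\rho_\infty(x) = \frac{\Gamma(\alpha+\beta)}{\Gamma(\alpha)\Gamma(\beta)}
#'   x^{\alpha-1}(1-x)^{\beta-1},}
#' a beta density whose shape parameters reflect the relative importance of
#' immigration (`alpha`) and local extinction/speciation (`beta_shape`)
#' against demographic stochasticity. When either shape parameter equals 1
#' the log-density is exactly linear in `log(x)` (resp. `log(1-x)`), i.e.
#' the SAD degenerates to a single power law.
#'
#' @param x proportional abundances, strictly inside (0, 1).
#' @param alpha positive shape parameter (immigration-related).
#' @param beta_shape positive shape parameter (extinction-related).
#' @param log logical; return log-density?
#' @return numeric vector of (log-)densities.
#' @seealso [fit_beta_sad()], [beta_sad_loglinearity()]
#' @examples
#' dbeta_sad(0.5, 1, 1)        # uniform special case
#' dbeta_sad(1e-9, 1, 2)       # -> 2 in the x -> 0 limit
#' @export
dbeta_sad <- function(x, alpha, beta_shape, log = FALSE) {
  check_shapes(alpha, beta_shape)
  if (any(x <= 0 | x >= 1))
    stop("`x` must lie strictly inside (0, 1)", call. = FALSE)
  stats::dbeta(x, shape1 = alpha, shape2 = beta_shape, log = log)
}

check_shapes <- function(alpha, beta_shape) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) || alpha <= 0)
    stop("`alpha` must be a single positive number", call. = FALSE)
  if (!is.numeric(beta_shape) || length(beta_shape) != 1L ||
      !is.finite(beta_shape) || beta_shape <= 0)
    stop("`beta_shape` must be a single positive number", call. = FALSE)
  invisible(TRUE)
}

#' Log-linearity diagnostic for the beta SAD power-law special case
#'
#' Evaluates the beta SAD log-density on a grid and regresses it on
#' `log(x)` and on `log(1 - x)`. With `alpha = 1` the regression on
#' `log(1 - x)` is exact (R-squared 1 to machine precision); with
#' `beta_shape = 1` the regression on `log(x)` is exact; with both shapes
#' away from 1 no single power law is exact.
#'
#' @inheritParams dbeta_sad
#' @param n grid size (equispaced interior points of (0, 1)).
#' @return list with components `r2_logx`, `r2_log1mx` (R-squared of the two
#'   regressions), `slope_logx`, `slope_log1mx`, and `power_law` (logical:
#'   is either regression exact to 1e-10?).
#' @export
beta_sad_loglinearity <- function(alpha, beta_shape, n = 200) {
  x <- seq(1 / (n + 1), n / (n + 1), length.out = n)
  ld <- dbeta_sad(x, alpha, beta_shape, log = TRUE)
  f1 <- stats::lm(ld ~ log(x))
  f2 <- stats::lm(ld ~ log1p(-x))
  # the power-law special cases fit exactly; silence the perfect-fit note
  r2 <- function(f) suppressWarnings(summary(f))$r.squared
  out <- list(r2_logx = r2(f1), r2_log1mx = r2(f2),
              slope_logx = unname(stats::coef(f1)[2L]),
              slope_log1mx = unname(stats::coef(f2)[2L]))
  out$power_law <- (1 - out$r2_logx) < 1e-10 || (1 - out$r2_log1mx) < 1e-10
  out
}

#' Fit the beta SAD by maximum likelihood
#'
#' Maximum-likelihood estimation of the shape parameters of the stationary
#' beta proportional-abundance distribution from observed species
#' proportional abundances. Estimation is delegated to
#' [fitdistrplus::fitdist()]; standard errors come from the observed
#' information.
#'
#' Values at exactly 0 or 1 are outside the support of the beta family and
#' are rejected. Observed boundary proportions (a species absent from, or
#' monopolising, a census) should be nudged inward first: with
#' `nudge = TRUE` and total community size `J`, 0 and 1 are replaced by
#' `1/(2J)` and `1 - 1/(2J)`, the usual proportional-data convention.
#'
#' @param x species proportional abundances in (0, 1); at least 10 values.
#' @param nudge logical; apply the boundary nudge to values at exactly 0/1.
#' @param J total community size; required when `nudge = TRUE`.
#' @return object of class `"beta_sad_fit"`: a list with `alpha`,
#'   `beta_shape`, `se` (named standard errors), `logLik`, `n`.
#' @examples
#' set.seed(1)
#' fit_beta_sad(rbeta(500, 2, 5))
#' @export
fit_beta_sad <- function(x, nudge = FALSE, J = NULL) {
  if (!is.numeric(x)) stop("`x` must be numeric", call. = FALSE)
  x <- x[!is.na(x)]
  if (nudge) {
    if (is.null(J) || J <= 0)
      stop("`J` (total community size) is required for the boundary nudge",
           call. = FALSE)
    x[x == 0] <- 1 / (2 * J)
    x[x == 1] <- 1 - 1 / (2 * J)
  }
  if (any(x <= 0 | x >= 1))
    stop("proportional abundances at exactly 0 or 1 are outside the beta ",
         "support; re-run with `nudge = TRUE` and the community size `J` ",
         "to apply the 1/(2J) boundary nudge", call. = FALSE)
  if (length(x) < 10L)
    stop("need at least 10 proportional abundances to fit the beta SAD",
         call. = FALSE)
  # optimizer excursions outside the parameter space trigger harmless
  # dbeta warnings; inputs are validated above
  fd <- suppressWarnings(
    fitdistrplus::fitdist(as.numeric(x), "beta", method = "mle"))
  est <- stats::coef(fd)
  se <- fd$sd
  if (is.null(se)) se <- c(shape1 = NA_real_, shape2 = NA_real_)
  structure(list(alpha = unname(est["shape1"]),
                 beta_shape = unname(est["shape2"]),
                 se = c(alpha = unname(se["shape1"]),
                        beta_shape = unname(se["shape2"])),
                 logLik = fd$loglik, n = length(x)),
            class = "beta_sad_fit")
}

#' @export
print.beta_sad_fit <- function(x, ...) {
  cat("Beta species proportional-abundance distribution (MLE)\n")
  cat(sprintf("  alpha = %.4f (se %.4f), beta = %.4f (se %.4f)\n",
              x$alpha, x$se["alpha"], x$beta_shape, x$se["beta_shape"]))
  cat(sprintf("  n = %d species, log-likelihood = %.2f\n", x$n, x$logLik))
  invisible(x)
}

#' @export
coef.beta_sad_fit <- function(object, ...) {
  c(alpha = object$alpha, beta = object$beta_shape)
}

#' @export
logLik.beta_sad_fit <- function(object, ...) {
  structure(object$logLik, df = 2L, nobs = object$n, class = "logLik")
}

# stable (m_max^s - m0^s)/s with s = lambda + 1; -> log(mmax/m0) as s -> 0
trunc_pareto_norm <- function(lam, m0, mmax) {
  s <- lam + 1
  L <- log(mmax / m0)
  if (abs(s) < 1e-12) return(L)
  m0^s * expm1(s * L) / s
}

#' Pareto and truncated Pareto size-spectrum distributions
#'
#' Density, distribution function, quantile function and random generation
#' for the individual size spectrum. The truncated Pareto density on
#' `[m0, mmax]` is
#' \deqn{f(m) = \frac{\lambda+1}{m_{max}^{\lambda+1} - m_0^{\lambda+1}}\, m^{\lambda},}
#' with the logarithmic limit \eqn{1/(m \log(m_{max}/m_0))} at
#' \eqn{\lambda = -1}. The plain Pareto (`dpareto`) is the `mmax -> Inf`
#' limit and requires `lambda < -1`. `lambda` is the density exponent
#' (negative for inverse-J size spectra; approximately -2 for assemblages at
#' demographic/resource steady state when size is stem diameter); see
#' [slope_magnitude()] for conversion to the positive "slope magnitude"
#' convention.
#'
#' Sizes outside `[m0, mmax]` have density 0 by convention (rather than
#' raising an error), so empirical samples with stray values can be scored
#' directly.
#'
#' @param m,q sizes (mass or diameter; units are the caller's).
#' @param p probabilities.
#' @param n number of draws.
#' @param lambda density exponent (any real; `-1` handled by its limit).
#' @param m0 minimum size, `> 0`.
#' @param mmax maximum size, `> m0`.
#' @param log,lower.tail usual distribution-function switches.
#' @return numeric vector.
#' @name trunc_pareto
#' @export
dtrunc_pareto <- function(m, lambda, m0, mmax, log = FALSE) {
  check_tp(lambda, m0, mmax)
  ld <- lambda * base::log(m) - base::log(trunc_pareto_norm(lambda, m0, mmax))
  ld[m < m0 | m > mmax] <- -Inf
  if (log) ld else exp(ld)
}

check_tp <- function(lambda, m0, mmax) {
  if (!is.finite(lambda)) stop("`lambda` must be finite", call. = FALSE)
  if (!is.finite(m0) || m0 <= 0) stop("`m0` must be positive", call. = FALSE)
  if (!is.finite(mmax) || m0 >= mmax)
    stop("need 0 < m0 < mmax", call. = FALSE)
  invisible(TRUE)
}

#' @rdname trunc_pareto
#' @export
ptrunc_pareto <- function(q, lambda, m0, mmax, lower.tail = TRUE) {
  check_tp(lambda, m0, mmax)
  s <- lambda + 1
  q <- pmin(pmax(q, m0), mmax)
  p <- if (abs(s) < 1e-12) {
    log(q / m0) / log(mmax / m0)
  } else {
    expm1(s * log(q / m0)) / expm1(s * log(mmax / m0))
  }
  if (lower.tail) p else 1 - p
}

#' @rdname trunc_pareto
#' @export
qtrunc_pareto <- function(p, lambda, m0, mmax) {
  check_tp(lambda, m0, mmax)
  if (any(p < 0 | p > 1)) stop("`p` must be in [0, 1]", call. = FALSE)
  s <- lambda + 1
  if (abs(s) < 1e-12) {
    m0 * exp(p * log(mmax / m0))
  } else {
    m0 * exp(log1p(p * expm1(s * log(mmax / m0))) / s)
  }
}

#' @rdname trunc_pareto
#' @export
rtrunc_pareto <- function(n, lambda, m0, mmax) {
  qtrunc_pareto(stats::runif(n), lambda, m0, mmax)
}

#' @rdname trunc_pareto
#' @export
dpareto <- function(m, lambda, m0, log = FALSE) {
  if (lambda >= -1)
    stop("plain Pareto needs `lambda` < -1 to be normalizable; ",
         "use the truncated form otherwise", call. = FALSE)
  if (m0 <= 0) stop("`m0` must be positive", call. = FALSE)
  # f(m) = -(lambda+1) m0^{-(lambda+1)} m^lambda
  ld <- log(-(lambda + 1)) - (lambda + 1) * log(m0) + lambda * base::log(m)
  ld[m < m0] <- -Inf
  if (log) ld else exp(ld)
}

#' Convert between density exponent and slope magnitude
#'
#' Size-spectrum exponents are quoted in two sign conventions: the density
#' exponent `lambda` (negative, the log-log slope of the size density) and
#' its positive magnitude. These helpers convert between them.
#'
#' @param lambda density exponent (typically negative).
#' @param magnitude positive slope magnitude.
#' @return the value in the other convention.
#' @export
slope_magnitude <- function(lambda) -lambda

#' @rdname slope_magnitude
#' @export
density_exponent <- function(magnitude) -magnitude

# profile log-likelihood in lambda with plug-in endpoints
tp_loglik <- function(lambda, logm, m0, mmax) {
  length(logm) * (-log(trunc_pareto_norm(lambda, m0, mmax))) +
    lambda * sum(logm)
}

#' Fit a truncated Pareto size spectrum by maximum likelihood
#'
#' Estimates the size-spectrum density exponent `lambda` by one-dimensional
#' maximum likelihood on `[-6, 2]`, with the endpoints fixed at the sample
#' minimum and maximum (plug-in convention: `m0 = min(sizes)`,
#' `mmax = max(sizes)`). A percentile bootstrap confidence interval for
#' `lambda` is attached, and an asymptotic standard error from the observed
#' information (numeric second derivative of the profile log-likelihood).
#'
#' @param sizes positive individual sizes; at least 30.
#' @param n_boot bootstrap replicates for the CI (0 disables the bootstrap).
#' @param seed integer seed for the bootstrap resampling.
#' @param conf confidence level.
#' @return object of class `"trunc_pareto_fit"`: list with `lambda`, `m0`,
#'   `mmax`, `se`, `ci` (length-2 or `NULL`), `logLik`, `n`.
#' @examples
#' set.seed(7)
#' fit_trunc_pareto(rtrunc_pareto(500, -2, 1, 100), n_boot = 50, seed = 1)
#' @export
fit_trunc_pareto <- function(sizes, n_boot = 200, seed = NULL, conf = 0.95) {
  sizes <- as.numeric(sizes[!is.na(sizes)])
  if (any(sizes <= 0)) stop("sizes must be positive", call. = FALSE)
  if (length(sizes) < 30L)
    stop("need at least 30 sizes to fit the truncated Pareto", call. = FALSE)
  m0 <- min(sizes); mmax <- max(sizes)
  if (m0 == mmax)
    stop("degenerate sample: all sizes identical", call. = FALSE)
  lam_hat <- tp_mle(sizes, m0, mmax)
  logm <- base::log(sizes)
  ll <- tp_loglik(lam_hat, logm, m0, mmax)
  # observed information by central difference
  h <- 1e-4
  d2 <- (tp_loglik(lam_hat + h, logm, m0, mmax) - 2 * ll +
           tp_loglik(lam_hat - h, logm, m0, mmax)) / h^2
  se <- if (is.finite(d2) && d2 < 0) sqrt(-1 / d2) else NA_real_
  ci <- NULL
  if (n_boot > 0) {
    if (!is.null(seed)) set.seed(seed)
    lam_b <- vapply(seq_len(n_boot), function(b) {
      s <- sample(sizes, replace = TRUE)
      tp_mle(s, min(s), max(s))
    }, numeric(1))
    a <- (1 - conf) / 2
    ci <- unname(stats::quantile(lam_b, c(a, 1 - a)))
  }
  structure(list(lambda = lam_hat, m0 = m0, mmax = mmax, se = se, ci = ci,
                 conf = conf, logLik = ll, n = length(sizes)),
            class = "trunc_pareto_fit")
}

tp_mle <- function(sizes, m0, mmax) {
  logm <- base::log(sizes)
  stats::optimize(tp_loglik, interval = c(-6, 2), logm = logm,
                  m0 = m0, mmax = mmax, maximum = TRUE,
                  tol = 1e-8)$maximum
}

#' @export
print.trunc_pareto_fit <- function(x, ...) {
  cat("Truncated Pareto size spectrum (MLE, plug-in endpoints)\n")
  cat(sprintf("  lambda = %.4f (se %.4f), m0 = %g, mmax = %g, n = %d\n",
              x$lambda, x$se, x$m0, x$mmax, x$n))
  if (!is.null(x$ci))
    cat(sprintf("  %g%% bootstrap CI for lambda: [%.4f, %.4f]\n",
                100 * x$conf, x$ci[1], x$ci[2]))
  invisible(x)
}

#' @export
coef.trunc_pareto_fit <- function(object, ...) {
  c(lambda = object$lambda, m0 = object$m0, mmax = object$mmax)
}

#' @export
confint.trunc_pareto_fit <- function(object, parm = "lambda", level = NULL, ...) {
  if (is.null(object$ci))
    stop("no bootstrap CI stored; refit with `n_boot` > 0", call. = FALSE)
  matrix(object$ci, nrow = 1,
         dimnames = list("lambda",
                         paste0(100 * c((1 - object$conf) / 2,
                                        1 - (1 - object$conf) / 2), "%")))
}

#' @export
logLik.trunc_pareto_fit <- function(object, ...) {
  structure(object$logLik, df = 1L, nobs = object$n, class = "logLik")
}

#' Fit the density-mass scaling relationship N = a M^-b
#'
#' Ordinary least squares of `log(N)` on `log(M)` across species. The
#' exponent is reported as the positive `b` of the inverse relationship
#' `N = a M^-b` (Damuth's rule / energetic-equivalence form), so a fitted
#' OLS slope of -0.75 is returned as `b = 0.75`.
#'
#' @param mass per-species mean body masses, positive.
#' @param abundance per-species population densities/counts, positive.
#' @return object of class `"density_mass_fit"`: list with `a`, `b`,
#'   `se_b`, `r_squared`, `n`, and the underlying `lm` fit.
#' @export
fit_density_mass_scaling <- function(mass, abundance) {
  if (length(mass) != length(abundance))
    stop("`mass` and `abundance` must have equal length", call. = FALSE)
  if (length(mass) < 3L) stop("need at least 3 species", call. = FALSE)
  if (any(mass <= 0) || any(abundance <= 0))
    stop("`mass` and `abundance` must be strictly positive", call. = FALSE)
  fit <- stats::lm(log(abundance) ~ log(mass))
  sm <- suppressWarnings(summary(fit))  # exact power laws fit perfectly
  structure(list(a = unname(exp(stats::coef(fit)[1L])),
                 b = unname(-stats::coef(fit)[2L]),
                 se_b = unname(sm$coefficients[2L, 2L]),
                 r_squared = sm$r.squared,
                 n = length(mass), fit = fit),
            class = "density_mass_fit")
}

#' @export
print.density_mass_fit <- function(x, ...) {
  cat("Density-mass scaling  N = a * M^-b  (OLS on logs)\n")
  cat(sprintf("  a = %.4g, b = %.4f (se %.4f), R^2 = %.4f, n = %d\n",
              x$a, x$b, x$se_b, x$r_squared, x$n))
  invisible(x)
}

#' @export
coef.density_mass_fit <- function(object, ...) c(a = object$a, b = object$b)
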