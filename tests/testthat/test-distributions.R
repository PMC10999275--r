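test_that("beta SAD density matches its closed form and special cases", {
  # uniform special case
  expect_equal(dbeta_sad(0.5, 1, 1), 1)
  # x -> 0 limit of Beta(1, 2): Gamma(3)/(Gamma(1)Gamma(2)) = 2
  expect_equal(dbeta_sad(1e-12, 1, 2), 2, tolerance = 1e-9)
  # closed form at a generic point
  a <- 2.3; b <- 4.1; x <- 0.37
  expect_equal(dbeta_sad(x, a, b),
               gamma(a + b) / (gamma(a) * gamma(b)) *
                 x^(a - 1) * (1 - x)^(b - 1))
  # domain and parameter errors
  expect_error(dbeta_sad(0, 1, 2), "inside")
  expect_error(dbeta_sad(1, 1, 2), "inside")
  expect_error(dbeta_sad(0.5, -1, 2), "positive")
  # normalization
  for (p in list(c(1, 1), c(2, 5), c(0.5, 3))) {
    q <- stats::integrate(dbeta_sad, 0 + 1e-12, 1 - 1e-12,
                          alpha = p[1], beta_shape = p[2],
                          rel.tol = 1e-8)
    expect_equal(q$value, 1, tolerance = 1e-6)
  }
})

test_that("beta SAD is exactly log-linear iff a shape parameter equals 1", {
  r <- beta_sad_loglinearity(1, 3)
  expect_lt(1 - r$r2_log1mx, 1e-10)
  expect_equal(r$slope_log1mx, 2)  # beta_shape - 1
  r2 <- beta_sad_loglinearity(3, 1)
  expect_lt(1 - r2$r2_logx, 1e-10)
  expect_equal(r2$slope_logx, 2)
  # both shapes away from 1: no single power law is exact
  r3 <- beta_sad_loglinearity(2, 5)
  expect_lt(r3$r2_logx, 1)
  expect_lt(r3$r2_log1mx, 1)
  expect_false(r3$power_law)
})

test_that("beta SAD MLE recovers generating shapes and is order-invariant", {
  set.seed(41)
  x <- rbeta(1e4, 2, 5)
  fit <- fit_beta_sad(x)
  expect_lt(abs(fit$alpha - 2), 3 * fit$se["alpha"])
  expect_lt(abs(fit$beta_shape - 5), 3 * fit$se["beta_shape"])
  # permutation invariance
  fit2 <- fit_beta_sad(sample(x))
  expect_identical(coef(fit), coef(fit2))
  # symmetry: sample symmetric under x -> 1-x gives alpha ~ beta
  xs <- c(x, 1 - x)
  fs <- fit_beta_sad(xs)
  expect_lt(abs(fs$alpha - fs$beta_shape),
            3 * sqrt(fs$se["alpha"]^2 + fs$se["beta_shape"]^2))
  # boundary values rejected with nudge instructions; nudge fixes them
  expect_error(fit_beta_sad(c(x[1:20], 0)), "nudge")
  expect_silent(fit_beta_sad(c(x[1:20], 0, 1), nudge = TRUE, J = 100))
  expect_error(fit_beta_sad(x[1:5]), "at least 10")
})

test_that("truncated Pareto density, cdf and quantiles are consistent", {
  # direct substitution: (lambda+1)/(mmax^(l+1)-m0^(l+1)) m^lambda
  expect_equal(dtrunc_pareto(1, -2, 1, 10), 1 / 0.9, tolerance = 1e-12)
  # normalization
  q <- stats::integrate(dtrunc_pareto, 1, 10, lambda = -2, m0 = 1, mmax = 10)
  expect_equal(q$value, 1, tolerance = 1e-6)
  q2 <- stats::integrate(dtrunc_pareto, 0.5, 7, lambda = -1, m0 = 0.5,
                         mmax = 7, rel.tol = 1e-9)
  expect_equal(q2$value, 1, tolerance = 1e-6)
  # continuity in lambda across the logarithmic limit at -1
  for (m in c(0.7, 2, 5)) {
    expect_equal(dtrunc_pareto(m, -1, 0.5, 7),
                 dtrunc_pareto(m, -1 + 1e-7, 0.5, 7), tolerance = 1e-6)
    expect_equal(dtrunc_pareto(m, -1, 0.5, 7),
                 dtrunc_pareto(m, -1 - 1e-7, 0.5, 7), tolerance = 1e-6)
  }
  # mmax -> Inf limit approaches the plain Pareto
  expect_equal(dtrunc_pareto(2, -2, 1, 1e6), dpareto(2, -2, 1),
               tolerance = 1e-4)
  # support convention and parameter validation
  expect_identical(dtrunc_pareto(c(0.5, 11), -2, 1, 10), c(0, 0))
  expect_error(dtrunc_pareto(1, -2, 5, 1), "m0 < mmax")
  expect_error(dpareto(1, -0.5, 1), "lambda")
  # quantile/cdf round trip incl. the lambda = -1 limit
  for (lam in c(-2.5, -1, 0.5)) {
    p <- c(0.01, 0.3, 0.77, 0.99)
    expect_equal(ptrunc_pareto(qtrunc_pareto(p, lam, 1, 100), lam, 1, 100),
                 p, tolerance = 1e-10)
  }
})

test_that("truncated Pareto MLE recovers the exponent with plug-in endpoints", {
  set.seed(5)
  s <- rtrunc_pareto(5e3, -2, 1, 100)
  fit <- fit_trunc_pareto(s, n_boot = 200, seed = 1)
  expect_gt(fit$lambda, -2.15)
  expect_lt(fit$lambda, -1.85)
  expect_identical(fit$m0, min(s))
  expect_identical(fit$mmax, max(s))
  # bootstrap CI brackets the point estimate and has sane width
  expect_lt(fit$ci[1], fit$lambda)
  expect_gt(fit$ci[2], fit$lambda)
  expect_lt(diff(fit$ci), 0.3)
  # deleting individuals below the median shallows the fitted exponent
  fit_cut <- fit_trunc_pareto(s[s >= stats::median(s)], n_boot = 0)
  expect_gt(fit_cut$lambda, fit$lambda)
  expect_error(fit_trunc_pareto(rep(2, 50)), "degenerate")
  expect_error(fit_trunc_pareto(s[1:10]), "at least 30")
})

test_that("sampling + fitting round trip recovers parameters within 3 SE", {
  # truncated Pareto family
  set.seed(11)
  ok_tp <- vapply(1:100, function(r) {
    s <- rtrunc_pareto(1e4, -2, 1, 100)
    f <- fit_trunc_pareto(s, n_boot = 0)
    abs(f$lambda + 2) < 3 * f$se
  }, logical(1))
  expect_gte(mean(ok_tp), 0.95)
  # beta family
  set.seed(12)
  ok_b <- vapply(1:100, function(r) {
    f <- fit_beta_sad(rbeta(1e4, 2, 5))
    abs(f$alpha - 2) < 3 * f$se["alpha"] &&
      abs(f$beta_shape - 5) < 3 * f$se["beta_shape"]
  }, logical(1))
  expect_gte(mean(ok_b), 0.95)
})

test_that("density-mass scaling fit recovers N = a M^-b", {
  M <- c(1, 10, 100)
  fit <- fit_density_mass_scaling(M, 10 * M^-0.75)
  expect_equal(fit$a, 10, tolerance = 1e-10)
  expect_equal(fit$b, 0.75, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  # changing mass units rescales a by 1000^b but leaves b unchanged
  fit2 <- fit_density_mass_scaling(M * 1000, 10 * M^-0.75)
  expect_equal(fit2$b, fit$b, tolerance = 1e-10)
  expect_equal(fit2$a, fit$a * 1000^fit$b, tolerance = 1e-8)
  # recovery under lognormal noise
  set.seed(21)
  M3 <- exp(runif(50, 0, 6))
  N3 <- 5 * M3^-0.75 * exp(rnorm(50, 0, 0.2))
  fit3 <- fit_density_mass_scaling(M3, N3)
  expect_lt(abs(fit3$b - 0.75), 2 * fit3$se_b)
  expect_error(fit_density_mass_scaling(c(1, -1, 2), c(1, 2, 3)), "positive")
  expect_error(fit_density_mass_scaling(1:2, 1:2), "at least 3")
})

test_that("exponent sign-convention helpers invert each other", {
  expect_equal(slope_magnitude(-2), 2)
  expect_equal(density_exponent(slope_magnitude(-1.7)), -1.7)
})
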