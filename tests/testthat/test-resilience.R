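test_that("pulse perturbations act on the targeted size range only", {
  set.seed(61)
  s <- rtrunc_pareto(2000, -2, 1, 100)
  # zero intensity is the identity
  expect_identical(
    apply_perturbation(s, perturbation("proportional_thinning", 0), seed = 1),
    s)
  # removing everything above the median leaves max <= median
  med <- stats::median(s)
  out <- apply_perturbation(s, perturbation("remove_large", 1, med), seed = 1)
  expect_lte(max(out), med)
  expect_true(all(out %in% s))
  # total removal is refused
  expect_error(
    apply_perturbation(s, perturbation("proportional_thinning", 1), seed = 1),
    "entire population")
  expect_error(perturbation("remove_small", 0.5), "threshold")
  expect_error(perturbation("remove_small", 1.5, 1), "intensity")
})

test_that("removing small individuals shallows the fitted exponent", {
  # scenario (b): the refitted lambda rises (shallows) relative to baseline
  set.seed(62)
  shallower <- vapply(1:100, function(r) {
    s <- rtrunc_pareto(3000, -2, 1, 100)
    thr <- stats::quantile(s, 0.25)
    pre <- fit_trunc_pareto(s, n_boot = 0)$lambda
    sp <- apply_perturbation(s, perturbation("remove_small", 0.9, thr))
    post <- fit_trunc_pareto(sp, n_boot = 0)$lambda
    post > pre
  }, logical(1))
  expect_gte(mean(shallower), 0.95)
})

test_that("rate_shift returns modified demographic rates for press disturbance", {
  g <- mst_growth()
  rates <- demographic_rates(g, steady_state_mortality(g))
  shifted <- apply_perturbation(
    rates, perturbation("rate_shift", intensity = 2, threshold = 0.1))
  expect_s3_class(shifted, "demographic_rates")
  expect_equal(shifted$M(0.05), 2 * rates$M(0.05))
  expect_equal(shifted$M(0.5), rates$M(0.5))
  expect_error(apply_perturbation(
    1:10, perturbation("rate_shift", 2, 0.1)), "demographic_rates")
})

test_that("baseline deviation metrics are distances with the right extremes", {
  set.seed(63)
  s <- rtrunc_pareto(1000, -2, 1, 100)
  fit <- fit_trunc_pareto(s, n_boot = 0)
  # identity of indiscernibles
  expect_equal(baseline_deviation(fit, fit, "ks"), 0)
  expect_equal(baseline_deviation(fit, fit, "hellinger"), 0)
  expect_equal(baseline_deviation(fit, fit, "param"), 0)
  f2 <- fit; f2$lambda <- -1.5
  # symmetry and boundedness of Hellinger
  expect_equal(baseline_deviation(fit, f2, "hellinger"),
               baseline_deviation(f2, fit, "hellinger"))
  expect_lte(baseline_deviation(fit, f2, "hellinger"), 1)
  expect_gt(baseline_deviation(fit, f2, "ks"), 0)
  bf <- fit_beta_sad(rbeta(100, 2, 5))
  expect_error(baseline_deviation(bf, fit, "param"), "same family")
})

test_that("parametric KS distance matches a brute-force numeric-cdf oracle", {
  f1 <- structure(list(lambda = -2, m0 = 1, mmax = 100),
                  class = "trunc_pareto_fit")
  f2 <- structure(list(lambda = -1.5, m0 = 1, mmax = 100),
                  class = "trunc_pareto_fit")
  # oracle: cdfs by numeric quadrature of the densities on a fine grid
  g <- exp(seq(log(1), log(100), length.out = 200001))
  cdf_num <- function(lam) {
    d <- dtrunc_pareto(g, lam, 1, 100)
    cs <- cumsum(c(0, (d[-1] + d[-length(d)]) / 2 * diff(g)))
    cs / cs[length(cs)]
  }
  oracle <- max(abs(cdf_num(-2) - cdf_num(-1.5)))
  expect_lt(abs(baseline_deviation(f1, f2, "ks") - oracle), 1e-6)
})

test_that("recovery time follows its definition and monotonicity laws", {
  traj <- data.frame(t = 1:8 / 4,
                     deviation = c(0.5, 0.3, 0.08, 0.07, 0.06, 0.09, 0.04,
                                   0.03))
  expect_equal(recovery_time(traj, tolerance = 0.1, persistence = 3), 0.75)
  # already below tolerance at the first sample
  expect_equal(recovery_time(traj, tolerance = 0.6, persistence = 1), 0.25)
  # never qualifying
  expect_identical(recovery_time(traj, tolerance = 0.01), Inf)
  # non-decreasing in persistence, non-increasing in tolerance
  rts_p <- vapply(1:4, function(p) recovery_time(traj, 0.1, p), numeric(1))
  expect_true(all(diff(rts_p) >= 0))
  rts_tol <- vapply(c(0.05, 0.1, 0.4), function(tol)
    recovery_time(traj, tol, 2), numeric(1))
  expect_true(all(diff(rts_tol) <= 0))
  expect_error(recovery_time(traj, tolerance = 0), "positive")
})

test_that("null trajectory fluctuates without trend around the baseline", {
  eq <- equilibrated_forest(n = 1500, seed = 99)
  tr <- track_recovery(eq$sizes, eq$growth, eq$mortality, eq$fit, spec = NULL,
                       horizon = 1.5, interval = 0.25, n_boot = 0, seed = 5)
  s <- tr$series
  # deviations stay modest (all below a loose cap) and show no trend
  expect_lt(max(s$deviation), 0.1)
  fit <- stats::lm(deviation ~ t, data = s)
  ci <- suppressMessages(stats::confint(fit)[2L, ])
  expect_true(ci[1] < 0 && ci[2] > 0)
  expect_error(track_recovery(eq$sizes, eq$growth, eq$mortality, eq$fit,
                              NULL, horizon = 0.1, interval = 0.25),
               "interval")
})

test_that("pulse removal of the largest individuals recovers; a press does not", {
  eq <- equilibrated_forest(n = 1500, seed = 99)
  tol <- calibrate_recovery_tolerance(eq$sizes, eq$growth, eq$mortality,
                                      eq$fit, horizon = 1.5, interval = 0.25,
                                      seeds = 1:3)
  d_spec <- perturbation("remove_large", intensity = 1,
                         threshold = stats::quantile(eq$sizes, 0.9))
  tr_d <- track_recovery(eq$sizes, eq$growth, eq$mortality, eq$fit, d_spec,
                         horizon = 2.5, interval = 0.25, seed = 7)
  expect_lt(recovery_time(tr_d, tol), Inf)
  ci_d <- tr_d$final_fit$ci
  expect_true(ci_d[1] <= -2 && -2 <= ci_d[2])
  c_spec <- perturbation("rate_shift", intensity = 2,
                         threshold = stats::median(eq$sizes))
  tr_c <- track_recovery(eq$sizes, eq$growth, eq$mortality, eq$fit, c_spec,
                         horizon = 2.5, interval = 0.25, seed = 7)
  expect_identical(recovery_time(tr_c, tol), Inf)
  ci_c <- tr_c$final_fit$ci
  expect_true(ci_c[2] < -2 || ci_c[1] > -2)
})
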