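test_that("Gillespie simulation honours absorbing and monotone chains", {
  pure_death <- rate_functions(function(n) 0 * n, function(n) n)
  tr <- gillespie_simulate(pure_death, init = 5, t_max = 100, seed = 1)
  expect_true(tr$absorbed)
  expect_identical(tr$final, 0)
  expect_true(all(diff(tr$events$count) <= 0))
  # identical seed and configuration give bit-identical trajectories
  tr2 <- gillespie_simulate(pure_death, init = 5, t_max = 100, seed = 1)
  expect_identical(tr$events, tr2$events)
  expect_error(gillespie_simulate(pure_death, init = 5, t_max = 0), "positive")
})

test_that("Gillespie Yule mean matches the closed form e^(beta t)", {
  yule <- rate_functions(function(n) n, function(n) 0 * n)
  set.seed(42)
  fin <- vapply(seq_len(2000),
                function(i) gillespie_simulate(yule, 1, 2)$final, numeric(1))
  se <- stats::sd(fin) / sqrt(length(fin))
  expect_lt(abs(mean(fin) - exp(2)), 3 * se)
})

test_that("critical linear birth-death chain conserves its mean", {
  bd <- rate_functions(function(n) n, function(n) n)
  set.seed(7)
  fin <- vapply(seq_len(1500),
                function(i) gillespie_simulate(bd, 10, 1)$final, numeric(1))
  se <- stats::sd(fin) / sqrt(length(fin))
  expect_lt(abs(mean(fin) - 10), 3 * se)
})

test_that("master-equation solution matches the closed-form Yule law", {
  # frozen chain
  p0 <- c(0.2, 0.5, 0.3, 0, 0)
  out <- solve_master_equation(p0, birth_rate = 0, t = 7)
  expect_identical(out$probs, p0)
  # Yule law p_n(t) = e^-bt (1 - e^-bt)^(n-1), started from n0 = 1
  p0 <- c(0, 1, rep(0, 398))
  out <- solve_master_equation(p0, birth_rate = 1, t = 1)
  yule <- exp(-1) * (1 - exp(-1))^(0:19)
  expect_lt(max(abs(out$probs[2:21] - yule)), 1e-6)
  # probability conserved; mean follows the first-moment equation
  expect_lt(abs(sum(out$probs) - 1), 1e-9)
  expect_lt(abs(sum(out$n * out$probs) - exp(1)), 1e-6)
  # truncation-mass guard
  expect_error(solve_master_equation(c(0, 1, rep(0, 3)), 1, 3), "n_max")
})

test_that("Gillespie and master-equation Yule distributions agree", {
  yule <- rate_functions(function(n) n, function(n) 0 * n)
  set.seed(99)
  fin <- vapply(seq_len(5000),
                function(i) gillespie_simulate(yule, 1, 1)$final, numeric(1))
  me <- solve_master_equation(c(0, 1, rep(0, 98)), 1, 1)
  k <- 8  # bins 1..k plus pooled tail
  obs <- c(tabulate(fin[fin <= k], nbins = k), sum(fin > k))
  pr <- c(me$probs[2:(k + 1)], 1 - sum(me$probs[2:(k + 1)]))
  chi <- suppressWarnings(stats::chisq.test(obs, p = pr))
  expect_gt(chi$p.value, 0.01)
})

test_that("rescaled rates converge to their diffusion limit as J grows", {
  mk <- function(extra) function(J) rate_functions(
    birth = function(n) n * (J - n) / J^2 + extra / J,
    death = function(n) 0 * n,
    rescaled_birth = function(x) x * (1 - x),
    rescaled_death = function(x) 0 * x)
  # per-J rate maps: gap 0 for the exactly rescaled family
  g0 <- do.call(rbind, lapply(c(100, 200, 400), function(J)
    diffusion_limit_check(mk(0)(J), J)))
  expect_equal(g0$gap_birth, c(0, 0, 0), tolerance = 1e-12)
  # constructed 1/J perturbation halves as J doubles
  g1 <- do.call(rbind, lapply(c(100, 200, 400), function(J)
    diffusion_limit_check(mk(1)(J), J)))
  expect_equal(g1$gap_birth, 1 / c(100, 200, 400), tolerance = 1e-10)
  expect_true(all(diff(g1$gap_birth) <= 0))
  expect_error(diffusion_limit_check(
    rate_functions(function(n) n, function(n) n), 100), "rescaled")
})

test_that("neutral zero-sum community conserves J and is seed-reproducible", {
  sim <- simulate_neutral_community(J = 60, S_meta = 6, m = 0.2,
                                    burn_in_gen = 2, n_samples = 3,
                                    sample_every_gen = 2, seed = 3,
                                    record_events = TRUE)
  expect_true(all(rowSums(sim$events) == 60))
  expect_true(all(sim$events >= 0))
  sim2 <- simulate_neutral_community(J = 60, S_meta = 6, m = 0.2,
                                     burn_in_gen = 2, n_samples = 3,
                                     sample_every_gen = 2, seed = 3)
  expect_identical(sim$samples, sim2$samples)
  expect_error(simulate_neutral_community(m = 0), "in \\(0, 1\\)")
})

test_that("KS stationarity test is self-consistent on direct beta samples", {
  set.seed(8)
  x <- rbeta(400, 5, 45)
  res <- stationary_abundance_test(x, 5, 45, seed = 9)
  expect_lt(res$statistic, res$crit)
  expect_gt(res$p.value, 0.05)
  # distance shrinks with sample size
  x2 <- rbeta(5000, 5, 45)
  res2 <- stationary_abundance_test(x2, 5, 45, seed = 9)
  expect_lt(res2$statistic, res$statistic)
  expect_error(stationary_abundance_test(x[1:50], 5, 45), "at least 200")
})

test_that("rank-abundance curve is deterministic, normalized and ordered", {
  ra <- rank_abundance(c(a = 5, b = 3, c = 2))
  expect_equal(ra$relative_abundance, c(0.5, 0.3, 0.2))
  expect_equal(ra$rank, 1:3)
  # permutation invariance
  ra2 <- rank_abundance(c(c = 2, a = 5, b = 3))
  expect_equal(ra, ra2)
  # ties broken lexicographically by species label
  rt <- rank_abundance(c(z = 2, a = 2))
  expect_equal(rt$species, c("a", "z"))
  # removing the top species: new top share >= old rank-2 share
  cnt <- c(a = 10, b = 4, c = 3, d = 1)
  ra3 <- rank_abundance(cnt[names(cnt) != "a"])
  expect_gte(ra3$relative_abundance[1], rank_abundance(cnt)$relative_abundance[2])
  expect_error(rank_abundance(c(0, 0)), "zero")
})

test_that("Bray-Curtis wrapper matches the definition", {
  x <- c(5, 0, 3); y <- c(2, 2, 3)
  expect_equal(bray_curtis(x, y), 1 - 2 * sum(pmin(x, y)) / (sum(x) + sum(y)))
  expect_equal(bray_curtis(x, x), 0)
})
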