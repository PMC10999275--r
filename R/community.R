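#' Birth-death rate functions for a focal community
#'
#' Bundles the per-species birth and death rate maps `B_J(n)`, `D_J(n)` of a
#' continuous-time birth-death chain, the interaction/migration scale `c_J`,
#' and (optionally) the rescaled diffusion-limit rates `b(x)`, `d(x)` on
#' `[0, 1]` used by [diffusion_limit_check()].
#'
#' @param birth vectorized function of the count `n`, returning `B_J(n) >= 0`.
#' @param death vectorized function of the count `n`, returning `D_J(n) >= 0`
#'   with `D_J(0) = 0` unless immigration is modelled as birth at 0.
#' @param c_J interaction/migration scale (free parameter; unused by the
#'   default neutral model).
#' @param rescaled_birth,rescaled_death optional functions of `x` in `[0, 1]`,
#'   the diffusion-limit rates.
#' @return object of class `"rate_functions"`.
#' @export
rate_functions <- function(birth, death, c_J = 0,
                           rescaled_birth = NULL, rescaled_death = NULL) {
  stopifnot(is.function(birth), is.function(death))
  structure(list(birth = birth, death = death, c_J = c_J,
                 rescaled_birth = rescaled_birth,
                 rescaled_death = rescaled_death),
            class = "rate_functions")
}

#' Exact stochastic simulation of a birth-death chain
#'
#' Gillespie (stochastic simulation algorithm) realization of the
#' continuous-time Markov chain with per-species transition probabilities
#' `P(n -> n+1) = B_J(n) h + o(h)` and `P(n -> n-1) = D_J(n) h + o(h)` over
#' a small interval `h`. Species evolve independently under the supplied
#' rate maps; every event is recorded. If the total rate hits zero before
#' `t_max` the trajectory ends early and is flagged absorbed.
#'
#' @param rates a [rate_functions()] object.
#' @param init integer vector of initial per-species counts.
#' @param t_max simulation horizon (model time units), `> 0`.
#' @param seed integer seed; identical seeds give bit-identical trajectories.
#' @param max_events safety cap on the number of events.
#' @return object of class `"bd_trajectory"`: list with `events` (data frame
#'   `t`, `species`, `count` — the post-event count of the species that
#'   moved), `init`, `final` (counts at the end), `t_end`, `absorbed`.
#' @examples
#' yule <- rate_functions(birth = function(n) n, death = function(n) 0 * n)
#' gillespie_simulate(yule, init = 1, t_max = 2, seed = 1)
#' @export
gillespie_simulate <- function(rates, init, t_max, seed = NULL,
                               max_events = 1e6) {
  stopifnot(inherits(rates, "rate_functions"))
  if (t_max <= 0) stop("`t_max` must be positive", call. = FALSE)
  if (any(init < 0)) stop("initial counts must be non-negative", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- as.numeric(init)
  S <- length(n)
  t <- 0
  ev_t <- numeric(0); ev_sp <- integer(0); ev_n <- numeric(0)
  absorbed <- FALSE
  k <- 0L
  repeat {
    b <- rates$birth(n); d <- rates$death(n)
    if (any(b < 0) || any(d < 0) || any(!is.finite(c(b, d))))
      stop("rates must be finite and non-negative on all reachable states",
           call. = FALSE)
    tot <- sum(b) + sum(d)
    if (tot == 0) { absorbed <- TRUE; break }
    t_next <- t + stats::rexp(1, tot)
    if (t_next > t_max) { t <- t_max; break }
    t <- t_next
    u <- stats::runif(1) * tot
    cb <- cumsum(c(b, d))
    j <- findInterval(u, cb) + 1L
    if (j <= S) n[j] <- n[j] + 1 else { j <- j - S; n[j] <- n[j] - 1 }
    k <- k + 1L
    ev_t[k] <- t; ev_sp[k] <- j; ev_n[k] <- n[j]
    if (k >= max_events) {
      warning("`max_events` reached before `t_max`")
      break
    }
  }
  structure(list(events = data.frame(t = ev_t, species = ev_sp, count = ev_n),
                 init = init, final = n, t_end = t, absorbed = absorbed),
            class = "bd_trajectory")
}

#' @export
print.bd_trajectory <- function(x, ...) {
  cat(sprintf("Birth-death trajectory: %d species, %d events, t_end = %.4g%s\n",
              length(x$final), nrow(x$events), x$t_end,
              if (x$absorbed) " (absorbed)" else ""))
  invisible(x)
}

#' Simulate the neutral zero-sum local community with immigration
#'
#' Moran-type neutral (symmetric) dynamics of a local community of fixed
#' size `J` coupled to a metacommunity: at every event one individual,
#' chosen uniformly, dies and is replaced either by an immigrant drawn from
#' the metacommunity relative abundances (probability `m`) or by the
#' offspring of a local individual chosen uniformly (probability `1 - m`).
#' Demographic equivalence of individuals across species makes the chain
#' neutral; the zero-sum constraint keeps `J` exact at every event. One
#' generation is defined as `J` events (each individual replaced once on
#' average). At quasi-stationarity the species proportional abundances
#' `x = n/J` follow the stationary beta distribution that [dbeta_sad()]
#' describes, with shape parameters set by the immigration-to-drift balance
#' (for a uniform metacommunity of `S_meta` species,
#' `alpha = I/S_meta`, `beta = I (1 - 1/S_meta)` with
#' `I = m (J - 1)/(1 - m)`).
#'
#' @param J community size (individuals).
#' @param S_meta number of species in the metacommunity source pool.
#' @param m immigration probability per replacement, in (0, 1).
#' @param meta_p metacommunity relative abundances (length `S_meta`, sums
#'   to 1); uniform by default.
#' @param burn_in_gen burn-in, in generations, before the first sample.
#' @param n_samples number of post-burn-in snapshots to record.
#' @param sample_every_gen spacing between snapshots, in generations. The
#'   default (3/m generations at the default `m`) is about three relaxation
#'   times of the abundance autocorrelation, so successive snapshots are
#'   nearly independent.
#' @param seed integer seed.
#' @param init initial counts (length `S_meta`, summing to `J`); default
#'   splits `J` as evenly as possible.
#' @param record_events record the full per-event count log (memory-heavy;
#'   intended for small runs and invariants testing).
#' @return object of class `"neutral_community_sim"`: list with `samples`
#'   (matrix `n_samples` x `S_meta` of counts), `x` (the same as
#'   proportions of `J`), `times` (generation index of each snapshot),
#'   `final`, `params`, and (optionally) `events`.
#' @export
simulate_neutral_community <- function(J = 500, S_meta = 10, m = 0.1,
                                       meta_p = NULL, burn_in_gen = 50,
                                       n_samples = 25,
                                       sample_every_gen = ceiling(3 / m),
                                       seed = NULL, init = NULL,
                                       record_events = FALSE) {
  if (m <= 0 || m >= 1) stop("`m` must be in (0, 1)", call. = FALSE)
  if (is.null(meta_p)) meta_p <- rep(1 / S_meta, S_meta)
  if (length(meta_p) != S_meta || abs(sum(meta_p) - 1) > 1e-8)
    stop("`meta_p` must have length `S_meta` and sum to 1", call. = FALSE)
  if (is.null(init)) {
    init <- rep(J %/% S_meta, S_meta)
    r <- J - sum(init)
    if (r > 0) init[seq_len(r)] <- init[seq_len(r)] + 1L
  }
  if (sum(init) != J) stop("`init` must sum to `J`", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  sample_at <- as.integer(burn_in_gen * J +
                            seq_len(n_samples) * sample_every_gen * J)
  res <- .moran_chain(as.numeric(init), J, m, cumsum(meta_p), sample_at,
                      record_events)
  samples <- res$samples
  counts <- res$final
  ev <- if (record_events) res$events else NULL
  structure(list(samples = samples, x = samples / J,
                 times = sample_at / J, final = counts,
                 params = list(J = J, S_meta = S_meta, m = m, meta_p = meta_p,
                               burn_in_gen = burn_in_gen,
                               n_samples = n_samples,
                               sample_every_gen = sample_every_gen,
                               seed = seed),
                 events = ev),
            class = "neutral_community_sim")
}

#' @export
print.neutral_community_sim <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "Neutral zero-sum community: J = %d, S_meta = %d, m = %.3g\n",
    p$J, p$S_meta, p$m))
  cat(sprintf("  %d snapshots every %d generations after %d burn-in generations\n",
              p$n_samples, p$sample_every_gen, p$burn_in_gen))
  invisible(x)
}

#' Matched beta shape parameters of the neutral community
#'
#' Diffusion-limit shape parameters of the stationary proportional-abundance
#' beta distribution for the neutral zero-sum model with immigration, for a
#' species with metacommunity relative abundance `p`:
#' `alpha = I p`, `beta = I (1 - p)` with `I = m (J - 1) / (1 - m)`.
#'
#' @param J community size.
#' @param m immigration probability.
#' @param p metacommunity relative abundance of the focal species.
#' @return named numeric vector `c(alpha, beta)`.
#' @export
neutral_beta_shapes <- function(J, m, p) {
  I <- m * (J - 1) / (1 - m)
  c(alpha = I * p, beta = I * (1 - p))
}

#' Solve the pure-birth master equation
#'
#' Numerically integrates the coupled linear system
#' `p_n'(t) = (n-1) beta p_{n-1}(t) - n beta p_n(t)` for a pure-birth (Yule)
#' process, truncated at `n_max = length(p0) - 1`. Integration uses
#' [deSolve::ode()] with tight tolerances so that total probability is
#' conserved to 1e-9. After solving, the mass in the top states is checked:
#' if more than 1e-6 has reached the truncation boundary an error advises a
#' larger `n_max`.
#'
#' @param p0 initial probability vector over counts `0..n_max` (sums to 1).
#' @param birth_rate per-capita birth rate `beta` (1/time).
#' @param t solution time, `>= 0`.
#' @return object of class `"master_equation_state"`: list with `probs`,
#'   `n` (the count grid `0..n_max`), `t`, `birth_rate`.
#' @export
solve_master_equation <- function(p0, birth_rate, t) {
  if (abs(sum(p0) - 1) > 1e-9 || any(p0 < 0))
    stop("`p0` must be a probability vector", call. = FALSE)
  if (birth_rate < 0) stop("`birth_rate` must be >= 0", call. = FALSE)
  n_max <- length(p0) - 1L
  nn <- 0:n_max
  if (birth_rate == 0 || t == 0) {
    return(structure(list(probs = p0, n = nn, t = t, birth_rate = birth_rate),
                     class = "master_equation_state"))
  }
  rhs <- function(time, p, parms) {
    inflow <- c(0, nn[-length(nn)] * p[-length(p)])
    list(parms * (inflow - nn * p))
  }
  sol <- deSolve::ode(y = p0, times = c(0, t), func = rhs, parms = birth_rate,
                      method = "lsoda", rtol = 1e-10, atol = 1e-12)
  p <- pmax(sol[nrow(sol), -1L], 0)
  tail_mass <- sum(p[max(1L, n_max - 2L):length(p)])
  if (tail_mass > 1e-6)
    stop(sprintf(paste0("probability mass %.3g has reached the truncation ",
                        "boundary; increase `n_max` (length of `p0`)"),
                 tail_mass), call. = FALSE)
  structure(list(probs = unname(p), n = nn, t = t, birth_rate = birth_rate),
            class = "master_equation_state")
}

#' @export
print.master_equation_state <- function(x, ...) {
  cat(sprintf("Master-equation state at t = %g (beta = %g): mean count %.4f\n",
              x$t, x$birth_rate, sum(x$n * x$probs)))
  invisible(x)
}

#' Check convergence of rescaled rates to their diffusion limit
#'
#' For community sizes `J` the birth-death rates are rescaled to the unit
#' interval via `x = n/J`; a rate family is diffusion-limit consistent when
#' `b_J(xJ) -> b(x)` and `d_J(xJ) -> d(x)` uniformly as `J -> infinity`.
#' This computes, for each `J`, the sup-norm gap over the lattice
#' `x = n/J, n = 0..J` between the rescaled finite-`J` rates and the
#' supplied limits.
#'
#' @param rates a [rate_functions()] object whose `rescaled_birth` and
#'   `rescaled_death` components hold the limits `b(x)`, `d(x)`.
#' @param J_values increasing vector of community sizes.
#' @return data frame with columns `J`, `gap_birth`, `gap_death`.
#' @export
diffusion_limit_check <- function(rates, J_values) {
  stopifnot(inherits(rates, "rate_functions"))
  if (is.null(rates$rescaled_birth) || is.null(rates$rescaled_death))
    stop("`rates` must carry `rescaled_birth` and `rescaled_death` limits",
         call. = FALSE)
  rows <- lapply(J_values, function(J) {
    n <- 0:J
    x <- n / J
    data.frame(J = J,
               gap_birth = max(abs(rates$birth(n) - rates$rescaled_birth(x))),
               gap_death = max(abs(rates$death(n) - rates$rescaled_death(x))))
  })
  do.call(rbind, rows)
}

# KS statistic of a sample against a cdf evaluated at the sample points
ks_statistic <- function(x, F) {
  n <- length(x)
  Fx <- sort(F)
  i <- seq_len(n)
  max(pmax(abs(i / n - Fx), abs((i - 1) / n - Fx)))
}

#' Goodness of fit of sampled proportional abundances to a beta baseline
#'
#' Kolmogorov-Smirnov distance between empirical proportional abundances
#' `x = n/J` sampled from a community trajectory at quasi-stationarity and a
#' beta baseline, with a parametric-bootstrap p-value and 95% critical
#' value: the null distribution of the KS statistic is simulated by drawing
#' samples of the same size from the baseline beta.
#'
#' @param x proportional abundances (e.g. the pooled post-burn-in snapshots
#'   of [simulate_neutral_community()]); at least 200 observations.
#' @param alpha,beta_shape baseline beta shape parameters.
#' @param n_boot bootstrap replicates.
#' @param seed integer seed for the bootstrap.
#' @return object of class `"ks_gof"`: list with `statistic`, `p.value`,
#'   `crit` (95% bootstrap critical value), `n`, `alpha`, `beta_shape`.
#' @export
stationary_abundance_test <- function(x, alpha, beta_shape, n_boot = 200,
                                      seed = NULL) {
  check_shapes(alpha, beta_shape)
  x <- x[!is.na(x)]
  if (length(x) < 200L)
    stop("need at least 200 proportional-abundance observations ",
         "(sample after burn-in)", call. = FALSE)
  D <- ks_statistic(x, stats::pbeta(sort(x), alpha, beta_shape))
  if (!is.null(seed)) set.seed(seed)
  n <- length(x)
  D0 <- vapply(seq_len(n_boot), function(b) {
    xb <- stats::rbeta(n, alpha, beta_shape)
    ks_statistic(xb, stats::pbeta(sort(xb), alpha, beta_shape))
  }, numeric(1))
  structure(list(statistic = D,
                 p.value = mean(D0 >= D),
                 crit = unname(stats::quantile(D0, 0.95)),
                 n = n, n_boot = n_boot,
                 alpha = alpha, beta_shape = beta_shape),
            class = "ks_gof")
}

#' @export
print.ks_gof <- function(x, ...) {
  cat(sprintf(paste0("KS test vs Beta(%.3g, %.3g): D = %.4f ",
                     "(95%% crit %.4f), bootstrap p = %.3f, n = %d\n"),
              x$alpha, x$beta_shape, x$statistic, x$crit, x$p.value, x$n))
  invisible(x)
}

#' Rank-abundance curve
#'
#' Orders species by decreasing relative abundance. Ties are broken by
#' species label (lexicographic) so the curve is deterministic; species with
#' zero counts are dropped.
#'
#' @param counts non-negative per-species counts, optionally named (unnamed
#'   counts are labelled `sp1`, `sp2`, ... in input order).
#' @return data frame with columns `rank`, `species`, `relative_abundance`
#'   (summing to 1, non-increasing in rank).
#' @export
rank_abundance <- function(counts) {
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (all(counts == 0)) stop("all counts are zero", call. = FALSE)
  if (is.null(names(counts)))
    names(counts) <- sprintf("sp%d", seq_along(counts))
  counts <- counts[counts > 0]
  rel <- counts / sum(counts)
  o <- order(-rel, names(rel))
  data.frame(rank = seq_along(o), species = names(rel)[o],
             relative_abundance = unname(rel[o]))
}

#' Bray-Curtis dissimilarity between two abundance vectors
#'
#' Thin wrapper over [vegan::vegdist()] used as the abundance-side
#' baseline-deviation metric for disturbance-recovery experiments (the
#' rank-abundance curve is not a density, so density metrics do not apply).
#'
#' @param x,y non-negative abundance vectors of equal length (aligned by
#'   species).
#' @return Bray-Curtis dissimilarity in `[0, 1]`.
#' @export
bray_curtis <- function(x, y) {
  if (length(x) != length(y))
    stop("`x` and `y` must be aligned abundance vectors", call. = FALSE)
  as.numeric(vegan::vegdist(rbind(x, y), method = "bray"))
}
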