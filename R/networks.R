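#' Random community interaction matrix
#'
#' Draws an `S x S` community matrix in the random-matrix tradition: each
#' ordered off-diagonal pair interacts independently with probability `C`
#' (the connectance), interaction strengths are zero-mean normal with
#' standard deviation `alpha_strength`, and the diagonal is a uniform
#' self-regulation term (default -1). The complexity parameter
#' `alpha_strength * sqrt(S C)` governs stability: large random communities
#' are almost surely stable below complexity 1 and almost surely unstable
#' above it.
#'
#' @param S number of species, `>= 2`.
#' @param C connectance probability in (0, 1].
#' @param alpha_strength interaction-strength standard deviation, `> 0`.
#' @param self_regulation diagonal entry (default -1).
#' @param seed integer seed.
#' @return `S x S` numeric matrix.
#' @export
random_community_matrix <- function(S, C, alpha_strength,
                                    self_regulation = -1, seed = NULL) {
  if (S < 2) stop("`S` must be >= 2", call. = FALSE)
  if (C <= 0 || C > 1) stop("`C` must be in (0, 1]", call. = FALSE)
  if (alpha_strength < 0) stop("`alpha_strength` must be >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  A <- matrix(0, S, S)
  off <- which(row(A) != col(A))
  link <- stats::runif(length(off)) < C
  A[off[link]] <- stats::rnorm(sum(link), 0, alpha_strength)
  diag(A) <- self_regulation
  A
}

#' Is a community matrix locally stable?
#'
#' A community matrix is locally (asymptotically) stable iff every
#' eigenvalue has strictly negative real part.
#'
#' @param m square numeric matrix.
#' @return logical.
#' @export
is_stable <- function(m) {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stop("`m` must be a square matrix", call. = FALSE)
  all(Re(eigen(m, only.values = TRUE)$values) < 0)
}

#' Monte-Carlo stability probability of random communities
#'
#' Fraction of stable draws among `reps` random community matrices, with an
#' exact (Clopper-Pearson) binomial confidence interval.
#'
#' @inheritParams random_community_matrix
#' @param reps Monte-Carlo replicates, `>= 50`.
#' @param conf confidence level for the binomial CI.
#' @return object of class `"stability_probability"`: list with
#'   `frac_stable`, `ci` (length 2), `complexity`
#'   (`alpha_strength * sqrt(S C)`), `S`, `C`, `alpha_strength`, `reps`.
#' @export
stability_probability <- function(S, C, alpha_strength, reps = 200,
                                  seed = NULL, self_regulation = -1,
                                  conf = 0.95) {
  if (reps < 50) stop("`reps` must be >= 50", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n_stable <- sum(vapply(seq_len(reps), function(r) {
    is_stable(random_community_matrix(S, C, alpha_strength,
                                      self_regulation = self_regulation))
  }, logical(1)))
  ci <- stats::binom.test(n_stable, reps, conf.level = conf)$conf.int
  structure(list(frac_stable = n_stable / reps, ci = as.numeric(ci),
                 complexity = alpha_strength * sqrt(S * C),
                 S = S, C = C, alpha_strength = alpha_strength, reps = reps),
            class = "stability_probability")
}

#' @export
print.stability_probability <- function(x, ...) {
  cat(sprintf(paste0("Random-community stability: S = %d, C = %.3g, ",
                     "alpha = %.3g (complexity %.3g)\n  stable fraction ",
                     "%.3f  [%.3f, %.3f] over %d draws\n"),
              x$S, x$C, x$alpha_strength, x$complexity,
              x$frac_stable, x$ci[1], x$ci[2], x$reps))
  invisible(x)
}

#' Stability under sparse connectance scaling
#'
#' Scans community sizes `S` with connectance `C = c0/S`. Under this sparse
#' scaling the complexity parameter `alpha_strength * sqrt(S C) =
#' alpha_strength * sqrt(c0)` is independent of `S`, so the stability
#' fraction should be statistically constant across sizes — large sparse
#' networks are no less stable than small ones, in contrast to
#' fixed-connectance networks whose stability collapses with size.
#'
#' @param S_values community sizes to scan.
#' @param alpha_strength interaction-strength standard deviation.
#' @param c0 sparse-scaling constant; rows with `c0/S > 1` are skipped with
#'   a warning.
#' @param reps Monte-Carlo replicates per size.
#' @param seed integer seed.
#' @return data frame with columns `S`, `C`, `alpha`, `complexity`,
#'   `frac_stable`, `ci_lo`, `ci_hi`.
#' @export
sparse_scaling_scan <- function(S_values, alpha_strength, c0, reps = 200,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(S_values, function(S) {
    C <- c0 / S
    if (C > 1) {
      warning(sprintf("S = %d infeasible (c0/S = %.3g > 1); row skipped",
                      S, C))
      return(NULL)
    }
    sp <- stability_probability(S, C, alpha_strength, reps = reps)
    data.frame(S = S, C = C, alpha = alpha_strength,
               complexity = sp$complexity, frac_stable = sp$frac_stable,
               ci_lo = sp$ci[1], ci_hi = sp$ci[2])
  })
  do.call(rbind, rows)
}
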