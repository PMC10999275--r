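#' Specify a one-dimensional drift-diffusion (forward Kolmogorov) problem
#'
#' The forward Kolmogorov (Fokker-Planck) equation evolved by
#' [fokker_planck_solve()] is the standard conservative form
#' \deqn{\partial_t P = -\partial_x\,(A(x)P) + \tfrac12 \partial_x^2\,(B(x)P),}
#' with drift `A` (state units/time) and diffusion `B >= 0` (state
#' units^2/time). Only this sign convention conserves probability with `A`
#' meaning the mean displacement rate and `B` its variance rate, so it is
#' the one implemented.
#'
#' @param drift vectorized function `A(x)`.
#' @param diffusion vectorized function `B(x) >= 0`.
#' @param lower,upper domain endpoints, `lower < upper`.
#' @param boundary character vector of length 2 (left, right), each
#'   `"reflecting"` (zero flux) or `"absorbing"`.
#' @return object of class `"drift_diffusion_spec"`.
#' @export
drift_diffusion_spec <- function(drift, diffusion, lower, upper,
                                 boundary = c("reflecting", "reflecting")) {
  stopifnot(is.function(drift), is.function(diffusion))
  if (!(lower < upper)) stop("need `lower` < `upper`", call. = FALSE)
  boundary <- match.arg(boundary, c("reflecting", "absorbing"),
                        several.ok = TRUE)
  if (length(boundary) == 1L) boundary <- rep(boundary, 2L)
  structure(list(drift = drift, diffusion = diffusion,
                 lower = lower, upper = upper, boundary = boundary),
            class = "drift_diffusion_spec")
}

# cell-centred finite-volume generator matrix L (dense, n x n) such that
# dP/dt = L P; upwind advection, central discretization of (1/2)(BP)''.
fp_generator <- function(spec, centers, h) {
  n <- length(centers)
  A <- spec$drift
  Bv <- spec$diffusion(centers)
  if (any(Bv < 0)) stop("diffusion `B(x)` must be non-negative", call. = FALSE)
  L <- matrix(0, n, n)
  faces <- centers[-n] + h / 2
  Af <- A(faces)
  ap <- pmax(Af, 0); am <- pmax(-Af, 0)
  cc <- ap + Bv[-n] / (2 * h)       # outflow coefficient of left cell
  dd <- am + Bv[-1] / (2 * h)       # outflow coefficient of right cell
  for (j in seq_len(n - 1L)) {
    L[j, j] <- L[j, j] - cc[j] / h
    L[j + 1L, j] <- L[j + 1L, j] + cc[j] / h
    L[j, j + 1L] <- L[j, j + 1L] + dd[j] / h
    L[j + 1L, j + 1L] <- L[j + 1L, j + 1L] - dd[j] / h
  }
  if (spec$boundary[1] == "absorbing") {
    A0 <- A(spec$lower)
    leak <- pmax(-A0, 0) + Bv[1] / (2 * h)
    L[1, 1] <- L[1, 1] - leak / h
  }
  if (spec$boundary[2] == "absorbing") {
    A1 <- A(spec$upper)
    leak <- pmax(A1, 0) + Bv[n] / (2 * h)
    L[n, n] <- L[n, n] - leak / h
  }
  L
}

#' Solve the forward Kolmogorov equation by finite volumes
#'
#' Conservative cell-centred finite-volume integration of the
#' drift-diffusion equation on a uniform grid: upwind advection, central
#' diffusion, implicit (backward Euler) time stepping, so non-negativity is
#' preserved and, under reflecting boundaries, total mass is conserved to
#' round-off. If the requested `dt` exceeds the advective CFL step the
#' solver sub-steps automatically and emits a warning (the implicit scheme
#' remains stable, but accuracy degrades beyond the CFL step).
#'
#' @param spec a [drift_diffusion_spec()].
#' @param init initial density: either a vectorized function of `x` or a
#'   numeric vector of cell-centre values of length `n`. It is normalized to
#'   unit mass.
#' @param t_end end time, `> 0`.
#' @param n number of grid cells.
#' @param dt time step; default is the advective CFL step (capped at
#'   `t_end/10`).
#' @param snapshot_times optional increasing times at which to record
#'   intermediate densities.
#' @return object of class `"density_grid"`: list with `nodes` (cell
#'   centres), `values` (density), `t`, `mass`, and `snapshots` (named list
#'   of densities at `snapshot_times`).
#' @export
fokker_planck_solve <- function(spec, init, t_end, n = 200, dt = NULL,
                                snapshot_times = NULL) {
  stopifnot(inherits(spec, "drift_diffusion_spec"))
  if (t_end <= 0) stop("`t_end` must be positive", call. = FALSE)
  h <- (spec$upper - spec$lower) / n
  centers <- spec$lower + (seq_len(n) - 0.5) * h
  P <- if (is.function(init)) init(centers) else as.numeric(init)
  if (length(P) != n) stop("`init` vector must have length `n`", call. = FALSE)
  if (any(P < 0)) stop("`init` must be non-negative", call. = FALSE)
  mass0 <- sum(P) * h
  if (mass0 <= 0) stop("`init` has zero mass", call. = FALSE)
  P <- P / mass0

  amax <- max(abs(spec$drift(c(centers, spec$lower, spec$upper))))
  dt_cfl <- if (amax > 0) h / amax else Inf
  if (is.null(dt)) {
    dt <- min(dt_cfl, t_end / 10)
  } else if (dt > dt_cfl) {
    warning(sprintf(
      "dt = %.3g exceeds the advective CFL step %.3g; sub-stepping", dt,
      dt_cfl))
    dt <- dt_cfl
  }
  n_steps <- max(1L, ceiling(t_end / dt))
  dt <- t_end / n_steps

  L <- fp_generator(spec, centers, h)
  M <- solve(diag(n) - dt * L)   # backward-Euler propagator

  snaps <- list()
  if (is.null(snapshot_times)) {
    # no intermediate output: apply M^n_steps via binary exponentiation
    k <- n_steps
    while (k > 0) {
      if (k %% 2 == 1) P <- as.numeric(M %*% P)
      k <- k %/% 2
      if (k > 0) M <- M %*% M
    }
  } else {
    snap_idx <- pmin(pmax(round(snapshot_times / dt), 1L), n_steps)
    for (k in seq_len(n_steps)) {
      P <- as.numeric(M %*% P)
      if (k %in% snap_idx) {
        for (w in which(snap_idx == k))
          snaps[[sprintf("t=%g", snapshot_times[w])]] <- P
      }
    }
  }
  structure(list(nodes = centers, values = P, t = t_end,
                 mass = sum(P) * h, h = h, snapshots = snaps),
            class = "density_grid")
}

#' @export
print.density_grid <- function(x, ...) {
  cat(sprintf("Density grid: %d cells on [%.4g, %.4g], t = %g, mass = %.6f\n",
              length(x$nodes), min(x$nodes) - x$h / 2,
              max(x$nodes) + x$h / 2, x$t, x$mass))
  invisible(x)
}

#' Stationary density of a drift-diffusion process
#'
#' Under reflecting (zero-flux) boundaries the stationary density solves
#' `(1/2)(B rho)' = A rho`, giving by quadrature
#' \deqn{\rho(x) \propto \frac{1}{B(x)} \exp\Big(\int^x \frac{2A(u)}{B(u)}\,du\Big).}
#' The integral is accumulated by the trapezoid rule on the cell centres and
#' the result normalized to unit mass. A diverging (non-normalizable)
#' solution raises an error naming the offending edge.
#'
#' @param spec a [drift_diffusion_spec()] with reflecting boundaries.
#' @param n number of grid cells.
#' @return object of class `"density_grid"`.
#' @examples
#' # neutral-model pair: stationary density is Beta(2, 5)
#' sp <- drift_diffusion_spec(
#'   drift = function(x) (2 * (1 - x) - 5 * x) / 2,
#'   diffusion = function(x) x * (1 - x),
#'   lower = 1e-3, upper = 1 - 1e-3)
#' fokker_planck_stationary(sp)
#' @export
fokker_planck_stationary <- function(spec, n = 400) {
  stopifnot(inherits(spec, "drift_diffusion_spec"))
  if (any(spec$boundary != "reflecting"))
    stop("stationary density requires reflecting (zero-flux) boundaries",
         call. = FALSE)
  h <- (spec$upper - spec$lower) / n
  x <- spec$lower + (seq_len(n) - 0.5) * h
  Bv <- spec$diffusion(x)
  if (any(Bv <= 0))
    stop("diffusion `B(x)` must be positive in the interior for the ",
         "zero-flux quadrature", call. = FALSE)
  g <- 2 * spec$drift(x) / Bv
  cumint <- c(0, cumsum((g[-1] + g[-n]) / 2 * diff(x)))
  lrho <- cumint - log(Bv)
  lrho <- lrho - max(lrho)
  rho <- exp(lrho)
  Z <- sum(rho) * h
  if (!is.finite(Z) || Z <= 0) {
    edge <- if (rho[1] >= rho[n]) "lower" else "upper"
    stop(sprintf("stationary density is not normalizable (diverges at the %s edge)",
                 edge), call. = FALSE)
  }
  structure(list(nodes = x, values = rho / Z, t = Inf, mass = 1, h = h,
                 snapshots = list()),
            class = "density_grid")
}
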