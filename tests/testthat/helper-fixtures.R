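# shared equilibrated forest states, built once per test run
.forest_cache <- new.env(parent = emptyenv())

equilibrated_forest <- function(n = 1500, seed = 99, t_max = 2.5) {
  key <- sprintf("n%d_s%d_t%g", n, seed, t_max)
  if (is.null(.forest_cache[[key]])) {
    g <- mst_growth()
    sim <- ibm_forest_simulate(growth = g,
                               mortality = steady_state_mortality(g),
                               n_init = n, t_max = t_max, seed = seed)
    .forest_cache[[key]] <- list(sizes = sim$sizes, growth = g,
                                 mortality = steady_state_mortality(g),
                                 fit = fit_trunc_pareto(sim$sizes, n_boot = 0))
  }
  .forest_cache[[key]]
}

# trapezoid integral, used by numeric oracles
num_trapz <- function(x, y) sum((y[-1] + y[-length(y)]) / 2 * diff(x))
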