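# shared fixtures and a cross-file cache for the heavier Monte-Carlo runs

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# Monte-Carlo run of a preset scenario, computed once per test session
cached_mc <- function(name, reps = NULL, ...) {
  cached(paste("mc", name, reps %||% "default", sep = "_"),
         run_monte_carlo(load_scenario(name), reps = reps, ...))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# a smooth_fit holding the exact trajectory and derivative of a model:
# what the smoother would produce with infinite data and zero noise
exact_fit <- function(model, eta, t_min, t_max, m = 401L,
                      observed = rep(TRUE, model$d)) {
  grid <- seq(t_min, t_max, length.out = m)
  sol <- solve_trajectory(model, eta, grid)
  theta <- eta[model$d + seq_len(model$p)]
  deriv <- t(apply(sol$states, 1L, function(x) model$rhs(x, theta, 0)))
  if (model$d == 1L) deriv <- matrix(deriv, ncol = 1L)
  xhat <- sol$states
  xhat[, !observed] <- NA_real_
  deriv[, !observed] <- NA_real_
  structure(list(grid = grid, xhat = xhat, xhat_prime = deriv,
                 bandwidth = NA_real_, degree = 2L,
                 observed_mask = observed),
            class = "smooth_fit")
}

# noise-free dataset whose residuals are exactly zero against the
# x-component of integrate_sensitivities (same augmented system)
exact_dataset <- function(model, eta, times, observed = rep(TRUE, model$d)) {
  sens <- integrate_sensitivities(model, eta, times)
  Y <- sens$x
  Y[, !observed] <- NA_real_
  list(dataset = ode_dataset(times, Y, observed = observed), sens = sens)
}

# truth values used by the registry scenarios
truth_of <- function(name) {
  scn <- load_scenario(name)
  scn$eta0[is.na(scn$fixed)]
}
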