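# simulation scenarios, synthetic data generation, Monte-Carlo driver

#' Simulation scenario
#'
#' A fully specified simulation experiment: the model, the true
#' parameters, the sampling design, the noise, which states are observed,
#' the estimation options and the replication count.  [load_scenario()]
#' returns the preset scenarios of the package's coverage studies;
#' this constructor builds custom ones.
#'
#' @param name identifier.
#' @param model registry model name (see [ode_model()]).
#' @param eta0 true `c(xi0, theta0)`.
#' @param times design time vector.
#' @param noise_sd per-state noise standard deviations (scalar broadcast).
#' @param fixed known components of `eta` (`NA` = free), see
#'   [sme_estimate()].
#' @param observed logical length-`d`: which states are measured.
#' @param reps Monte-Carlo replication count.
#' @param seed base RNG seed; replicate `r` uses a stream derived from
#'   `(seed, r)`.
#' @param method,variant,lambda,degree,min_points estimation options,
#'   see [select_estimate()].
#' @param bw bandwidth-grid settings: list with `N`, `c_min`, `c_max`
#'   (candidates `n^(-1/3) * c * span/10`).
#' @param per_state_sigma use per-state noise variances in the Fisher
#'   information (heteroscedastic setups).
#' @param fisher_grid `NULL` for the empirical-design Fisher information,
#'   or a grid size for the uniform-F_T trapezoid evaluation (see
#'   [fisher_information()]).
#' @return An object of class `ode_scenario`.
#' @export
scenario <- function(name, model, eta0, times, noise_sd,
                     fixed = NULL, observed = NULL, reps = 500L,
                     seed = 20260101L, method = "integral",
                     variant = "damped", lambda = 0.01, degree = 2L,
                     min_points = degree + 2L,
                     bw = list(N = 10L, c_min = 0.02, c_max = 3),
                     per_state_sigma = FALSE, fisher_grid = NULL) {
  m <- ode_model(model)
  d <- m$d
  eta0 <- check_numeric(eta0, d + m$p, "eta0")
  observed <- observed %||% rep(TRUE, d)
  noise_sd <- rep(noise_sd, length.out = d)
  if (any(noise_sd[observed] <= 0))
    stop_odestep("input", "noise SDs of observed states must be positive")
  fx <- fixed_template(m, fixed)
  n_free <- sum(is.na(fx))
  if (length(times) < max(8L, n_free + 1L))
    stop_odestep("input", sprintf(
      "design must provide at least %d observations", max(8L, n_free + 1L)))
  structure(list(name = name, model = model, eta0 = eta0,
                 times = as.numeric(times), noise_sd = noise_sd,
                 fixed = fx, observed = observed, reps = as.integer(reps),
                 seed = as.integer(seed), method = method,
                 variant = variant, lambda = lambda,
                 degree = as.integer(degree),
                 min_points = as.integer(min_points), bw = bw,
                 per_state_sigma = isTRUE(per_state_sigma),
                 fisher_grid = fisher_grid),
            class = "ode_scenario")
}

#' @export
print.ode_scenario <- function(x, ...) {
  cat(sprintf(
    "<ode_scenario '%s'> model %s, n = %d on [%g, %g], reps = %d, method = %s\n",
    x$name, x$model, length(x$times), x$times[1L],
    x$times[length(x$times)], x$reps, x$method))
  invisible(x)
}

#' Preset scenario registry
#'
#' Returns the named simulation setups used by the package's coverage
#' studies (see the methods vignette for the constants of each setup).
#'
#' @param name scenario identifier; see [scenario_names()].
#' @return An `ode_scenario`.
#' @export
load_scenario <- function(name) {
  reg <- scenario_registry()
  if (!name %in% names(reg))
    stop_odestep("lookup", sprintf("unknown scenario '%s'; available: %s",
                                   name, paste(names(reg), collapse = ", ")))
  reg[[name]]()
}

#' @rdname load_scenario
#' @export
scenario_names <- function() names(scenario_registry())

scenario_registry <- function() {
  out <- list()
  setups <- list(A = c(0.5, -1), B = c(0.5, 1), C = c(1, -1), D = c(1, 1))
  for (s in names(setups)) for (n in c(21L, 51L)) {
    local({
      s0 <- s; n0 <- n
      out[[sprintf("table1_%s_n%d", s0, n0)]] <<- function()
        scenario(sprintf("table1_%s_n%d", s0, n0), "linear",
                 eta0 = setups[[s0]], times = seq(0, 10, length.out = n0),
                 noise_sd = 0.05, reps = 500L, method = "integral")
    })
  }
  for (n in c(21L, 51L)) {
    local({
      n0 <- n
      out[[sprintf("table2_n%d", n0)]] <<- function()
        scenario(sprintf("table2_n%d", n0), "lotka_volterra",
                 eta0 = c(1, 0.5, 0.5, 0.5, 0.5, 0.5),
                 times = seq(0, 10, length.out = n0),
                 noise_sd = 0.05, reps = 500L, method = "sme")
    })
  }
  for (n in c(250L, 500L, 1000L)) for (sig in c(0.1, 0.2, 0.3)) {
    local({
      n0 <- n; sg <- sig
      nm <- sprintf("table4_n%d_s%02d", n0, round(10 * sg))
      out[[nm]] <<- function()
        scenario(nm, "linear", eta0 = c(1, 1),
                 times = seq(0, 1, length.out = n0),
                 noise_sd = sg, reps = 1000L, method = "integral")
    })
  }
  out[["table6"]] <- function()
    scenario("table6", "nitrogen_oxide",
             eta0 = c(0, 4.577e-06, 2.797e-04),
             times = seq(0, 40, by = 2), noise_sd = 0.5,
             reps = 500L, method = "sme")
  for (a in c(0.02, 0.1)) {
    local({
      a0 <- a
      nm <- sprintf("table9_a%03d", round(100 * a0))
      out[[nm]] <<- function()
        scenario(nm, "alpha_pinene",
                 eta0 = c(88.35, 7.3, 2.3, 0.4, 1.75,
                          5.926e-05, 2.963e-05, 2.047e-05, 2.744e-04,
                          3.997e-05),
                 times = c(1230, 3060, 4920, 7800, 10680, 15030, 22620,
                           36420),
                 noise_sd = a0 * c(44.6833, 36.4111, 4.9570, 1.6339,
                                   12.4147),
                 fixed = c(88.35, 7.3, 2.3, 0.4, 1.75, rep(NA_real_, 5)),
                 reps = 500L, method = "integral", fisher_grid = 1001L)
    })
  }
  out[["robertson"]] <- function() {
    m <- ode_model("robertson")
    eta0 <- c(1, 0, 0, 1e4, 0.04, 3e7)
    times <- seq(0, 10, by = 0.5)
    traj <- solve_trajectory(m, eta0, times)
    # noise scale per state: 0.01 x time-average of the true solution
    # (read as the standard deviation; see the methods vignette)
    means <- apply(traj$states, 2L, function(v) trapz(times, v)) /
      (times[length(times)] - times[1L])
    scenario("robertson", "robertson", eta0 = eta0, times = times,
             noise_sd = 0.01 * means,
             fixed = c(1, 0, 0, rep(NA_real_, 3)),
             reps = 100L, method = "sme")
  }
  for (sig in c(0.01, 0.15, 0.25)) {
    local({
      sg <- sig
      nm <- sprintf("goodwin_s%03d", round(100 * sg))
      out[[nm]] <<- function()
        scenario(nm, "goodwin",
                 eta0 = c(0, 0, 0, 1, 3, 2, 1, 0.5),
                 times = seq(0, 80, length.out = 50L),
                 noise_sd = sg,
                 fixed = c(0, 0, 0, NA, 3, 2, 1, NA),
                 observed = c(TRUE, TRUE, FALSE),
                 reps = 100L, method = "integral", min_points = 3L)
    })
  }
  out
}

replicate_seed <- function(seed, replicate) {
  as.integer((as.double(seed) + 48271 * as.double(replicate)) %% 2147483629)
}

#' Generate one synthetic dataset from a scenario
#'
#' Integrates the model at the true parameter and adds independent
#' Gaussian measurement noise, state by state; unobserved states are
#' masked (`NA`).  The RNG stream is derived deterministically from the
#' scenario seed and the replicate index, so a given `(scenario,
#' replicate)` pair always yields the same dataset.
#'
#' @param scn an [scenario()] object.
#' @param replicate replicate index (>= 1).
#' @param options integrator settings.
#' @return An [ode_dataset()].
#' @export
generate_dataset <- function(scn, replicate = 1L, options = ode_options()) {
  stopifnot(inherits(scn, "ode_scenario"))
  m <- ode_model(scn$model)
  traj <- tryCatch(solve_trajectory(m, scn$eta0, scn$times, options),
                   odestep_integration = function(e)
                     stop_odestep("scenario", paste(
                       "true trajectory cannot be integrated:",
                       conditionMessage(e))))
  set.seed(replicate_seed(scn$seed, replicate))
  n <- length(scn$times)
  Y <- traj$states
  for (i in seq_len(m$d)) {
    Y[, i] <- if (scn$observed[i])
      Y[, i] + rnorm(n, 0, scn$noise_sd[i]) else NA_real_
  }
  ode_dataset(scn$times, Y, observed = scn$observed,
              meta = list(scenario = scn$name, seed = scn$seed,
                          replicate = replicate))
}

scenario_bandwidths <- function(scn) {
  n <- length(scn$times)
  span <- scn$times[n] - scn$times[1L]
  bandwidth_grid(n, N = scn$bw$N, c_min = scn$bw$c_min,
                 c_max = scn$bw$c_max, span = span)$values
}

#' Run the Monte-Carlo study of a scenario
#'
#' For each replicate: generate a dataset, run the data-driven one-step
#' pipeline with the scenario's estimation options, and collect the point
#' estimate, the preliminary estimate it corrected, the estimated
#' asymptotic variances and the confidence-interval coverage indicator.
#' Optionally also runs the iterated nonlinear least squares baseline
#' initialized at the selected preliminary estimate.  Replicate-level
#' failures are recorded, not fatal (unless every replicate fails).
#'
#' @param scn an [scenario()] object.
#' @param reps override of the scenario replication count.
#' @param include_nls also fit the NLS baseline per replicate.
#' @param alpha interval miscoverage level.
#' @param progress print a dot every 50 replicates.
#' @param options integrator settings.
#' @return An object of class `mc_summary`: a data frame with one row per
#'   free parameter (columns `parameter`, `truth`, `mean`, `ste`, `asym`,
#'   `coverage`, `prelim_mean`, `prelim_ste`, and NLS columns when
#'   requested) with attributes `reps`, `failures`, `draws` (the raw
#'   per-replicate estimates).
#' @export
run_monte_carlo <- function(scn, reps = NULL, include_nls = FALSE,
                            alpha = 0.05, progress = FALSE,
                            options = ode_options()) {
  stopifnot(inherits(scn, "ode_scenario"))
  reps <- as.integer(reps %||% scn$reps)
  if (reps < 1L) stop_odestep("input", "reps must be >= 1")
  m <- ode_model(scn$model)
  free <- is.na(scn$fixed)
  k <- sum(free)
  bw <- scenario_bandwidths(scn)
  truth <- scn$eta0[free]

  est <- matrix(NA_real_, reps, k)
  prelim <- matrix(NA_real_, reps, k)
  avar <- matrix(NA_real_, reps, k)
  cover <- matrix(NA, reps, k)
  nls_est <- if (include_nls) matrix(NA_real_, reps, k) else NULL
  nls_cover <- if (include_nls) matrix(NA, reps, k) else NULL
  failures <- character(0)

  for (r in seq_len(reps)) {
    ds <- generate_dataset(scn, r, options)
    fit <- tryCatch(
      one_step_fit(m, ds, bandwidths = bw, fixed = scn$fixed,
                   method = scn$method, variant = scn$variant,
                   lambda = scn$lambda, degree = scn$degree,
                   min_points = scn$min_points, alpha = alpha,
                   per_state_sigma = scn$per_state_sigma,
                   fisher_grid_size = scn$fisher_grid,
                   options = options),
      error = function(e) e)
    if (inherits(fit, "error")) {
      failures <- c(failures, sprintf("replicate %d: %s", r,
                                      conditionMessage(fit)))
    } else {
      est[r, ] <- fit$eta_bar[free]
      prelim[r, ] <- fit$eta_hat[free]
      avar[r, ] <- fit$intervals$se^2
      cover[r, ] <- fit$intervals$lower <= truth &
        truth <= fit$intervals$upper
      if (include_nls) {
        nf <- tryCatch({
          nfit <- nls_fit(m, ds, eta_init = fit$eta_hat, fixed = scn$fixed,
                          lambda0 = scn$lambda, options = options)
          s2 <- estimate_noise_variance(m, nfit$eta, ds,
                                        per_state = scn$per_state_sigma,
                                        options = options)
          fi <- fisher_information(m, nfit$eta, s2, ds$times, free = free,
                                   options = options)
          ci <- confidence_intervals(nfit$eta, fi, length(ds$times),
                                     alpha = alpha, free = free)
          list(eta = nfit$eta[free],
               cover = ci$lower <= truth & truth <= ci$upper)
        }, error = function(e) NULL)
        if (!is.null(nf)) {
          nls_est[r, ] <- nf$eta
          nls_cover[r, ] <- nf$cover
        }
      }
    }
    if (progress && r %% 50L == 0L) cat(".")
  }
  if (progress) cat("\n")
  ok <- rowSums(is.na(est)) == 0L
  if (!any(ok))
    stop_odestep("all_replicates_failed", paste(
      "all replicates failed; first failure:", failures[1L]))

  lab <- c(m$state_names, m$param_names)[free]
  out <- data.frame(
    parameter = lab,
    truth = truth,
    mean = colMeans(est[ok, , drop = FALSE]),
    ste = apply(est[ok, , drop = FALSE], 2L, sd),
    asym = sqrt(colMeans(avar[ok, , drop = FALSE])),
    coverage = colMeans(cover[ok, , drop = FALSE]),
    prelim_mean = colMeans(prelim[ok, , drop = FALSE]),
    prelim_ste = apply(prelim[ok, , drop = FALSE], 2L, sd))
  if (include_nls) {
    nok <- ok & rowSums(is.na(nls_est)) == 0L
    out$nls_mean <- colMeans(nls_est[nok, , drop = FALSE])
    out$nls_ste <- apply(nls_est[nok, , drop = FALSE], 2L, sd)
    out$nls_coverage <- colMeans(nls_cover[nok, , drop = FALSE])
  }
  structure(out, class = c("mc_summary", "data.frame"),
            reps = reps, successes = sum(ok), failures = failures,
            scenario = scn$name,
            draws = list(est = est, prelim = prelim, avar = avar,
                         cover = cover))
}

#' @export
print.mc_summary <- function(x, ...) {
  cat(sprintf("Monte-Carlo summary for '%s': %d/%d replicates succeeded\n",
              attr(x, "scenario"), attr(x, "successes"), attr(x, "reps")))
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], signif, digits = 4)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Serialize / parse a scenario
#'
#' Round-trippable JSON representation of an [scenario()] (requires the
#' `jsonlite` package).
#'
#' @param scn an `ode_scenario`.
#' @return [scenario_to_json()] a JSON string; [scenario_from_json()] an
#'   `ode_scenario`.
#' @export
scenario_to_json <- function(scn) {
  stopifnot(inherits(scn, "ode_scenario"))
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop_odestep("configuration", "jsonlite is required for serialization")
  jsonlite::toJSON(unclass(scn), digits = NA, auto_unbox = TRUE,
                   na = "null", null = "null")
}

#' @rdname scenario_to_json
#' @param json JSON string produced by [scenario_to_json()].
#' @export
scenario_from_json <- function(json) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop_odestep("configuration", "jsonlite is required for serialization")
  x <- jsonlite::fromJSON(json)
  fx <- as.numeric(x$fixed)
  scenario(x$name, x$model, as.numeric(x$eta0), as.numeric(x$times),
           as.numeric(x$noise_sd), fixed = fx,
           observed = as.logical(x$observed), reps = x$reps,
           seed = x$seed, method = x$method, variant = x$variant,
           lambda = x$lambda, degree = x$degree,
           min_points = x$min_points,
           fisher_grid = if (is.null(x$fisher_grid)) NULL else
             as.integer(x$fisher_grid), bw = list(N = as.integer(x$bw$N), c_min = x$bw$c_min,
                     c_max = x$bw$c_max),
           per_state_sigma = isTRUE(x$per_state_sigma))
}
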