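# noise variance, Fisher information, confidence intervals, NLS baseline

#' Estimate the measurement-noise variance
#'
#' Plug-in residual estimator
#' `sigma2_hat = sum_ij (Y_ij - x_i(eta, t_j))^2 / (d_obs * (n - 1))`,
#' summing over observed states only (`d_obs` of them).  With
#' `per_state = TRUE` a vector of per-state variances (divisor `n - 1`
#' each) is returned instead, for heteroscedastic noise.
#'
#' @param model an [ode_model][define_ode_model].
#' @param eta parameter vector at which the trajectory is evaluated
#'   (typically the one-step estimate).
#' @param dataset an [ode_dataset()].
#' @param per_state return one variance per observed state.
#' @param options integrator settings.
#' @return Scalar pooled variance, or a length-`d` vector (`NA` for
#'   unobserved states) when `per_state = TRUE`.
#' @export
estimate_noise_variance <- function(model, eta, dataset, per_state = FALSE,
                                    options = ode_options()) {
  n <- length(dataset$times)
  if (n < 2L) stop_odestep("input", "need at least two observations")
  traj <- solve_trajectory(model, eta, dataset$times, options)
  obs <- which(dataset$observed[seq_len(model$d)])
  R <- dataset$Y[, obs, drop = FALSE] - traj$states[, obs, drop = FALSE]
  if (per_state) {
    out <- rep(NA_real_, model$d)
    out[obs] <- colSums(R^2) / (n - 1)
    out
  } else sum(R^2) / (length(obs) * (n - 1))
}

#' Fisher information of the trajectory model
#'
#' Evaluates
#' `I(eta) = sum_{i observed} integral (dx_i/deta)^T (dx_i/deta) dF_T(t) / sigma_i^2`
#' where `F_T` is the design distribution and the sensitivities
#' `dx/deta` come from one integration of the sensitivity equations.
#' Rows/columns of fixed parameters are removed.  The inverse of this
#' matrix divided by `n` is the asymptotic covariance of the one-step (and
#' nonlinear least squares) estimator.
#'
#' By default `F_T` is the empirical design distribution, so the integral
#' is the average of `s(t_j)^T s(t_j)` over the actual observation times
#' (the classical nonlinear-regression Gram matrix).  Supplying
#' `grid_size` instead approximates a uniform `F_T` on the design span by
#' the trapezoidal rule on a dense grid, which is the right object for
#' *theoretical* asymptotic variances under a uniform sampling
#' distribution; the two differ noticeably when the sensitivities vary on
#' the scale of the design spacing.
#'
#' @inheritParams estimate_noise_variance
#' @param sigma2 noise variance: a scalar, or a length-`d` vector of
#'   per-state variances for heteroscedastic errors.
#' @param times design times.
#' @param free logical mask over `eta` (default all free).
#' @param grid_size `NULL` (default) for the empirical design
#'   distribution, or the number of quadrature points for a uniform `F_T`.
#' @return A symmetric positive semi-definite matrix of dimension
#'   `sum(free)`.
#' @export
fisher_information <- function(model, eta, sigma2, times, free = NULL,
                               grid_size = NULL, options = ode_options()) {
  free <- free_indices(model, free)
  fidx <- which(free)
  if (is.null(grid_size)) {
    tt <- times
    w <- rep(1 / length(times), length(times))
  } else {
    tt <- seq(times[1L], times[length(times)], length.out = grid_size)
    w <- trapz_weights(tt) / (tt[length(tt)] - tt[1L])
  }
  sens <- integrate_sensitivities(model, eta, tt, options)
  s2 <- if (length(sigma2) == 1L) rep(sigma2, model$d) else sigma2
  k <- length(fidx)
  I <- matrix(0, k, k)
  for (i in seq_len(model$d)) {
    if (is.na(s2[i])) next
    Si <- matrix(sens$s[, i, fidx], length(tt), k)
    I <- I + crossprod(Si * sqrt(w)) / s2[i]
  }
  attr(I, "condition") <- tryCatch(kappa(I, exact = FALSE),
                                   error = function(e) NA_real_)
  (I + t(I)) / 2
}

#' Wald confidence intervals from the Fisher information
#'
#' Per free parameter `j`:
#' `eta_j +/- z_{1 - alpha/2} * sqrt((I^{-1})_jj / n)`.
#'
#' @param eta full parameter vector.
#' @param fisher information matrix over the free components
#'   ([fisher_information()]).
#' @param n sample size (number of time points).
#' @param alpha miscoverage level (default 0.05 for 95% intervals).
#' @param free logical mask matching `fisher`.
#' @return A data frame with columns `parameter`, `estimate`, `se`,
#'   `lower`, `upper` (rows = free components; `level` attribute).
#' @export
confidence_intervals <- function(eta, fisher, n, alpha = 0.05, free = NULL) {
  free <- free %||% rep(TRUE, length(eta))
  inv <- svd_inverse(fisher)
  v <- diag(inv) / n
  if (any(v < 0)) v <- pmax(v, 0)
  se <- sqrt(v)
  z <- qnorm(1 - alpha / 2)
  est <- eta[free]
  out <- data.frame(parameter = which(free), estimate = est, se = se,
                    lower = est - z * se, upper = est + z * se)
  attr(out, "level") <- 1 - alpha
  out
}

#' Full one-step fit with inference
#'
#' Convenience wrapper running the data-driven one-step pipeline
#' ([select_estimate()]) and attaching the noise-variance estimate, the
#' plug-in Fisher information at the selected estimate, and Wald
#' confidence intervals.
#'
#' @inheritParams select_estimate
#' @param min_points minimal observations per smoothing window.
#' @param alpha miscoverage level for the intervals.
#' @param per_state_sigma use per-state noise variances in the information
#'   (for heteroscedastic noise).
#' @param fisher_grid_size quadrature points for [fisher_information()]
#'   (`NULL`: empirical design distribution).
#' @return A `one_step_fit` object: the `one_step_result` plus
#'   `sigma2_hat`, `fisher`, `intervals`, `n`, `alpha`.
#' @export
one_step_fit <- function(model, dataset, bandwidths = NULL, fixed = NULL,
                         method = c("integral", "sme"),
                         variant = c("damped", "gauss_newton", "newton"),
                         lambda = 0.01, degree = 2L,
                         min_points = degree + 2L, alpha = 0.05,
                         per_state_sigma = FALSE, fisher_grid_size = NULL,
                         options = ode_options()) {
  sel <- select_estimate(model, dataset, bandwidths = bandwidths,
                         fixed = fixed, method = method, variant = variant,
                         lambda = lambda, degree = degree,
                         min_points = min_points, options = options)
  s2 <- estimate_noise_variance(model, sel$eta_bar, dataset,
                                per_state = per_state_sigma,
                                options = options)
  fi <- fisher_information(model, sel$eta_bar, s2, dataset$times,
                           free = sel$free, grid_size = fisher_grid_size,
                           options = options)
  ci <- confidence_intervals(sel$eta_bar, fi, length(dataset$times),
                             alpha = alpha, free = sel$free)
  sel$sigma2_hat <- s2
  sel$fisher <- fi
  sel$intervals <- ci
  sel$n <- length(dataset$times)
  sel$alpha <- alpha
  class(sel) <- c("one_step_fit", class(sel))
  sel
}

#' @export
print.one_step_fit <- function(x, ...) {
  cat(sprintf(
    "One-step fit (variant %s, bandwidth %.4g, sigma2_hat %.4g, n = %d)\n",
    x$variant, x$bandwidth, mean(x$sigma2_hat, na.rm = TRUE), x$n))
  ci <- x$intervals
  lab <- parameter_labels(length(x$eta_bar), attr(x, "model_names"))
  tab <- data.frame(parameter = lab[ci$parameter],
                    estimate = signif(ci$estimate, 6),
                    se = signif(ci$se, 4),
                    lower = signif(ci$lower, 6),
                    upper = signif(ci$upper, 6))
  print(tab, row.names = FALSE)
  invisible(x)
}

parameter_labels <- function(q, names = NULL) {
  if (!is.null(names) && length(names) == q) return(names)
  paste0("eta", seq_len(q))
}

#' Nonlinear least squares via Levenberg-Marquardt
#'
#' Iterated minimization of the trajectory least-squares criterion
#' `R_n(eta)` using sensitivity-equation Jacobians and the standard
#' damping schedule: a proposal solves
#' `(J^T J + lambda I) delta = J^T r`; accepted steps (criterion
#' decreases) divide `lambda` by 10, rejected ones multiply it by 10.
#' Integration failures at a proposal count as rejections.  The first
#' iteration from a given start with fixed `lambda` coincides with the
#' damped one-step update.
#'
#' @inheritParams select_estimate
#' @param eta_init full starting vector `c(xi, theta)`.
#' @param max_iter maximal number of accepted iterations.
#' @param lambda0 initial damping parameter.
#' @param ftol,xtol relative tolerances on criterion decrease and step
#'   size.
#' @param max_reject maximal consecutive rejections before declaring
#'   non-convergence.
#' @return A list with `eta`, `rss`, `iterations`, `converged`,
#'   `lambda`, and `message`.
#' @export
nls_fit <- function(model, dataset, eta_init, fixed = NULL,
                    max_iter = 100L, lambda0 = 0.01,
                    ftol = 1e-10, xtol = 1e-10, max_reject = 25L,
                    options = ode_options()) {
  check_numeric(eta_init, model$d + model$p, "eta_init")
  fx <- fixed_template(model, fixed)
  free <- is.na(fx)
  eta <- eta_init
  eta[!free] <- fx[!free]
  lam <- lambda0
  obs <- which(dataset$observed[seq_len(model$d)])
  fidx <- which(free)

  eval_at <- function(eta) {
    sens <- integrate_sensitivities(model, eta, dataset$times, options)
    R <- dataset$Y[, obs, drop = FALSE] - sens$x[, obs, drop = FALSE]
    J <- do.call(rbind, lapply(seq_along(dataset$times), function(j)
      matrix(sens$s[j, obs, fidx], length(obs), length(fidx))))
    list(rss = sum(R^2), r = as.vector(t(R)), J = J)
  }
  cur <- tryCatch(eval_at(eta), error = function(e)
    stop_odestep("integration", paste("initial point infeasible:",
                                      conditionMessage(e))))
  it <- 0L; accepted <- 0L; msg <- "converged"
  converged <- FALSE
  while (it < max_iter) {
    it <- it + 1L
    g <- crossprod(cur$J, cur$r)           # = Psi_n(eta), free part
    A <- crossprod(cur$J)
    rejections <- 0L
    repeat {
      delta <- tryCatch(solve(A + lam * diag(length(fidx)), g),
                        error = function(e) NULL)
      prop <- eta
      if (!is.null(delta) && all(is.finite(delta)))
        prop[fidx] <- eta[fidx] + as.numeric(delta)
      cand <- if (is.null(delta) || any(!is.finite(prop))) NULL else
        tryCatch(eval_at(prop), error = function(e) NULL)
      if (!is.null(cand) && cand$rss <= cur$rss) break
      lam <- lam * 10
      rejections <- rejections + 1L
      if (rejections > max_reject) {
        return(list(eta = eta, rss = cur$rss, iterations = it - 1L,
                    converged = FALSE, lambda = lam,
                    message = "damping escalation limit reached"))
      }
    }
    accepted <- accepted + 1L
    dstep <- sqrt(sum((prop[fidx] - eta[fidx])^2)) /
      max(sqrt(sum(eta[fidx]^2)), 1e-12)
    drss <- (cur$rss - cand$rss) / max(cur$rss, 1e-300)
    eta <- prop; cur <- cand
    lam <- max(lam / 10, 1e-12)
    if (dstep < xtol || drss < ftol) { converged <- TRUE; break }
  }
  if (!converged && it >= max_iter) msg <- "max_iter reached"
  list(eta = eta, rss = cur$rss, iterations = it, converged = converged,
       lambda = lam, message = msg)
}
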