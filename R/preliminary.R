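# root-n-consistent preliminary estimators built on the smoothed trajectory

# `fixed` convention used across the package: a numeric vector of length
# d + p holding the known value of every fixed component of eta = (xi, theta)
# and NA for every free component; NULL means everything is free.
fixed_template <- function(model, fixed) {
  q <- model$d + model$p
  if (is.null(fixed)) return(rep(NA_real_, q))
  check_len <- length(fixed) == q
  if (!check_len) stop_odestep("input", sprintf(
    "'fixed' must have length d + p = %d (NA marks free components)", q))
  as.numeric(fixed)
}

free_mask <- function(model, fixed) is.na(fixed_template(model, fixed))

new_preliminary <- function(eta, model, bandwidth, method, criterion) {
  structure(list(eta = eta,
                 xi_hat = eta[seq_len(model$d)],
                 theta_hat = eta[model$d + seq_len(model$p)],
                 bandwidth = bandwidth, method = method,
                 criterion_value = criterion),
            class = "preliminary_estimate")
}

# interior weight: indicator of [t_1 + delta, t_n - delta], delta = trim * span
interior_weights <- function(grid, trim) {
  w <- trapz_weights(grid)
  if (trim > 0) {
    span <- grid[length(grid)] - grid[1L]
    w[grid < grid[1L] + trim * span | grid > grid[length(grid)] - trim * span] <- 0
  }
  w
}

#' Smooth-and-match preliminary estimator
#'
#' Estimates `theta` by matching the smoothed derivative to the model
#' right-hand side evaluated along the smoothed trajectory: it minimizes
#' the quadrature approximation of
#' `integral( || xhat'(t) - F(xhat(t); theta) ||^2 w(t) dt )`,
#' where the weight `w` is the indicator of the interior of the design
#' (boundary-trimmed, since derivative estimates are least reliable there).
#' When the model declares linearity in `theta` the minimizer is a
#' closed-form weighted linear least squares solution; otherwise the
#' criterion is minimized numerically.
#'
#' Free initial values are subsequently estimated by
#' [estimate_initial_values()].  The method requires every state entering
#' `F` to be observed.
#'
#' @param model an [ode_model][define_ode_model].
#' @param fit a [smooth_dataset()] result.
#' @param fixed numeric length `d + p`; known components of
#'   `eta = (xi, theta)` at their values, `NA` for free ones (default: all
#'   free).
#' @param trim fraction of the design span trimmed from each boundary in
#'   the matching weight (default 0.05).
#' @param theta_init starting point for the numeric minimizer when the
#'   model has no parameter-linearity decomposition.
#' @return A `preliminary_estimate`: list with the full `eta`, its
#'   components `xi_hat` and `theta_hat`, the `bandwidth`, `method` and
#'   the attained `criterion_value`.
#' @export
sme_estimate <- function(model, fit, fixed = NULL, trim = 0.05,
                         theta_init = NULL) {
  fx <- fixed_template(model, fixed)
  if (!all(fit$observed_mask[seq_len(model$d)]))
    stop_odestep("unsupported_observation_pattern",
                 "smooth-and-match needs all states observed; see integral_estimate for partially observed systems")
  w <- interior_weights(fit$grid, trim)
  keep <- w > 0
  sw <- sqrt(w[keep])
  m <- sum(keep)
  d <- model$d; p <- model$p
  th_fixed <- fx[d + seq_len(p)]
  free_th <- is.na(th_fixed)

  if (!is.null(model$G)) {
    # stack sqrt(w) * [ xhat' - g0 - G[, fixed] theta_fixed ]  ~  G[, free]
    Gbig <- matrix(0, m * d, p)
    resp <- numeric(m * d)
    idx <- which(keep)
    for (jj in seq_along(idx)) {
      k <- idx[jj]
      x <- fit$xhat[k, ]
      Gk <- model$G(x, fit$grid[k])
      g0k <- if (is.null(model$g0)) numeric(d) else model$g0(x, fit$grid[k])
      rows <- (jj - 1L) * d + seq_len(d)
      Gbig[rows, ] <- sw[jj] * Gk
      resp[rows] <- sw[jj] * (fit$xhat_prime[k, ] - g0k)
    }
    if (any(!free_th))
      resp <- resp - Gbig[, !free_th, drop = FALSE] %*% th_fixed[!free_th]
    th <- th_fixed
    if (any(free_th)) {
      ls <- tryCatch(qr.solve(Gbig[, free_th, drop = FALSE], resp),
                     error = function(e) stop_odestep("degenerate_design",
                       "normal equations of the smooth-and-match criterion are singular"))
      th[free_th] <- ls
    }
    crit <- sum((resp - Gbig[, free_th, drop = FALSE] %*% th[free_th])^2)
  } else {
    obj <- function(thf) {
      th <- th_fixed; th[free_th] <- thf
      s <- 0
      idx <- which(keep)
      for (jj in seq_along(idx)) {
        k <- idx[jj]
        r <- fit$xhat_prime[k, ] - model$rhs(fit$xhat[k, ], th, fit$grid[k])
        s <- s + w[k] * sum(r^2)
      }
      s
    }
    init <- theta_init %||% rep(1, p)
    opt <- optim(init[free_th], obj, method = "BFGS",
                 control = list(maxit = 500, reltol = 1e-12))
    th <- th_fixed; th[free_th] <- opt$par
    crit <- opt$value
  }
  xi <- estimate_initial_values(model, fit, th,
                                fixed_xi = fx[seq_len(d)])
  new_preliminary(c(xi, th), model, fit$bandwidth, "sme", crit)
}

#' Initial-value estimator given a parameter estimate
#'
#' With `theta_hat` in hand, the initial value minimizing the quadrature
#' approximation of
#' `integral( || xhat(t) - xi - integral_0^t F(xhat(s); theta_hat) ds ||^2 dt )`
#' is, coordinate-wise, the time-average of
#' `xhat_i(t) - integral F_i`, a closed-form linear least squares solution.
#'
#' @inheritParams sme_estimate
#' @param theta_hat parameter vector (length `p`).
#' @param fixed_xi numeric length `d` with known initial values, `NA` for
#'   free ones.
#' @return The length-`d` initial-value estimate (fixed entries passed
#'   through unchanged).
#' @export
estimate_initial_values <- function(model, fit, theta_hat, fixed_xi = NULL) {
  d <- model$d
  fixed_xi <- fixed_xi %||% rep(NA_real_, d)
  xi <- fixed_xi
  if (!any(is.na(fixed_xi))) return(xi)
  if (!all(fit$observed_mask[seq_len(d)]))
    stop_odestep("unsupported_observation_pattern",
                 "initial-value estimation needs all states observed")
  Fmat <- matrix(0, length(fit$grid), d)
  for (k in seq_along(fit$grid))
    Fmat[k, ] <- model$rhs(fit$xhat[k, ], theta_hat, fit$grid[k])
  cumF <- cumtrapz(fit$grid, Fmat)
  w <- trapz_weights(fit$grid)
  w <- w / sum(w)
  for (i in which(is.na(fixed_xi)))
    xi[i] <- sum(w * (fit$xhat[, i] - cumF[, i]))
  xi
}

#' Direct integral preliminary estimator
#'
#' Jointly estimates the free components of `(xi, theta)` by minimizing
#' the quadrature approximation of
#' `integral( || xhat(t) - xi - integral_0^t F(xhat(s); theta) ds ||^2 dt )`
#' over the design span.  No derivative estimate enters the criterion,
#' which makes this estimator more stable than smooth-and-match for sparse
#' or noisy designs.  For models linear in `theta` the inner integrals are
#' cumulative trapezoids of the columns of `G(xhat)` and the problem is a
#' closed-form linear least squares fit.
#'
#' For the partially observed Goodwin system (repressor never measured,
#' `theta2..theta4` and the initial values known) the unobserved state is
#' reconstructed by integrating its own linear equation driven by the
#' smoothed protein trajectory at candidate values of `theta5`; the
#' criterion, restricted to the observed states, is then profiled over the
#' production rate `theta1` (linear) and minimized over `theta5` on a grid
#' refined by golden-section search.
#'
#' @inheritParams sme_estimate
#' @return A `preliminary_estimate` (see [sme_estimate()]).
#' @export
integral_estimate <- function(model, fit, fixed = NULL) {
  fx <- fixed_template(model, fixed)
  d <- model$d; p <- model$p
  if (!all(fit$observed_mask[seq_len(d)])) {
    if (model$name == "goodwin")
      return(goodwin_integral_estimate(model, fit, fx))
    stop_odestep("unsupported_observation_pattern", sprintf(
      "state(s) %s unobserved and no reconstruction rule applies for model '%s'",
      paste(which(!fit$observed_mask), collapse = ","), model$name))
  }
  if (is.null(model$G))
    stop_odestep("configuration",
                 "integral_estimate requires a parameter-linearity decomposition (G, g0)")
  grid <- fit$grid
  m <- length(grid)
  # cumulative integrals of each column of G(xhat) and of g0(xhat)
  Gflat <- matrix(0, m, d * p)
  g0m <- matrix(0, m, d)
  for (k in seq_len(m)) {
    Gflat[k, ] <- as.vector(model$G(fit$xhat[k, ], grid[k]))
    if (!is.null(model$g0)) g0m[k, ] <- model$g0(fit$xhat[k, ], grid[k])
  }
  A <- cumtrapz(grid, Gflat)            # m x (d*p), [k, (j-1)*d + i]
  a0 <- cumtrapz(grid, g0m)             # m x d
  w <- trapz_weights(grid)
  sw <- sqrt(w)

  xi_fixed <- fx[seq_len(d)]
  th_fixed <- fx[d + seq_len(p)]
  free_xi <- is.na(xi_fixed)
  free_th <- is.na(th_fixed)
  ncol_des <- sum(free_xi) + sum(free_th)
  X <- matrix(0, m * d, ncol_des)
  resp <- numeric(m * d)
  for (i in seq_len(d)) {
    rows <- (seq_len(m) - 1L) * d + i
    r <- fit$xhat[, i] - a0[, i]
    Ai <- A[, (seq_len(p) - 1L) * d + i, drop = FALSE]   # m x p for state i
    if (any(!free_th))
      r <- r - Ai[, !free_th, drop = FALSE] %*% th_fixed[!free_th]
    if (!free_xi[i]) r <- r - xi_fixed[i]
    col <- 0L
    for (ii in which(free_xi)) {
      col <- col + 1L
      if (ii == i) X[rows, col] <- sw
    }
    X[rows, sum(free_xi) + seq_len(sum(free_th))] <-
      sw * Ai[, free_th, drop = FALSE]
    resp[rows] <- sw * r
  }
  beta <- tryCatch(qr.solve(X, resp),
                   error = function(e) stop_odestep("degenerate_design",
                     "normal equations of the integral criterion are singular"))
  xi <- xi_fixed; th <- th_fixed
  xi[free_xi] <- beta[seq_len(sum(free_xi))]
  th[free_th] <- beta[sum(free_xi) + seq_len(sum(free_th))]
  crit <- sum((resp - X %*% beta)^2)
  new_preliminary(c(xi, th), model, fit$bandwidth, "integral", crit)
}

# reconstruct the unobserved Goodwin repressor x3 on the smoothing grid by
# trapezoid-implicit integration of x3' = theta4 * xhat2 - theta5 * x3
goodwin_reconstruct_x3 <- function(grid, xhat2, theta4, theta5, x3_0 = 0) {
  m <- length(grid)
  x3 <- numeric(m)
  x3[1L] <- x3_0
  dt <- diff(grid)
  for (k in seq_len(m - 1L)) {
    drive <- theta4 * (xhat2[k] + xhat2[k + 1L]) / 2
    x3[k + 1L] <- (x3[k] * (1 - theta5 * dt[k] / 2) + dt[k] * drive) /
      (1 + theta5 * dt[k] / 2)
  }
  x3
}

goodwin_integral_estimate <- function(model, fit, fx,
                                      theta5_range = c(0.02, 5),
                                      grid_points = 60L) {
  d <- model$d
  if (!all(fit$observed_mask[1:2]) || fit$observed_mask[3L])
    stop_odestep("unsupported_observation_pattern",
                 "the Goodwin reconstruction assumes x1, x2 observed and x3 missing")
  th_fixed <- fx[d + 1:5]
  if (anyNA(th_fixed[2:4]) || anyNA(fx[1:3]))
    stop_odestep("configuration",
                 "Goodwin estimation assumes theta2..theta4 and the initial values known")
  xi <- fx[1:3]
  grid <- fit$grid
  w <- trapz_weights(grid)
  x1 <- fit$xhat[, 1L]; x2 <- fit$xhat[, 2L]
  Cx1 <- cumtrapz(grid, x1)[, 1L]
  Cx2 <- cumtrapz(grid, x2)[, 1L]

  profile <- function(theta5) {
    x3 <- goodwin_reconstruct_x3(grid, x2, th_fixed[4L], theta5, xi[3L])
    u <- 1 / (1 + th_fixed[2L] * x3^10)
    Cu <- cumtrapz(grid, u)[, 1L]
    b1 <- x1 - xi[1L] + theta5 * Cx1
    th1 <- sum(w * Cu * b1) / sum(w * Cu^2)
    r1 <- b1 - th1 * Cu
    r2 <- x2 - xi[2L] - th_fixed[3L] * Cx1 + theta5 * Cx2
    list(value = sum(w * (r1^2 + r2^2)), theta1 = th1)
  }
  cand <- exp(seq(log(theta5_range[1L]), log(theta5_range[2L]),
                  length.out = grid_points))
  vals <- vapply(cand, function(t5) profile(t5)$value, numeric(1))
  k <- which.min(vals)
  lo <- cand[max(1L, k - 1L)]; hi <- cand[min(grid_points, k + 1L)]
  opt <- optimize(function(t5) profile(t5)$value, c(lo, hi), tol = 1e-8)
  best <- profile(opt$minimum)
  th <- th_fixed
  th[1L] <- if (is.na(th_fixed[1L])) best$theta1 else th_fixed[1L]
  th[5L] <- opt$minimum
  new_preliminary(c(xi, th), model, fit$bandwidth, "integral", best$value)
}
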