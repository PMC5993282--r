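lv_truth <- c(1, 0.5, rep(0.5, 4))

test_that("sensitivity solutions satisfy the initial condition and closed forms", {
  lin <- ode_model("linear")
  times <- seq(0, 5, length.out = 21)
  s <- integrate_sensitivities(lin, c(1, 0.8), times)
  expect_equal(matrix(s$s[1, , ], 1, 2), cbind(diag(1), 0))
  # x = xi e^{theta t}:  dx/dxi = e^{theta t},  dx/dtheta = xi t e^{theta t}
  expect_equal(s$s[, 1, 1], exp(0.8 * times), tolerance = 1e-7)
  expect_equal(s$s[, 1, 2], times * exp(0.8 * times), tolerance = 1e-7)
})

test_that("sensitivities match finite differences of the trajectory", {
  lv <- ode_model("lotka_volterra")
  times <- seq(0, 10, length.out = 21)
  s <- integrate_sensitivities(lv, lv_truth, times)
  for (k in seq_along(lv_truth)) {
    h <- 1e-6
    ep <- em <- lv_truth
    ep[k] <- ep[k] + h; em[k] <- em[k] - h
    fd <- (solve_trajectory(lv, ep, times)$states -
             solve_trajectory(lv, em, times)$states) / (2 * h)
    scale <- max(abs(fd))
    expect_lt(max(abs(s$s[, , k] - fd)) / scale, 1e-5)
  }
})

test_that("variational solutions satisfy z(0) = 0 and closed forms", {
  lin <- ode_model("linear")
  times <- seq(0, 5, length.out = 21)
  v <- integrate_variational(lin, c(0.7, 0.8), times)
  expect_equal(array(v$z[1, , , ], c(2, 2)), matrix(0, 2, 2))
  # second derivatives of xi e^{theta t}
  e <- exp(0.8 * times)
  expect_equal(v$z[, 1, 1, 1], rep(0, 21), tolerance = 1e-6)
  expect_equal(v$z[, 1, 1, 2], times * e, tolerance = 1e-6)
  expect_equal(v$z[, 1, 2, 1], times * e, tolerance = 1e-6)
  expect_equal(v$z[, 1, 2, 2], 0.7 * times^2 * e, tolerance = 1e-5)
})

test_that("variational solutions match finite differences of the sensitivities", {
  no <- ode_model("nitrogen_oxide")
  eta <- c(0, 4.577e-06, 2.797e-04)
  times <- seq(0, 40, length.out = 21)
  tight <- ode_options(rtol = 1e-12, atol = 1e-14)
  v <- integrate_variational(no, eta, times, tight)
  for (l in 1:3) {
    h <- if (eta[l] == 0) 1e-6 else 1e-3 * abs(eta[l])
    ep <- em <- eta
    ep[l] <- ep[l] + h; em[l] <- em[l] - h
    fd <- (integrate_sensitivities(no, ep, times, tight)$s -
             integrate_sensitivities(no, em, times, tight)$s) / (2 * h)
    zl <- array(v$z[, , , l], dim = dim(fd))
    expect_lt(max(abs(zl - fd)) / max(abs(fd), 1), 1e-4)
  }
})

test_that("the score vanishes on exact data and sums residual projections", {
  lv <- ode_model("lotka_volterra")
  ex <- exact_dataset(lv, lv_truth, seq(0, 10, length.out = 21))
  psi <- score(lv, lv_truth, ex$dataset, sens = ex$sens)
  expect_equal(psi, rep(0, 6))
  # hand-computable case: linear model, xi = 2, theta = 0 (x constant = 2,
  # s(t) = (1, 2t)); residuals (0, 0.5) at t = (0, 1)
  lin <- ode_model("linear")
  ds <- ode_dataset(c(0, 1), matrix(c(2, 2.5), 2, 1))
  psi <- score(lin, c(2, 0), ds)
  expect_equal(psi, c(0.5, 1.0), tolerance = 1e-8)
})

test_that("the score is minus half the gradient of the least-squares criterion", {
  set.seed(8)
  lv <- ode_model("lotka_volterra")
  times <- seq(0, 10, length.out = 21)
  tr <- solve_trajectory(lv, lv_truth, times)
  ds <- ode_dataset(times, tr$states + matrix(rnorm(42, 0, 0.05), 21, 2))
  eta <- lv_truth * c(1.05, 0.95, 1.02, 0.97, 1.04, 0.99)
  psi <- score(lv, eta, ds)
  rn <- function(e) odestep:::rn_criterion(lv, e, ds)
  for (k in 1:6) {
    h <- 1e-6
    ep <- em <- eta
    ep[k] <- ep[k] + h; em[k] <- em[k] - h
    grad_k <- (rn(ep) - rn(em)) / (2 * h)
    expect_equal(psi[k], -grad_k / 2, tolerance = 1e-4)
  }
})

test_that("step matrices have the Gram structure and match score derivatives", {
  set.seed(9)
  lv <- ode_model("lotka_volterra")
  times <- seq(0, 10, length.out = 21)
  ex <- exact_dataset(lv, lv_truth, times)
  # zero residuals: newton coincides with gauss_newton
  Mn <- step_matrix(lv, lv_truth, ex$dataset, variant = "newton")
  Mg <- step_matrix(lv, lv_truth, ex$dataset, variant = "gauss_newton")
  expect_equal(Mn, Mg, tolerance = 1e-6)
  # gauss_newton is symmetric negative semidefinite; damped negative definite
  ds <- ode_dataset(times, ex$dataset$Y + matrix(rnorm(42, 0, 0.05), 21, 2))
  Mg <- step_matrix(lv, lv_truth, ds, variant = "gauss_newton")
  expect_equal(Mg, t(Mg))
  expect_true(all(eigen(Mg, symmetric = TRUE)$values <= 1e-10))
  Md <- step_matrix(lv, lv_truth, ds, variant = "damped", lambda = 0.5)
  expect_true(all(eigen(Md, symmetric = TRUE)$values <= -0.5 + 1e-8))
  expect_equal(Md, Mg - 0.5 * diag(6))
  # newton equals the finite-difference Jacobian of the score (linear model)
  lin <- ode_model("linear")
  lds <- ode_dataset(times, 0.5 * exp(-times) + rnorm(21, 0, 0.05))
  eta <- c(0.52, -0.95)
  Mn <- step_matrix(lin, eta, lds, variant = "newton")
  for (k in 1:2) {
    h <- 1e-6
    ep <- em <- eta
    ep[k] <- ep[k] + h; em[k] <- em[k] - h
    fd <- (score(lin, ep, lds) - score(lin, em, lds)) / (2 * h)
    expect_equal(Mn[, k], fd, tolerance = 1e-4)
  }
})

test_that("zero-noise data at the truth are a fixed point for every variant and model", {
  scns <- list(linear = c(0.5, -1), lotka_volterra = lv_truth,
               robertson = c(1, 0, 0, 1e4, 0.04, 3e7),
               goodwin = c(0, 0, 0, 1, 3, 2, 1, 0.5),
               nitrogen_oxide = c(0, 4.577e-06, 2.797e-04),
               alpha_pinene = c(88.35, 7.3, 2.3, 0.4, 1.75, 5.926e-05,
                                2.963e-05, 2.047e-05, 2.744e-04, 3.997e-05))
  horizons <- c(linear = 10, lotka_volterra = 10, robertson = 10,
                goodwin = 80, nitrogen_oxide = 40, alpha_pinene = 36420)
  for (nm in names(scns)) {
    m <- ode_model(nm)
    eta0 <- scns[[nm]]
    observed <- if (nm == "goodwin") c(TRUE, TRUE, FALSE) else rep(TRUE, m$d)
    ex <- exact_dataset(m, eta0, seq(0, horizons[nm], length.out = 21),
                        observed = observed)
    psi <- score(m, eta0, ex$dataset, sens = ex$sens)
    expect_equal(psi, rep(0, m$d + m$p), info = nm)
    for (variant in c("damped", "gauss_newton", "newton")) {
      M <- if (variant == "newton" && nm %in% c("robertson", "goodwin"))
        NULL   # exact-zero score short-circuits before the matrix is needed
      else step_matrix(m, eta0, ex$dataset, variant = variant,
                       sens = ex$sens)
      eta_bar <- one_step_update(eta0, psi, M %||% diag(m$d + m$p))
      expect_identical(eta_bar, eta0)
    }
  }
})

test_that("a damped update equals one hand-rolled Levenberg-Marquardt iteration", {
  set.seed(12)
  lv <- ode_model("lotka_volterra")
  times <- seq(0, 10, length.out = 21)
  tr <- solve_trajectory(lv, lv_truth, times)
  ds <- ode_dataset(times, tr$states + matrix(rnorm(42, 0, 0.05), 21, 2))
  eta_hat <- lv_truth * c(1.03, 0.98, 1.02, 0.99, 1.01, 0.97)
  lambda <- 0.01
  # hand-rolled LM iteration on Rn with the same damping
  sens <- integrate_sensitivities(lv, eta_hat, times)
  J <- do.call(rbind, lapply(1:21, function(j) matrix(sens$s[j, , ], 2, 6)))
  r <- as.vector(t(ds$Y - sens$x))
  lm_step <- solve(crossprod(J) + lambda * diag(6), crossprod(J, r))
  lm_eta <- eta_hat + as.numeric(lm_step)
  # package path
  psi <- score(lv, eta_hat, ds, sens = sens)
  M <- step_matrix(lv, eta_hat, ds, variant = "damped", lambda = lambda,
                   sens = sens)
  eta_bar <- one_step_update(eta_hat, psi, M)
  expect_equal(eta_bar, lm_eta, tolerance = 1e-10)
  # and equals the first iterate of the NLS baseline at the same damping
  nf <- nls_fit(lv, ds, eta_init = eta_hat, max_iter = 1, lambda0 = lambda)
  expect_equal(nf$eta, lm_eta, tolerance = 1e-10)
})

test_that("candidate selection returns the minimal-Rn bandwidth with diagnostics", {
  set.seed(31)
  lin <- ode_model("linear")
  times <- seq(0, 10, length.out = 21)
  ds <- ode_dataset(times, 0.5 * exp(-times) + rnorm(21, 0, 0.05))
  # single candidate
  single <- select_estimate(lin, ds, bandwidths = 1.0, method = "sme")
  expect_equal(single$bandwidth, 1.0)
  expect_equal(nrow(single$candidates), 1L)
  # full grid: reported rss is the minimum over succeeding candidates
  sel <- select_estimate(lin, ds, method = "sme")
  expect_equal(sel$rss, min(sel$candidates$rss, na.rm = TRUE))
  expect_true(sel$bandwidth %in% sel$candidates$bandwidth)
  # permuting the candidate grid does not change the selection
  sel2 <- select_estimate(lin, ds, bandwidths = rev(sel$candidates$bandwidth),
                          method = "sme")
  expect_equal(sel2$eta_bar, sel$eta_bar)
  # all candidates failing raises an aggregate error listing causes
  expect_error(
    select_estimate(lin, ds, bandwidths = 1e-6, method = "sme",
                    min_points = 30L),
    class = "odestep_all_candidates_failed")
})
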