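# quadrature criterion used by both the closed forms and the brute-force
# oracles below (trapezoid weights, optional interior trimming)
sme_criterion <- function(model, fit, theta, trim = 0.05) {
  w <- odestep:::interior_weights(fit$grid, trim)
  s <- 0
  for (k in seq_along(fit$grid)) {
    r <- fit$xhat_prime[k, ] - model$rhs(fit$xhat[k, ], theta, fit$grid[k])
    s <- s + w[k] * sum(r^2)
  }
  s
}

integral_criterion <- function(model, fit, xi, theta) {
  Fm <- t(vapply(seq_along(fit$grid), function(k)
    model$rhs(fit$xhat[k, ], theta, fit$grid[k]), numeric(model$d)))
  if (model$d == 1L) Fm <- matrix(Fm, ncol = 1)
  cumF <- odestep:::cumtrapz(fit$grid, Fm)
  w <- odestep:::trapz_weights(fit$grid)
  s <- 0
  for (i in seq_len(model$d))
    s <- s + sum(w * (fit$xhat[, i] - xi[i] - cumF[, i])^2)
  s
}

test_that("estimators recover the truth exactly from noise-free fits", {
  lv <- ode_model("lotka_volterra")
  eta0 <- c(1, 0.5, rep(0.5, 4))
  fit <- exact_fit(lv, eta0, 0, 10, m = 1001)
  sme <- sme_estimate(lv, fit)
  expect_equal(sme$theta_hat, rep(0.5, 4), tolerance = 1e-6)
  expect_lt(sme$criterion_value, 1e-10)
  expect_equal(sme$xi_hat, c(1, 0.5), tolerance = 1e-4)
  intg <- integral_estimate(lv, fit)
  expect_equal(intg$eta, eta0, tolerance = 1e-4)
  # linear model with the exact exponential: theta-hat identically 1
  lin <- ode_model("linear")
  lfit <- exact_fit(lin, c(1, 1), 0, 10, m = 1001)
  expect_equal(sme_estimate(lin, lfit)$theta_hat, 1, tolerance = 1e-8)
  li <- integral_estimate(lin, lfit)
  expect_equal(li$xi_hat, 1, tolerance = 1e-3)
  expect_equal(li$theta_hat, 1, tolerance = 1e-3)
})

test_that("closed-form estimators match brute-force minimizers of the same criterion", {
  set.seed(21)
  lv <- ode_model("lotka_volterra")
  eta0 <- c(1, 0.5, rep(0.5, 4))
  tr <- solve_trajectory(lv, eta0, seq(0, 10, length.out = 51))
  ds <- ode_dataset(tr$times, tr$states + matrix(rnorm(102, 0, 0.05), 51, 2))
  fit <- smooth_dataset(ds, 0.8)
  # smooth-and-match: quadratic in theta, so BFGS from two starts nails it
  sme <- sme_estimate(lv, fit)
  oracle <- optim(rep(0.4, 4), function(th) sme_criterion(lv, fit, th),
                  method = "BFGS",
                  control = list(maxit = 1000, reltol = 1e-16))
  oracle <- optim(oracle$par, function(th) sme_criterion(lv, fit, th),
                  method = "BFGS",
                  control = list(maxit = 1000, reltol = 1e-16))
  expect_equal(sme$theta_hat, oracle$par, tolerance = 1e-8)
  # initial values: closed-form average equals per-coordinate minimization
  xi <- estimate_initial_values(lv, fit, sme$theta_hat)
  for (i in 1:2) {
    obj <- function(v) {
      x <- xi; x[i] <- v
      integral_criterion(lv, fit, x, sme$theta_hat)
    }
    o <- optimize(obj, xi[i] + c(-0.5, 0.5), tol = 1e-12)
    expect_equal(xi[i], o$minimum, tolerance = 1e-10)
  }
  # integral estimator: joint closed form beats/meets a numeric minimizer
  intg <- integral_estimate(lv, fit)
  oracle2 <- optim(intg$eta * 0.9, function(e)
    integral_criterion(lv, fit, e[1:2], e[3:6]), method = "BFGS",
    control = list(maxit = 2000, reltol = 1e-16))
  expect_equal(intg$eta, oracle2$par, tolerance = 1e-6)
  expect_lte(integral_criterion(lv, fit, intg$xi_hat, intg$theta_hat),
             oracle2$value * (1 + 1e-10))
})

test_that("scaling the observations of the linear model leaves theta-hat invariant", {
  set.seed(5)
  lin <- ode_model("linear")
  times <- seq(0, 10, length.out = 51)
  y <- 0.5 * exp(-times) + rnorm(51, 0, 0.02)
  for (c_scale in c(2, 10)) {
    f1 <- smooth_dataset(ode_dataset(times, y), 0.8)
    f2 <- smooth_dataset(ode_dataset(times, c_scale * y), 0.8)
    expect_equal(sme_estimate(lin, f1)$theta_hat,
                 sme_estimate(lin, f2)$theta_hat, tolerance = 1e-10)
  }
})

test_that("preliminary estimators are root-n consistent (rate check)", {
  rmse <- cached("sqrt_n_rmse", {
    lin <- ode_model("linear")
    ns <- c(51, 101, 201, 401)
    sapply(ns, function(n) {
      times <- seq(0, 10, length.out = n)
      x0 <- 0.5 * exp(-times)
      errs <- vapply(1:200, function(r) {
        set.seed(1000 + r)
        ds <- ode_dataset(times, x0 + rnorm(n, 0, 0.05))
        fit <- smooth_dataset(ds, 1.3 * n^(-1 / 3))
        integral_estimate(lin, fit)$theta_hat + 1
      }, numeric(1))
      sqrt(mean(errs^2))
    })
  })
  slope <- coef(lm(log(rmse) ~ log(c(51, 101, 201, 401))))[2]
  expect_gt(slope, -0.65)
  expect_lt(slope, -0.35)
})

test_that("partially observed systems without a reconstruction rule error cleanly", {
  lv <- ode_model("lotka_volterra")
  fit <- exact_fit(lv, c(1, 0.5, rep(0.5, 4)), 0, 10,
                   observed = c(TRUE, FALSE))
  expect_error(sme_estimate(lv, fit),
               class = "odestep_unsupported_observation_pattern")
  expect_error(integral_estimate(lv, fit),
               class = "odestep_unsupported_observation_pattern")
})

test_that("the Goodwin cascade reconstructs the unobserved repressor", {
  gw <- ode_model("goodwin")
  eta0 <- c(0, 0, 0, 1, 3, 2, 1, 0.5)
  grid <- seq(0, 80, length.out = 801)
  tr <- solve_trajectory(gw, eta0, grid)
  # x3' = theta4 x2 - theta5 x3 driven by the exact x2 recovers exact x3
  x3 <- odestep:::goodwin_reconstruct_x3(grid, tr$states[, 2], 1, 0.5, 0)
  expect_equal(x3, tr$states[, 3], tolerance = 1e-3)
  # full preliminary from an exact partial fit recovers (theta1, theta5)
  fit <- exact_fit(gw, eta0, 0, 80, m = 801,
                   observed = c(TRUE, TRUE, FALSE))
  pre <- integral_estimate(gw, fit, fixed = c(0, 0, 0, NA, 3, 2, 1, NA))
  expect_equal(pre$theta_hat[1], 1, tolerance = 0.01)
  expect_equal(pre$theta_hat[5], 0.5, tolerance = 0.01)
})
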