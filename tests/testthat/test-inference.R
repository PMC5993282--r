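test_that("the noise-variance estimator implements the pooled residual formula", {
  lin <- ode_model("linear")
  times <- c(0, 1, 2)
  x <- 0.5 * exp(-times)
  # zero residuals
  expect_equal(estimate_noise_variance(lin, c(0.5, -1),
                                       ode_dataset(times, x)), 0)
  # d = 1, n = 3, residuals (1, 1, 1):  3 / (1 * 2) = 1.5
  expect_equal(estimate_noise_variance(lin, c(0.5, -1),
                                       ode_dataset(times, x + 1)), 1.5,
               tolerance = 1e-7)
  # per-state variant on a 2-state model
  lv <- ode_model("lotka_volterra")
  tr <- solve_trajectory(lv, c(1, 0.5, rep(0.5, 4)), times)
  Y <- tr$states + cbind(rep(1, 3), rep(2, 3))
  s2 <- estimate_noise_variance(lv, c(1, 0.5, rep(0.5, 4)),
                                ode_dataset(times, Y), per_state = TRUE)
  expect_equal(s2, c(1.5, 6), tolerance = 1e-7)
  expect_error(estimate_noise_variance(lin, c(0.5, -1),
                                       ode_dataset(0.5, matrix(1))),
               class = "odestep_input")
})

test_that("Fisher information of the linear model matches closed-form integrals", {
  # x = xi e^{theta t}: entries are integrals of e^{2 theta t},
  # xi t e^{2 theta t}, xi^2 t^2 e^{2 theta t} over uniform F_T
  lin <- ode_model("linear")
  xi <- 1; theta <- 1; sig <- 0.1; T_end <- 10
  I <- fisher_information(lin, c(xi, theta), sig^2, c(0, T_end),
                          grid_size = 20001L)
  a <- integrate(function(t) exp(2 * theta * t), 0, T_end,
                 rel.tol = 1e-12)$value
  b <- integrate(function(t) xi * t * exp(2 * theta * t), 0, T_end,
                 rel.tol = 1e-12)$value
  cc <- integrate(function(t) xi^2 * t^2 * exp(2 * theta * t), 0, T_end,
                  rel.tol = 1e-12)$value
  closed <- matrix(c(a, b, b, cc), 2, 2) / (sig^2 * T_end)
  expect_equal(I / closed, matrix(1, 2, 2), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(I, t(I))
  expect_true(all(eigen(I, symmetric = TRUE)$values > 0))
})

test_that("the asymptotic variance of xi-hat does not depend on xi", {
  lin <- ode_model("linear")
  tight <- ode_options(rtol = 1e-13, atol = 1e-15)
  v <- sapply(c(0.5, 1), function(xi) {
    I <- fisher_information(lin, c(xi, -1), 0.05^2, c(0, 10),
                            grid_size = 2001L, options = tight)
    solve(I)[1, 1]
  })
  expect_equal(v[1], v[2], tolerance = 1e-10)
})

test_that("confidence intervals use the normal quantile and scale as 1/sqrt(n)", {
  I <- matrix(c(4, 1, 1, 2), 2, 2)
  ci100 <- confidence_intervals(c(1, 2), I, n = 100)
  expect_equal(attr(ci100, "level"), 0.95)
  se <- sqrt(diag(solve(I)) / 100)
  expect_equal(ci100$upper - ci100$estimate, 1.959964 * se, tolerance = 1e-6)
  ci400 <- confidence_intervals(c(1, 2), I, n = 400)
  expect_equal((ci400$upper - ci400$lower) / (ci100$upper - ci100$lower),
               rep(0.5, 2), tolerance = 1e-12)
  # duality: a value is outside the interval iff its standardized distance
  # exceeds the quantile
  truth <- c(1.1, 1.9)
  outside <- truth < ci100$lower | truth > ci100$upper
  expect_identical(outside, abs(truth - ci100$estimate) / se > 1.959964)
  expect_error(confidence_intervals(c(1, 2), matrix(0, 2, 2), 100),
               class = "odestep_singular_information")
})

test_that("the NLS baseline converges and matches linear least squares", {
  # model linear in eta: x(t) = xi + theta t  (rhs constant in x)
  toy <- define_ode_model("ramp", 1, 1,
                          rhs = function(x, theta, t) theta[1],
                          jac_x = function(x, theta, t) matrix(0, 1, 1),
                          jac_theta = function(x, theta, t) matrix(1, 1, 1),
                          G = function(x, t) matrix(1, 1, 1))
  set.seed(2)
  times <- seq(0, 10, length.out = 31)
  y <- 2 + 0.7 * times + rnorm(31, 0, 0.1)
  ds <- ode_dataset(times, y)
  fit <- nls_fit(toy, ds, eta_init = c(0, 0))
  ls <- unname(coef(lm(y ~ times)))
  expect_true(fit$converged)
  expect_equal(fit$eta, ls, tolerance = 1e-8)
  # noise-free start at the truth: immediate convergence at the truth
  lv <- ode_model("lotka_volterra")
  eta0 <- c(1, 0.5, rep(0.5, 4))
  tr <- solve_trajectory(lv, eta0, seq(0, 10, length.out = 21))
  nf <- nls_fit(lv, ode_dataset(tr$times, tr$states), eta_init = eta0)
  expect_true(nf$converged)
  expect_equal(nf$eta, eta0, tolerance = 1e-8)
  expect_lt(nf$rss, 1e-12)
  # accepted iterations never increase the criterion
  set.seed(3)
  dsn <- ode_dataset(tr$times, tr$states + matrix(rnorm(42, 0, 0.05), 21, 2))
  f1 <- nls_fit(lv, dsn, eta_init = eta0 * 1.2, max_iter = 1)
  f5 <- nls_fit(lv, dsn, eta_init = eta0 * 1.2, max_iter = 5)
  full <- nls_fit(lv, dsn, eta_init = eta0 * 1.2)
  expect_lte(f5$rss, f1$rss)
  expect_lte(full$rss, f5$rss)
})

test_that("the NLS baseline agrees with an independent Levenberg-Marquardt solver", {
  skip_if_not_installed("minpack.lm")
  set.seed(4)
  lin <- ode_model("linear")
  times <- seq(0, 10, length.out = 31)
  y <- 0.5 * exp(-times) + rnorm(31, 0, 0.05)
  ds <- ode_dataset(times, y)
  ours <- nls_fit(lin, ds, eta_init = c(0.4, -0.8))
  ref <- minpack.lm::nls.lm(
    par = c(0.4, -0.8),
    fn = function(p) y - p[1] * exp(p[2] * times),
    control = minpack.lm::nls.lm.control(ftol = 1e-12, ptol = 1e-12))
  expect_equal(ours$eta, unname(coef(ref)), tolerance = 1e-6)
})
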