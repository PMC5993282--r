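#' Built-in model registry
#'
#' Returns one of the benchmark systems shipped with the package, addressed
#' by name:
#'
#' * `"linear"`: scalar exponential growth/decay `x' = theta * x`.
#' * `"lotka_volterra"`: two-species predator-prey system with rates
#'   `(theta1, ..., theta4)`.
#' * `"robertson"`: the classical stiff three-species chemical kinetics
#'   benchmark; the state sum is conserved.
#' * `"goodwin"`: the three-state Goodwin oscillator for negative-feedback
#'   gene regulation (Hill coefficient 10); in the standard estimation
#'   setup only `(theta1, theta5)` are free and `x3` is unobserved.
#' * `"nitrogen_oxide"`: reversible gas-phase oxidation of nitric oxide,
#'   `x' = theta1 (126.2 - x)(91.9 - x)^2 - theta2 x^2`.
#' * `"alpha_pinene"`: five-state linear kinetics of the thermal
#'   isomerization of alpha-pinene.
#'
#' All registry models carry analytic Jacobians and, where the right-hand
#' side is linear in `theta`, the `G`/`g0` decomposition used by the
#' closed-form preliminary estimators.  Goodwin is nonlinear in `theta2`
#' but linear in the customarily estimated pair `(theta1, theta5)`; its
#' partially observed preliminary estimator is handled by a dedicated
#' cascade construction in [integral_estimate()].
#'
#' @param name one of `registry_names()`.
#' @return An [ode_model][define_ode_model] object.
#' @examples
#' m <- ode_model("lotka_volterra")
#' evaluate_rhs(m, c(1, 0.5), rep(0.5, 4))
#' @export
ode_model <- function(name) {
  builders <- registry_builders()
  if (!name %in% names(builders))
    stop_odestep("lookup", sprintf(
      "unknown model '%s'; available: %s", name,
      paste(names(builders), collapse = ", ")))
  builders[[name]]()
}

#' @rdname ode_model
#' @export
registry_names <- function() names(registry_builders())

registry_builders <- function() list(
  linear = model_linear,
  lotka_volterra = model_lotka_volterra,
  robertson = model_robertson,
  goodwin = model_goodwin,
  nitrogen_oxide = model_nitrogen_oxide,
  alpha_pinene = model_alpha_pinene)

model_linear <- function() {
  define_ode_model(
    name = "linear", d = 1L, p = 1L,
    rhs = function(x, theta, t) theta[1L] * x,
    jac_x = function(x, theta, t) matrix(theta[1L], 1L, 1L),
    jac_theta = function(x, theta, t) matrix(x[1L], 1L, 1L),
    G = function(x, t) matrix(x[1L], 1L, 1L),
    second = list(
      f_xx = function(x, theta, t) array(0, c(1, 1, 1)),
      f_xth = function(x, theta, t) array(1, c(1, 1, 1)),
      f_thth = function(x, theta, t) array(0, c(1, 1, 1))),
    state_names = "x", param_names = "theta")
}

model_lotka_volterra <- function() {
  define_ode_model(
    name = "lotka_volterra", d = 2L, p = 4L,
    rhs = function(x, theta, t)
      c(theta[1L] * x[1L] - theta[2L] * x[1L] * x[2L],
        -theta[3L] * x[2L] + theta[4L] * x[1L] * x[2L]),
    jac_x = function(x, theta, t)
      matrix(c(theta[1L] - theta[2L] * x[2L], theta[4L] * x[2L],
               -theta[2L] * x[1L], -theta[3L] + theta[4L] * x[1L]), 2L, 2L),
    jac_theta = function(x, theta, t)
      matrix(c(x[1L], 0, -x[1L] * x[2L], 0,
               0, -x[2L], 0, x[1L] * x[2L]), 2L, 4L),
    G = function(x, t)
      matrix(c(x[1L], 0, -x[1L] * x[2L], 0,
               0, -x[2L], 0, x[1L] * x[2L]), 2L, 4L),
    state_names = c("prey", "predator"))
}

model_robertson <- function() {
  define_ode_model(
    name = "robertson", d = 3L, p = 3L,
    rhs = function(x, theta, t)
      c(theta[1L] * x[2L] * x[3L] - theta[2L] * x[1L],
        theta[2L] * x[1L] - theta[1L] * x[2L] * x[3L] - theta[3L] * x[2L]^2,
        theta[3L] * x[2L]^2),
    jac_x = function(x, theta, t)
      matrix(c(-theta[2L], theta[2L], 0,
               theta[1L] * x[3L], -theta[1L] * x[3L] - 2 * theta[3L] * x[2L],
               2 * theta[3L] * x[2L],
               theta[1L] * x[2L], -theta[1L] * x[2L], 0), 3L, 3L),
    jac_theta = function(x, theta, t)
      matrix(c(x[2L] * x[3L], -x[2L] * x[3L], 0,
               -x[1L], x[1L], 0,
               0, -x[2L]^2, x[2L]^2), 3L, 3L),
    G = function(x, t)
      matrix(c(x[2L] * x[3L], -x[2L] * x[3L], 0,
               -x[1L], x[1L], 0,
               0, -x[2L]^2, x[2L]^2), 3L, 3L),
    stiff = TRUE)
}

model_goodwin <- function() {
  # hill(x3) = 1 / (1 + theta2 * x3^10)
  define_ode_model(
    name = "goodwin", d = 3L, p = 5L,
    rhs = function(x, theta, t) {
      hill <- 1 / (1 + theta[2L] * x[3L]^10)
      c(theta[1L] * hill - theta[5L] * x[1L],
        theta[3L] * x[1L] - theta[5L] * x[2L],
        theta[4L] * x[2L] - theta[5L] * x[3L])
    },
    jac_x = function(x, theta, t) {
      den <- (1 + theta[2L] * x[3L]^10)
      dhill <- -10 * theta[2L] * x[3L]^9 / den^2
      matrix(c(-theta[5L], theta[3L], 0,
               0, -theta[5L], theta[4L],
               theta[1L] * dhill, 0, -theta[5L]), 3L, 3L)
    },
    jac_theta = function(x, theta, t) {
      den <- (1 + theta[2L] * x[3L]^10)
      matrix(c(1 / den, 0, 0,
               -theta[1L] * x[3L]^10 / den^2, 0, 0,
               0, x[1L], 0,
               0, 0, x[2L],
               -x[1L], -x[2L], -x[3L]), 3L, 5L)
    },
    state_names = c("mRNA", "protein", "repressor"))
}

model_nitrogen_oxide <- function() {
  define_ode_model(
    name = "nitrogen_oxide", d = 1L, p = 2L,
    rhs = function(x, theta, t)
      theta[1L] * (126.2 - x[1L]) * (91.9 - x[1L])^2 - theta[2L] * x[1L]^2,
    jac_x = function(x, theta, t)
      matrix(theta[1L] * (-(91.9 - x[1L])^2 -
                            2 * (126.2 - x[1L]) * (91.9 - x[1L])) -
               2 * theta[2L] * x[1L], 1L, 1L),
    jac_theta = function(x, theta, t)
      matrix(c((126.2 - x[1L]) * (91.9 - x[1L])^2, -x[1L]^2), 1L, 2L),
    G = function(x, t)
      matrix(c((126.2 - x[1L]) * (91.9 - x[1L])^2, -x[1L]^2), 1L, 2L),
    second = list(
      f_xx = function(x, theta, t)
        array(theta[1L] * (4 * (91.9 - x[1L]) + 2 * (126.2 - x[1L])) -
                2 * theta[2L], c(1, 1, 1)),
      f_xth = function(x, theta, t)
        array(c(-(91.9 - x[1L])^2 - 2 * (126.2 - x[1L]) * (91.9 - x[1L]),
                -2 * x[1L]), c(1, 1, 2)),
      f_thth = function(x, theta, t) array(0, c(1, 2, 2))),
    state_names = "NO2")
}

model_alpha_pinene <- function() {
  define_ode_model(
    name = "alpha_pinene", d = 5L, p = 5L,
    rhs = function(x, theta, t)
      c(-(theta[1L] + theta[2L]) * x[1L],
        theta[1L] * x[1L],
        theta[2L] * x[1L] - (theta[3L] + theta[4L]) * x[3L] + theta[5L] * x[5L],
        theta[3L] * x[3L],
        theta[4L] * x[3L] - theta[5L] * x[5L]),
    jac_x = function(x, theta, t) {
      J <- matrix(0, 5L, 5L)
      J[1L, 1L] <- -(theta[1L] + theta[2L])
      J[2L, 1L] <- theta[1L]
      J[3L, 1L] <- theta[2L]; J[3L, 3L] <- -(theta[3L] + theta[4L])
      J[3L, 5L] <- theta[5L]
      J[4L, 3L] <- theta[3L]
      J[5L, 3L] <- theta[4L]; J[5L, 5L] <- -theta[5L]
      J
    },
    jac_theta = function(x, theta, t) alpha_pinene_G(x),
    G = function(x, t) alpha_pinene_G(x),
    state_names = c("pinene", "dipentene", "alloocimene", "pyronene", "dimer"))
}

alpha_pinene_G <- function(x) {
  J <- matrix(0, 5L, 5L)
  J[1L, 1L] <- -x[1L]; J[2L, 1L] <- x[1L]
  J[1L, 2L] <- -x[1L]; J[3L, 2L] <- x[1L]
  J[3L, 3L] <- -x[3L]; J[4L, 3L] <- x[3L]
  J[3L, 4L] <- -x[3L]; J[5L, 4L] <- x[3L]
  J[3L, 5L] <- x[5L]; J[5L, 5L] <- -x[5L]
  J
}
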