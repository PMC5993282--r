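#' Define an ODE model
#'
#' Constructs the model object used throughout the package: a first-order
#' autonomous system `x'(t) = F(x, theta)` of dimension `d` with a
#' `p`-dimensional rate parameter `theta` and initial condition
#' `x(t_1) = xi`.  The combined parameter is `eta = (xi, theta)`.
#'
#' Analytic Jacobians are strongly recommended; when omitted they are
#' replaced by central finite differences of `rhs`.  If the right-hand side
#' is linear in `theta`, i.e. `F(x, theta) = G(x, t) %*% theta + g0(x, t)`,
#' supplying the decomposition via `G` and `g0` unlocks closed-form
#' preliminary estimators.
#'
#' @param name model identifier.
#' @param d state dimension.
#' @param p parameter dimension.
#' @param rhs function `(x, theta, t)` returning the length-`d` derivative.
#' @param jac_x function `(x, theta, t)` returning the `d x d` matrix
#'   `dF/dx`; `NULL` for a finite-difference fallback.
#' @param jac_theta function `(x, theta, t)` returning the `d x p` matrix
#'   `dF/dtheta`; `NULL` for a finite-difference fallback.
#' @param G,g0 optional parameter-linearity decomposition: `G(x, t)` is
#'   `d x p`, `g0(x, t)` a `d`-vector, with
#'   `rhs(x, theta, t) == G(x, t) %*% theta + g0(x, t)`.
#' @param second optional list of analytic second derivatives with elements
#'   `f_xx` (`d x d x d` array, `[i, a, b] = d2 F_i / dx_a dx_b`),
#'   `f_xth` (`d x d x p`, `[i, a, k] = d2 F_i / dx_a dtheta_k`) and
#'   `f_thth` (`d x p x p`), each a function `(x, theta, t)`.  When absent,
#'   central finite differences of the Jacobians are used.
#' @param stiff logical hint; stiff models are integrated with an implicit
#'   (backward-differentiation) method by default.
#' @param state_names,param_names labels for states and parameters.
#'
#' @return An object of class `ode_model`.
#' @seealso [ode_model()] for the built-in registry,
#'   [solve_trajectory()], [integrate_sensitivities()].
#' @export
define_ode_model <- function(name, d, p, rhs,
                             jac_x = NULL, jac_theta = NULL,
                             G = NULL, g0 = NULL, second = NULL,
                             stiff = FALSE,
                             state_names = paste0("x", seq_len(d)),
                             param_names = paste0("theta", seq_len(p))) {
  stopifnot(is.function(rhs), d >= 1L, p >= 1L)
  if (is.null(jac_x)) jac_x <- fd_jac_x(rhs, d)
  if (is.null(jac_theta)) jac_theta <- fd_jac_theta(rhs, d, p)
  if (!is.null(G) && is.null(g0)) g0 <- function(x, t) numeric(d)
  m <- structure(list(name = name, d = as.integer(d), p = as.integer(p),
                      rhs = rhs, jac_x = jac_x, jac_theta = jac_theta,
                      G = G, g0 = g0, second = second, stiff = isTRUE(stiff),
                      state_names = state_names, param_names = param_names),
                 class = "ode_model")
  m
}

#' @export
print.ode_model <- function(x, ...) {
  cat(sprintf("<ode_model '%s'>  d = %d state(s): %s;  p = %d parameter(s): %s%s%s\n",
              x$name, x$d, paste(x$state_names, collapse = ", "),
              x$p, paste(x$param_names, collapse = ", "),
              if (!is.null(x$G)) ";  linear in theta" else "",
              if (x$stiff) ";  stiff" else ""))
  invisible(x)
}

fd_jac_x <- function(rhs, d) {
  function(x, theta, t) {
    J <- matrix(0, d, d)
    for (a in seq_len(d)) {
      h <- 1e-6 * (1 + abs(x[a]))
      e <- numeric(d); e[a] <- h
      J[, a] <- (rhs(x + e, theta, t) - rhs(x - e, theta, t)) / (2 * h)
    }
    J
  }
}

fd_jac_theta <- function(rhs, d, p) {
  function(x, theta, t) {
    J <- matrix(0, d, p)
    for (k in seq_len(p)) {
      h <- 1e-6 * (1 + abs(theta[k]))
      e <- numeric(p); e[k] <- h
      J[, k] <- (rhs(x, theta + e, t) - rhs(x, theta - e, t)) / (2 * h)
    }
    J
  }
}

#' Evaluate the right-hand side of a model
#'
#' @param model an [ode_model][define_ode_model] object.
#' @param x state vector (length `d`).
#' @param theta parameter vector (length `p`).
#' @param t time (used only by time-augmented models; defaults to 0).
#' @return The length-`d` derivative `F(x, theta)`.
#' @export
evaluate_rhs <- function(model, x, theta, t = 0) {
  check_numeric(x, model$d, "x")
  check_numeric(theta, model$p, "theta")
  f <- model$rhs(as.numeric(x), as.numeric(theta), t)
  if (length(f) != model$d)
    stop_odestep("input", "rhs returned wrong dimension")
  f
}

#' Evaluate the state and parameter Jacobians of a model
#'
#' @inheritParams evaluate_rhs
#' @return A list with `jx` (`d x d` matrix `dF/dx`) and
#'   `jtheta` (`d x p` matrix `dF/dtheta`).
#' @export
evaluate_jacobians <- function(model, x, theta, t = 0) {
  check_numeric(x, model$d, "x")
  check_numeric(theta, model$p, "theta")
  list(jx = model$jac_x(as.numeric(x), as.numeric(theta), t),
       jtheta = model$jac_theta(as.numeric(x), as.numeric(theta), t))
}

#' Integrator settings
#'
#' @param rtol,atol relative/absolute integration tolerances.
#' @param method deSolve method; `NULL` selects `"lsoda"` for non-stiff and
#'   `"bdf"` for models flagged stiff.
#' @param maxsteps maximal number of internal steps per output interval.
#' @return A list of settings passed to the integration routines.
#' @export
ode_options <- function(rtol = 1e-8, atol = 1e-10, method = NULL,
                        maxsteps = 50000L) {
  list(rtol = rtol, atol = atol, method = method, maxsteps = maxsteps)
}

desolve_method <- function(model, options) {
  options$method %||% if (model$stiff) "bdf" else "lsoda"
}

run_desolve <- function(y0, times, func, model, options, what) {
  meth <- desolve_method(model, options)
  out <- tryCatch(
    suppressWarnings(deSolve::ode(y = y0, times = times, func = func,
                                  parms = NULL, method = meth,
                                  rtol = options$rtol, atol = options$atol,
                                  maxsteps = options$maxsteps)),
    error = function(e) e)
  bad <- inherits(out, "error") || nrow(out) < length(times) ||
    anyNA(out) || any(!is.finite(out))
  if (bad) {
    t_fail <- if (inherits(out, "error") || nrow(out) == 0) times[1L] else {
      ok <- apply(out, 1L, function(r) all(is.finite(r)))
      times[min(which(!ok), nrow(out) + 1L, na.rm = TRUE)]
    }
    stop_odestep("integration",
                 sprintf("integration of %s for model '%s' failed near t = %g",
                         what, model$name, t_fail),
                 time = t_fail)
  }
  out
}

#' Integrate a model trajectory
#'
#' Solves the initial value problem for `eta = (xi, theta)` with
#' `x(times[1]) = xi` and returns the solution at the requested times.
#' Models flagged stiff use an implicit (BDF) integrator.
#'
#' @param model an [ode_model][define_ode_model] object.
#' @param eta numeric vector `c(xi, theta)` of length `d + p`.
#' @param times increasing time vector; the trajectory is anchored at
#'   `times[1]`.
#' @param options integrator settings from [ode_options()].
#' @return An object of class `ode_trajectory`: list with `times`,
#'   `states` (an `n x d` matrix) and `eta`.
#' @export
solve_trajectory <- function(model, eta, times, options = ode_options()) {
  check_numeric(eta, model$d + model$p, "eta")
  if (is.unsorted(times, strictly = TRUE))
    stop_odestep("input", "times must be strictly increasing")
  xi <- eta[seq_len(model$d)]
  theta <- eta[model$d + seq_len(model$p)]
  func <- function(t, y, parms) list(model$rhs(y, theta, t))
  out <- run_desolve(xi, times, func, model, options, "the state equation")
  structure(list(times = times,
                 states = matrix(out[, -1L, drop = FALSE],
                                 nrow = length(times),
                                 dimnames = list(NULL, model$state_names)),
                 eta = eta),
            class = "ode_trajectory")
}

# second-derivative tensors, analytic when supplied, else central finite
# differences of the Jacobians (step 1e-5 * (1 + |value|))
model_second <- function(model) {
  if (!is.null(model$second)) return(model$second)
  d <- model$d; p <- model$p
  list(
    f_xx = function(x, theta, t) {
      A <- array(0, c(d, d, d))
      for (b in seq_len(d)) {
        h <- 1e-5 * (1 + abs(x[b])); e <- numeric(d); e[b] <- h
        A[, , b] <- (model$jac_x(x + e, theta, t) -
                       model$jac_x(x - e, theta, t)) / (2 * h)
      }
      A
    },
    f_xth = function(x, theta, t) {
      A <- array(0, c(d, d, p))
      for (k in seq_len(p)) {
        h <- 1e-5 * (1 + abs(theta[k])); e <- numeric(p); e[k] <- h
        A[, , k] <- (model$jac_x(x, theta + e, t) -
                       model$jac_x(x, theta - e, t)) / (2 * h)
      }
      A
    },
    f_thth = function(x, theta, t) {
      A <- array(0, c(d, p, p))
      for (k in seq_len(p)) {
        h <- 1e-5 * (1 + abs(theta[k])); e <- numeric(p); e[k] <- h
        A[, , k] <- (model$jac_theta(x, theta + e, t) -
                       model$jac_theta(x, theta - e, t)) / (2 * h)
      }
      A
    })
}

#' Reduce a non-autonomous model to autonomous form
#'
#' Wraps a right-hand side that depends explicitly on time,
#' `x'(t) = F(x, t, theta)`, as an autonomous system by appending time as an
#' extra state with unit derivative.  All downstream machinery (sensitivity
#' integration, estimation) then applies unchanged; the appended clock state
#' has known initial value `times[1]` and is never observed.
#'
#' @param model an [ode_model][define_ode_model] whose `rhs`/Jacobians use
#'   their `t` argument.
#' @return An `ode_model` of dimension `d + 1` whose last state is time.
#' @export
augment_time <- function(model) {
  d <- model$d; p <- model$p
  define_ode_model(
    name = paste0(model$name, "_autonomous"), d = d + 1L, p = p,
    rhs = function(x, theta, t) c(model$rhs(x[seq_len(d)], theta, x[d + 1L]), 1),
    jac_x = function(x, theta, t) {
      J <- matrix(0, d + 1L, d + 1L)
      J[seq_len(d), seq_len(d)] <- model$jac_x(x[seq_len(d)], theta, x[d + 1L])
      # column for the clock state: explicit time derivative of F
      h <- 1e-6 * (1 + abs(x[d + 1L]))
      J[seq_len(d), d + 1L] <-
        (model$rhs(x[seq_len(d)], theta, x[d + 1L] + h) -
           model$rhs(x[seq_len(d)], theta, x[d + 1L] - h)) / (2 * h)
      J
    },
    jac_theta = function(x, theta, t)
      rbind(model$jac_theta(x[seq_len(d)], theta, x[d + 1L]), 0),
    stiff = model$stiff,
    state_names = c(model$state_names, ".time"),
    param_names = model$param_names)
}
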