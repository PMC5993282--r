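# internal numerical helpers

# trapezoid-rule weights for an (increasing, possibly non-uniform) grid
trapz_weights <- function(t) {
  n <- length(t)
  if (n < 2L) stop("need at least two grid points for quadrature")
  dt <- diff(t)
  w <- numeric(n)
  w[1L] <- dt[1L] / 2
  w[n] <- dt[n - 1L] / 2
  if (n > 2L) w[2:(n - 1L)] <- (dt[-(n - 1L)] + dt[-1L]) / 2
  w
}

trapz <- function(t, y) sum(trapz_weights(t) * y)

# cumulative trapezoid integral of each column of y along t; first row is 0
cumtrapz <- function(t, y) {
  y <- as.matrix(y)
  dt <- diff(t)
  inc <- (y[-nrow(y), , drop = FALSE] + y[-1L, , drop = FALSE]) / 2 * dt
  rbind(0, apply(inc, 2L, cumsum))
}

# matrix inverse via SVD; tolerates extreme ill-conditioning (the Fisher
# information of badly scaled kinetic constants can have condition numbers
# beyond what solve() accepts, yet its exact inverse is still the quantity
# the plug-in variance formula calls for)
svd_inverse <- function(m) {
  s <- svd((m + t(m)) / 2)
  if (any(s$d <= 0)) stop_odestep("singular_information",
    sprintf("information matrix is singular (min singular value %.3e, condition %.3e)",
            min(s$d), max(s$d) / max(min(s$d), .Machine$double.xmin)))
  s$v %*% (t(s$u) / s$d)
}

stop_odestep <- function(class, message, ...) {
  stop(structure(class = c(paste0("odestep_", class), "odestep_error",
                           "error", "condition"),
                 list(message = message, call = sys.call(-1L), ...)))
}

check_numeric <- function(x, len, what) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x)))
    stop_odestep("input", sprintf("%s must be finite numeric", what))
  if (!missing(len) && length(x) != len)
    stop_odestep("input", sprintf("%s must have length %d, got %d",
                                  what, len, length(x)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
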