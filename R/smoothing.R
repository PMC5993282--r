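#' Local polynomial trajectory and derivative estimate for one state
#'
#' Fits, at every evaluation grid point, a weighted polynomial of the given
#' degree in time centred at that point, using an Epanechnikov kernel with
#' the supplied bandwidth.  The fitted intercept estimates the trajectory
#' value and the fitted slope its derivative.  Windows near the boundary
#' are asymmetric; no reflection or truncation tricks are applied.
#'
#' By default a window that contains fewer than `min_points` observations
#' is widened to the nearest `min_points` observations (a nearest-neighbour
#' floor, as in classical local regression), so that every candidate
#' bandwidth in a data-driven grid yields a well-defined fit even for
#' sparse designs.  With `expand = FALSE` such windows raise a
#' singular-window error naming the grid point instead.
#'
#' @param times increasing observation times.
#' @param y observations of one state at `times`.
#' @param bandwidth kernel half-width, in time units.
#' @param degree polynomial degree (default 2: local quadratic, which gives
#'   low-bias derivative estimates).
#' @param grid evaluation times (defaults to `times`).
#' @param expand widen deficient windows instead of failing.
#' @param min_points minimal number of observations per window; default
#'   `degree + 2` so every fit retains a residual degree of freedom.
#' @return A list with `value` and `deriv` (length of `grid`), and
#'   `bandwidth_used`, the possibly widened per-point half-width.
#' @export
local_poly_fit <- function(times, y, bandwidth, degree = 2L, grid = times,
                           expand = TRUE, min_points = degree + 2L) {
  check_numeric(times, what = "times")
  check_numeric(y, length(times), "y")
  if (is.unsorted(times, strictly = TRUE))
    stop_odestep("input", "times must be strictly increasing")
  if (!is.numeric(bandwidth) || bandwidth <= 0)
    stop_odestep("input", "bandwidth must be positive")
  if (degree < 0) stop_odestep("input", "degree must be >= 0")
  out <- tryCatch(
    local_poly_cpp(as.numeric(times), as.numeric(y), bandwidth,
                   as.integer(degree), as.numeric(grid), isTRUE(expand),
                   as.integer(max(min_points, degree + 1L))),
    error = function(e) {
      if (grepl("singular", conditionMessage(e)))
        stop_odestep("singular_window", conditionMessage(e))
      stop(e)
    })
  lapply(out, as.numeric)
}

#' Bandwidth candidate grid
#'
#' Builds the candidate set of bandwidths `n^(-1/3) * c` for `N` equispaced
#' multipliers `c` between `c_min` and `c_max`.  The `n^(-1/3)` rate is the
#' one under which the smoothing-based preliminary estimators retain the
#' root-n convergence rate required by the one-step correction.
#'
#' The multipliers are calibrated for a design spanning 10 time units; for
#' another horizon supply `span` and the values are rescaled by `span / 10`.
#'
#' @param n sample size.
#' @param N number of candidates.
#' @param c_min,c_max smallest and largest multiplier.
#' @param span time-span of the design (default 10).
#' @return An object of class `bandwidth_grid`: list with `values`
#'   (increasing bandwidths), `n` and the multiplier vector `c`.
#' @export
bandwidth_grid <- function(n, N = 10L, c_min = 0.02, c_max = 3, span = 10) {
  if (N < 1L) stop_odestep("input", "N must be >= 1")
  if (!(c_min > 0 && c_max >= c_min))
    stop_odestep("input", "need 0 < c_min <= c_max")
  cs <- if (N == 1L) c_min else seq(c_min, c_max, length.out = N)
  structure(list(values = n^(-1 / 3) * cs * (span / 10), n = n, c = cs),
            class = "bandwidth_grid")
}

#' Smooth every observed state of a dataset
#'
#' Applies [local_poly_fit()] to each observed state on a shared
#' equispaced evaluation grid spanning the design, producing the smoothed
#' trajectory and derivative that the preliminary estimators consume.
#' Unobserved states are flagged in `observed_mask` and their columns are
#' `NA`, never silently zero.
#'
#' @param dataset an [ode_dataset()].
#' @param bandwidth kernel half-width.
#' @param degree polynomial degree (default 2).
#' @param grid_size number of evaluation points (default
#'   `max(n, 101)`).
#' @param expand,min_points window handling, see [local_poly_fit()].
#' @return An object of class `smooth_fit`: list with `grid`, matrices
#'   `xhat` and `xhat_prime` (`grid_size x d`), `bandwidth`, `degree` and
#'   `observed_mask`.
#' @export
smooth_dataset <- function(dataset, bandwidth, degree = 2L,
                           grid_size = NULL, expand = TRUE,
                           min_points = degree + 2L) {
  stopifnot(inherits(dataset, "ode_dataset"))
  n <- length(dataset$times)
  d <- ncol(dataset$Y)
  if (!any(dataset$observed)) stop_odestep("input", "no observed states")
  m <- grid_size %||% max(n, 101L)
  grid <- seq(dataset$times[1L], dataset$times[n], length.out = m)
  xhat <- matrix(NA_real_, m, d)
  xhat_prime <- matrix(NA_real_, m, d)
  for (i in which(dataset$observed)) {
    f <- local_poly_fit(dataset$times, dataset$Y[, i], bandwidth,
                        degree = degree, grid = grid, expand = expand,
                        min_points = min_points)
    xhat[, i] <- f$value
    xhat_prime[, i] <- f$deriv
  }
  structure(list(grid = grid, xhat = xhat, xhat_prime = xhat_prime,
                 bandwidth = bandwidth, degree = as.integer(degree),
                 observed_mask = dataset$observed),
            class = "smooth_fit")
}

#' @export
as.data.frame.smooth_fit <- function(x, ...) {
  d <- ncol(x$xhat)
  out <- data.frame(time = x$grid)
  for (i in seq_len(d)) {
    out[[paste0("xhat", i)]] <- x$xhat[, i]
    out[[paste0("dxhat", i)]] <- x$xhat_prime[, i]
  }
  out
}
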