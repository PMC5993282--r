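#' Time-course dataset
#'
#' Container for noisy observations of an ODE system: a strictly increasing
#' time vector and an `n x d` observation matrix.  A state is either
#' observed at all times or at none; fully missing columns (all `NA`) are
#' flagged in `observed`.
#'
#' @param times length-`n` strictly increasing time vector.
#' @param Y `n x d` numeric matrix (or vector when `d = 1`); a completely
#'   `NA` column marks an unobserved state.
#' @param observed optional logical length-`d` override of the
#'   missing-state flags.
#' @param meta optional provenance list (scenario name, seed, replicate).
#' @return An object of class `ode_dataset`.
#' @export
ode_dataset <- function(times, Y, observed = NULL, meta = list()) {
  Y <- as.matrix(Y)
  check_numeric(times, nrow(Y), "times")
  if (is.unsorted(times, strictly = TRUE))
    stop_odestep("input", "times must be strictly increasing")
  auto <- apply(Y, 2L, function(col) !all(is.na(col)))
  observed <- observed %||% auto
  if (!any(observed)) stop_odestep("input", "at least one state must be observed")
  for (i in which(observed)) if (anyNA(Y[, i]))
    stop_odestep("input", sprintf(
      "state %d is flagged observed but contains missing values; missingness must be whole-state", i))
  structure(list(times = as.numeric(times), Y = Y,
                 observed = as.logical(observed), meta = meta),
            class = "ode_dataset")
}

#' @export
print.ode_dataset <- function(x, ...) {
  cat(sprintf("<ode_dataset> n = %d times on [%g, %g], %d state(s) (%d observed)\n",
              length(x$times), x$times[1L], x$times[length(x$times)],
              ncol(x$Y), sum(x$observed)))
  invisible(x)
}

#' Read / write a time-course CSV
#'
#' The dialect is a comma-separated file with header `time,y1,...,yd`,
#' missing entries empty, no row names.
#'
#' @param path file path.
#' @return [read_dataset()] returns an [ode_dataset()];
#'   [write_dataset()] invisibly returns `path`.
#' @export
read_dataset <- function(path) {
  df <- read.csv(path, header = TRUE)
  if (names(df)[1L] != "time")
    stop_odestep("input", "first CSV column must be named 'time'")
  ode_dataset(df$time, as.matrix(df[, -1L, drop = FALSE]),
              meta = list(source = path))
}

#' @rdname read_dataset
#' @param dataset an [ode_dataset()].
#' @export
write_dataset <- function(dataset, path) {
  df <- data.frame(time = dataset$times)
  for (i in seq_len(ncol(dataset$Y)))
    df[[paste0("y", i)]] <- dataset$Y[, i]
  write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}
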