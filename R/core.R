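#' Evenly spaced normalized time grid
#'
#' Returns the canonical time grid used throughout the package: `n` points
#' `i/(n-1)` for `i = 0, ..., n-1`, so the first point is 0 and the last is 1.
#' All estimators operate on this normalized scale; raw timestamps (calendar
#' months, seconds, ...) are mapped onto it affinely and never seen by the
#' fitting code.
#'
#' @param n Number of grid points; must be at least 2.
#' @return Numeric vector of length `n`, strictly increasing from 0 to 1.
#' @examples
#' normalize_time(3)  # 0, 0.5, 1
#' @export
normalize_time <- function(n) {
  if (length(n) != 1L || !is.finite(n) || n != round(n) || n < 2)
    stop("'n' must be a single integer >= 2", call. = FALSE)
  seq.int(0L, n - 1L) / (n - 1)
}

#' Multivariate time series on a normalized grid
#'
#' Light container for an observed (possibly multivariate) series.  Values
#' are stored as a `T x p` matrix in time order together with a strictly
#' increasing time grid normalized to `[0, 1]`.
#'
#' @param x Numeric vector (univariate) or matrix/data frame with one column
#'   per component and one row per time point.
#' @param times Optional raw numeric timestamps, affinely rescaled to
#'   `[0, 1]`.  Defaults to equal spacing by row order.
#' @return Object of class `"tvar_series"`: list with `values` (T x p
#'   matrix), `times`, `p` and `n_time`.
#' @export
tvar_series <- function(x, times = NULL) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.vector(x) && is.numeric(x)) x <- matrix(x, ncol = 1L)
  if (!is.matrix(x) || !is.numeric(x))
    stop("'x' must be a numeric vector or matrix", call. = FALSE)
  storage.mode(x) <- "double"
  n <- nrow(x)
  if (n < 2L) stop("a series needs at least 2 time points", call. = FALSE)
  if (any(!is.finite(x)))
    stop("series values must be finite", call. = FALSE)
  if (is.null(times)) {
    times <- normalize_time(n)
  } else {
    if (length(times) != n)
      stop("'times' length must match the number of rows", call. = FALSE)
    if (any(!is.finite(times)) || any(diff(times) <= 0))
      stop("'times' must be finite and strictly increasing", call. = FALSE)
    times <- (times - times[1L]) / (times[n] - times[1L])
  }
  if (is.null(colnames(x)))
    colnames(x) <- if (ncol(x) == 1L) "y" else paste0("y", seq_len(ncol(x)))
  structure(list(values = x, times = as.numeric(times),
                 p = ncol(x), n_time = n),
            class = "tvar_series")
}

as_tvar_series <- function(x, times = NULL) {
  if (inherits(x, "tvar_series")) x else tvar_series(x, times)
}

#' @export
print.tvar_series <- function(x, ...) {
  cat(sprintf("Time series on [0, 1]: %d points x %d component%s (%s)\n",
              x$n_time, x$p, if (x$p > 1L) "s" else "",
              paste(colnames(x$values), collapse = ", ")))
  invisible(x)
}

#' Lagged regression design for an autoregression of order r
#'
#' Builds the response matrix and augmented lagged regressor rows used by
#' every estimator.  The row for response index `t` (0-based internally,
#' `t = r, ..., T-1`) is
#' `z_t = [1, y_1(t-1), ..., y_p(t-1), ..., y_1(t-r), ..., y_p(t-r)]`
#' (lag-major ordering: all `p` components of lag 1, then lag 2, ...).
#'
#' @param series A [tvar_series()] (or anything coercible to one).
#' @param r Lag order, a positive integer strictly less than the series
#'   length.
#' @return List with `target` ((T-r) x p response matrix), `rows`
#'   ((T-r) x (rp+1) regressor matrix whose first column is 1), `times`
#'   (response-time grid) and `r`.
#' @examples
#' d <- build_lagged_design(tvar_series(c(1, 2, 3)), r = 1)
#' d$rows    # [1 1; 1 2]
#' d$target  # 2, 3
#' @export
build_lagged_design <- function(series, r) {
  series <- as_tvar_series(series)
  if (length(r) != 1L || r != round(r) || r < 1L)
    stop("'r' must be a single positive integer", call. = FALSE)
  n <- series$n_time
  p <- series$p
  if (r >= n)
    stop(sprintf("insufficient data: need more than r = %d observations, have %d",
                 r, n), call. = FALSE)
  idx <- (r + 1L):n
  m <- length(idx)
  rows <- matrix(1, m, r * p + 1L)
  for (k in seq_len(r)) {
    cols <- 1L + (k - 1L) * p + seq_len(p)
    rows[, cols] <- series$values[idx - k, , drop = FALSE]
  }
  list(target = series$values[idx, , drop = FALSE],
       rows = rows,
       times = series$times[idx],
       r = r)
}

# Normalized time step of a fitted model's training grid.
time_step <- function(times) (times[length(times)] - times[1L]) / (length(times) - 1L)
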