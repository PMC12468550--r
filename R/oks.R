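# One-sided Gaussian-kernel smoothing: weighted constrained least squares at
# the series endpoint, with bandwidth selected by forward-chaining
# cross-validation.

#' Gaussian kernel weight
#'
#' `K_b(t, t*) = exp(-(t - t*)^2 / (2 b^2)) / sqrt(2 pi b^2)`.  The source
#' formulation prints the exponent denominator as "2b*"; it is implemented
#' as `2 b^2`, the standard Gaussian kernel.
#'
#' @param t Numeric vector of times.
#' @param t_star Target time.
#' @param b Bandwidth, in normalized-time units; must be positive.
#' @return Nonnegative weights, same length as `t`.
#' @examples
#' kernel_weight(0, 0, 1)  # 1/sqrt(2*pi)
#' @export
kernel_weight <- function(t, t_star, b) {
  if (length(b) != 1L || !is.finite(b) || b <= 0)
    stop("bandwidth 'b' must be a single positive number", call. = FALSE)
  exp(-(t - t_star)^2 / (2 * b^2)) / sqrt(2 * pi * b^2)
}

fit_oks <- function(series, r = 1, bandwidth = NULL, t_star = NULL,
                    bw_grid = c(0.05, 0.1, 0.15, 0.2, 0.3, 0.5),
                    radius = 1, constraint = c("absolute", "signed")) {
  constraint <- match.arg(constraint)
  series <- as_tvar_series(series)
  p <- series$p
  cv <- NULL
  if (is.null(bandwidth)) {
    cv <- select_bandwidth(series, r, grid = bw_grid, details = TRUE)
    bandwidth <- cv$bandwidth
  }
  if (is.null(t_star)) t_star <- series$times[series$n_time]
  if (t_star < series$times[1L] || t_star > series$times[series$n_time])
    stop("'t_star' must lie within the series time range", call. = FALSE)
  design <- build_lagged_design(series, r)
  keep <- design$times <= t_star + 1e-12
  if (sum(keep) <= r * p + 1L)
    stop("too few observations at or before t_star", call. = FALSE)
  w <- kernel_weight(design$times[keep], t_star, bandwidth)
  if (max(w) < .Machine$double.xmin ||
      sum(w > max(w) * 1e-12) <= r * p + 1L)
    stop("degenerate weights: bandwidth too small for this grid", call. = FALSE)
  X <- design$rows[keep, , drop = FALSE]
  beta <- matrix(0, r * p + 1L, p)
  objective <- numeric(p)
  constraint_value <- numeric(p)
  for (j in seq_len(p)) {
    sol <- constrained_ls(X, design$target[keep, j], weights = w,
                          penalized = 2:(r * p + 1L), radius = radius,
                          constraint = constraint)
    beta[, j] <- sol$coefficients
    objective[j] <- sol$objective
    constraint_value[j] <- sol$constraint_value
  }
  structure(list(method = "oks", r = r, p = p,
                 beta = beta, bandwidth = bandwidth, t_star = t_star,
                 radius = radius, constraint = constraint, cv = cv,
                 objective = objective, constraint_value = constraint_value,
                 times = series$times, dt = time_step(series$times),
                 series = series, labels = colnames(series$values)),
            class = c("tvar_oks", "tvar"))
}

#' Cross-validated bandwidth for one-sided kernel smoothing
#'
#' Forward-chaining (expanding window) cross-validation: for each time index
#' `tau` in the last quarter of the series, the kernel estimator is fitted at
#' `t* = t[tau]` using only data up to `tau` and scored on the one-step-ahead
#' squared forecast error at `tau + 1`.  The grid bandwidth minimizing the
#' mean score is returned (ties resolved toward the larger, smoother
#' bandwidth).
#'
#' @param series A [tvar_series()] or coercible object.
#' @param r Lag order.
#' @param grid Candidate bandwidths (positive, normalized-time units).
#' @param radius Bound on the summed absolute non-intercept coefficients.
#' @param details Return the per-bandwidth score table as well.
#' @return The selected bandwidth, or when `details = TRUE` a list with
#'   `bandwidth` and the `scores` data frame.
#' @export
select_bandwidth <- function(series, r = 1,
                             grid = c(0.05, 0.1, 0.15, 0.2, 0.3, 0.5),
                             radius = 1, details = FALSE) {
  series <- as_tvar_series(series)
  if (length(grid) < 1L) stop("bandwidth grid is empty", call. = FALSE)
  if (any(grid <= 0)) stop("bandwidths must be positive", call. = FALSE)
  n <- series$n_time
  p <- series$p
  design <- build_lagged_design(series, r)
  taus <- seq.int(max(ceiling(0.75 * n), r + r * p + 3L), n - 1L)
  if (length(taus) < 1L)
    stop("series too short for bandwidth cross-validation", call. = FALSE)
  scores <- numeric(length(grid))
  for (gi in seq_along(grid)) {
    b <- grid[gi]
    se <- 0
    for (tau in taus) {
      keep <- which(design$times <= series$times[tau] + 1e-12)
      w <- kernel_weight(design$times[keep], series$times[tau], b)
      X <- design$rows[keep, , drop = FALSE]
      znext <- design$rows[keep[length(keep)] + 1L, ]
      for (j in seq_len(p)) {
        sol <- constrained_ls(X, design$target[keep, j], weights = w,
                              penalized = 2:(r * p + 1L), radius = radius)
        pred <- sum(sol$coefficients * znext)
        se <- se + (series$values[tau + 1L, j] - pred)^2
      }
    }
    scores[gi] <- se / (length(taus) * p)
  }
  best <- grid[scores <= min(scores) + 0]
  bandwidth <- max(best)
  if (!details) return(bandwidth)
  list(bandwidth = bandwidth,
       scores = data.frame(bandwidth = grid, cv_mse = scores))
}
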