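#' Mean absolute error
#'
#' @param pred,truth Numeric vectors or matrices of equal size.
#' @return `mean(|pred - truth|)`.
#' @examples
#' mae(c(1, 2, 4), c(1, 3, 2))  # 1
#' @export
mae <- function(pred, truth) {
  if (length(pred) == 0L) stop("empty input", call. = FALSE)
  if (length(pred) != length(truth))
    stop("'pred' and 'truth' must have equal length", call. = FALSE)
  mean(abs(pred - truth))
}

#' Root sample variance
#'
#' Square root of the unbiased (n-1 denominator) sample variance; used to
#' summarize the spread of absolute forecast errors across Monte-Carlo
#' replications.
#'
#' @param x Numeric vector, length at least 2.
#' @return `sqrt(var(x))`.
#' @examples
#' rsv(c(0, 2))  # sqrt(2)
#' @export
rsv <- function(x) {
  if (length(x) < 2L) stop("need at least 2 values", call. = FALSE)
  sqrt(stats::var(x))
}

#' Roll-forward trajectory reconstruction
#'
#' Starting from the first `r` observed values, the fitted model's recursion
#' is iterated to the end of the series using its own predictions as lagged
#' inputs, so the entire trajectory is regenerated from initial conditions
#' alone.  Time for row `i` of the series is taken from the model's training
#' time map (`(i-1) * dt`), so a model trained on a prefix of the series
#' extrapolates its coefficient trajectories past `t = 1` for the remaining
#' rows.
#'
#' @param object A fitted [tvar()] model or a [truth_model()] wrapper.
#' @param series Series to reconstruct; defaults to the model's training
#'   series.
#' @return Object of class `"tvar_recon"`: list with `values`
#'   ((n-r) x p reconstructed matrix), `times`, `observed` (matching
#'   observed rows) and `mae` (mean absolute reconstruction error against
#'   the observed rows).
#' @export
tvar_reconstruct <- function(object, series = NULL) {
  stopifnot(inherits(object, "tvar"))
  if (is.null(series)) series <- object$series
  series <- as_tvar_series(series)
  r <- object$r
  p <- object$p
  if (series$p != p) stop("series dimension mismatch", call. = FALSE)
  n <- series$n_time
  if (n <= r) stop("series shorter than the lag order", call. = FALSE)
  tt <- (seq_len(n) - 1L) * object$dt
  cf <- coef_path(object, tt)
  y <- matrix(0, n, p, dimnames = list(NULL, colnames(series$values)))
  y[seq_len(r), ] <- series$values[seq_len(r), ]
  for (i in (r + 1L):n) {
    acc <- cf$intercept[i, ]
    for (k in seq_len(r))
      acc <- acc + matrix(cf$lag[i, k, , ], p, p) %*% y[i - k, ]
    if (any(!is.finite(acc)) || any(abs(acc) > 1e6))
      stop(sprintf("reconstruction diverged at time index %d", i), call. = FALSE)
    y[i, ] <- acc
  }
  observed <- series$values[(r + 1L):n, , drop = FALSE]
  values <- y[(r + 1L):n, , drop = FALSE]
  structure(list(values = values, times = tt[(r + 1L):n],
                 observed = observed, mae = mae(values, observed),
                 method = object$method, r = r),
            class = "tvar_recon")
}

#' @export
print.tvar_recon <- function(x, ...) {
  cat(sprintf("Roll-forward reconstruction (%s, r = %d): %d steps, MAE vs observed %.4g\n",
              x$method, x$r, nrow(x$values), x$mae))
  invisible(x)
}
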