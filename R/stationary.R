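# Stationary AR(r)/VAR(r) baseline: per-equation ordinary least squares on
# the lagged design, no coefficient constraint.

fit_stationary <- function(series, r = 1) {
  series <- as_tvar_series(series)
  p <- series$p
  design <- build_lagged_design(series, r)
  X <- design$rows
  if (nrow(X) <= ncol(X))
    stop("not enough observations for the stationary fit", call. = FALSE)
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("rank-deficient design matrix", call. = FALSE)
  coeffs <- qr.coef(qrX, design$target)
  coeffs <- matrix(coeffs, ncol = p)
  resid <- design$target - X %*% coeffs
  dfres <- nrow(X) - ncol(X)
  structure(list(method = "stationary", r = r, p = p,
                 coeffs = coeffs,
                 residual_variance = colSums(resid^2) / dfres,
                 times = series$times, dt = time_step(series$times),
                 series = series, labels = colnames(series$values)),
            class = c("tvar_stationary", "tvar"))
}
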