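# Varying-coefficient (basis expansion) estimator: each time-varying
# coefficient is a linear combination of fixed smooth basis functions, and
# the basis weights are fitted by least squares under an L1 bound on the
# non-intercept weights.

# Expanded design: intercept block f_j(t), then for lag k and component m
# the block f_j(t - k dt) * y_m(t - k) (lag-time evaluation; with
# lag_time_basis = FALSE the basis is evaluated at the response time t,
# the standard varying-coefficient form).
gam_design <- function(design, basis, dt, p, lag_time_basis = TRUE) {
  n <- basis$n
  r <- design$r
  tt <- design$times
  blocks <- vector("list", r * p + 1L)
  blocks[[1L]] <- eval_basis(basis, tt)
  for (k in seq_len(r)) {
    Fk <- if (lag_time_basis) eval_basis(basis, tt - k * dt)
          else blocks[[1L]]
    for (m in seq_len(p)) {
      ylag <- design$rows[, 1L + (k - 1L) * p + m]
      blocks[[1L + (k - 1L) * p + m]] <- Fk * ylag
    }
  }
  do.call(cbind, blocks)
}

fit_gam <- function(series, r = 1, basis = tvar_basis(),
                    lag_time_basis = TRUE, radius = 1,
                    constraint = c("absolute", "signed")) {
  constraint <- match.arg(constraint)
  series <- as_tvar_series(series)
  design <- build_lagged_design(series, r)
  p <- series$p
  n <- basis$n
  ncoef <- n * (r * p + 1L)
  if (nrow(design$rows) <= ncoef)
    stop(sprintf("need more than %d observations after lagging to fit %d basis weights",
                 ncoef, ncoef), call. = FALSE)
  dt <- time_step(series$times)
  G <- gam_design(design, basis, dt, p, lag_time_basis)
  penalized <- (n + 1L):ncoef
  zeta <- matrix(0, ncoef, p)
  objective <- numeric(p)
  constraint_value <- numeric(p)
  for (j in seq_len(p)) {
    sol <- constrained_ls(G, design$target[, j], penalized = penalized,
                          radius = radius, constraint = constraint)
    zeta[, j] <- sol$coefficients
    objective[j] <- sol$objective
    constraint_value[j] <- sol$constraint_value
  }
  structure(list(method = "gam", r = r, p = p,
                 zeta = zeta, basis = basis,
                 lag_time_basis = lag_time_basis, radius = radius,
                 constraint = constraint,
                 objective = objective, constraint_value = constraint_value,
                 times = series$times, dt = dt, series = series,
                 labels = colnames(series$values)),
            class = c("tvar_gam", "tvar"))
}

# Trajectories implied by the fitted basis weights, evaluated on a grid.
# coef() places the basis at the requested time for every block; prediction
# uses at_lag_time to mirror the training design exactly.
gam_trajectories <- function(fit, grid, at_lag_time = FALSE) {
  n <- fit$basis$n
  p <- fit$p
  r <- fit$r
  G <- length(grid)
  B0 <- eval_basis(fit$basis, grid)
  intercept <- B0 %*% fit$zeta[seq_len(n), , drop = FALSE]
  lag <- array(0, dim = c(G, r, p, p))
  for (k in seq_len(r)) {
    Bk <- if (at_lag_time) eval_basis(fit$basis, grid - k * fit$dt) else B0
    for (m in seq_len(p)) {
      rows <- n * (1L + (k - 1L) * p + m - 1L) + seq_len(n)
      lag[, k, , m] <- Bk %*% fit$zeta[rows, , drop = FALSE]
    }
  }
  list(grid = grid, intercept = intercept, lag = lag)
}
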