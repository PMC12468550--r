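#' Fit a time-varying (vector) autoregression
#'
#' Single entry point for the four estimators of the model
#' `Y(t) = C(t) + sum_k B_k(t) Y(t-k) + noise` on normalized time:
#'
#' * `"pinn"` — a feed-forward neural network maps `t` to the coefficient
#'   vector `[c(t), B_1(t), ..., B_r(t)]` per response dimension and is
#'   trained by minimizing the mean squared autoregressive residual with
#'   L-BFGS-B (analytic backpropagation gradients).
#' * `"gam"` — each time-varying coefficient is a linear combination of
#'   fixed smooth basis functions ([tvar_basis()]); the weights solve a
#'   least-squares problem under the bound `sum |zeta| <= 1` over the
#'   non-intercept weights.
#' * `"oks"` — one-sided Gaussian-kernel-weighted least squares at the
#'   series endpoint `t*` (coefficients are treated as locally constant);
#'   bandwidth chosen by forward-chaining cross-validation when not given.
#' * `"stationary"` — constant-coefficient AR/VAR by ordinary least squares,
#'   the conventional baseline (no coefficient constraint).
#'
#' For multivariate series every estimator fits each response dimension
#' independently (equation-by-equation decomposition).
#'
#' @param x Series: numeric vector, matrix/data frame (rows = time points),
#'   or a [tvar_series()].
#' @param r Lag order (positive integer).
#' @param method Estimator, see Details.
#' @param times Optional raw timestamps, affinely mapped to `[0, 1]`.
#' @param ... Method-specific options. `"pinn"`: `hidden` (default
#'   `c(10, 10, 10)`), `activation` (`"tanh"`), `maxit` (800), `seed` (1),
#'   `weight_bounds` (`NULL`, optional box for L-BFGS-B).  `"gam"`:
#'   `basis` (default [tvar_basis()]), `lag_time_basis` (`TRUE`: basis in a
#'   lag-k block is evaluated at the lagged time `t - k dt`; `FALSE`
#'   evaluates at the response time, the standard varying-coefficient form),
#'   `radius` (1).  `"oks"`: `bandwidth` (`NULL` selects by CV),
#'   `bw_grid`, `t_star`, `radius`.
#' @return An object of class `"tvar"` (and a method-specific subclass) with
#'   `coef()`, `predict()`, `residuals()`, `fitted()`, `plot()`,
#'   `simulate()` and `summary()` methods.
#' @examples
#' sim <- tvar_scenario(2, n_time = 120, seed = 7)
#' fit <- tvar(sim$series, r = 1, method = "gam")
#' predict(fit, h = 2)
#' @export
tvar <- function(x, r = 1, method = c("pinn", "gam", "oks", "stationary"),
                 times = NULL, ...) {
  method <- match.arg(method)
  series <- if (inherits(x, "tvar_series")) x else tvar_series(x, times)
  switch(method,
         pinn = fit_pinn(series, r, ...),
         gam = fit_gam(series, r, ...),
         oks = fit_oks(series, r, ...),
         stationary = fit_stationary(series, r, ...))
}

method_label <- function(object) {
  switch(object$method,
         pinn = "neural-network (PINN)",
         gam = "basis expansion (GAM)",
         oks = "one-sided kernel smoothing (OKS)",
         stationary = if (object$p > 1L) "stationary VAR" else "stationary AR",
         truth = "ground-truth trajectories",
         object$method)
}

# ---- coefficient-provider contract ----------------------------------------
# Every tvar object can evaluate its coefficient trajectories on an arbitrary
# grid (including extrapolated times beyond the training window, which the
# recursive forecaster needs): list(grid, intercept G x p, lag G x r x p x p).
coef_path <- function(object, grid) UseMethod("coef_path")

#' @export
coef_path.tvar_gam <- function(object, grid)
  gam_trajectories(object, grid, at_lag_time = object$lag_time_basis)

#' @export
coef_path.tvar_pinn <- function(object, grid) pinn_trajectories(object, grid)

constant_path <- function(beta, grid, r, p) {
  G <- length(grid)
  intercept <- matrix(beta[1L, ], G, p, byrow = TRUE)
  lag <- array(0, dim = c(G, r, p, p))
  for (k in seq_len(r))
    for (m in seq_len(p))
      lag[, k, , m] <- matrix(beta[1L + (k - 1L) * p + m, ], G, p, byrow = TRUE)
  list(grid = grid, intercept = intercept, lag = lag)
}

#' @export
coef_path.tvar_oks <- function(object, grid)
  constant_path(object$beta, grid, object$r, object$p)

#' @export
coef_path.tvar_stationary <- function(object, grid)
  constant_path(object$coeffs, grid, object$r, object$p)

#' @export
coef_path.tvar_truth <- function(object, grid) {
  tr <- object$truth
  G <- length(grid)
  p <- object$p
  r <- object$r
  interp <- function(v) stats::approx(tr$grid, v, xout = grid, rule = 2)$y
  intercept <- apply(tr$intercept, 2L, interp)
  intercept <- matrix(intercept, G, p)
  lag <- array(0, dim = c(G, r, p, p))
  for (k in seq_len(r))
    for (j in seq_len(p))
      for (m in seq_len(p))
        lag[, k, j, m] <- interp(tr$lag[, k, j, m])
  list(grid = grid, intercept = intercept, lag = lag)
}

# ---- standard S3 surface ---------------------------------------------------

#' Coefficient trajectories of a fitted time-varying autoregression
#'
#' @param object A fitted [tvar()] model.
#' @param grid Time grid on which to evaluate the trajectories; defaults to
#'   the training grid.  For the basis-expansion fit the basis functions are
#'   evaluated directly at the grid times in every block; for the kernel and
#'   stationary fits the trajectories are constant.
#' @param ... Unused.
#' @return Object of class `"tvar_coefs"`: list with `grid`, `intercept`
#'   (G x p) and `lag` (G x r x p x p array).
#' @export
coef.tvar <- function(object, grid = NULL, ...) {
  if (is.null(grid)) grid <- object$times
  out <- if (inherits(object, "tvar_gam"))
    gam_trajectories(object, grid, at_lag_time = FALSE)
  else coef_path(object, grid)
  structure(out, class = "tvar_coefs", r = object$r, p = object$p)
}

#' @export
print.tvar_coefs <- function(x, ...) {
  cat(sprintf("Coefficient trajectories on %d grid points (r = %d, p = %d)\n",
              length(x$grid), attr(x, "r"), attr(x, "p")))
  cat("intercept range:", paste(signif(range(x$intercept), 4), collapse = " .. "),
      "\nlag-coefficient range:", paste(signif(range(x$lag), 4), collapse = " .. "),
      "\n")
  invisible(x)
}

#' Recursive multi-step forecast
#'
#' Rolls the fitted model forward: for each step the coefficient
#' trajectories are evaluated at the (extrapolated) time of the step, the
#' one-step mean is computed from the current lagged values, and the
#' prediction is appended to the working history.  Beyond the training
#' window the affine time map is extended, so step `T + h` of a length-`T`
#' training series sits at normalized time `1 + h dt`.  The kernel and
#' stationary fits hold their coefficients fixed over the horizon.
#'
#' @param object A fitted [tvar()] model (or [truth_model()] wrapper).
#' @param h Forecast horizon (number of steps).
#' @param history Observations to forecast from; defaults to the training
#'   series.  Supply a matrix/vector on the model's grid ending at the
#'   forecast origin.
#' @param ... Unused.
#' @return `h x p` matrix of predictions with the step times in
#'   `attr(, "times")`.
#' @export
predict.tvar <- function(object, h = 1, history = NULL, ...) {
  r <- object$r
  p <- object$p
  hist_s <- if (is.null(history)) object$series else as_tvar_series(history)
  if (hist_s$p != p) stop("history dimension mismatch", call. = FALSE)
  if (hist_s$n_time < r) stop("history shorter than the lag order", call. = FALSE)
  if (h < 1) stop("'h' must be at least 1", call. = FALSE)
  dt <- object$dt
  t_end <- hist_s$times[hist_s$n_time]
  steps <- t_end + seq_len(h) * dt
  cf <- coef_path(object, steps)
  y <- hist_s$values
  pred <- matrix(0, h, p, dimnames = list(NULL, colnames(y)))
  for (s in seq_len(h)) {
    acc <- cf$intercept[s, ]
    for (k in seq_len(r)) {
      ylag <- y[nrow(y) + 1L - k, ]   # lag-k value for the step being predicted
      acc <- acc + matrix(cf$lag[s, k, , ], p, p) %*% ylag
    }
    pred[s, ] <- acc
    y <- rbind(y, pred[s, , drop = FALSE])
  }
  attr(pred, "times") <- steps
  pred
}

#' @export
residuals.tvar <- function(object, ...) {
  design <- build_lagged_design(object$series, object$r)
  pred <- one_step_means(object, design)
  design$target - pred
}

#' @export
fitted.tvar <- function(object, ...) {
  design <- build_lagged_design(object$series, object$r)
  one_step_means(object, design)
}

# In-sample one-step conditional means at the design's response times.
one_step_means <- function(object, design) {
  cf <- coef_path(object, design$times)
  p <- object$p
  r <- object$r
  pred <- cf$intercept
  for (k in seq_len(r))
    for (j in seq_len(p))
      for (m in seq_len(p))
        pred[, j] <- pred[, j] +
          cf$lag[, k, j, m] * design$rows[, 1L + (k - 1L) * p + m]
  pred
}

#' @export
print.tvar <- function(x, ...) {
  cat(sprintf("Time-varying %sAR(%d) fit, method: %s\n",
              if (x$p > 1L) "V" else "", x$r, method_label(x)))
  cat(sprintf("  %d training points, %d component%s\n",
              x$series$n_time, x$p, if (x$p > 1L) "s" else ""))
  if (x$method == "pinn")
    cat(sprintf("  hidden layers [%s], activation %s, final loss %s\n",
                paste(x$hidden, collapse = ", "), x$activation,
                paste(signif(x$final_loss, 4), collapse = ", ")))
  if (x$method == "oks")
    cat(sprintf("  bandwidth %g at t* = %g\n", x$bandwidth, x$t_star))
  if (x$method == "gam")
    cat(sprintf("  basis [%s], constraint value %s\n",
                paste(names(x$basis$functions), collapse = ", "),
                paste(signif(x$constraint_value, 4), collapse = ", ")))
  invisible(x)
}

#' @export
summary.tvar <- function(object, ...) {
  res <- residuals(object)
  structure(list(fit = object,
                 resid_sd = apply(res, 2L, stats::sd),
                 resid_mean_abs = colMeans(abs(res))),
            class = "summary.tvar")
}

#' @export
print.summary.tvar <- function(x, ...) {
  print(x$fit)
  cat("One-step in-sample residuals:\n")
  tab <- rbind(`sd` = x$resid_sd, `mean |resid|` = x$resid_mean_abs)
  colnames(tab) <- x$fit$labels
  print(signif(tab, 4))
  if (x$fit$method == "stationary") {
    cat("Coefficients (per response dimension):\n")
    print(signif(x$fit$coeffs, 4))
  }
  if (x$fit$method == "oks" && !is.null(x$fit$cv)) {
    cat("Bandwidth cross-validation scores:\n")
    print(signif(x$fit$cv$scores, 4))
  }
  invisible(x)
}

#' Plot coefficient trajectories
#'
#' Draws the fitted intercept and lag-coefficient trajectories for one
#' response dimension, optionally overlaying the ground truth from a
#' simulation.
#'
#' @param x A fitted [tvar()] model.
#' @param dimension Response dimension to plot (1-based).
#' @param truth Optional `"tvar_sim"` whose stored true trajectories are
#'   overlaid as dashed lines.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.tvar <- function(x, dimension = 1, truth = NULL, ...) {
  grid <- x$times
  cf <- coef_path(x, grid)
  p <- x$p
  r <- x$r
  curves <- cbind(cf$intercept[, dimension],
                  matrix(cf$lag[, , dimension, ], length(grid), r * p))
  labs <- c("intercept",
            paste0("lag", rep(seq_len(r), each = p), ".",
                   rep(x$labels, times = r)))
  graphics::matplot(grid, curves, type = "l", lty = 1,
                    xlab = "normalized time", ylab = "coefficient",
                    main = sprintf("%s: dimension %s", method_label(x),
                                   x$labels[dimension]), ...)
  if (!is.null(truth)) {
    stopifnot(inherits(truth, "tvar_sim"))
    tcurves <- cbind(truth$truth$intercept[, dimension],
                     matrix(truth$truth$lag[, , dimension, ],
                            length(truth$truth$grid), r * p))
    graphics::matlines(truth$truth$grid, tcurves, lty = 2)
  }
  graphics::legend("topright", legend = labs, col = seq_along(labs),
                   lty = 1, cex = 0.8)
  invisible(x)
}

#' Simulate new series from a fitted model
#'
#' Draws Gaussian innovations with the fitted one-step residual standard
#' deviation and rolls the fitted coefficient trajectories forward from the
#' first `r` observed values on the training grid.
#'
#' @param object A fitted [tvar()] model.
#' @param nsim Number of series to simulate.
#' @param seed Optional integer seed (caller's RNG stream preserved).
#' @param ... Unused.
#' @return A list of `nsim` matrices, each `n_time x p`.
#' @export
simulate.tvar <- function(object, nsim = 1, seed = NULL, ...) {
  r <- object$r
  p <- object$p
  n <- object$series$n_time
  sds <- apply(residuals(object), 2L, stats::sd)
  cf <- coef_path(object, object$times)
  with_seed(seed, {
    lapply(seq_len(nsim), function(s) {
      y <- matrix(0, n, p, dimnames = list(NULL, object$labels))
      y[seq_len(r), ] <- object$series$values[seq_len(r), ]
      for (i in (r + 1L):n) {
        acc <- cf$intercept[i, ]
        for (k in seq_len(r))
          acc <- acc + matrix(cf$lag[i, k, , ], p, p) %*% y[i - k, ]
        y[i, ] <- acc + rnorm(p, sd = sds)
      }
      y
    })
  })
}
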