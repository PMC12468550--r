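# Synthetic data-generating processes: first-order TV-AR / TV-VAR recursions
# with smooth coefficient drift, plus a general simulator for arbitrary
# coefficient trajectories.

#' Coefficient drift functions for the simulation scenarios
#'
#' Three smooth perturbation curves on normalized time:
#' `g_sigmoid_s1(t) = t / (1 + exp(-10 (t - 0.5)))` (sigmoid-like transition
#' with a leading linear factor, Scenario 1), `g_logistic(t) =
#' 1 / (1 + exp(-10 (t - 0.5)))` (pure logistic, Scenario 3) and
#' `g_quadratic(t) = (t - 0.5)^2` (Scenarios 2 and 4).
#'
#' @param t Numeric vector of (normalized) times.
#' @return Numeric vector of the same length.
#' @examples
#' g_sigmoid_s1(0.5)  # 0.25
#' g_quadratic(0)     # 0.25
#' @export
g_sigmoid_s1 <- function(t) t / (1 + exp(-10 * (t - 0.5)))

#' @rdname g_sigmoid_s1
#' @export
g_logistic <- function(t) 1 / (1 + exp(-10 * (t - 0.5)))

#' @rdname g_sigmoid_s1
#' @export
g_quadratic <- function(t) (t - 0.5)^2

# Run code with a temporarily seeded RNG, restoring the caller's stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

div_guard <- function(y, i) {
  if (any(!is.finite(y)) || any(abs(y) > 1e6))
    stop(sprintf("simulated series diverged at time index %d (|y| > 1e6 or non-finite)", i),
         call. = FALSE)
}

#' Simulate one of the four synthetic study scenarios
#'
#' Generates a first-order time-varying autoregression on an evenly spaced
#' normalized grid, together with the ground-truth coefficient trajectories.
#'
#' Scenarios 1 and 2 are univariate: draw `a0 ~ U[0, 1]` and
#' `y0 ~ U[init_range]`; the lag coefficient is `f(t) = a0 - g(t)` with
#' `g = ` [g_sigmoid_s1()] (scenario 1) or [g_quadratic()] (scenario 2), the
#' intercept is `c(t) = t - 0.5`, and
#' `y(t) = c(t) + f(t) y(t-1) + W * e(t)`, `e ~ N(0, sigma^2)`.
#'
#' Scenarios 3 and 4 are bivariate: a nonnegative random matrix `A0` is
#' row-normalized to a row-stochastic matrix and its first column is
#' perturbed over time, entry (1,1) by `+g(t)` and entry (2,1) by `-g(t)`
#' with `g = ` [g_logistic()] (scenario 3) or [g_quadratic()] (scenario 4);
#' the second column is the row complement so every row of `F(t)` sums to 1.
#' The intercept is `C(t) = (t - 0.5)/10` in both components.  By default
#' (`saturate = TRUE`) the perturbed entries are clamped to `[0, 1]` so that
#' `F(t)` remains a genuine row-stochastic matrix at every `t`; this also
#' bounds its second eigenvalue `a - b` by 1 in magnitude, so the recursion
#' cannot explode.  With `saturate = FALSE` the perturbation is applied
#' literally; once `g(t)` is large the second eigenvalue exceeds 1 and the
#' recursion grows without bound until the divergence guard stops it.
#'
#' @param scenario Integer 1-4.
#' @param n_time Series length `T` (at least 10).
#' @param noise_weight Scalar weight `W` multiplying the unit-variance
#'   Gaussian innovations.  The study default is `1/10`.
#' @param seed Integer seed; the same seed reproduces the series and truth
#'   exactly.  The caller's RNG stream is left untouched.
#' @param init_range Interval from which initial values are drawn uniformly.
#' @param recursion_mode `"static"` perturbs the initial matrix entries,
#'   `a(t) = A0 +/- g(t)`; `"recursive"` accumulates, `a(t) = a(t-1) +/-
#'   g(t)`.  Only scenarios 3-4 distinguish the two.
#' @param saturate Clamp the perturbed matrix entries to `[0, 1]` (scenarios
#'   3-4 only); see Details.
#' @return Object of class `"tvar_sim"`: list with `series` (a
#'   [tvar_series()]), `truth` (list `grid`, `intercept` G x p, `lag`
#'   G x r x p x p array of true trajectories), `innovations` ((T-1) x p
#'   matrix of unscaled standard-normal draws) and `config`.
#' @examples
#' sim <- tvar_scenario(1, n_time = 50, seed = 1)
#' sim$truth$lag[1:3, 1, 1, 1]  # f(t) on the first grid points
#' @export
tvar_scenario <- function(scenario, n_time = 200, noise_weight = 0.1,
                          seed = NULL, init_range = c(-10, 10),
                          recursion_mode = c("static", "recursive"),
                          saturate = TRUE) {
  if (!scenario %in% 1:4) stop("'scenario' must be 1, 2, 3 or 4", call. = FALSE)
  if (n_time < 10) stop("'n_time' must be at least 10", call. = FALSE)
  recursion_mode <- match.arg(recursion_mode)
  p <- if (scenario <= 2) 1L else 2L
  tt <- normalize_time(n_time)

  draws <- with_seed(seed, {
    if (p == 1L) {
      list(a0 = runif(1), y0 = runif(1, init_range[1], init_range[2]),
           eps = matrix(rnorm(n_time - 1L), ncol = 1L))
    } else {
      A0 <- matrix(runif(p * p), p, p)
      A0 <- A0 / rowSums(A0)
      list(a0 = A0, y0 = runif(p, init_range[1], init_range[2]),
           eps = matrix(rnorm((n_time - 1L) * p), ncol = p))
    }
  })

  g <- switch(scenario, g_sigmoid_s1, g_quadratic, g_logistic, g_quadratic)
  intercept <- matrix(0, n_time, p)
  lag <- array(0, dim = c(n_time, 1L, p, p))
  y <- matrix(0, n_time, p)
  y[1L, ] <- draws$y0

  if (p == 1L) {
    f <- draws$a0 - g(tt)
    intercept[, 1L] <- tt - 0.5
    lag[, 1L, 1L, 1L] <- f
    for (i in 2:n_time) {
      y[i, 1L] <- intercept[i, 1L] + f[i] * y[i - 1L, 1L] +
        noise_weight * draws$eps[i - 1L, 1L]
      div_guard(y[i, ], i)
    }
  } else {
    a_prev <- draws$a0[, 1L]
    for (i in 1:n_time) {
      gi <- g(tt[i])
      a <- if (recursion_mode == "static")
        draws$a0[, 1L] + c(gi, -gi)
      else if (i == 1L) a_prev else a_prev + c(gi, -gi)
      if (saturate) a <- pmin(1, pmax(0, a))
      a_prev <- a
      Fi <- cbind(a, 1 - a)
      intercept[i, ] <- (tt[i] - 0.5) / 10
      lag[i, 1L, , ] <- Fi
      if (i > 1L) {
        y[i, ] <- intercept[i, ] + Fi %*% y[i - 1L, ] +
          noise_weight * draws$eps[i - 1L, ]
        div_guard(y[i, ], i)
      }
    }
  }

  colnames(y) <- if (p == 1L) "y" else paste0("y", 1:p)
  structure(list(
    series = tvar_series(y, times = NULL),
    truth = list(grid = tt, intercept = intercept, lag = lag),
    innovations = draws$eps,
    config = list(scenario = scenario, n_time = n_time, p = p, r = 1L,
                  noise_weight = noise_weight, seed = seed,
                  init_range = init_range, recursion_mode = recursion_mode,
                  saturate = saturate, a0 = draws$a0, y0 = draws$y0)),
    class = "tvar_sim")
}

#' @export
print.tvar_sim <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Simulated TV-%sAR(1) series: scenario %s, T = %d, p = %d, noise weight %g\n",
              if (cfg$p > 1) "V" else "", format(cfg$scenario), cfg$n_time,
              cfg$p, cfg$noise_weight))
  invisible(x)
}

#' Simulate a TV-(V)AR process from arbitrary coefficient trajectories
#'
#' Runs the recursion `y(t) = c(t) + sum_k B_k(t) y(t-k) + W e(t)` on the
#' normalized grid, with coefficients supplied as a function of time.
#'
#' @param coef_fn Function of a single normalized time returning a list with
#'   `c` (intercept, length p) and `B` (array `r x p x p`, or for p = 1 a
#'   vector of length `r`).
#' @param r Lag order of the supplied trajectories.
#' @param n_time Series length.
#' @param noise_weight Scalar multiplier on the innovations.
#' @param sigma Innovation scale: scalar standard deviation, or a p x p
#'   covariance matrix.
#' @param seed Optional integer seed (caller's RNG stream preserved).
#' @param y_init Initial observations, an `r x p` matrix (or length-p vector
#'   when `r = 1`); drawn uniformly from `init_range` when missing.
#' @param init_range Interval for the default initial draw.
#' @return A `"tvar_sim"` object (see [tvar_scenario()]); `config$scenario`
#'   is `"custom"`.
#' @export
simulate_tvar <- function(coef_fn, r = 1, n_time = 100, noise_weight = 1,
                          sigma = 1, seed = NULL, y_init = NULL,
                          init_range = c(-10, 10)) {
  probe <- coef_fn(0)
  if (!is.list(probe) || is.null(probe$c) || is.null(probe$B))
    stop("'coef_fn' must return list(c = ..., B = ...)", call. = FALSE)
  p <- length(probe$c)
  B0 <- coef_array(probe$B, r, p)
  if (n_time <= r) stop("'n_time' must exceed 'r'", call. = FALSE)
  if (is.null(y_init)) {
    y_init <- with_seed(if (is.null(seed)) NULL else seed + 1L,
                        matrix(runif(r * p, init_range[1], init_range[2]), r, p))
  } else {
    y_init <- matrix(y_init, nrow = r)
    if (ncol(y_init) != p)
      stop(sprintf("'y_init' implies p = %d but coef_fn returns p = %d",
                   ncol(y_init), p), call. = FALSE)
  }
  L <- if (is.matrix(sigma)) {
    if (!isSymmetric(unname(sigma)))
      stop("'sigma' covariance must be symmetric", call. = FALSE)
    chol(sigma)
  } else {
    if (sigma < 0) stop("'sigma' must be nonnegative", call. = FALSE)
    diag(sigma, p)
  }
  tt <- normalize_time(n_time)
  eps <- with_seed(seed, matrix(rnorm((n_time - r) * p), ncol = p))
  y <- matrix(0, n_time, p)
  y[seq_len(r), ] <- y_init
  intercept <- matrix(0, n_time, p)
  lag <- array(0, dim = c(n_time, r, p, p))
  for (i in seq_len(n_time)) {
    cf <- coef_fn(tt[i])
    intercept[i, ] <- cf$c
    lag[i, , , ] <- coef_array(cf$B, r, p)
    if (i > r) {
      acc <- intercept[i, ]
      for (k in seq_len(r))
        acc <- acc + lag[i, k, , ] %*% y[i - k, ]
      y[i, ] <- acc + noise_weight * drop(t(L) %*% eps[i - r, ])
      div_guard(y[i, ], i)
    }
  }
  colnames(y) <- if (p == 1L) "y" else paste0("y", 1:p)
  structure(list(
    series = tvar_series(y),
    truth = list(grid = tt, intercept = intercept, lag = lag),
    innovations = eps,
    config = list(scenario = "custom", n_time = n_time, p = p, r = r,
                  noise_weight = noise_weight, sigma = sigma, seed = seed,
                  y_init = y_init)),
    class = "tvar_sim")
}

# Coerce a user-supplied lag-coefficient object to an r x p x p array.
coef_array <- function(B, r, p) {
  if (is.array(B) && length(dim(B)) == 3L) {
    if (!all(dim(B) == c(r, p, p)))
      stop(sprintf("lag coefficient array must be %d x %d x %d", r, p, p),
           call. = FALSE)
    return(B)
  }
  if (p == 1L && length(B) == r) return(array(B, dim = c(r, 1L, 1L)))
  if (is.matrix(B) && r == 1L && all(dim(B) == c(p, p)))
    return(array(B, dim = c(1L, p, p)))
  stop("cannot interpret lag coefficients: supply an r x p x p array",
       call. = FALSE)
}

#' Ground-truth coefficient model from a simulation
#'
#' Wraps the stored true trajectories of a [tvar_scenario()] /
#' [simulate_tvar()] run as a coefficient provider that can be used wherever
#' a fitted model is expected (forecasting, reconstruction).  Times between
#' grid points are linearly interpolated; times beyond the grid use the
#' nearest endpoint value.
#'
#' @param sim A `"tvar_sim"` object.
#' @return Object of class `c("tvar_truth", "tvar")`.
#' @export
truth_model <- function(sim) {
  stopifnot(inherits(sim, "tvar_sim"))
  structure(list(method = "truth", r = sim$config$r, p = sim$config$p,
                 times = sim$truth$grid, dt = time_step(sim$truth$grid),
                 series = sim$series, truth = sim$truth),
            class = c("tvar_truth", "tvar"))
}
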