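test_that("default basis functions evaluate to their closed forms", {
  bs <- tvar_basis()
  expect_identical(bs$n, 6L)
  B <- eval_basis(bs, c(0, 0.3, 0.5, 1))
  expect_equal(B[2, "linear"], 0.3, ignore_attr = TRUE)
  expect_equal(B[, "quadratic"], c(0, 0.09, 0.25, 1), ignore_attr = TRUE)
  expect_equal(B[3, "gaussian"], 1, ignore_attr = TRUE)  # peak at the center
  expect_equal(B[1, "cosine"], 1, ignore_attr = TRUE)
  expect_equal(B[3, "cosine"], -1, ignore_attr = TRUE)
  expect_equal(B[3, "tanh"], 0, ignore_attr = TRUE)
  expect_equal(B[, "exponential"], exp(c(0, 0.3, 0.5, 1)), ignore_attr = TRUE)
  expect_error(tvar_basis("spline"), "unknown basis name")
})

test_that("a single constant basis reduces the design to the lagged design", {
  y <- const_ar1(0.5, 0.1, 20, y0 = 3, noise_sd = 0.2, seed = 1)
  s <- tvar_series(y)
  d <- build_lagged_design(s, 1)
  G <- tvarnet:::gam_design(d, tvar_basis("constant"), dt = 1 / 19, p = 1)
  expect_equal(G, d$rows, ignore_attr = TRUE)
})

test_that("design width is n(rp + 1) and entries follow the printed row formula", {
  y <- c(0.3, -1.2, 0.5, 2.0, -0.7)
  s <- tvar_series(y)
  bs <- tvar_basis(c("linear", "cosine"))
  d <- build_lagged_design(s, 1)
  dt <- 1 / 4
  G <- tvarnet:::gam_design(d, bs, dt = dt, p = 1)
  expect_equal(ncol(G), 4L)              # n (r p + 1) with n = 2
  # element-by-element loop over the printed layout: intercept block f_j(t),
  # lag block f_j(t - dt) y(t - 1)
  for (i in 1:4) {
    t <- d$times[i]
    expect_equal(G[i, 1], t, ignore_attr = TRUE)
    expect_equal(G[i, 2], cos(2 * pi * t), ignore_attr = TRUE)
    expect_equal(G[i, 3], (t - dt) * y[i], ignore_attr = TRUE)
    expect_equal(G[i, 4], cos(2 * pi * (t - dt)) * y[i], ignore_attr = TRUE)
  }
  # full default basis on a univariate r = 1 fit: 12 columns
  G6 <- tvarnet:::gam_design(d, tvar_basis(), dt = dt, p = 1)
  expect_equal(ncol(G6), 12L)
})

test_that("noiseless constant-coefficient data is interpolated exactly", {
  y <- const_ar1(0.5, 0, 40, y0 = 6)
  fit <- tvar(y, 1, "gam", basis = tvar_basis(c("constant", "linear")))
  expect_lt(sum(residuals(fit)^2), 1e-10)
  # recovered lag-coefficient trajectory is identically 0.5
  cf <- coef(fit, grid = seq(0, 1, 0.1))
  expect_equal(cf$lag[, 1, 1, 1], rep(0.5, 11), tolerance = 1e-6)
})

test_that("the constraint contract holds on scenario data", {
  sim <- tvar_scenario(1, n_time = 150, seed = 2)
  fit <- tvar(sim$series, 1, "gam")
  expect_lte(fit$constraint_value, 1 + 1e-6)
  expect_s3_class(fit, "tvar_gam")
})

test_that("an inactive constraint yields the normal-equations solution", {
  # mildly autoregressive noisy data keeps the L1 norm of the lag weights
  # well under 1, so the constrained fit must equal plain least squares
  y <- const_ar1(0.3, 0.05, 120, y0 = 0.5, noise_sd = 0.4, seed = 9)
  bs <- tvar_basis(c("constant", "linear"))
  fit <- tvar(y, 1, "gam", basis = bs)
  d <- build_lagged_design(tvar_series(y), 1)
  G <- tvarnet:::gam_design(d, bs, dt = 1 / 119, p = 1)
  expect_lt(fit$constraint_value, 1)
  expect_equal(drop(fit$zeta), ols_oracle(G, drop(d$target)),
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("the fit is invariant to permuting the basis order", {
  sim <- tvar_scenario(2, n_time = 150, seed = 4)
  nm <- c("linear", "quadratic", "tanh", "exponential", "gaussian", "cosine")
  perm <- c(4, 1, 6, 2, 5, 3)
  f1 <- tvar(sim$series, 1, "gam", basis = tvar_basis(nm))
  f2 <- tvar(sim$series, 1, "gam", basis = tvar_basis(nm[perm]))
  z1 <- matrix(f1$zeta, ncol = 2)        # blocks: intercept, lag
  z2 <- matrix(f2$zeta, ncol = 2)
  # entry i of the permuted fit weights basis nm[perm[i]]
  expect_equal(z2, z1[perm, ], tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(f1$objective, f2$objective, tolerance = 1e-8)
})

test_that("objective at the solution is no worse than the zero vector", {
  sim <- tvar_scenario(2, n_time = 120, seed = 6)
  fit <- tvar(sim$series, 1, "gam")
  d <- build_lagged_design(sim$series, 1)
  expect_lte(fit$objective, sum(d$target^2))
})

test_that("trajectory evaluation is linear in the basis weights", {
  sim <- tvar_scenario(1, n_time = 100, seed = 8)
  fit <- tvar(sim$series, 1, "gam")
  grid <- seq(0, 1, length.out = 21)
  c1 <- coef(fit, grid)
  fit2 <- fit
  fit2$zeta <- 2 * fit$zeta
  c2 <- coef(fit2, grid)
  expect_equal(c2$intercept, 2 * c1$intercept)
  expect_equal(c2$lag, 2 * c1$lag)
  fit0 <- fit
  fit0$zeta[] <- 0
  c0 <- coef(fit0, grid)
  expect_true(all(c0$intercept == 0) && all(c0$lag == 0))
})

test_that("signed-sum constraint variant solves its KKT system exactly", {
  sim <- tvar_scenario(2, n_time = 150, seed = 13)
  fit <- tvar(sim$series, 1, "gam", constraint = "signed")
  n <- fit$basis$n
  expect_lte(sum(fit$zeta[(n + 1):(2 * n), 1]), 1 + 1e-8)
})
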