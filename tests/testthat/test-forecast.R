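test_that("mae and rsv match hand-computed values and a two-pass oracle", {
  expect_equal(mae(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(mae(0, 1), 1)
  expect_equal(mae(c(1, 2, 4), c(1, 3, 2)), 1)
  expect_error(mae(numeric(0), numeric(0)), "empty")
  expect_error(mae(1:3, 1:4), "equal length")

  expect_equal(rsv(c(2, 2, 2)), 0)
  expect_equal(rsv(c(0, 2)), sqrt(2))
  set.seed(5)
  x <- rnorm(40)
  two_pass <- sqrt(sum((x - mean(x))^2) / (length(x) - 1))
  expect_equal(rsv(x), two_pass)
  expect_error(rsv(1), "at least 2")
})

test_that("one-step forecast equals the direct formula and h=2 a manual roll", {
  y <- const_ar1(0.6, 0.3, 50, y0 = 2, noise_sd = 0.2, seed = 14)
  fit <- tvar(y, 1, "stationary")
  cc <- fit$coeffs[1, 1]
  ff <- fit$coeffs[2, 1]
  p1 <- predict(fit, h = 1)
  expect_equal(p1[1, 1], cc + ff * y[50], ignore_attr = TRUE)
  p2 <- predict(fit, h = 2)
  step1 <- cc + ff * y[50]
  expect_equal(unname(p2[, 1]), c(step1, cc + ff * step1))
})

test_that("zero lag coefficients forecast the intercept trajectory", {
  cf <- function(t) list(c = 2 * t, B = 0)
  sim <- simulate_tvar(cf, r = 1, n_time = 30, noise_weight = 0, y_init = 1)
  tm <- truth_model(sim)
  pred <- predict(tm, h = 3)
  dt <- 1 / 29
  # beyond the grid the truth provider extends its endpoint value
  expect_equal(unname(pred[, 1]), rep(2, 3))
  expect_equal(attr(pred, "times"), 1 + dt * (1:3))
})

test_that("forecast times extrapolate the affine map beyond training", {
  sim <- tvar_scenario(1, n_time = 100, seed = 4)
  fit <- tvar(sim$series, 1, "stationary")
  pred <- predict(fit, h = 2)
  expect_equal(attr(pred, "times"), 1 + (1:2) / 99)
})

test_that("truth-provider reconstruction replays a noiseless series exactly", {
  for (sc in c(1, 3)) {
    sim <- tvar_scenario(sc, n_time = 60, noise_weight = 0, seed = sc + 20)
    rec <- tvar_reconstruct(truth_model(sim))
    expect_equal(rec$values, rec$observed, tolerance = 1e-12)
    expect_equal(nrow(rec$values), 59L)   # length n - r
    expect_equal(rec$mae, 0, tolerance = 1e-13)
  }
})

test_that("reconstruction agrees with a manual roll of the fitted recursion", {
  sim <- tvar_scenario(2, n_time = 80, seed = 17)
  fit <- tvar(sim$series, 1, "gam")
  rec <- tvar_reconstruct(fit)
  tt <- (0:79) / 79
  cf <- tvarnet:::coef_path(fit, tt)
  y <- sim$series$values[1, 1]
  for (i in 2:4) {
    y <- cf$intercept[i, 1] + cf$lag[i, 1, 1, 1] * y
    expect_equal(rec$values[i - 1, 1], y)
  }
})

test_that("benchmark tables are complete, deterministic and seed-driven", {
  b1 <- tvar_benchmark(scenarios = 1, methods = "stationary", lags = c(1, 2),
                       horizons = c(1, 2), reps = 3, base_seed = 5)
  expect_equal(nrow(b1), 4L)             # |methods| x |lags| x |horizons|
  b2 <- tvar_benchmark(scenarios = 1, methods = "stationary", lags = c(1, 2),
                       horizons = c(1, 2), reps = 3, base_seed = 5)
  expect_identical(as.data.frame(b1), as.data.frame(b2))
  b3 <- tvar_benchmark(scenarios = 1, methods = "stationary", lags = 1,
                       horizons = 1, reps = 3, base_seed = 6)
  expect_false(isTRUE(all.equal(b1$mae[1], b3$mae[1])))
})

test_that("benchmark horizon-1 rows equal a direct one-step computation", {
  reps <- 5
  b <- tvar_benchmark(scenarios = 2, methods = "stationary", lags = 1,
                      horizons = c(1, 2), reps = reps, base_seed = 9)
  direct <- vapply(seq_len(reps), function(k) {
    sim <- tvar_scenario(2, n_time = 200, noise_weight = 0.1, seed = 9 + k)
    train <- tvar_series(sim$series$values[1:198, , drop = FALSE])
    fit <- tvar(train, 1, "stationary")
    abs(predict(fit, h = 1)[1, 1] - sim$series$values[199, 1])
  }, numeric(1))
  expect_equal(b$mae[b$horizon == 1], mean(direct), tolerance = 1e-12)
})

test_that("cumulative step errors average the per-step errors", {
  b_fin <- tvar_benchmark(scenarios = 1, methods = "stationary", lags = 1,
                          horizons = c(1, 2), reps = 4, base_seed = 3,
                          keep_errors = TRUE)
  b_cum <- tvar_benchmark(scenarios = 1, methods = "stationary", lags = 1,
                          horizons = c(1, 2), reps = 4, base_seed = 3,
                          step_error = "cumulative", keep_errors = TRUE)
  e <- attr(b_fin, "errors")
  expect_equal(b_cum$mae[b_cum$horizon == 2],
               mean((e[1, 1, 1, 1, ] + e[1, 1, 1, 2, ]) / 2))
  expect_equal(b_cum$mae[b_cum$horizon == 1], b_fin$mae[b_fin$horizon == 1])
})

test_that("forecast error floor rises with the innovation weight", {
  maes <- vapply(c(0.05, 0.1, 0.2), function(w) {
    b <- tvar_benchmark(scenarios = 1, methods = "stationary", lags = 1,
                        horizons = 1, reps = 10, base_seed = 2,
                        noise_weight = w)
    b$mae
  }, numeric(1))
  expect_true(all(diff(maes) > 0))
})
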