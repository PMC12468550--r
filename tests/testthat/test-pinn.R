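test_that("parameter counts match enumeration of all weights and biases", {
  expect_identical(pinn_n_params(c(5, 5), r = 1, p = 1), 52L)
  expect_identical(pinn_n_params(c(10, 10, 10), r = 1, p = 1), 262L)
  # brute force: count the entries of actual initialized layers
  set.seed(1)
  for (i in 1:5) {
    hidden <- sample(1:8, sample(1:3, 1))
    r <- sample(1:3, 1)
    p <- sample(1:2, 1)
    layers <- tvarnet:::pinn_init(hidden, r, p, seed = i)
    n_brute <- sum(vapply(layers, function(l) length(l$W) + length(l$b), 0))
    expect_identical(pinn_n_params(hidden, r, p), as.integer(n_brute))
  }
})

test_that("initialization is seeded and reproducible", {
  a <- tvarnet:::pinn_init(c(5, 5), 1, 1, seed = 42)
  b <- tvarnet:::pinn_init(c(5, 5), 1, 1, seed = 42)
  expect_identical(a, b)
  c3 <- tvarnet:::pinn_init(c(5, 5), 1, 1, seed = 43)
  expect_false(identical(a, c3))
})

test_that("forward pass is the documented affine/tanh composition", {
  act <- tvarnet:::activation_fns("tanh")
  # all parameters zero: output is the zero vector at any time
  zero <- tvarnet:::pinn_unpack(rep(0, pinn_n_params(c(4, 4), 1, 1)),
                                tvarnet:::pinn_layer_sizes(c(4, 4), 1, 1))
  expect_equal(tvarnet:::pinn_forward(zero, c(0, 0.5, 1), act),
               matrix(0, 2, 3))
  # hand-computed 1-2-2 network
  W1 <- matrix(c(0.5, -1), 2, 1)
  b1 <- c(0.1, 0.2)
  W2 <- matrix(c(1, 0.3, -0.4, 2), 2, 2)
  b2 <- c(-0.5, 0)
  layers <- list(list(W = W1, b = b1), list(W = W2, b = b2))
  t0 <- 0.7
  manual <- W2 %*% tanh(W1 %*% t0 + b1) + b2
  expect_equal(tvarnet:::pinn_forward(layers, t0, act), manual)
  # output length is rp + 1 for any (r, p)
  for (r in 1:2) for (p in 1:2) {
    ly <- tvarnet:::pinn_init(c(3), r, p, seed = 1)
    expect_equal(nrow(tvarnet:::pinn_forward(ly, 0.3, act)), r * p + 1L)
  }
})

test_that("the residual loss vanishes when the network outputs the truth", {
  y <- const_ar1(0.5, 0.1, 30, y0 = 4)
  d <- build_lagged_design(tvar_series(y), 1)
  sz <- tvarnet:::pinn_layer_sizes(c(3), 1, 1)
  act <- tvarnet:::activation_fns("tanh")
  # zero weights, output biases equal to the true constant coefficients
  par <- rep(0, pinn_n_params(c(3), 1, 1))
  par[(length(par) - 1):length(par)] <- c(0.1, 0.5)
  val <- tvarnet:::pinn_loss_grad(par, sz, act, d$times, d$rows,
                                  drop(d$target), want_grad = FALSE)
  expect_equal(val$loss, 0, tolerance = 1e-28)
  # and the loss is nonnegative at a random point
  set.seed(2)
  par2 <- rnorm(length(par))
  expect_gte(tvarnet:::pinn_loss_grad(par2, sz, act, d$times, d$rows,
                                      drop(d$target), want_grad = FALSE)$loss, 0)
})

test_that("backpropagation matches central finite differences", {
  set.seed(7)
  y <- const_ar1(0.4, 0.2, 12, y0 = 3, noise_sd = 0.5, seed = 7)
  d <- build_lagged_design(tvar_series(y), 1)
  sz <- tvarnet:::pinn_layer_sizes(c(3), 1, 1)
  act <- tvarnet:::activation_fns("tanh")
  par <- 0.5 * rnorm(pinn_n_params(c(3), 1, 1))
  g_analytic <- tvarnet:::pinn_loss_grad(par, sz, act, d$times, d$rows,
                                         drop(d$target))$grad
  g_fd <- fd_grad(function(p)
    tvarnet:::pinn_loss_grad(p, sz, act, d$times, d$rows, drop(d$target),
                             want_grad = FALSE)$loss, par)
  expect_lt(max(abs(g_analytic - g_fd)) / max(abs(g_fd)), 1e-4)
})

test_that("training is deterministic given a seed and reduces the loss", {
  sim <- tvar_scenario(1, n_time = 80, seed = 5)
  f1 <- tvar(sim$series, 1, "pinn", seed = 11, maxit = 150)
  f2 <- tvar(sim$series, 1, "pinn", seed = 11, maxit = 150)
  expect_identical(f1$params, f2$params)
  expect_lte(f1$final_loss, f1$initial_loss)
})

test_that("a constant-coefficient series is recovered along the trajectory", {
  y <- const_ar1(0.5, 0.1, 100, y0 = 5)
  fit <- tvar(y, 1, "pinn", seed = 2)
  cf <- coef(fit, grid = normalize_time(100))
  expect_lt(max(abs(cf$lag[, 1, 1, 1] - 0.5)), 0.1)
  expect_lt(max(abs(cf$intercept - 0.1)), 0.05)
  expect_lt(fit$final_loss, 1e-5)
})

test_that("trajectories agree with the forward pass and are continuous", {
  sim <- tvar_scenario(3, n_time = 60, seed = 9)
  fit <- tvar(sim$series, 1, "pinn", seed = 9, maxit = 200)
  expect_identical(fit$p, 2L)
  grid <- fit$times
  cf <- coef(fit, grid)
  expect_equal(dim(cf$intercept), c(60L, 2L))
  act <- tvarnet:::activation_fns(fit$activation)
  out1 <- tvarnet:::pinn_forward(fit$params[[1]], grid, act)
  expect_equal(cf$intercept[, 1], out1[1, ])
  expect_equal(cf$lag[, 1, 1, ], t(out1[2:3, ]))
  # a tanh network is Lipschitz: bound finite differences by the product of
  # layer spectral norms
  fine <- seq(0, 1, length.out = 400)
  cf2 <- coef(fit, fine)
  lip <- prod(vapply(fit$params[[1]], function(l) norm(l$W, "2"), 0))
  steps <- abs(diff(cf2$intercept[, 1]))
  expect_lte(max(steps), lip * diff(fine)[1] * (1 + 1e-9))
})

test_that("bound constraints are honored when requested", {
  sim <- tvar_scenario(1, n_time = 60, seed = 3)
  fit <- tvar(sim$series, 1, "pinn", seed = 3, maxit = 100,
              weight_bounds = c(-0.2, 0.2))
  flat <- tvarnet:::pinn_pack(fit$params[[1]])
  expect_true(all(flat >= -0.2 - 1e-12 & flat <= 0.2 + 1e-12))
})
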