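# Neural-network estimator: a small feed-forward network maps normalized
# time t to the (rp+1)-vector of autoregressive coefficients
# [c(t), B_1(t), ..., B_r(t)] (row for one response dimension).  Training
# minimizes the mean squared TV-(V)AR residual, i.e. the structural equation
# itself is the training constraint; gradients are analytic
# backpropagation and the optimizer is L-BFGS-B.

activation_fns <- function(name) {
  switch(name,
    tanh = list(f = tanh, df = function(a) 1 - a^2),
    logistic = list(f = function(z) 1 / (1 + exp(-z)),
                    df = function(a) a * (1 - a)),
    relu = list(f = function(z) pmax(z, 0),
                df = function(a) (a > 0) + 0),
    stop(sprintf("unknown activation '%s'", name), call. = FALSE))
}

# Layer sizes: input 1 -> hidden widths -> output rp+1.
pinn_layer_sizes <- function(hidden, r, p) c(1L, as.integer(hidden), r * p + 1L)

#' Trainable parameter count of a coefficient network
#'
#' Number of weights and biases of the feed-forward network mapping scalar
#' time to the `rp+1` coefficient outputs: `sum_l (in_l * out_l + out_l)`.
#'
#' @param hidden Integer vector of hidden-layer widths.
#' @param r Lag order.
#' @param p Series dimension.
#' @return Integer parameter count.
#' @examples
#' pinn_n_params(c(5, 5), r = 1, p = 1)  # 52
#' @export
pinn_n_params <- function(hidden, r = 1, p = 1) {
  sz <- pinn_layer_sizes(hidden, r, p)
  as.integer(sum(sz[-length(sz)] * sz[-1L] + sz[-1L]))
}

# Seeded Glorot-style initialization: W ~ U(-l, l) with l = sqrt(6/(in+out)),
# biases zero.
pinn_init <- function(hidden, r, p, seed = NULL) {
  sz <- pinn_layer_sizes(hidden, r, p)
  with_seed(seed, {
    lapply(seq_len(length(sz) - 1L), function(l) {
      lim <- sqrt(6 / (sz[l] + sz[l + 1L]))
      list(W = matrix(runif(sz[l] * sz[l + 1L], -lim, lim), sz[l + 1L], sz[l]),
           b = numeric(sz[l + 1L]))
    })
  })
}

pinn_pack <- function(layers) unlist(lapply(layers, function(l) c(l$W, l$b)))

pinn_unpack <- function(par, sz) {
  layers <- vector("list", length(sz) - 1L)
  off <- 0L
  for (l in seq_along(layers)) {
    nw <- sz[l] * sz[l + 1L]
    layers[[l]] <- list(W = matrix(par[off + seq_len(nw)], sz[l + 1L], sz[l]),
                        b = par[off + nw + seq_len(sz[l + 1L])])
    off <- off + nw + sz[l + 1L]
  }
  layers
}

# Forward pass over a time grid.  Returns the output matrix ((rp+1) x G) and,
# if keep = TRUE, the post-activation values of every layer for backprop.
pinn_forward <- function(layers, t, act, keep = FALSE) {
  A <- matrix(t, nrow = 1L)
  acts <- if (keep) vector("list", length(layers) + 1L)
  if (keep) acts[[1L]] <- A
  nl <- length(layers)
  for (l in seq_len(nl)) {
    Z <- layers[[l]]$W %*% A + layers[[l]]$b
    A <- if (l < nl) act$f(Z) else Z    # affine output layer
    if (keep) acts[[l + 1L]] <- A
  }
  if (keep) list(out = A, acts = acts) else A
}

# Mean squared residual of the structural equation for one response
# dimension, plus its gradient w.r.t. the packed parameters.
pinn_loss_grad <- function(par, sz, act, tt, Z, y, want_grad = TRUE) {
  layers <- pinn_unpack(par, sz)
  fw <- pinn_forward(layers, tt, act, keep = want_grad)
  out <- if (want_grad) fw$out else fw
  N <- length(y)
  pred <- colSums(out * t(Z))
  resid <- y - pred
  loss <- mean(resid^2)
  if (!want_grad) return(list(loss = loss))
  nl <- length(layers)
  delta <- -(2 / N) * t(Z * resid)          # (rp+1) x N
  grads <- vector("list", nl)
  for (l in nl:1) {
    A_prev <- fw$acts[[l]]
    grads[[l]] <- list(W = delta %*% t(A_prev), b = rowSums(delta))
    if (l > 1L)
      delta <- (t(layers[[l]]$W) %*% delta) * act$df(fw$acts[[l]])
  }
  list(loss = loss, grad = pinn_pack(grads))
}

fit_pinn <- function(series, r = 1, hidden = c(10, 10, 10),
                     activation = "tanh", maxit = 800, seed = 1,
                     weight_bounds = NULL) {
  series <- as_tvar_series(series)
  p <- series$p
  if (series$n_time <= r * p + 1L)
    stop("series too short for the requested lag order", call. = FALSE)
  design <- build_lagged_design(series, r)
  sz <- pinn_layer_sizes(hidden, r, p)
  act <- activation_fns(activation)
  tt <- design$times
  Z <- design$rows
  lower <- if (is.null(weight_bounds)) -Inf else weight_bounds[1L]
  upper <- if (is.null(weight_bounds)) Inf else weight_bounds[2L]

  params <- vector("list", p)
  final_loss <- numeric(p)
  initial_loss <- numeric(p)
  iterations <- integer(p)
  for (j in seq_len(p)) {
    par0 <- pinn_pack(pinn_init(hidden, r, p, seed = seed + (j - 1L)))
    y <- design$target[, j]
    cache <- new.env(parent = emptyenv())
    evaluate <- function(par) {
      if (!is.null(cache$par) && identical(par, cache$par)) return(cache$val)
      val <- pinn_loss_grad(par, sz, act, tt, Z, y)
      if (!is.finite(val$loss))
        stop("network training diverged: non-finite loss", call. = FALSE)
      cache$par <- par
      cache$val <- val
      val
    }
    initial_loss[j] <- evaluate(par0)$loss
    opt <- optim(par0,
                 fn = function(par) evaluate(par)$loss,
                 gr = function(par) evaluate(par)$grad,
                 method = "L-BFGS-B", lower = lower, upper = upper,
                 control = list(maxit = maxit, factr = 1e7))
    params[[j]] <- pinn_unpack(opt$par, sz)
    final_loss[j] <- opt$value
    iterations[j] <- opt$counts[1L]
  }
  structure(list(method = "pinn", r = r, p = p,
                 params = params, hidden = as.integer(hidden),
                 activation = activation, maxit = maxit, seed = seed,
                 weight_bounds = weight_bounds,
                 final_loss = final_loss, initial_loss = initial_loss,
                 iterations = iterations,
                 times = series$times, dt = time_step(series$times),
                 series = series, labels = colnames(series$values)),
            class = c("tvar_pinn", "tvar"))
}

# Coefficient trajectories for all response dimensions on a grid:
# list(intercept G x p, lag G x r x p x p).
pinn_trajectories <- function(fit, grid) {
  act <- activation_fns(fit$activation)
  G <- length(grid)
  p <- fit$p
  r <- fit$r
  intercept <- matrix(0, G, p)
  lag <- array(0, dim = c(G, r, p, p))
  for (j in seq_len(p)) {
    out <- pinn_forward(fit$params[[j]], grid, act)   # (rp+1) x G
    intercept[, j] <- out[1L, ]
    for (k in seq_len(r))
      lag[, k, j, ] <- t(out[1L + (k - 1L) * p + seq_len(p), , drop = FALSE])
  }
  list(grid = grid, intercept = intercept, lag = lag)
}
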