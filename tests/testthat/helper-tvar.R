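# Shared fixtures: tiny deterministic generators and independent oracles.

# Constant-coefficient AR(1) rolled out by an explicit loop (independent of
# the package's simulators).
const_ar1 <- function(f, c0, n, y0, noise_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  e <- if (noise_sd > 0) rnorm(n, sd = noise_sd) else numeric(n)
  y <- numeric(n)
  y[1] <- y0
  for (i in 2:n) y[i] <- c0 + f * y[i - 1] + e[i]
  y
}

# Normal-equations solution, the linear-algebra oracle for the fits.
ols_oracle <- function(X, y, w = NULL) {
  if (!is.null(w)) {
    X <- X * sqrt(w)
    y <- y * sqrt(w)
  }
  qr.solve(X, y)
}

# Central finite differences of a scalar function.
fd_grad <- function(fn, x, h = 1e-6) {
  vapply(seq_along(x), function(i) {
    xp <- x; xm <- x
    xp[i] <- xp[i] + h
    xm[i] <- xm[i] - h
    (fn(xp) - fn(xm)) / (2 * h)
  }, numeric(1))
}
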