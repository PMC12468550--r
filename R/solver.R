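# Least squares with a bound on a subset S of the coefficients:
#   constraint = "absolute":  sum_{j in S} |b_j| <= radius  (L1 ball)
#   constraint = "signed":    sum_{j in S}  b_j  <= radius  (halfspace)
#
# Strategy: the unconstrained QR solution is exact and is returned whenever it
# is feasible.  Otherwise the optimum lies on the constraint boundary; the
# halfspace case is a single equality-constrained QP solved exactly, and the
# L1-ball case is found by projected gradient (FISTA with adaptive restart)
# polished by solving the KKT system of the identified active sign pattern,
# which gives a machine-precision boundary solution when the pattern is
# correct.

constrained_ls <- function(X, y, weights = NULL, penalized, radius = 1,
                           constraint = c("absolute", "signed"),
                           tol = 1e-12, max_iter = 100000L) {
  constraint <- match.arg(constraint)
  X <- as.matrix(X)
  y <- as.numeric(y)
  m <- ncol(X)
  if (!is.null(weights)) {
    if (any(weights < 0)) stop("negative weights", call. = FALSE)
    if (max(weights) <= 0)
      stop("degenerate weights: all kernel weights vanish", call. = FALSE)
    sw <- sqrt(weights)
    Xw <- X * sw
    yw <- y * sw
  } else {
    Xw <- X
    yw <- y
  }

  qrX <- qr(Xw)
  if (qrX$rank < m)
    stop("rank-deficient design matrix", call. = FALSE)
  b_ols <- qr.coef(qrX, yw)
  cval <- function(b) if (constraint == "absolute") sum(abs(b[penalized]))
                      else sum(b[penalized])
  if (cval(b_ols) <= radius * (1 + 1e-9) + 1e-12) {
    r <- yw - Xw %*% b_ols
    return(list(coefficients = as.numeric(b_ols),
                objective = sum(r^2),
                constraint_value = cval(b_ols),
                active = FALSE, iterations = 0L, converged = TRUE))
  }

  XtX <- crossprod(Xw)
  Xty <- drop(crossprod(Xw, yw))

  if (constraint == "signed") {
    # single linear equality at the optimum: solve the KKT system directly
    s <- numeric(m)
    s[penalized] <- 1
    M <- rbind(cbind(2 * XtX, s), c(s, 0))
    sol <- solve(M, c(2 * Xty, radius))
    b <- sol[seq_len(m)]
    rr <- yw - Xw %*% b
    return(list(coefficients = as.numeric(b), objective = sum(rr^2),
                constraint_value = cval(b), active = TRUE,
                iterations = 1L, converged = TRUE))
  }
  L <- 2 * norm(Xw, "2")^2          # Lipschitz constant of the gradient
  step <- 1 / L
  obj <- function(b) {
    r <- yw - Xw %*% b
    sum(r^2)
  }
  proj <- function(b) {
    b[penalized] <- project_l1(b[penalized], radius)
    b
  }

  b <- proj(b_ols)
  z <- b
  tmom <- 1
  f_prev <- obj(b)
  it <- 0L
  converged <- FALSE
  while (it < max_iter) {
    it <- it + 1L
    grad <- 2 * (XtX %*% z - Xty)
    b_new <- proj(z - step * grad)
    t_new <- (1 + sqrt(1 + 4 * tmom^2)) / 2
    z <- b_new + ((tmom - 1) / t_new) * (b_new - b)
    f_new <- obj(b_new)
    if (f_new > f_prev) {          # adaptive restart
      z <- b_new
      t_new <- 1
    }
    if (it %% 250L == 0L) {
      # a KKT-validated active-set solve is exact for this convex QP
      polished <- polish_active_set(XtX, Xty, b_new, penalized, radius)
      if (!is.null(polished)) {
        b <- polished
        converged <- TRUE
        break
      }
      if (max(abs(b_new - b)) < tol * (1 + max(abs(b)))) {
        b <- b_new
        converged <- TRUE
        break
      }
    }
    b <- b_new
    tmom <- t_new
    f_prev <- f_new
  }

  if (!converged) {
    polished <- polish_active_set(XtX, Xty, b, penalized, radius)
    if (!is.null(polished) && obj(polished) <= obj(b) + 1e-12 * (1 + obj(b))) {
      b <- polished
      converged <- TRUE
    }
  }
  if (!converged) {
    gnorm <- max(abs(2 * (XtX %*% b - Xty)))
    stop(sprintf(paste0("constrained least-squares solver did not converge: ",
                        "constraint value %.6g, gradient norm %.3g"),
                 sum(abs(b[penalized])), gnorm), call. = FALSE)
  }
  list(coefficients = as.numeric(b),
       objective = obj(b),
       constraint_value = sum(abs(b[penalized])),
       active = TRUE, iterations = it, converged = TRUE)
}

# Euclidean projection of v onto the L1 ball of given radius (exact,
# sort-based soft threshold).
project_l1 <- function(v, radius) {
  a <- abs(v)
  if (sum(a) <= radius) return(v)
  u <- sort(a, decreasing = TRUE)
  css <- cumsum(u)
  k <- max(which(u > (css - radius) / seq_along(u)))
  theta <- (css[k] - radius) / k
  sign(v) * pmax(a - theta, 0)
}

# Solve the equality-constrained QP implied by the sign pattern of b:
#   min b' XtX b - 2 Xty' b   s.t.  sum_{j in A} s_j b_j = radius,
# zero coefficients outside the active set.  Returns NULL if the KKT
# conditions reject the pattern.
polish_active_set <- function(XtX, Xty, b, penalized, radius,
                              zero_tol = 1e-7) {
  m <- length(b)
  is_pen <- logical(m)
  is_pen[penalized] <- TRUE
  act_pen <- which(is_pen & abs(b) > zero_tol)
  keep <- which(!is_pen | abs(b) > zero_tol)
  if (length(act_pen) == 0L) return(NULL)
  s <- numeric(m)
  s[act_pen] <- sign(b[act_pen])
  k <- length(keep)
  M <- matrix(0, k + 1L, k + 1L)
  M[seq_len(k), seq_len(k)] <- 2 * XtX[keep, keep, drop = FALSE]
  M[seq_len(k), k + 1L] <- s[keep]
  M[k + 1L, seq_len(k)] <- s[keep]
  rhs <- c(2 * Xty[keep], radius)
  sol <- tryCatch(solve(M, rhs), error = function(e) NULL)
  if (is.null(sol)) return(NULL)
  bp <- numeric(m)
  bp[keep] <- sol[seq_len(k)]
  mu <- sol[k + 1L]
  if (mu < -1e-8) return(NULL)
  if (any(sign(bp[act_pen]) != s[act_pen])) return(NULL)
  # excluded penalized coordinates must satisfy |grad_j| <= mu
  excl <- which(is_pen & abs(b) <= zero_tol)
  if (length(excl)) {
    g <- 2 * (XtX[excl, , drop = FALSE] %*% bp - Xty[excl])
    if (any(abs(g) > abs(mu) + 1e-6)) return(NULL)
  }
  bp
}
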