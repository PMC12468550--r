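#' Smooth basis set for the varying-coefficient estimator
#'
#' Builds an ordered set of named scalar basis functions on `[0, 1]`.  The
#' default set covers polynomial trend, saturation, localized and periodic
#' shapes: linear `t`, quadratic `t^2`, `tanh(scale (t - center))`,
#' exponential `exp(t)`, Gaussian `exp(-(t - center)^2 / (2 sd^2))` and
#' cosine `cos(2 pi freq t)`.  A `"constant"` basis (identically 1) is also
#' available; with it alone the varying-coefficient design reduces to the
#' plain stationary lagged design.
#'
#' @param names Character vector of basis names, a subset of `"linear"`,
#'   `"quadratic"`, `"tanh"`, `"exponential"`, `"gaussian"`, `"cosine"`,
#'   `"constant"`.  Repeats are allowed (e.g. two Gaussians with different
#'   centers).
#' @param tanh_scale,tanh_center Shape of the tanh basis (default
#'   `tanh(5 (t - 0.5))`).
#' @param gauss_center,gauss_sd Shape of the Gaussian basis (default center
#'   0.5, sd 0.2).
#' @param cos_freq Frequency of the cosine basis in cycles per unit time.
#' @return Object of class `"tvar_basis"`: list of named functions plus the
#'   parameter record used for serialization.
#' @examples
#' bs <- tvar_basis()
#' eval_basis(bs, c(0, 0.5, 1))
#' @export
tvar_basis <- function(names = c("linear", "quadratic", "tanh",
                                 "exponential", "gaussian", "cosine"),
                       tanh_scale = 5, tanh_center = 0.5,
                       gauss_center = 0.5, gauss_sd = 0.2,
                       cos_freq = 1) {
  if (length(names) < 1L) stop("need at least one basis function", call. = FALSE)
  make1 <- function(nm) {
    switch(nm,
      constant    = function(t) rep(1, length(t)),
      linear      = function(t) t,
      quadratic   = function(t) t^2,
      tanh        = function(t) tanh(tanh_scale * (t - tanh_center)),
      exponential = function(t) exp(t),
      gaussian    = function(t) exp(-(t - gauss_center)^2 / (2 * gauss_sd^2)),
      cosine      = function(t) cos(2 * pi * cos_freq * t),
      stop(sprintf("unknown basis name '%s'", nm), call. = FALSE))
  }
  fns <- lapply(names, make1)
  names(fns) <- make.unique(names)
  structure(list(functions = fns, n = length(fns), names = names,
                 params = list(tanh_scale = tanh_scale,
                               tanh_center = tanh_center,
                               gauss_center = gauss_center,
                               gauss_sd = gauss_sd,
                               cos_freq = cos_freq)),
            class = "tvar_basis")
}

#' @export
print.tvar_basis <- function(x, ...) {
  cat(sprintf("Basis set with %d functions: %s\n", x$n,
              paste(names(x$functions), collapse = ", ")))
  invisible(x)
}

#' Evaluate a basis set on a time grid
#'
#' @param basis A [tvar_basis()].
#' @param t Numeric vector of times.
#' @return `length(t) x n` matrix, one column per basis function.
#' @export
eval_basis <- function(basis, t) {
  stopifnot(inherits(basis, "tvar_basis"))
  out <- vapply(basis$functions, function(f) as.numeric(f(t)),
                numeric(length(t)))
  if (length(t) == 1L) out <- matrix(out, nrow = 1L)
  colnames(out) <- names(basis$functions)
  if (any(!is.finite(out)))
    stop("basis function evaluated to a non-finite value", call. = FALSE)
  out
}
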