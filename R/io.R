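# CSV series input/output and JSON fit serialization.

#' Read a time series from CSV
#'
#' Expects a header row, a leading time column and one or more numeric value
#' columns.  A numeric time column is affinely mapped to `[0, 1]`; a
#' non-numeric one (dates, month labels) is taken to index equally spaced
#' observations in row order.
#'
#' @param path CSV file path.
#' @return A [tvar_series()] with the value column names as dimension
#'   labels.
#' @export
read_tvar_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  nf <- utils::count.fields(path, sep = ",", quote = "\"")
  if (length(unique(nf)) > 1L)
    stop(sprintf("parse error: ragged row at line %d of %s",
                 which(nf != nf[1L])[1L], path), call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  if (nrow(df) < 2L)
    stop(sprintf("parse error: %s has fewer than 2 data rows", path),
         call. = FALSE)
  if (ncol(df) < 2L)
    stop(sprintf("parse error: %s needs a time column and at least one value column", path),
         call. = FALSE)
  times_raw <- suppressWarnings(as.numeric(df[[1L]]))
  times <- if (anyNA(times_raw)) NULL else times_raw
  vals <- matrix(0, nrow(df), ncol(df) - 1L)
  for (j in 2:ncol(df)) {
    v <- suppressWarnings(as.numeric(df[[j]]))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1L]
      stop(sprintf("parse error: non-numeric value in column '%s' at line %d of %s",
                   names(df)[j], bad + 1L, path), call. = FALSE)
    }
    vals[, j - 1L] <- v
  }
  colnames(vals) <- names(df)[-1L]
  tvar_series(vals, times = times)
}

#' Write a time series to CSV
#'
#' Values are printed with 17 significant digits so a write/read round trip
#' reproduces them bit-exactly.
#'
#' @param series A [tvar_series()] (or coercible object).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_tvar_csv <- function(series, path) {
  series <- as_tvar_series(series)
  df <- data.frame(t = sprintf("%.17g", series$times),
                   apply(series$values, 2L, function(v) sprintf("%.17g", v)),
                   check.names = FALSE)
  names(df) <- c("t", colnames(series$values))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Ground-truth trajectory table: t, intercept per component, then lag
# coefficients in lag-major, row-major order (b<k>.<row><col>).
write_truth_csv <- function(sim, path) {
  tr <- sim$truth
  p <- dim(tr$lag)[3L]
  r <- dim(tr$lag)[2L]
  cols <- list(t = sprintf("%.17g", tr$grid))
  for (j in seq_len(p))
    cols[[paste0("c", j)]] <- sprintf("%.17g", tr$intercept[, j])
  for (k in seq_len(r))
    for (j in seq_len(p))
      for (m in seq_len(p))
        cols[[sprintf("b%d.%d%d", k, j, m)]] <- sprintf("%.17g", tr$lag[, k, j, m])
  utils::write.csv(as.data.frame(cols, check.names = FALSE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

schema_stop <- function(msg) stop(errorCondition(paste("invalid fit file:", msg),
                                                 class = c("tvar_schema_error", "error")))

#' Save / load a fitted model as JSON
#'
#' The file records a method tag, a format version and the method-specific
#' parameters (basis weights, kernel coefficients, network weights, or OLS
#' coefficients) together with the training series, so the restored object
#' reproduces the original's coefficient trajectories and forecasts.
#'
#' @param fit A fitted [tvar()] model.
#' @param path JSON file path.
#' @return `tvar_save` returns the path invisibly; `tvar_load` returns the
#'   restored `"tvar"` object.
#' @export
tvar_save <- function(fit, path) {
  stopifnot(inherits(fit, "tvar"))
  payload <- list(package = "tvarnet", format_version = 1L,
                  method = fit$method, r = fit$r, p = fit$p,
                  labels = fit$labels,
                  times = fit$times,
                  values = fit$series$values)
  payload <- c(payload, switch(fit$method,
    gam = list(zeta = fit$zeta,
               basis_names = fit$basis$names,
               basis_params = fit$basis$params,
               lag_time_basis = fit$lag_time_basis,
               radius = fit$radius,
               objective = fit$objective,
               constraint_value = fit$constraint_value),
    oks = c(list(beta = fit$beta, bandwidth = fit$bandwidth,
                 t_star = fit$t_star, radius = fit$radius,
                 objective = fit$objective,
                 constraint_value = fit$constraint_value),
            if (!is.null(fit$cv)) list(cv_scores = fit$cv$scores)),
    pinn = list(hidden = fit$hidden, activation = fit$activation,
                maxit = fit$maxit, seed = fit$seed,
                params = lapply(fit$params, pinn_pack),
                final_loss = fit$final_loss,
                iterations = fit$iterations),
    stationary = list(coeffs = fit$coeffs,
                      residual_variance = fit$residual_variance),
    schema_stop(sprintf("cannot serialize method '%s'", fit$method))))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname tvar_save
#' @export
tvar_load <- function(path) {
  if (!file.exists(path)) schema_stop(sprintf("no such file: %s", path))
  payload <- tryCatch(jsonlite::fromJSON(path),
                      error = function(e) schema_stop(conditionMessage(e)))
  need <- c("package", "format_version", "method", "r", "p", "times", "values")
  miss <- setdiff(need, names(payload))
  if (length(miss))
    schema_stop(paste("missing fields:", paste(miss, collapse = ", ")))
  if (!identical(payload$package, "tvarnet"))
    schema_stop("not a tvarnet fit file")
  if (payload$format_version != 1L)
    schema_stop(sprintf("unsupported format version %s",
                        format(payload$format_version)))
  method <- payload$method
  if (!method %in% c("gam", "oks", "pinn", "stationary"))
    schema_stop(sprintf("unknown method '%s'", method))
  vals <- matrix(as.numeric(payload$values), ncol = payload$p)
  colnames(vals) <- payload$labels
  series <- tvar_series(vals, times = payload$times)
  r <- as.integer(payload$r)
  p <- as.integer(payload$p)
  common <- list(method = method, r = r, p = p,
                 times = series$times, dt = time_step(series$times),
                 series = series, labels = payload$labels)
  obj <- switch(method,
    gam = {
      basis <- do.call(tvar_basis, c(list(names = payload$basis_names),
                                     payload$basis_params))
      c(common, list(zeta = matrix(as.numeric(payload$zeta), ncol = p),
                     basis = basis,
                     lag_time_basis = isTRUE(payload$lag_time_basis),
                     radius = payload$radius,
                     objective = payload$objective,
                     constraint_value = payload$constraint_value))
    },
    oks = c(common, list(beta = matrix(as.numeric(payload$beta), ncol = p),
                         bandwidth = payload$bandwidth,
                         t_star = payload$t_star, radius = payload$radius,
                         cv = if (!is.null(payload$cv_scores))
                           list(bandwidth = payload$bandwidth,
                                scores = as.data.frame(payload$cv_scores)),
                         objective = payload$objective,
                         constraint_value = payload$constraint_value)),
    pinn = {
      sz <- pinn_layer_sizes(payload$hidden, r, p)
      plist <- payload$params
      if (is.matrix(plist)) plist <- split(plist, row(plist))
      if (!is.list(plist)) plist <- list(as.numeric(plist))
      c(common, list(hidden = as.integer(payload$hidden),
                     activation = payload$activation,
                     maxit = payload$maxit, seed = payload$seed,
                     params = lapply(plist, function(v)
                       pinn_unpack(as.numeric(v), sz)),
                     final_loss = payload$final_loss,
                     iterations = payload$iterations))
    },
    stationary = c(common,
                   list(coeffs = matrix(as.numeric(payload$coeffs), ncol = p),
                        residual_variance = payload$residual_variance)))
  structure(obj, class = c(paste0("tvar_", method), "tvar"))
}
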