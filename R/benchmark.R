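#' Monte-Carlo forecast benchmark over the synthetic scenarios
#'
#' For each replication `k = 1, ..., reps` a scenario series of length
#' `n_time` is simulated with seed `base_seed + k`, every requested
#' method/lag combination is fitted on the first `n_time - max(horizons)`
#' points, a recursive forecast of `max(horizons)` steps is produced, and
#' the absolute error at each horizon is recorded (for multivariate
#' scenarios, averaged over the components at that step).  Rows report the
#' mean absolute error (MAE) and the root sample variance (RSV) of the
#' absolute errors across replications.
#'
#' By default the horizon-`H` row records the error of forecast step `H`
#' only; `step_error = "cumulative"` records the average absolute error over
#' steps `1..H` instead.
#'
#' @param scenarios Integer vector, subset of 1-4.
#' @param methods Character vector, subset of `"pinn"`, `"gam"`, `"oks"`,
#'   `"stationary"`.
#' @param lags Lag orders to fit.
#' @param horizons Forecast horizons to score.
#' @param reps Number of Monte-Carlo replications.
#' @param base_seed Integer; replication `k` uses seed `base_seed + k`, so
#'   the whole table is reproducible from this one integer.
#' @param n_time Length of each simulated series.
#' @param noise_weight Innovation weight of the generator.
#' @param step_error `"final"` or `"cumulative"`, see Details.
#' @param train_len Training window length; default `n_time - max(horizons)`.
#' @param keep_errors Attach the per-replication error table as
#'   `attr(, "errors")`.
#' @param control Named list of extra arguments per method, e.g.
#'   `list(pinn = list(maxit = 400))`.
#' @param progress Print one line per replication to stderr.
#' @return Data frame of class `"tvar_bench"` with columns `scenario`,
#'   `method`, `lag`, `horizon`, `mae`, `rsv`, `n_ok`, `reps`, `base_seed`.
#'   A row is emitted only if at least 90% of its replications succeeded;
#'   failures are reported in a warning.
#' @export
tvar_benchmark <- function(scenarios = 1:4,
                           methods = c("stationary", "gam", "oks", "pinn"),
                           lags = 1, horizons = c(1, 2), reps = 50,
                           base_seed = 1, n_time = 200, noise_weight = 0.1,
                           step_error = c("final", "cumulative"),
                           train_len = NULL, keep_errors = FALSE,
                           control = list(), progress = FALSE) {
  step_error <- match.arg(step_error)
  methods <- match.arg(methods, c("stationary", "gam", "oks", "pinn"),
                       several.ok = TRUE)
  hmax <- max(horizons)
  if (is.null(train_len)) train_len <- n_time - hmax
  if (train_len + hmax > n_time)
    stop("train_len + max(horizons) exceeds n_time", call. = FALSE)
  err <- array(NA_real_,
               dim = c(length(scenarios), length(methods), length(lags),
                       length(horizons), reps))
  fail_msgs <- character(0)
  for (si in seq_along(scenarios)) {
    sc <- scenarios[si]
    for (k in seq_len(reps)) {
      sim <- tvar_scenario(sc, n_time = n_time, noise_weight = noise_weight,
                           seed = base_seed + k)
      train <- tvar_series(sim$series$values[seq_len(train_len), , drop = FALSE])
      actual <- sim$series$values[train_len + horizons, , drop = FALSE]
      for (mi in seq_along(methods)) {
        for (li in seq_along(lags)) {
          res <- tryCatch({
            args <- c(list(train, r = lags[li], method = methods[mi]),
                      if (methods[mi] == "pinn")
                        utils::modifyList(list(seed = base_seed + k),
                                          control$pinn %||% list())
                      else control[[methods[mi]]] %||% list())
            fit <- do.call(tvar, args)
            pred <- predict(fit, h = hmax)
            step_abs <- rowMeans(abs(pred - sim$series$values[train_len +
                                                                seq_len(hmax), ,
                                                              drop = FALSE]))
            vapply(seq_along(horizons), function(hi) {
              H <- horizons[hi]
              if (step_error == "final") step_abs[H]
              else mean(step_abs[seq_len(H)])
            }, numeric(1))
          }, error = function(e) {
            fail_msgs <<- c(fail_msgs,
                            sprintf("scenario %s %s(r=%d) rep %d: %s", sc,
                                    methods[mi], lags[li], k, conditionMessage(e)))
            rep(NA_real_, length(horizons))
          })
          err[si, mi, li, , k] <- res
        }
      }
      if (progress)
        message(sprintf("scenario %s: replication %d/%d done", sc, k, reps))
    }
  }
  rows <- expand.grid(horizon = horizons, lag = lags, method = methods,
                      scenario = scenarios, stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(seq_len(nrow(rows)), function(i) {
    si <- match(rows$scenario[i], scenarios)
    mi <- match(rows$method[i], methods)
    li <- match(rows$lag[i], lags)
    hi <- match(rows$horizon[i], horizons)
    e <- err[si, mi, li, hi, ]
    ok <- sum(!is.na(e))
    if (ok < 0.9 * reps) return(NULL)
    data.frame(scenario = rows$scenario[i], method = rows$method[i],
               lag = rows$lag[i], horizon = rows$horizon[i],
               mae = mean(e, na.rm = TRUE),
               rsv = if (ok >= 2) rsv(e[!is.na(e)]) else NA_real_,
               n_ok = ok, reps = reps, base_seed = base_seed)
  }))
  if (length(fail_msgs))
    warning(sprintf("%d replication fit(s) failed:\n%s", length(fail_msgs),
                    paste(utils::head(fail_msgs, 5L), collapse = "\n")),
            call. = FALSE)
  if (is.null(out))
    stop("no benchmark row had >= 90% successful replications", call. = FALSE)
  rownames(out) <- NULL
  class(out) <- c("tvar_bench", "data.frame")
  if (keep_errors) attr(out, "errors") <- err
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.tvar_bench <- function(x, digits = 4, ...) {
  cat(sprintf("Forecast benchmark: %d replications, base seed %d\n",
              x$reps[1L], x$base_seed[1L]))
  df <- as.data.frame(x)
  df$mae <- signif(df$mae, digits)
  df$rsv <- signif(df$rsv, digits)
  print(df[, c("scenario", "method", "lag", "horizon", "mae", "rsv", "n_ok")],
        row.names = FALSE)
  invisible(x)
}
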