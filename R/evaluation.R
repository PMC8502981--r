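#' Root mean square error
#'
#' `sqrt(mean((predicted - target)^2))`, computed on the (possibly
#' nonuniform) resampled grid exactly as trained — no time weighting.
#'
#' @param target,predicted Equal-length numeric vectors.
#' @return A non-negative scalar.
#' @examples
#' rmse(c(0, 1), c(1, 1))  # sqrt(1/2)
#' @export
rmse <- function(target, predicted) {
  if (length(target) != length(predicted)) abort("length mismatch")
  if (length(target) == 0) abort("empty sequences")
  sqrt(mean((predicted - target)^2))
}

#' Extract per-beat action potential durations
#'
#' An action potential duration (APD) is the time interval over which the
#' voltage stays continuously above `threshold` (0.3 for the synthetic
#' datasets on the unit voltage scale). Crossing times are refined by
#' linear interpolation between the bracketing samples; runs touching the
#' first or last sample are discarded as truncated.
#'
#' @param series A series tibble (unit-rescaled voltage).
#' @param threshold Crossing level.
#' @return A tibble of class `apd_series` with columns `onset` (up-crossing
#'   time), `offset` (down-crossing time) and `apd` (ms), plus a
#'   `threshold` attribute. Zero rows when no complete crossing exists.
#' @examples
#' tri <- tibble::tibble(time = c(0, 50, 100), voltage = c(0, 1, 0))
#' extract_apds(tri, threshold = 0.5)$apd  # 50
#' @export
extract_apds <- function(series, threshold = 0.3) {
  check_series(series)
  v <- series$voltage
  t <- series$time
  above <- v > threshold
  n <- length(v)
  empty <- tibble(onset = numeric(0), offset = numeric(0),
                  apd = numeric(0))
  if (!any(above)) {
    return(structure(empty, threshold = threshold,
                     class = c("apd_series", class(empty))))
  }
  d <- diff(above)
  ups <- which(d == 1)        # v[i] <= thr < v[i+1]
  downs <- which(d == -1)     # v[i] > thr >= v[i+1]
  # keep only complete runs: an up-crossing followed by a down-crossing
  if (above[1]) downs <- downs[downs > if (length(ups)) ups[1] else n]
  m <- min(length(ups), length(downs))
  if (m == 0) {
    return(structure(empty, threshold = threshold,
                     class = c("apd_series", class(empty))))
  }
  ups <- ups[seq_len(m)]
  downs <- downs[seq_len(m)]
  interp <- function(i) {
    t[i] + (threshold - v[i]) / (v[i + 1] - v[i]) * (t[i + 1] - t[i])
  }
  onset <- interp(ups)
  offset <- interp(downs)
  out <- tibble(onset = onset, offset = offset, apd = offset - onset)
  structure(out, threshold = threshold,
            class = c("apd_series", class(out)))
}

#' Per-beat absolute APD error
#'
#' Matches predicted beats to true beats by onset proximity (nearest
#' predicted onset within `max_gap`, defaulting to half the median true
#' cycle length) and reports the absolute APD difference per matched beat.
#' Unmatched true beats are reported as misses, not errors.
#'
#' @param true,pred `apd_series` tibbles from [extract_apds()].
#' @param max_gap Maximum onset separation for a match (ms).
#' @return A tibble with one row per true beat: `onset_true`, `apd_true`,
#'   `apd_pred`, `abs_error`, `matched`.
#' @export
apd_error <- function(true, pred, max_gap = NULL) {
  if (is.null(max_gap)) {
    cl <- diff(true$onset)
    max_gap <- if (length(cl) > 0) median(cl) / 2 else Inf
  }
  rows <- lapply(seq_len(nrow(true)), function(i) {
    if (nrow(pred) == 0) {
      return(tibble(onset_true = true$onset[i], apd_true = true$apd[i],
                    apd_pred = NA_real_, abs_error = NA_real_,
                    matched = FALSE))
    }
    gap <- abs(pred$onset - true$onset[i])
    j <- which.min(gap)
    ok <- gap[j] <= max_gap
    tibble(
      onset_true = true$onset[i], apd_true = true$apd[i],
      apd_pred = if (ok) pred$apd[j] else NA_real_,
      abs_error = if (ok) abs(pred$apd[j] - true$apd[i]) else NA_real_,
      matched = ok
    )
  })
  bind_rows(rows)
}

#' Evaluate a closed-loop forecast
#'
#' Computes the test-grid RMSE and the per-beat APD comparison between the
#' true test segment and the predictions, and bundles them with run
#' metadata into an evaluation report.
#'
#' @param split The [split_train_test()] object.
#' @param predictions A tibble `time`, `voltage` aligned with `split$test`
#'   (as returned by the forecasters).
#' @param threshold APD threshold (0.3 for synthetic data).
#' @param forecaster Label recorded in the report.
#' @param n_neurons,seed,hyperparameters Metadata recorded in the report.
#' @param wall_time Elapsed seconds, if measured.
#' @return An object of class `eval_report`.
#' @export
evaluate_forecast <- function(split, predictions, threshold = 0.3,
                              forecaster = "esn", n_neurons = NA_integer_,
                              seed = NA_integer_, hyperparameters = list(),
                              wall_time = NA_real_) {
  stopifnot(inherits(split, "dataset_split"))
  if (nrow(predictions) != nrow(split$test))
    abort("predictions must align with the test grid")
  err <- rmse(split$test$voltage, predictions$voltage)
  apd_true <- extract_apds(split$test, threshold)
  apd_pred <- extract_apds(predictions, threshold)
  structure(
    list(rmse = err, apd_true = apd_true, apd_pred = apd_pred,
         apd = apd_error(apd_true, apd_pred), threshold = threshold,
         forecaster = forecaster, n_neurons = n_neurons, seed = seed,
         hyperparameters = hyperparameters, wall_time = wall_time,
         predictions = predictions, test = split$test),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  matched <- x$apd$abs_error[x$apd$matched]
  cat(sprintf(
    paste0("<eval_report> %s: RMSE %.4f; APD |err| median %.2f ms, ",
           "max %.2f ms over %d matched beats (%d missed)\n"),
    x$forecaster, x$rmse,
    if (length(matched)) median(matched) else NA,
    if (length(matched)) max(matched) else NA,
    length(matched), sum(!x$apd$matched)
  ))
  invisible(x)
}
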