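#' Rescale a voltage series onto the unit interval
#'
#' Linearly maps the voltage column so its minimum becomes 0 and its maximum
#' 1, recording the affine map in the `rescale_map` attribute so predictions
#' can be mapped back to physical units. Series flagged as already scaled
#' (the Fenton-Karma model's voltage by construction peaks near 1) pass
#' through unchanged with an identity map.
#'
#' @param series A series tibble (`time`, `voltage`[, `stimulus`]).
#' @param prescaled If `TRUE`, return the series unchanged with an identity
#'   map recorded.
#' @return The rescaled series with attribute `rescale_map`, a list
#'   `(offset, scale)` such that `scaled = (voltage - offset) / scale`.
#' @examples
#' s <- tibble::tibble(time = 0:3, voltage = c(-80, -20, 40, -80))
#' r <- rescale_unit_interval(s)
#' range(r$voltage)
#' attr(r, "rescale_map")
#' @export
rescale_unit_interval <- function(series, prescaled = FALSE) {
  check_series(series)
  if (prescaled) {
    attr(series, "rescale_map") <- list(offset = 0, scale = 1)
    return(series)
  }
  lo <- min(series$voltage)
  hi <- max(series$voltage)
  if (hi - lo <= 0) abort("cannot rescale a constant voltage series")
  out <- series
  out$voltage <- (series$voltage - lo) / (hi - lo)
  attr(out, "rescale_map") <- list(offset = lo, scale = hi - lo)
  out
}

#' Invert a unit-interval rescaling
#'
#' @param series A rescaled series carrying a `rescale_map` attribute (or an
#'   explicit `map`).
#' @param map Optional list `(offset, scale)` overriding the attribute.
#' @return The series with voltage mapped back to original units.
#' @export
unrescale <- function(series, map = NULL) {
  check_series(series)
  map <- map %||% attr(series, "rescale_map")
  if (is.null(map)) abort("no rescale map available")
  out <- series
  out$voltage <- series$voltage * map$scale + map$offset
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Voltage-adaptive undersampling of a series
#'
#' Uniform-in-time sampling over-represents the slow plateau and rest phases
#' of an action potential relative to the rapid upstroke. This resampler
#' keeps a point only if its voltage differs from the last kept point by at
#' least `dv_threshold`, or if more than `dt_max` has elapsed since the last
#' kept point (so slowly varying phases retain a minimum density). The first
#' point is always kept, every kept point is a point of the input, and with
#' `dv_threshold = 0` the series is unchanged.
#'
#' @param series A series tibble.
#' @param dv_threshold Minimum voltage change (same units as `voltage`),
#'   >= 0.
#' @param dt_max Maximum time gap between kept points (ms), > 0.
#' @return The undersampled series (all columns subset at kept rows).
#' @examples
#' s <- tibble::tibble(time = seq(0, 10, 0.5), voltage = sin(seq(0, 10, 0.5)))
#' nrow(resample_series(s, dv_threshold = 0.2, dt_max = 3))
#' @export
resample_series <- function(series, dv_threshold = 0.02, dt_max = 20) {
  check_series(series)
  if (dv_threshold < 0) abort("dv_threshold must be >= 0")
  if (dt_max <= 0) abort("dt_max must be > 0")
  if (dv_threshold == 0) return(series)
  keep <- .resample_keep_idx(series$time, series$voltage, dv_threshold,
                             dt_max)
  out <- series[keep, , drop = FALSE]
  for (a in c("rescale_map", "model", "dt", "params", "protocol")) {
    attr(out, a) <- attr(series, a)
  }
  out
}

#' Detect beat onsets by threshold crossing
#'
#' Finds the upward crossings of `upstroke_threshold` in the voltage trace,
#' with a refractory lockout so the noisy shoulder of a single upstroke is
#' not double-counted. Intended for unit-rescaled series.
#'
#' @param series A series tibble (voltage on, or near, `[0, 1]`).
#' @param upstroke_threshold Crossing level.
#' @param lockout Minimum spacing between detected onsets (ms).
#' @return Numeric vector of onset times (possibly empty).
#' @export
detect_beat_onsets <- function(series, upstroke_threshold = 0.15,
                               lockout = 50) {
  check_series(series)
  v <- series$voltage
  t <- series$time
  up <- which(v[-1] >= upstroke_threshold & v[-length(v)] < upstroke_threshold)
  if (length(up) == 0) return(numeric(0))
  # linear interpolation of the crossing time within the bracketing pair
  frac <- (upstroke_threshold - v[up]) / (v[up + 1] - v[up])
  times <- t[up] + frac * (t[up + 1] - t[up])
  onsets <- times[1]
  for (tt in times[-1]) {
    if (tt - onsets[length(onsets)] >= lockout) onsets <- c(onsets, tt)
  }
  onsets
}

#' Reconstruct a square-pulse stimulus channel on a sampling grid
#'
#' Stamps 2-ms square pulses of relative magnitude 0.2 (configurable) at the
#' given onset times onto an arbitrary, possibly nonuniform, sampling grid:
#' a grid point carries `amplitude` iff it lies inside some
#' `[onset, onset + duration)`. Used when stimulus timing is known only
#' through detected beat onsets.
#'
#' @param onsets Pulse onset times (ms), strictly increasing.
#' @param grid_times Sampling grid (ms).
#' @param duration,amplitude Pulse shape; defaults 2 ms and 0.2.
#' @return Numeric stimulus vector aligned with `grid_times`. Warns if a
#'   pulse covers no grid point.
#' @export
reconstruct_stimulus_channel <- function(onsets, grid_times, duration = 2,
                                         amplitude = 0.2) {
  if (length(onsets) == 0) return(numeric(length(grid_times)))
  if (any(diff(onsets) <= 0)) abort("onsets must be strictly increasing")
  if (any(diff(onsets) < duration)) abort("overlapping pulses")
  if (min(onsets) < min(grid_times) ||
      max(onsets) > max(grid_times))
    abort("onsets must lie within the grid span")
  proto <- stim_protocol(onsets, duration = duration, amplitude = amplitude)
  out <- square_pulse_current(grid_times, proto)
  hit <- vapply(onsets, function(o) {
    any(grid_times >= o & grid_times < o + duration)
  }, logical(1))
  if (!all(hit)) {
    warn(sprintf("%d pulse(s) cover no grid point", sum(!hit)))
  }
  out
}

#' Replace artifact windows by cubic-spline interpolation
#'
#' Voltage samples falling inside each window are replaced by a natural
#' cubic spline fitted to the surrounding clean samples, as used to remove
#' pacing artifacts from microelectrode recordings. Samples outside every
#' window are untouched.
#'
#' @param series A series tibble.
#' @param windows A list of `c(start, end)` time intervals (ms),
#'   non-overlapping, each strictly inside the series time span.
#' @param margin Width of the clean anchor region on each side (ms).
#' @return The series with interpolated voltage inside the windows.
#' @export
remove_artifacts_spline <- function(series, windows, margin = 10) {
  check_series(series)
  if (length(windows) == 0) return(series)
  w <- do.call(rbind, lapply(windows, function(x) sort(as.numeric(x))))
  w <- w[order(w[, 1]), , drop = FALSE]
  if (any(w[-1, 1] < w[-nrow(w), 2])) abort("windows must not overlap")
  if (w[1, 1] <= min(series$time) || w[nrow(w), 2] >= max(series$time))
    abort("windows must not cover the series start or end")
  out <- series
  for (i in seq_len(nrow(w))) {
    inside <- out$time >= w[i, 1] & out$time <= w[i, 2]
    if (!any(inside)) next
    anchor <- !inside &
      out$time >= w[i, 1] - margin & out$time <= w[i, 2] + margin
    if (sum(anchor) < 4) abort("too few anchor samples around a window")
    fit <- spline(out$time[anchor], out$voltage[anchor],
                  xout = out$time[inside], method = "natural")
    out$voltage[inside] <- fit$y
  }
  out
}

#' Split a series into warmup, training and test segments at beat onsets
#'
#' Partitions the series contiguously at beat boundaries: the first
#' `n_warmup_beats` beats are the transient (washout) segment, used to
#' develop forecaster state but never to fit parameters; the next
#' `n_train_beats` are training data; all remaining beats form the test
#' (prediction) horizon.
#'
#' @param series A (typically resampled, rescaled) series tibble.
#' @param onsets Beat onset times from [detect_beat_onsets()].
#' @param n_warmup_beats,n_train_beats Beat counts for the first two
#'   segments; at least one beat must remain for testing.
#' @return An object of class `dataset_split`: a list with series tibbles
#'   `pre_train`, `train`, `test`, the full `series`, `beat_onsets`, and the
#'   boundary indices.
#' @export
split_train_test <- function(series, onsets, n_warmup_beats = 10,
                             n_train_beats = 71) {
  check_series(series)
  n_beats <- length(onsets)
  if (n_beats < n_warmup_beats + n_train_beats + 1) {
    abort(sprintf(
      "need > %d beats for %d warmup + %d training, have %d",
      n_warmup_beats + n_train_beats, n_warmup_beats, n_train_beats, n_beats
    ))
  }
  t_train_start <- onsets[n_warmup_beats + 1]
  t_test_start <- onsets[n_warmup_beats + n_train_beats + 1]
  seg <- findInterval(series$time, c(t_train_start, t_test_start))
  out <- structure(
    list(
      pre_train = series[seg == 0, , drop = FALSE],
      train = series[seg == 1, , drop = FALSE],
      test = series[seg == 2, , drop = FALSE],
      series = series,
      beat_onsets = onsets,
      n_warmup_beats = n_warmup_beats,
      n_train_beats = n_train_beats,
      n_test_beats = n_beats - n_warmup_beats - n_train_beats,
      rescale_map = attr(series, "rescale_map") %||%
        list(offset = 0, scale = 1)
    ),
    class = "dataset_split"
  )
  out
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf(
    paste0("<dataset_split> %d beats (%d warmup / %d train / %d test), ",
           "%d samples (%d train, %d test)\n"),
    length(x$beat_onsets), x$n_warmup_beats, x$n_train_beats,
    x$n_test_beats, nrow(x$series), nrow(x$train), nrow(x$test)
  ))
  invisible(x)
}
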