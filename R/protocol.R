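#' Stimulus protocols
#'
#' A stimulus protocol is the list of square-pulse onset times delivered to a
#' paced cell, together with the common pulse duration and amplitude. The
#' random-cycle-length constructor draws successive inter-stimulus intervals
#' from a normal distribution, which is the pacing regime that produces
#' irregular beat-to-beat action-potential-duration (APD) dynamics, including
#' alternans, in the Fenton-Karma model.
#'
#' @param pulse_times Strictly increasing pulse onset times (ms).
#' @param duration Pulse duration (ms), > 0.
#' @param amplitude Dimensionless pulse current magnitude, >= 0.
#'
#' @return An object of class `stim_protocol`: a list with elements
#'   `pulse_times`, `duration`, `amplitude` and (for random protocols)
#'   `n_redraws`, the number of intervals redrawn at the cycle-length floor.
#' @examples
#' p <- stim_protocol(c(0, 300, 600), duration = 2, amplitude = 0.4)
#' square_pulse_current(c(0, 1.9, 2, 150, 300), p)
#' @export
stim_protocol <- function(pulse_times, duration = 2, amplitude = 0.4) {
  pulse_times <- as.numeric(pulse_times)
  if (length(pulse_times) == 0) abort("protocol needs at least one pulse")
  if (any(diff(pulse_times) <= 0)) {
    abort("pulse_times must be strictly increasing")
  }
  if (duration <= 0) abort("pulse_duration must be positive")
  if (amplitude < 0) abort("pulse_amplitude must be non-negative")
  structure(
    list(pulse_times = pulse_times, duration = duration,
         amplitude = amplitude, n_redraws = 0L),
    class = "stim_protocol"
  )
}

#' @export
print.stim_protocol <- function(x, ...) {
  cat(sprintf(
    "<stim_protocol> %d pulses, %.3g ms x %.3g; onsets %.1f..%.1f ms\n",
    length(x$pulse_times), x$duration, x$amplitude,
    min(x$pulse_times), max(x$pulse_times)
  ))
  invisible(x)
}

#' Random-cycle-length pacing protocol
#'
#' Draws `n_beats` inter-stimulus intervals from Normal(`mean_cl`, `sd_cl`)
#' and accumulates them into pulse onset times. Intervals below `cl_floor`
#' (non-physiological: inside the cell's refractory period) are redrawn; the
#' number of redraws is recorded on the returned protocol. The first pulse is
#' delivered at `t_start`.
#'
#' @param n_beats Number of stimuli, > 0.
#' @param mean_cl Mean cycle length (ms), > `duration`.
#' @param sd_cl Cycle-length standard deviation (ms), >= 0.
#' @param duration,amplitude Square-pulse duration (ms) and magnitude.
#' @param seed Integer seed; the protocol is reproducible given the seed.
#' @param cl_floor Minimum admissible cycle length (ms).
#' @param t_start Onset of the first pulse (ms).
#' @param max_redraws Bound on redraw attempts per interval before failing.
#'
#' @return A `stim_protocol`.
#' @examples
#' p <- make_random_cl_protocol(10, mean_cl = 320, sd_cl = 50, seed = 1)
#' diff(p$pulse_times)
#' @export
make_random_cl_protocol <- function(n_beats, mean_cl = 320, sd_cl = 50,
                                    duration = 2, amplitude = 0.4,
                                    seed = 1L, cl_floor = 150,
                                    t_start = 50, max_redraws = 1000L) {
  if (n_beats <= 0) abort("n_beats must be positive")
  if (mean_cl <= 0) abort("mean_cl must be positive")
  if (sd_cl < 0) abort("sd_cl must be non-negative")
  if (mean_cl <= duration) abort("mean_cl must exceed the pulse duration")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  n_redraws <- 0L
  intervals <- numeric(if (n_beats > 1) n_beats - 1 else 0)
  for (i in seq_along(intervals)) {
    cl <- rnorm(1, mean_cl, sd_cl)
    tries <- 0L
    while (cl < cl_floor) {
      tries <- tries + 1L
      if (tries > max_redraws) {
        abort("cycle-length draw stayed below the floor after max_redraws")
      }
      cl <- rnorm(1, mean_cl, sd_cl)
    }
    n_redraws <- n_redraws + tries
    intervals[i] <- cl
  }
  p <- stim_protocol(t_start + c(0, cumsum(intervals)),
                     duration = duration, amplitude = amplitude)
  p$n_redraws <- n_redraws
  p
}

#' Square-pulse stimulus current
#'
#' Evaluates the protocol's stimulus current at arbitrary times. Each pulse
#' occupies the half-open interval `[onset, onset + duration)`.
#'
#' @param t Times (ms), vectorised.
#' @param protocol A [stim_protocol()].
#' @return Numeric vector of current values (0 or `amplitude`).
#' @export
square_pulse_current <- function(t, protocol) {
  stopifnot(inherits(protocol, "stim_protocol"))
  idx <- findInterval(t, protocol$pulse_times)
  on <- idx >= 1 &
    t < protocol$pulse_times[pmax(idx, 1L)] + protocol$duration
  ifelse(on, protocol$amplitude, 0)
}

# Save/restore the global RNG state so seeded constructors do not perturb
# the caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# Internal: run code under a temporary seed, restoring the caller's stream.
with_seed <- function(seed, code) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  force(code)
}
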