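#' Model parameter sets
#'
#' Constructors for the three cell-model configurations. `fk_params()`
#' returns the Fenton-Karma three-variable parameters; the default
#' `"set3"` is the Beeler-Reuter fitting (parameter set 3 of Fenton,
#' Cherry, Hastings & Evans 2002, Chaos 12:852, Table 1). `ms_params()`
#' returns the Corrado-Niederer variant of the Mitchell-Schaeffer
#' two-variable model with the time constants used throughout this package,
#' and `noble_lorenz_params()` the configuration of the Noble (1962)
#' Purkinje model driven by a time-rescaled Lorenz system.
#'
#' @param set Named FK parameter set; only `"set3"` is built in, but any
#'   value can be overridden through `...`.
#' @param ... Named overrides of individual constants.
#'
#' @return A named list of model constants.
#' @examples
#' fk_params()$tau_r
#' ms_params(v_gate = 0.2)
#' @export
fk_params <- function(set = "set3", ...) {
  if (!identical(set, "set3")) abort("unknown FK parameter set")
  base <- list(
    # Beeler-Reuter fit: Fenton et al. 2002, Table 1, set 3
    tau_d = 0.25, tau_r = 33.33, tau_si = 29, tau_0 = 12.5,
    tau_v_plus = 3.33, tau_v1_minus = 1250, tau_v2_minus = 19.6,
    tau_w_plus = 870, tau_w_minus = 41,
    u_c = 0.13, u_v = 0.04, u_c_si = 0.85, k = 10
  )
  pars <- modifyList(base, list(...))
  taus <- grep("^tau", names(pars), value = TRUE)
  if (any(unlist(pars[taus]) <= 0)) abort("all FK time constants must be > 0")
  pars
}

#' @rdname fk_params
#' @export
ms_params <- function(...) {
  base <- list(
    tau_in = 0.3, tau_out = 6, tau_open = 120, tau_close = 150,
    v_gate = 0.13
  )
  pars <- modifyList(base, list(...))
  if (any(unlist(pars[c("tau_in", "tau_out", "tau_open", "tau_close")]) <= 0))
    abort("all MS time constants must be > 0")
  if (pars$v_gate <= 0 || pars$v_gate > 1) abort("v_gate must lie in (0, 1]")
  pars
}

#' @rdname fk_params
#' @export
noble_lorenz_params <- function(...) {
  base <- list(
    rho = 28, b = 8 / 3, sigma = 10,
    lorenz_time_factor = 0.001,
    # anionic conductance g(z): linear through g(0) = 0, g(60) = 0.2,
    # clipped below at 0
    g_an_slope = 0.2 / 60
  )
  pars <- modifyList(base, list(...))
  if (pars$lorenz_time_factor <= 0) abort("lorenz_time_factor must be > 0")
  pars
}

# Internal constructor/validator for the universal series currency: a tibble
# with strictly increasing `time` (ms), `voltage`, and optionally `stimulus`.
new_series <- function(time, voltage, stimulus = NULL) {
  if (length(time) != length(voltage)) abort("time/voltage length mismatch")
  if (any(!is.finite(time)) || any(!is.finite(voltage)))
    abort("series values must be finite")
  if (any(diff(time) <= 0)) abort("series times must be strictly increasing")
  if (is.null(stimulus)) {
    tibble(time = time, voltage = voltage)
  } else {
    if (length(stimulus) != length(time)) abort("stimulus length mismatch")
    tibble(time = time, voltage = voltage, stimulus = stimulus)
  }
}

check_series <- function(series) {
  if (!is.data.frame(series) ||
      !all(c("time", "voltage") %in% names(series)))
    abort("a series needs `time` and `voltage` columns")
  if (any(diff(series$time) <= 0))
    abort("series times must be strictly increasing")
  invisible(series)
}

#' Simulate the Fenton-Karma model under a pacing protocol
#'
#' Integrates the three-variable Fenton-Karma model (voltage `u` plus gates
#' `v`, `w`) by forward Euler on a uniform grid and returns the voltage
#' together with the applied stimulus channel. The model's voltage is
#' dimensionless with an upstroke maximum near 1, so no rescaling is needed
#' downstream.
#'
#' @param protocol A [stim_protocol()].
#' @param t_end End of integration (ms); defaults to one mean cycle past the
#'   final pulse.
#' @param dt Euler step (ms).
#' @param params Constants from [fk_params()].
#' @param init Initial `(u, v, w)`; the default is the rested state.
#'
#' @return A tibble with columns `time`, `voltage`, `stimulus` and
#'   attributes `model`, `dt`, `params`.
#' @examples
#' p <- stim_protocol(10, duration = 2, amplitude = 0.4)
#' s <- simulate_fk(p, t_end = 400)
#' max(s$voltage)
#' @export
simulate_fk <- function(protocol, t_end = NULL, dt = 0.1,
                        params = fk_params(), init = c(0, 1, 1)) {
  stopifnot(inherits(protocol, "stim_protocol"))
  if (dt <= 0) abort("dt must be positive")
  if (dt > protocol$duration)
    abort("dt must not exceed the pulse duration")
  if (is.null(t_end)) {
    t_end <- max(protocol$pulse_times) +
      mean(c(diff(protocol$pulse_times), 350))
  }
  if (t_end < max(protocol$pulse_times) + protocol$duration)
    abort("t_end must cover every pulse")
  out <- .fk_integrate(params, protocol$pulse_times, protocol$duration,
                       protocol$amplitude, t_end, dt, as.numeric(init))
  s <- new_series(out$time, out$voltage, out$stimulus)
  attr(s, "model") <- "fenton_karma"
  attr(s, "dt") <- dt
  attr(s, "params") <- params
  attr(s, "protocol") <- protocol
  s
}

#' Simulate the Mitchell-Schaeffer (Corrado-Niederer) model
#'
#' Two-variable knowledge-based model used by the hybrid forecaster. The
#' inward current is the gated cubic `h v (v - v_gate)(1 - v) / tau_in`, so
#' the rest state is stable and each suprathreshold pulse elicits one action
#' potential on the `[0, 1]` voltage scale.
#'
#' @inheritParams simulate_fk
#' @param params Constants from [ms_params()].
#' @param init Initial `(v, h)`; default is rest with the gate fully open.
#' @return A tibble with `time`, `voltage`, `stimulus` columns.
#' @export
simulate_ms <- function(protocol, t_end = NULL, dt = 0.1,
                        params = ms_params(), init = c(0, 1)) {
  stopifnot(inherits(protocol, "stim_protocol"))
  if (dt <= 0) abort("dt must be positive")
  if (dt > protocol$duration)
    abort("dt must not exceed the pulse duration")
  if (is.null(t_end)) {
    t_end <- max(protocol$pulse_times) +
      mean(c(diff(protocol$pulse_times), 350))
  }
  if (t_end < max(protocol$pulse_times) + protocol$duration)
    abort("t_end must cover every pulse")
  out <- .ms_integrate(params, protocol$pulse_times, protocol$duration,
                       protocol$amplitude, t_end, dt, as.numeric(init))
  s <- new_series(out$time, out$voltage, out$stimulus)
  attr(s, "model") <- "mitchell_schaeffer_cn"
  attr(s, "dt") <- dt
  attr(s, "params") <- params
  attr(s, "protocol") <- protocol
  s
}

#' Simulate the Noble model driven by a chaotic Lorenz system
#'
#' Co-integrates the four-variable Noble (1962) Purkinje model with the
#' Lorenz system in its chaotic regime (`rho = 28`, `b = 8/3`,
#' `sigma = 10`). The Lorenz right-hand sides are multiplied by
#' `lorenz_time_factor` so the chaotic forcing evolves on the millisecond
#' scale, and the Noble anionic conductance is slaved to the Lorenz `z`
#' variable through a linear map with `g(0) = 0` and `g(60) = 0.2`. Action
#' potentials arise without external pacing, so the returned series is
#' univariate (no stimulus column); its voltage is in mV and should be
#' rescaled with [rescale_unit_interval()] before forecasting.
#'
#' @param t_end Length of the retained recording (ms), after burn-in.
#' @param dt Euler step (ms); the fast sodium activation gate needs a small
#'   step under forward Euler.
#' @param params Constants from [noble_lorenz_params()].
#' @param seed Integer seed jittering the Lorenz initial condition.
#' @param burn_in Discarded initial transient (ms).
#' @param keep_every Keep every k-th integration point (thinning factor), so
#'   the stored series has spacing `dt * keep_every`.
#' @param noble_init,lorenz_init Initial states `(V, m, h, n)` and
#'   `(x, y, z)`.
#'
#' @return A tibble with columns `time`, `voltage` (mV) and attribute
#'   `lorenz_z` holding the sampled Lorenz `z` trajectory.
#' @export
simulate_noble_lorenz <- function(t_end = 30000, dt = 0.01,
                                  params = noble_lorenz_params(),
                                  seed = 1L, burn_in = 5000,
                                  keep_every = 10L,
                                  noble_init = c(-80, 0.05, 0.8, 0.55),
                                  lorenz_init = c(1, 1, 25)) {
  if (t_end <= 0 || dt <= 0) abort("t_end and dt must be positive")
  jitter <- with_seed(seed, runif(3, -0.5, 0.5))
  out <- .noble_lorenz_integrate(
    t_end + burn_in, dt, as.numeric(noble_init),
    as.numeric(lorenz_init) + jitter,
    params$rho, params$b, params$sigma, params$lorenz_time_factor,
    params$g_an_slope, as.numeric(keep_every), burn_in
  )
  s <- new_series(out$time, out$voltage)
  attr(s, "model") <- "noble_lorenz"
  attr(s, "dt") <- dt * keep_every
  attr(s, "params") <- params
  attr(s, "lorenz_z") <- out$lorenz_z
  s
}
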