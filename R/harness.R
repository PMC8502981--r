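#' Build the Fenton-Karma forecasting dataset
#'
#' Runs the full data-generation pipeline for the randomly paced
#' Fenton-Karma cell: draw a random-cycle-length protocol
#' (Normal(`mean_cl`, `sd_cl`), 2-ms pulses of magnitude 0.4), integrate by
#' forward Euler at `dt`, undersample adaptively, detect beat onsets, and
#' split at beat boundaries into warmup / training / test segments. The FK
#' voltage is already on the unit scale, so no rescaling is applied.
#'
#' @param seed Integer seed for the pacing draw.
#' @param n_beats Number of stimuli (100 in the standard dataset).
#' @param mean_cl,sd_cl Cycle-length distribution (ms).
#' @param amplitude,duration Stimulus magnitude and width (ms).
#' @param dt Euler step (ms).
#' @param dv_threshold,dt_max Resampling thresholds.
#' @param n_warmup_beats,n_train_beats Beat counts of the warmup and
#'   training segments; the remainder (about 19 with the defaults) is the
#'   test horizon.
#' @return A `dataset_split` with the pacing protocol in `$protocol`.
#' @export
make_fk_dataset <- function(seed = 1L, n_beats = 100, mean_cl = 320,
                            sd_cl = 50, amplitude = 0.4, duration = 2,
                            dt = 0.1, dv_threshold = 0.02, dt_max = 20,
                            n_warmup_beats = 10, n_train_beats = 71) {
  proto <- make_random_cl_protocol(n_beats, mean_cl, sd_cl, duration,
                                   amplitude, seed = seed)
  raw <- simulate_fk(proto, dt = dt)
  scaled <- rescale_unit_interval(raw, prescaled = TRUE)
  res <- resample_series(scaled, dv_threshold, dt_max)
  onsets <- detect_beat_onsets(res)
  split <- split_train_test(res, onsets, n_warmup_beats, n_train_beats)
  split$protocol <- proto
  split$raw <- raw
  split
}

#' Build the Noble-Lorenz forecasting dataset
#'
#' Simulates the Noble (1962) Purkinje model driven by the time-rescaled
#' chaotic Lorenz system, rescales the voltage to the unit interval,
#' undersamples, and splits at beat onsets. The series is univariate (no
#' stimulus channel): the cell fires whenever the Lorenz-driven anionic
#' current depolarizes it past threshold.
#'
#' @param seed Integer seed (jitters the Lorenz initial condition).
#' @param t_end Retained recording length (ms); the default yields roughly
#'   90 action potentials.
#' @param dt Euler step (ms).
#' @inheritParams make_fk_dataset
#' @return A `dataset_split`.
#' @export
make_noble_dataset <- function(seed = 1L, t_end = 50000, dt = 0.01,
                               dv_threshold = 0.02, dt_max = 20,
                               n_warmup_beats = 10, n_train_beats = 65) {
  raw <- simulate_noble_lorenz(t_end = t_end, dt = dt, seed = seed)
  scaled <- rescale_unit_interval(raw)
  res <- resample_series(scaled, dv_threshold, dt_max)
  onsets <- detect_beat_onsets(res)
  split <- split_train_test(res, onsets, n_warmup_beats, n_train_beats)
  split$raw <- raw
  split
}

#' Knowledge-based model channel for the hybrid forecaster
#'
#' Integrates the Corrado-Niederer Mitchell-Schaeffer model under the
#' dataset's own stimulus protocol and samples its voltage at every point
#' of the dataset's (resampled, nonuniform) grid by linear interpolation,
#' giving the auxiliary input channel that runs in lockstep with the data.
#'
#' @param split A `dataset_split` carrying a `$protocol` (multivariate
#'   datasets only).
#' @param params Knowledge-based model constants, default [ms_params()].
#' @param dt Euler step for the knowledge-based integration (ms).
#' @return Numeric vector aligned with `split$series$time`.
#' @export
make_kb_series <- function(split, params = ms_params(), dt = 0.1) {
  stopifnot(inherits(split, "dataset_split"))
  if (is.null(split$protocol))
    abort("the dataset carries no stimulus protocol")
  kb <- simulate_ms(split$protocol,
                    t_end = max(split$series$time) + 1,
                    dt = dt, params = params)
  approx(kb$time, kb$voltage, xout = split$series$time, rule = 2)$y
}

#' Train and forecast with any of the five methods
#'
#' Unified interface over the five forecasters: `"esn"` (baseline),
#' `"clustered_esn"`, `"hybrid_esn"` (physics-informed, with a
#' knowledge-based Mitchell-Schaeffer channel), `"lstm"`, and `"gru"`.
#' Trains on the dataset's training segment and returns the evaluated
#' closed-loop forecast of the test horizon.
#'
#' @param split A `dataset_split`.
#' @param method One of `"esn"`, `"clustered_esn"`, `"hybrid_esn"`,
#'   `"lstm"`, `"gru"`.
#' @param n_neurons Reservoir size or hidden units (default 100).
#' @param seed Seed for reservoir construction / weight initialization.
#' @param esn_args Named overrides for [reservoir_spec()].
#' @param gated_args Named overrides for [gated_spec()] (e.g. `n_layers`).
#' @param train_args Named overrides for [train_config()] (e.g.
#'   `max_epochs`, `learning_rate`).
#' @param kb_series Knowledge-based channel for `"hybrid_esn"`; computed
#'   with [make_kb_series()] when omitted.
#' @param threshold APD threshold for the evaluation.
#' @return An `eval_report` (with the fitted model in `$model`).
#' @export
forecast_with <- function(split,
                          method = c("esn", "clustered_esn", "hybrid_esn",
                                     "lstm", "gru"),
                          n_neurons = 100, seed = 1L, esn_args = list(),
                          gated_args = list(), train_args = list(),
                          kb_series = NULL, threshold = 0.3) {
  method <- match.arg(method)
  use_stim <- "stimulus" %in% names(split$series)
  t0 <- proc.time()[["elapsed"]]
  if (method %in% c("esn", "clustered_esn", "hybrid_esn")) {
    defaults <- list(n_neurons = n_neurons, seed = seed)
    if (method == "clustered_esn") defaults$n_clusters <- 4
    spec <- do.call(reservoir_spec, modifyList(defaults, esn_args))
    if (method == "hybrid_esn") {
      kb_series <- kb_series %||% make_kb_series(split)
    } else {
      kb_series <- NULL
    }
    model <- esn_train(split, spec, kb_series, use_stimulus = use_stim)
    pred <- forecast_closed_loop(model, split, kb_series)
    hyper <- spec
  } else {
    n_in <- 1L + use_stim + !is.null(kb_series)
    spec <- do.call(gated_spec, modifyList(
      list(cell_kind = method, n_hidden = n_neurons, n_inputs = n_in),
      gated_args
    ))
    config <- do.call(train_config, modifyList(list(seed = seed),
                                               train_args))
    model <- gated_train(split, spec, config, kb_series,
                         use_stimulus = use_stim)
    pred <- forecast_recursive(model, split, kb_series)
    hyper <- c(unclass(spec), config)
  }
  report <- evaluate_forecast(
    split, pred, threshold = threshold, forecaster = method,
    n_neurons = n_neurons, seed = seed,
    hyperparameters = hyper,
    wall_time = proc.time()[["elapsed"]] - t0
  )
  report$model <- model
  report
}

#' Seed-averaged evaluation of a stochastic forecaster
#'
#' Repeats [forecast_with()] over `n_seeds` seeds (reservoir construction
#' and weight initialization are the stochastic elements) and returns the
#' individual reports plus the mean test RMSE, the convention used for all
#' reservoir-family results.
#'
#' @inheritParams forecast_with
#' @param n_seeds Number of seeds (10 for reported reservoir results).
#' @param seeds Explicit seed vector overriding `seed + 0:(n_seeds-1)`.
#' @param ... Passed on to [forecast_with()].
#' @return A list with `reports`, `rmse_mean`, `rmse_sd`, and the pooled
#'   per-beat APD error table `apd`.
#' @export
forecast_seed_averaged <- function(split, method = "esn", n_seeds = 10,
                                   seed = 1L, seeds = NULL, ...) {
  seeds <- seeds %||% (seed + seq_len(n_seeds) - 1L)
  reports <- lapply(seeds, function(s) {
    forecast_with(split, method, seed = s, ...)
  })
  rmses <- vapply(reports, function(r) r$rmse, numeric(1))
  apd <- bind_rows(lapply(seq_along(reports), function(i) {
    mutate(reports[[i]]$apd, seed = seeds[i])
  }))
  list(reports = reports, rmse_mean = mean(rmses), rmse_sd = sd(rmses),
       rmse = rmses, apd = apd)
}

#' Exhaustive hyperparameter grid search
#'
#' Evaluates every combination of the supplied candidate lists on the test
#' RMSE (seed-averaged for the reservoir family) and returns the arg-min
#' configuration. Ties are broken toward the smallest `ridge_beta`, then
#' the smallest `spectral_radius` (stability preference). Failing cells
#' are recorded with `NA` score rather than aborting the search.
#'
#' @param split A `dataset_split`.
#' @param method Forecaster kind, as in [forecast_with()].
#' @param grid Named list of candidate vectors. Names matching
#'   [reservoir_spec()] / [gated_spec()] / [train_config()] arguments are
#'   routed accordingly; `dv_threshold`/`dt_max` are not searchable here
#'   (resample before splitting).
#' @param n_seeds Seeds per cell for reservoir-family methods.
#' @param seed Base seed.
#' @param ... Fixed arguments passed to [forecast_with()].
#' @return A list with `best` (named parameter list), `best_score`, and the
#'   full `log` tibble.
#' @export
grid_search <- function(split, method = "esn", grid, n_seeds = 10,
                        seed = 1L, ...) {
  if (length(grid) == 0 || any(lengths(grid) == 0))
    abort("grid must contain nonempty candidate lists")
  cells <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE,
                       stringsAsFactors = FALSE)
  esn_names <- setdiff(names(formals(reservoir_spec)), "seed")
  gated_names <- setdiff(names(formals(gated_spec)), "cell_kind")
  train_names <- setdiff(names(formals(train_config)), "seed")
  is_esn <- method %in% c("esn", "clustered_esn", "hybrid_esn")

  score_cell <- function(cell) {
    esn_args <- cell[intersect(names(cell), esn_names)]
    gated_args <- cell[intersect(names(cell), gated_names)]
    train_args <- cell[intersect(names(cell), train_names)]
    tryCatch({
      if (is_esn) {
        res <- forecast_seed_averaged(split, method, n_seeds = n_seeds,
                                      seed = seed, esn_args = esn_args,
                                      ...)
        res$rmse_mean
      } else {
        forecast_with(split, method, seed = seed,
                      gated_args = gated_args,
                      train_args = train_args, ...)$rmse
      }
    }, error = function(e) NA_real_)
  }

  scores <- vapply(seq_len(nrow(cells)), function(i) {
    score_cell(as.list(cells[i, , drop = FALSE]))
  }, numeric(1))

  log <- as_tibble(cells)
  log$score <- scores
  if (all(is.na(scores))) abort("every grid cell failed")
  ord <- order(
    scores,
    if ("ridge_beta" %in% names(cells)) cells$ridge_beta else
      rep(0, nrow(cells)),
    if ("spectral_radius" %in% names(cells)) cells$spectral_radius else
      rep(0, nrow(cells))
  )
  best_i <- ord[1]
  list(best = as.list(cells[best_i, , drop = FALSE]),
       best_score = scores[best_i], log = log)
}

#' Cross-method comparison table
#'
#' Runs each requested method at each network size and tabulates the test
#' RMSE (seed-averaged for the reservoir family), the per-beat APD error
#' summary, and wall time, mirroring the standard method-by-size
#' comparison. Per-cell failures are recorded as `NA` rows.
#'
#' @param split A `dataset_split`.
#' @param methods Character vector of forecaster kinds.
#' @param sizes Integer vector of network sizes.
#' @param n_seeds Seeds for the reservoir family (gated nets run once).
#' @param ... Passed to [forecast_with()].
#' @return A tibble with columns `method`, `n_neurons`, `rmse_mean`,
#'   `rmse_sd`, `apd_mae`, `apd_max`, `seeds`, `wall_time`.
#' @export
compare_methods <- function(split, methods = c("esn", "clustered_esn",
                                               "hybrid_esn", "lstm",
                                               "gru"),
                            sizes = 100, n_seeds = 10, ...) {
  rows <- list()
  for (m in methods) {
    for (sz in sizes) {
      t0 <- proc.time()[["elapsed"]]
      row <- tryCatch({
        if (m %in% c("esn", "clustered_esn", "hybrid_esn")) {
          res <- forecast_seed_averaged(split, m, n_seeds = n_seeds,
                                        n_neurons = sz, ...)
          err <- res$apd$abs_error[res$apd$matched]
          tibble(method = m, n_neurons = sz, rmse_mean = res$rmse_mean,
                 rmse_sd = res$rmse_sd, apd_mae = mean(err),
                 apd_max = max(err), seeds = n_seeds)
        } else {
          rep <- forecast_with(split, m, n_neurons = sz, ...)
          err <- rep$apd$abs_error[rep$apd$matched]
          tibble(method = m, n_neurons = sz, rmse_mean = rep$rmse,
                 rmse_sd = NA_real_, apd_mae = mean(err),
                 apd_max = max(err), seeds = 1L)
        }
      }, error = function(e) {
        tibble(method = m, n_neurons = sz, rmse_mean = NA_real_,
               rmse_sd = NA_real_, apd_mae = NA_real_, apd_max = NA_real_,
               seeds = NA_integer_)
      })
      row$wall_time <- proc.time()[["elapsed"]] - t0
      rows[[length(rows) + 1]] <- row
    }
  }
  bind_rows(rows)
}
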