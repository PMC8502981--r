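#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an evaluation report
#'
#' One row per test beat with the true and predicted APD and the absolute
#' error.
#'
#' @param x An `eval_report`.
#' @param ... Unused.
#' @return A tibble `forecaster`, `beat`, `onset`, `apd_true`, `apd_pred`,
#'   `abs_error`, `matched`.
#' @export
tidy.eval_report <- function(x, ...) {
  mutate(x$apd, forecaster = x$forecaster,
         beat = seq_len(nrow(x$apd)),
         onset = .data$onset_true) %>%
    select("forecaster", "beat", "onset", "apd_true", "apd_pred",
           "abs_error", "matched")
}

#' Summarise an evaluation report in one row
#'
#' @param x An `eval_report`.
#' @param ... Unused.
#' @return A one-row tibble: `forecaster`, `n_neurons`, `seed`, `rmse`,
#'   `apd_mae`, `apd_median`, `apd_max`, `n_beats`, `n_missed`,
#'   `wall_time`.
#' @export
glance.eval_report <- function(x, ...) {
  err <- x$apd$abs_error[x$apd$matched]
  tibble(
    forecaster = x$forecaster, n_neurons = x$n_neurons, seed = x$seed,
    rmse = x$rmse,
    apd_mae = if (length(err)) mean(err) else NA_real_,
    apd_median = if (length(err)) median(err) else NA_real_,
    apd_max = if (length(err)) max(err) else NA_real_,
    n_beats = nrow(x$apd), n_missed = sum(!x$apd$matched),
    wall_time = x$wall_time
  )
}

#' Tidy a trained ESN: readout weights by input block
#'
#' @param x An `esn_model`.
#' @param ... Unused.
#' @return A tibble `term`, `estimate` for the readout weight vector
#'   (bias, input slots, reservoir units).
#' @export
tidy.esn_model <- function(x, ...) {
  n_in <- ncol(x$W_in)
  in_names <- c(if (x$use_stimulus) "stimulus",
                if (x$hybrid) "kb_voltage", "voltage")
  terms <- c("bias", in_names[seq_len(n_in)],
             paste0("unit_", seq_len(nrow(x$W))))
  tibble(term = terms, estimate = x$W_out)
}

#' @export
glance.esn_model <- function(x, ...) {
  tibble(
    n_neurons = x$spec$n_neurons, n_clusters = x$spec$n_clusters,
    spectral_radius = x$spec$spectral_radius,
    leaking_rate = x$alpha, ridge_beta = x$spec$ridge_beta,
    hybrid = x$hybrid, train_rmse = x$train_rmse, seed = x$spec$seed
  )
}

#' @export
glance.gated_model <- function(x, ...) {
  tibble(
    cell_kind = x$spec$cell_kind, n_hidden = x$spec$n_hidden,
    n_layers = x$spec$n_layers,
    n_parameters = n_gated_params(x$spec),
    epochs = length(x$loss_history),
    final_loss = tail(x$loss_history, 1),
    learning_rate = x$config$learning_rate, seed = x$config$seed
  )
}
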