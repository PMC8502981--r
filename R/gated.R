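#' Gated recurrent network specification and training configuration
#'
#' `gated_spec()` describes an LSTM or GRU sequence-to-sequence regressor:
#' cell kind, hidden width, number of stacked layers, and input
#' dimensionality (1 for univariate voltage, 2 with a stimulus channel,
#' 3 when a knowledge-based channel is added). `train_config()` holds the
#' Adam optimizer settings; the defaults follow common deep-learning
#' toolbox practice (`beta1 = 0.9`, `beta2 = 0.999`, `eps = 1e-8`) with a
#' maximum of 30 epochs of full-sequence backpropagation through time.
#'
#' @param cell_kind `"lstm"` or `"gru"`.
#' @param n_hidden Hidden units per layer.
#' @param n_layers Number of stacked gated layers.
#' @param n_inputs Input vector length.
#' @return A list of class `gated_spec`.
#' @export
gated_spec <- function(cell_kind = c("lstm", "gru"), n_hidden = 100,
                       n_layers = 1, n_inputs = 2) {
  cell_kind <- match.arg(cell_kind)
  if (n_hidden < 1 || n_layers < 1) abort("n_hidden and n_layers must be >= 1")
  structure(
    list(cell_kind = cell_kind, n_hidden = as.integer(n_hidden),
         n_layers = as.integer(n_layers), n_inputs = as.integer(n_inputs)),
    class = "gated_spec"
  )
}

#' @rdname gated_spec
#' @param max_epochs Maximum training epochs.
#' @param learning_rate Initial (constant) Adam learning rate.
#' @param beta1,beta2,eps Adam moment decay rates and stabilizer.
#' @param seed Integer seed for weight initialization.
#' @export
train_config <- function(max_epochs = 30, learning_rate = 5e-3,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                         seed = 1L) {
  if (max_epochs <= 0) abort("max_epochs must be positive")
  if (learning_rate <= 0) abort("learning_rate must be positive")
  list(max_epochs = as.integer(max_epochs), learning_rate = learning_rate,
       beta1 = beta1, beta2 = beta2, eps = eps, seed = as.integer(seed))
}

#' Single LSTM cell step
#'
#' Computes one update of an LSTM memory cell:
#' input/forget/output gates through the logistic sigmoid, candidate state
#' through tanh, `c_t = f * c + i * cand`, `h_t = tanh(c_t) * o` (all
#' products elementwise).
#'
#' @param params Named list of matrices `Wi, Ui, bi, Wf, Uf, bf, Wo, Uo,
#'   bo, Wc, Uc, bc` (biases as column vectors).
#' @param x_t Input vector.
#' @param h_prev,c_prev Previous hidden and cell state vectors.
#' @return A list with the new `h` and `c`.
#' @export
lstm_step <- function(params, x_t, h_prev, c_prev) {
  sg <- function(z) 1 / (1 + exp(-z))
  i <- sg(params$Wi %*% x_t + params$Ui %*% h_prev + params$bi)
  f <- sg(params$Wf %*% x_t + params$Uf %*% h_prev + params$bf)
  o <- sg(params$Wo %*% x_t + params$Uo %*% h_prev + params$bo)
  cand <- tanh(params$Wc %*% x_t + params$Uc %*% h_prev + params$bc)
  c_t <- f * c_prev + i * cand
  h_t <- tanh(c_t) * o
  list(h = as.numeric(h_t), c = as.numeric(c_t))
}

#' Single GRU cell step
#'
#' Update and reset gates through the logistic sigmoid, candidate
#' `tanh(Wh x + Uh (r * h) + bh)`, and
#' `h_t = (1 - z) * h + z * cand` (elementwise).
#'
#' @param params Named list of matrices `Wz, Uz, bz, Wr, Ur, br, Wh, Uh,
#'   bh`.
#' @param x_t Input vector.
#' @param h_prev Previous hidden state.
#' @return The new hidden state vector.
#' @export
gru_step <- function(params, x_t, h_prev) {
  sg <- function(z) 1 / (1 + exp(-z))
  z <- sg(params$Wz %*% x_t + params$Uz %*% h_prev + params$bz)
  r <- sg(params$Wr %*% x_t + params$Ur %*% h_prev + params$br)
  cand <- tanh(params$Wh %*% x_t + params$Uh %*% (r * h_prev) + params$bh)
  as.numeric((1 - z) * h_prev + z * cand)
}

# Glorot-uniform matrix draw.
glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(runif(nr * nc, -lim, lim), nr, nc)
}

# Random orthogonal matrix (QR of a Gaussian draw, sign-fixed).
ortho <- function(n) {
  qr_ <- qr(matrix(rnorm(n * n), n, n))
  q <- qr.Q(qr_)
  q * sign(diag(qr.R(qr_)))[col(q)]
}

#' Initialize gated-network parameters
#'
#' Glorot-uniform input matrices, orthogonal recurrent matrices, zero
#' biases except the LSTM forget-gate bias which starts at 1 (the usual
#' toolbox default, keeping early memory open).
#'
#' @param spec A [gated_spec()].
#' @param seed Integer seed.
#' @return A parameter list (`kind`, `layers`, `Wy`, `by`) consumed by the
#'   training and forecasting routines.
#' @export
init_gated_params <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "gated_spec"))
  H <- spec$n_hidden
  with_seed(seed, {
    layers <- vector("list", spec$n_layers)
    for (l in seq_len(spec$n_layers)) {
      d <- if (l == 1) spec$n_inputs else H
      zero <- matrix(0, H, 1)
      if (spec$cell_kind == "lstm") {
        layers[[l]] <- list(
          Wi = glorot(H, d), Ui = ortho(H), bi = zero,
          Wf = glorot(H, d), Uf = ortho(H), bf = matrix(1, H, 1),
          Wo = glorot(H, d), Uo = ortho(H), bo = zero,
          Wc = glorot(H, d), Uc = ortho(H), bc = zero
        )
      } else {
        layers[[l]] <- list(
          Wz = glorot(H, d), Uz = ortho(H), bz = zero,
          Wr = glorot(H, d), Ur = ortho(H), br = zero,
          Wh = glorot(H, d), Uh = ortho(H), bh = zero
        )
      }
    }
    list(kind = spec$cell_kind, layers = layers,
         Wy = glorot(1, H), by = matrix(0, 1, 1))
  })
}

#' Number of trainable parameters of a gated network
#'
#' @param spec A [gated_spec()].
#' @return Integer parameter count (gates + readout).
#' @export
n_gated_params <- function(spec) {
  H <- spec$n_hidden
  gates <- if (spec$cell_kind == "lstm") 4L else 3L
  total <- 0L
  for (l in seq_len(spec$n_layers)) {
    d <- if (l == 1) spec$n_inputs else H
    total <- total + gates * (H * d + H * H + H)
  }
  total + H + 1L
}

#' Train a gated sequence-to-sequence forecaster
#'
#' One-step-ahead regression on the training segment: at each resampled
#' sample the network maps the input vector (exogenous channels plus
#' current voltage) to the next voltage. Trained by full-sequence
#' backpropagation through time with Adam for at most
#' `config$max_epochs` epochs.
#'
#' @param split A [split_train_test()] result.
#' @param spec A [gated_spec()]; `n_inputs` must match the available
#'   channels (`1 + use_stimulus + !is.null(kb_series)`).
#' @param config A [train_config()].
#' @param kb_series Optional knowledge-based voltage on the full series
#'   grid (hybrid-style input, normally unused for gated nets).
#' @param use_stimulus Include the stimulus channel.
#' @return An object of class `gated_model` with trained parameters and the
#'   per-epoch loss history.
#' @export
gated_train <- function(split, spec, config = train_config(),
                        kb_series = NULL,
                        use_stimulus = "stimulus" %in% names(split$series)) {
  stopifnot(inherits(split, "dataset_split"), inherits(spec, "gated_spec"))
  n_in_needed <- 1L + use_stimulus + !is.null(kb_series)
  if (spec$n_inputs != n_in_needed)
    abort(sprintf("spec$n_inputs is %d but the data provide %d channels",
                  spec$n_inputs, n_in_needed))
  n_pre <- nrow(split$pre_train)
  kb_train <- if (!is.null(kb_series))
    kb_series[n_pre + seq_len(nrow(split$train))]
  X <- esn_inputs(split$train, use_stimulus, kb_train)
  inputs <- t(X[-nrow(X), , drop = FALSE])   # n_in x (T-1)
  targets <- split$train$voltage[-1]

  params <- init_gated_params(spec, config$seed)
  fit <- .gated_train(params, inputs, targets, config$max_epochs,
                      config$learning_rate, config$beta1, config$beta2,
                      config$eps)
  structure(
    list(params = fit$params, spec = spec, config = config,
         use_stimulus = use_stimulus, hybrid = !is.null(kb_series),
         loss_history = as.numeric(fit$loss_history)),
    class = "gated_model"
  )
}

#' @export
print.gated_model <- function(x, ...) {
  cat(sprintf(
    "<gated_model> %s, %d x %d hidden, final training MSE %.4g (%d epochs)\n",
    toupper(x$spec$cell_kind), x$spec$n_layers, x$spec$n_hidden,
    tail(x$loss_history, 1), length(x$loss_history)
  ))
  invisible(x)
}

#' Closed-loop forecast with a gated network
#'
#' Warms the hidden (and cell) states by a forward pass over the warmup and
#' training samples, then predicts the test horizon recursively: each
#' predicted voltage is fed back as the next step's voltage input while the
#' stimulus (and optional knowledge-based) channels come from their known
#' values. Drop-in interchangeable with [forecast_closed_loop()].
#'
#' @param model A trained `gated_model`.
#' @param split The [split_train_test()] object used for training.
#' @param kb_series Knowledge-based voltage on the full grid, if used in
#'   training.
#' @return A tibble `time`, `voltage` aligned with `split$test`.
#' @export
forecast_recursive <- function(model, split, kb_series = NULL) {
  stopifnot(inherits(model, "gated_model"))
  if (model$hybrid && is.null(kb_series))
    abort("model was trained with a knowledge-based channel")
  n_steps <- nrow(split$test)
  if (n_steps == 0) {
    return(tibble(time = numeric(0), voltage = numeric(0)))
  }
  n_hist <- nrow(split$pre_train) + nrow(split$train)
  hist <- split$series[seq_len(n_hist), , drop = FALSE]
  kb_hist <- if (!is.null(kb_series)) kb_series[seq_len(n_hist)]
  Xh <- esn_inputs(hist, model$use_stimulus, kb_hist)
  # warm states over history inputs up to the penultimate sample; the final
  # sample's channels enter as the first closed-loop step (same convention
  # as the ESN forecaster)
  warm <- .gated_forward(model$params, t(Xh[-nrow(Xh), , drop = FALSE]))
  exo <- forecast_exo(split, model$use_stimulus,
                      if (model$hybrid) kb_series)
  out <- .gated_forecast(model$params, warm$h, warm$c, exo,
                         hist$voltage[nrow(hist)], n_steps)
  tibble(time = split$test$time, voltage = as.numeric(out$predictions))
}
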