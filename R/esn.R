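#' Reservoir specification
#'
#' Collects the hyperparameters of an echo state network reservoir:
#' size, Erdős–Rényi connection probability, target spectral radius,
#' input-weight scale, leaking rate, ridge regularization, and (for the
#' clustered variant) the number of sub-reservoirs and the inter-cluster
#' connection probability. `n_clusters = 1` is the baseline topology.
#'
#' @param n_neurons Reservoir size.
#' @param connect_prob Edge probability of the (directed) Erdős–Rényi
#'   reservoir graph; within-cluster probability for clustered reservoirs.
#' @param spectral_radius Target spectral radius after rescaling; values
#'   below 1 together with a positive leaking rate give the echo state
#'   (fading memory) property.
#' @param input_scale Input weights are drawn Uniform(-`input_scale`,
#'   `input_scale`).
#' @param leaking_rate Leaky-update coefficient `alpha` in `[0, 1]`.
#' @param ridge_beta Tikhonov factor for the readout regression.
#' @param n_clusters Number of sub-reservoirs (>= 1).
#' @param inter_cluster_prob Edge probability between different clusters.
#' @param seed Integer seed controlling reservoir and input-weight draws.
#' @return A list of class `reservoir_spec`.
#' @export
reservoir_spec <- function(n_neurons = 100, connect_prob = 0.05,
                           spectral_radius = 0.3, input_scale = 0.2,
                           leaking_rate = 0.3, ridge_beta = 1e-4,
                           n_clusters = 1, inter_cluster_prob = 0.01,
                           seed = 1L) {
  if (n_neurons < 1) abort("n_neurons must be >= 1")
  if (connect_prob <= 0 || connect_prob > 1)
    abort("connect_prob must be in (0, 1]")
  if (spectral_radius <= 0) abort("spectral_radius must be > 0")
  if (leaking_rate < 0 || leaking_rate > 1)
    abort("leaking_rate must be in [0, 1]")
  if (n_clusters < 1 || n_clusters > n_neurons)
    abort("n_clusters must be in [1, n_neurons]")
  structure(
    list(n_neurons = as.integer(n_neurons), connect_prob = connect_prob,
         spectral_radius = spectral_radius, input_scale = input_scale,
         leaking_rate = leaking_rate, ridge_beta = ridge_beta,
         n_clusters = as.integer(n_clusters),
         inter_cluster_prob = inter_cluster_prob, seed = as.integer(seed)),
    class = "reservoir_spec"
  )
}

#' Build a reservoir weight matrix
#'
#' Generates a directed Erdős–Rényi graph with edge probability
#' `connect_prob`, weights Uniform(-1, 1), then rescales the matrix so its
#' spectral radius equals `spectral_radius` exactly. For
#' `n_clusters > 1`, within-cluster edges use `connect_prob` and edges
#' between clusters appear with probability `inter_cluster_prob`; the same
#' global spectral rescaling is then applied. An all-zero draw is redrawn.
#'
#' @param spec A [reservoir_spec()].
#' @return The `n_neurons x n_neurons` reservoir matrix `W`.
#' @examples
#' W <- build_reservoir(reservoir_spec(50, seed = 7))
#' max(abs(eigen(W, only.values = TRUE)$values))
#' @export
build_reservoir <- function(spec) {
  stopifnot(inherits(spec, "reservoir_spec"))
  n <- spec$n_neurons
  with_seed(spec$seed, {
    for (attempt in 1:100) {
      if (spec$n_clusters == 1) {
        mask <- matrix(runif(n * n) < spec$connect_prob, n, n)
      } else {
        cluster <- cluster_assignment(n, spec$n_clusters)
        same <- outer(cluster, cluster, "==")
        prob <- ifelse(same, spec$connect_prob, spec$inter_cluster_prob)
        mask <- matrix(runif(n * n), n, n) < prob
      }
      W <- matrix(runif(n * n, -1, 1), n, n) * mask
      rho <- max(abs(eigen(W, only.values = TRUE)$values))
      if (rho > 0) {
        return(W * (spec$spectral_radius / rho))
      }
    }
    abort("reservoir draw had zero spectral radius after 100 attempts")
  })
}

# Partition n neurons into k contiguous clusters; remainder goes to the
# last cluster.
cluster_assignment <- function(n, k) {
  size <- n %/% k
  cl <- rep(seq_len(k), each = size)
  c(cl, rep(k, n - length(cl)))
}

#' Single leaky reservoir state update
#'
#' `h <- (1 - alpha) h + alpha tanh(W_in x + W h)`.
#'
#' @param model An `esn_model` (or any list with `W_in`, `W`, `alpha`).
#' @param x_t Input vector of length `ncol(W_in)`.
#' @param h Current state; defaults to the model's stored state.
#' @return The updated state vector.
#' @export
esn_step <- function(model, x_t, h = model$h) {
  if (length(x_t) != ncol(model$W_in)) abort("input length mismatch")
  h <- as.numeric(
    (1 - model$alpha) * h +
      model$alpha * tanh(model$W_in %*% x_t + model$W %*% h)
  )
  if (any(!is.finite(h))) abort("reservoir state diverged")
  h
}

#' Teacher-forced state collection
#'
#' Runs the reservoir open-loop over the rows of `inputs` and returns the
#' design matrix whose rows are `[1, x_t, h_t]` (a constant bias column,
#' the input, and the state), with the first `n_washout_rows` rows dropped
#' so the arbitrary initial state is washed out.
#'
#' @param model An `esn_model`.
#' @param inputs Matrix of input rows.
#' @param n_washout_rows Leading rows to discard (< `nrow(inputs)`).
#' @param h0 Initial state (defaults to zeros).
#' @return A list with the `design` matrix, the retained row indices
#'   `kept`, and the final state `h`.
#' @export
collect_states <- function(model, inputs, n_washout_rows = 0,
                           h0 = rep(0, nrow(model$W))) {
  inputs <- as.matrix(inputs)
  if (nrow(inputs) == 0) abort("inputs must be nonempty")
  if (n_washout_rows >= nrow(inputs))
    abort("washout must be shorter than the input sequence")
  H <- .esn_collect_states(model$W_in, model$W, model$alpha, inputs, h0)
  keep <- seq.int(n_washout_rows + 1, nrow(inputs))
  list(design = cbind(1, inputs, H)[keep, , drop = FALSE],
       kept = keep, h = H[nrow(H), ])
}

#' Ridge (Tikhonov) readout fit
#'
#' Solves `argmin ||D w - y||^2 + beta ||w||^2` in closed form via the
#' normal equations `(D'D + beta I) w = D'y`.
#'
#' @param design Design matrix `D` (rows `[1, x, h]`).
#' @param targets Target vector `y` (next-step voltages).
#' @param ridge_beta Regularization factor `beta` >= 0.
#' @return The readout weight vector.
#' @export
fit_readout <- function(design, targets, ridge_beta = 1e-6) {
  design <- as.matrix(design)
  if (nrow(design) != length(targets)) abort("design/target length mismatch")
  G <- crossprod(design) + diag(ridge_beta, ncol(design))
  w <- tryCatch(
    solve(G, crossprod(design, targets)),
    error = function(e) abort("singular normal equations (increase ridge_beta)")
  )
  as.numeric(w)
}

# Assemble the input matrix for a series segment: exogenous channels first
# (stimulus, then knowledge-based voltage when present), the endogenous
# voltage slot last. `kb` is a voltage vector aligned with `series`.
esn_inputs <- function(series, use_stimulus, kb = NULL) {
  cols <- list()
  if (use_stimulus) cols$stimulus <- series$stimulus
  if (!is.null(kb)) cols$kb <- kb
  cols$voltage <- series$voltage
  do.call(cbind, cols)
}

#' Train an echo state network forecaster
#'
#' Builds the reservoir and input weights from `spec`, runs a teacher-forced
#' pass over the warmup + training segments of `split`, discards the rows
#' whose targets fall in the warmup (washout) beats, and fits the linear
#' readout by ridge regression to the next-sample voltage. Variants:
#' `n_clusters > 1` in `spec` gives the clustered topology, and supplying
#' `kb_series` (a knowledge-based model voltage evaluated on the same
#' sampling grid as `split$series`) gives the physics-informed hybrid input
#' vector `[stimulus; kb voltage; voltage]`.
#'
#' @param split A [split_train_test()] result.
#' @param spec A [reservoir_spec()].
#' @param kb_series Optional knowledge-based voltage vector, aligned
#'   sample-for-sample with `split$series`.
#' @param use_stimulus Include the stimulus channel as an exogenous input
#'   (requires a `stimulus` column). Defaults to its presence.
#' @return An object of class `esn_model` with the trained readout, final
#'   reservoir state, and everything needed for closed-loop forecasting.
#' @export
esn_train <- function(split, spec, kb_series = NULL,
                      use_stimulus = "stimulus" %in% names(split$series)) {
  stopifnot(inherits(split, "dataset_split"),
            inherits(spec, "reservoir_spec"))
  if (!is.null(kb_series) && !use_stimulus)
    abort("the hybrid variant needs a stimulus channel")
  n_pre <- nrow(split$pre_train)
  n_fit <- n_pre + nrow(split$train)
  hist <- split$series[seq_len(n_fit), , drop = FALSE]
  kb_hist <- if (!is.null(kb_series)) kb_series[seq_len(n_fit)]
  n_in <- 1L + use_stimulus + !is.null(kb_series)

  W <- build_reservoir(spec)
  W_in <- with_seed(spec$seed + 1L, {
    matrix(runif(spec$n_neurons * n_in, -spec$input_scale,
                 spec$input_scale),
           spec$n_neurons, n_in)
  })

  model <- structure(
    list(W_in = W_in, W = W, alpha = spec$leaking_rate, spec = spec,
         use_stimulus = use_stimulus, hybrid = !is.null(kb_series)),
    class = "esn_model"
  )

  X <- esn_inputs(hist, use_stimulus, kb_hist)
  inputs <- X[-nrow(X), , drop = FALSE]    # x_i predicts v_{i+1}
  targets <- hist$voltage[-1]
  washout <- max(0L, n_pre - 1L)           # targets inside warmup beats
  st <- collect_states(model, inputs, n_washout_rows = washout)
  model$W_out <- fit_readout(st$design, targets[st$kept], spec$ridge_beta)
  model$h <- st$h
  model$last_input <- X[nrow(X), ]
  model$last_voltage <- hist$voltage[nrow(hist)]
  model$train_rmse <- rmse(targets[st$kept],
                           as.numeric(st$design %*% model$W_out))
  model
}

#' @export
print.esn_model <- function(x, ...) {
  cat(sprintf(
    "<esn_model> %d neurons%s%s, alpha %.2f, rho %.2f, train RMSE %.4g\n",
    x$spec$n_neurons,
    if (x$spec$n_clusters > 1) sprintf(", %d clusters", x$spec$n_clusters)
    else "",
    if (x$hybrid) ", hybrid" else "", x$alpha, x$spec$spectral_radius,
    x$train_rmse
  ))
  invisible(x)
}

#' Closed-loop (recursive) multi-step forecast
#'
#' Starting from the reservoir state reached at the end of the training
#' pass, predicts the test horizon one sample at a time: the voltage input
#' slot carries the previous prediction while the exogenous slots (stimulus
#' timing and, for the hybrid, the knowledge-based voltage) come from their
#' known channels. Timestamps of the test grid are attached for APD and
#' RMSE bookkeeping; the recurrence itself treats samples as uniform steps.
#'
#' @param model A trained `esn_model`.
#' @param split The same [split_train_test()] object used for training.
#' @param kb_series Knowledge-based voltage on the full series grid (hybrid
#'   models only; must match training).
#' @return A tibble `time`, `voltage` (predicted), aligned with
#'   `split$test`.
#' @export
forecast_closed_loop <- function(model, split, kb_series = NULL) {
  stopifnot(inherits(model, "esn_model"))
  if (model$hybrid && is.null(kb_series))
    abort("hybrid model needs kb_series for the forecast horizon")
  n_steps <- nrow(split$test)
  if (n_steps == 0) {
    return(tibble(time = numeric(0), voltage = numeric(0)))
  }
  exo <- forecast_exo(split, model$use_stimulus,
                      if (model$hybrid) kb_series)
  out <- .esn_forecast(model$W_in, model$W, model$W_out, model$alpha,
                       model$h, exo, model$last_voltage, n_steps)
  tibble(time = split$test$time, voltage = as.numeric(out$predictions))
}

# Exogenous rows for the forecast horizon. Row j carries the channels of
# the grid point preceding test sample j (training convention: input at
# sample i predicts the voltage at sample i + 1).
forecast_exo <- function(split, use_stimulus, kb_series = NULL) {
  n_hist <- nrow(split$pre_train) + nrow(split$train)
  n_steps <- nrow(split$test)
  idx <- n_hist + seq_len(n_steps) - 1L  # last train sample, then test 1..M-1
  cols <- list()
  if (use_stimulus) cols$stimulus <- split$series$stimulus[idx]
  if (!is.null(kb_series)) cols$kb <- kb_series[idx]
  if (length(cols) == 0) {
    matrix(numeric(0), nrow = n_steps, ncol = 0)
  } else {
    do.call(cbind, cols)
  }
}
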