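test_that("reservoir matrices hit the target spectral radius exactly", {
  for (seed in 1:3) {
    spec <- reservoir_spec(60, connect_prob = 0.1, spectral_radius = 0.8,
                           seed = seed)
    W <- build_reservoir(spec)
    rho <- max(abs(eigen(W, only.values = TRUE)$values))
    expect_equal(rho, 0.8, tolerance = 1e-6)
  }
  # 1x1 reservoir with full connectivity: |entry| equals the radius
  W1 <- build_reservoir(reservoir_spec(1, 1, 0.7, seed = 2))
  expect_equal(abs(W1[1, 1]), 0.7, tolerance = 1e-12)
})

test_that("clustered reservoirs are block-diagonal at zero inter-cluster
           probability", {
  spec <- reservoir_spec(40, connect_prob = 0.4, n_clusters = 4,
                         inter_cluster_prob = 0, seed = 6)
  W <- build_reservoir(spec)
  cl <- rep(1:4, each = 10)
  off_block <- W[outer(cl, cl, "!=")]
  expect_true(all(off_block == 0))
  expect_gt(sum(W != 0), 0)
})

test_that("reservoir generation is reproducible given the seed", {
  s <- reservoir_spec(50, seed = 12)
  expect_identical(build_reservoir(s), build_reservoir(s))
})

test_that("the leaky state update matches its equation", {
  set.seed(3)
  n <- 7
  model <- list(W_in = matrix(rnorm(n * 2), n, 2),
                W = matrix(rnorm(n * n, sd = 0.2), n, n), alpha = 0.4)
  h <- rnorm(n)
  x <- rnorm(2)
  expect_equal(esn_step(model, x, h),
               esn_step_oracle(model$W_in, model$W, 0.4, x, h),
               tolerance = 1e-12)
  # alpha = 0 leaves the state unchanged
  m0 <- model; m0$alpha <- 0
  expect_equal(esn_step(m0, x, h), h)
  # alpha = 1 with zero weights collapses the state to zero
  m1 <- list(W_in = matrix(0, n, 2), W = matrix(0, n, n), alpha = 1)
  expect_equal(esn_step(m1, x, h), rep(0, n))
})

test_that("state collection discards washout rows and concatenates
           [1; x; h]", {
  set.seed(5)
  n <- 6
  model <- list(W_in = matrix(rnorm(n), n, 1),
                W = 0.5 * diag(n), alpha = 0.7)
  X <- matrix(rnorm(20), 20, 1)
  st <- collect_states(model, X, n_washout_rows = 0)
  expect_equal(dim(st$design), c(20, 1 + 1 + n))
  expect_equal(st$design[, 1], rep(1, 20))
  expect_equal(st$design[, 2], X[, 1])
  # manual recurrence oracle for the final state
  h <- rep(0, n)
  for (t in 1:20) h <- esn_step_oracle(model$W_in, model$W, 0.7, X[t, ], h)
  expect_equal(st$h, h, tolerance = 1e-12)
  expect_equal(nrow(collect_states(model, X, 19)$design), 1)
  expect_error(collect_states(model, X, 20), "washout")
})

test_that("echo state property: initial conditions wash out", {
  spec <- reservoir_spec(80, spectral_radius = 0.8, leaking_rate = 0.5,
                         seed = 21)
  W <- build_reservoir(spec)
  W_in <- matrix(runif(80, -0.5, 0.5), 80, 1)
  model <- list(W_in = W_in, W = W, alpha = 0.5)
  set.seed(1)
  X <- matrix(runif(400), 400, 1)
  h1 <- rep(0, 80)
  h2 <- runif(80, -1, 1)
  for (t in 1:400) {
    h1 <- esn_step(model, X[t, ], h1)
    h2 <- esn_step(model, X[t, ], h2)
  }
  expect_lt(max(abs(h1 - h2)), 1e-6)
})

test_that("ridge readout equals the explicit normal-equation oracle", {
  set.seed(9)
  D <- cbind(1, matrix(rnorm(200), 40, 5))
  y <- rnorm(40)
  for (beta in c(1e-6, 1e-2, 1)) {
    oracle <- solve(t(D) %*% D + beta * diag(ncol(D)), t(D) %*% y)
    expect_equal(fit_readout(D, y, beta), as.numeric(oracle),
                 tolerance = 1e-8)
  }
  # noiseless linear targets with beta = 0 are recovered exactly
  w_true <- rnorm(6)
  y_lin <- as.numeric(D %*% w_true)
  w_hat <- fit_readout(D, y_lin, 0)
  expect_lt(max(abs(D %*% w_hat - y_lin)), 1e-8)
  # enormous ridge shrinks the readout toward zero
  expect_lt(sum(abs(fit_readout(D, y, 1e12))), 1e-6)
  # singular system with beta = 0 is rejected
  Dsing <- cbind(1, 1, matrix(rnorm(40), 20, 2))
  expect_error(fit_readout(Dsing, rnorm(20), 0), "singular")
})

test_that("closed-loop forecasting reproduces a learned fixed point", {
  # teach a 1-neuron, alpha = 0 network the identity map: y = x.
  # In closed loop every prediction then equals the seed voltage.
  model <- structure(
    list(W_in = matrix(0, 1, 1), W = matrix(0, 1, 1), alpha = 0,
         W_out = c(0, 1, 0), h = 0, last_voltage = 0.42,
         use_stimulus = FALSE, hybrid = FALSE,
         spec = reservoir_spec(1)),
    class = "esn_model"
  )
  split <- structure(
    list(pre_train = lin_series(numeric(0), numeric(0)),
         train = lin_series(1:3, c(0.42, 0.42, 0.42)),
         test = lin_series(4:8, rep(0.42, 5)),
         series = lin_series(1:8, rep(0.42, 8))),
    class = "dataset_split"
  )
  pred <- forecast_closed_loop(model, split)
  expect_equal(pred$voltage, rep(0.42, 5))
  # zero-step horizon gives an empty prediction
  split0 <- split
  split0$test <- lin_series(numeric(0), numeric(0))
  expect_equal(nrow(forecast_closed_loop(model, split0)), 0)
})

test_that("the trained ESN pipeline is bit-reproducible under a fixed
           seed", {
  split <- fk_split_small()
  r1 <- forecast_with(split, "esn", n_neurons = 40, seed = 3)
  r2 <- forecast_with(split, "esn", n_neurons = 40, seed = 3)
  expect_identical(r1$predictions, r2$predictions)
  expect_identical(r1$rmse, r2$rmse)
})

test_that("clustered ESN with one cluster degenerates to the baseline", {
  split <- fk_split_small()
  base <- forecast_with(split, "esn", n_neurons = 40, seed = 7)
  clus <- forecast_with(split, "clustered_esn", n_neurons = 40, seed = 7,
                        esn_args = list(n_clusters = 1))
  expect_identical(base$predictions, clus$predictions)
})

test_that("hybrid ESN with a zero knowledge-based channel reduces to a
           baseline with one extra dead input", {
  split <- fk_split_small()
  kb0 <- rep(0, nrow(split$series))
  hyb <- forecast_with(split, "hybrid_esn", n_neurons = 40, seed = 2,
                       kb_series = kb0)
  expect_true(all(is.finite(hyb$predictions$voltage)))
  expect_equal(nrow(hyb$predictions), nrow(split$test))
})

test_that("a knowledge-based model matched to the data generator makes
           the forecast near-trivial", {
  split <- fk_split_small()
  # kb channel = the data-generating model itself, sampled on the grid
  kb <- split$series$voltage
  base <- forecast_with(split, "esn", n_neurons = 40, seed = 5)
  hyb <- forecast_with(split, "hybrid_esn", n_neurons = 40, seed = 5,
                       kb_series = kb)
  expect_lt(hyb$rmse, base$rmse)
})
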