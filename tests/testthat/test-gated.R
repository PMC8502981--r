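make_lstm_params <- function(H, d, seed = 1) {
  with_seed <- beatcast:::with_seed
  with_seed(seed, {
    rnd <- function(nr, nc) matrix(rnorm(nr * nc, sd = 0.3), nr, nc)
    list(Wi = rnd(H, d), Ui = rnd(H, H), bi = rnd(H, 1),
         Wf = rnd(H, d), Uf = rnd(H, H), bf = rnd(H, 1),
         Wo = rnd(H, d), Uo = rnd(H, H), bo = rnd(H, 1),
         Wc = rnd(H, d), Uc = rnd(H, H), bc = rnd(H, 1))
  })
}

make_gru_params <- function(H, d, seed = 1) {
  with_seed <- beatcast:::with_seed
  with_seed(seed, {
    rnd <- function(nr, nc) matrix(rnorm(nr * nc, sd = 0.3), nr, nc)
    list(Wz = rnd(H, d), Uz = rnd(H, H), bz = rnd(H, 1),
         Wr = rnd(H, d), Ur = rnd(H, H), br = rnd(H, 1),
         Wh = rnd(H, d), Uh = rnd(H, H), bh = rnd(H, 1))
  })
}

test_that("LSTM step reproduces the analytic zero-weight limits", {
  H <- 4
  zero <- lapply(make_lstm_params(H, 2), function(m) m * 0)
  # all-zero parameters and cell state: gates 0.5, state and output 0
  st <- lstm_step(zero, c(1, -1), rep(0.3, H), rep(0, H))
  expect_equal(st$c, rep(0, H))
  expect_equal(st$h, rep(0, H))
  # zero weights with c_prev = c: c_t = 0.5 c, h_t = 0.5 tanh(0.5 c)
  cp <- c(0.8, -0.4, 0.1, 1)
  st2 <- lstm_step(zero, c(1, -1), rep(0, H), cp)
  expect_equal(st2$c, 0.5 * cp)
  expect_equal(st2$h, 0.5 * tanh(0.5 * cp))
})

test_that("LSTM step matches an independent transcription", {
  H <- 5; d <- 3
  p <- make_lstm_params(H, d, seed = 8)
  x <- rnorm(d); h0 <- rnorm(H); c0 <- rnorm(H)
  sg <- function(z) 1 / (1 + exp(-z))
  i <- sg(p$Wi %*% x + p$Ui %*% h0 + p$bi)
  f <- sg(p$Wf %*% x + p$Uf %*% h0 + p$bf)
  o <- sg(p$Wo %*% x + p$Uo %*% h0 + p$bo)
  cb <- tanh(p$Wc %*% x + p$Uc %*% h0 + p$bc)
  ct <- as.numeric(f * c0 + i * cb)
  ht <- as.numeric(tanh(ct) * o)
  st <- lstm_step(p, x, h0, c0)
  expect_equal(st$c, ct, tolerance = 1e-12)
  expect_equal(st$h, ht, tolerance = 1e-12)
  expect_true(all(i > 0 & i < 1 & f > 0 & f < 1 & o > 0 & o < 1))
  expect_true(all(abs(st$h) <= 1))
})

test_that("GRU step matches its equation and limits", {
  H <- 4
  zero <- lapply(make_gru_params(H, 2), function(m) m * 0)
  h0 <- c(0.5, -0.2, 0.9, 0)
  # zero weights: z = 0.5, candidate 0, so h <- 0.5 h
  expect_equal(gru_step(zero, c(1, 1), h0), 0.5 * h0)
  # large negative update-gate bias freezes the state
  frozen <- zero; frozen$bz <- matrix(-50, H, 1)
  expect_equal(gru_step(frozen, c(1, 1), h0), h0, tolerance = 1e-12)
  # random instance against an independent transcription
  p <- make_gru_params(H, 3, seed = 4)
  x <- rnorm(3); h <- rnorm(H)
  sg <- function(z) 1 / (1 + exp(-z))
  z <- sg(p$Wz %*% x + p$Uz %*% h + p$bz)
  r <- sg(p$Wr %*% x + p$Ur %*% h + p$br)
  hb <- tanh(p$Wh %*% x + p$Uh %*% (r * h) + p$bh)
  expect_equal(gru_step(p, x, h), as.numeric((1 - z) * h + z * hb),
               tolerance = 1e-12)
})

test_that("compiled forward pass equals composition of the R step
           functions", {
  spec <- gated_spec("lstm", n_hidden = 6, n_layers = 2, n_inputs = 2)
  params <- init_gated_params(spec, seed = 13)
  X <- matrix(rnorm(24), 2, 12)
  out <- beatcast:::.gated_forward(params, X)
  h1 <- h2 <- rep(0, 6); c1 <- c2 <- rep(0, 6)
  ys <- numeric(12)
  for (t in 1:12) {
    s1 <- lstm_step(params$layers[[1]], X[, t], h1, c1)
    h1 <- s1$h; c1 <- s1$c
    s2 <- lstm_step(params$layers[[2]], h1, h2, c2)
    h2 <- s2$h; c2 <- s2$c
    ys[t] <- as.numeric(params$Wy %*% h2) + params$by[1, 1]
  }
  expect_equal(as.numeric(out$outputs), ys, tolerance = 1e-10)
  expect_equal(as.numeric(out$h[[2]]), h2, tolerance = 1e-10)
})

test_that("analytic BPTT gradients agree with finite differences", {
  for (kind in c("lstm", "gru")) {
    spec <- gated_spec(kind, n_hidden = 3, n_layers = 2, n_inputs = 2)
    p <- init_gated_params(spec, seed = 3)
    set.seed(31)
    X <- matrix(rnorm(20), 2, 10)
    y <- rnorm(10)
    lg <- beatcast:::.gated_loss_grad(p, X, y)
    eps <- 1e-6
    worst <- 0
    for (l in 1:2) {
      for (nm in names(p$layers[[l]])) {
        for (k in seq_len(min(2, length(p$layers[[l]][[nm]])))) {
          pp <- p; pp$layers[[l]][[nm]][k] <- pp$layers[[l]][[nm]][k] + eps
          pm <- p; pm$layers[[l]][[nm]][k] <- pm$layers[[l]][[nm]][k] - eps
          num <- (beatcast:::.gated_loss_grad(pp, X, y)$loss -
                    beatcast:::.gated_loss_grad(pm, X, y)$loss) / (2 * eps)
          ana <- lg$grad$layers[[l]][[nm]][k]
          worst <- max(worst, abs(num - ana) /
                         max(abs(num) + abs(ana), 1e-8))
        }
      }
    }
    expect_lt(worst, 1e-4)
  }
})

test_that("a GRU has fewer trainable parameters than an LSTM of equal
           width", {
  for (H in c(10, 100)) {
    expect_lt(n_gated_params(gated_spec("gru", H, 1, 2)),
              n_gated_params(gated_spec("lstm", H, 1, 2)))
  }
})

test_that("training fits a constant series to near-zero loss", {
  t <- seq(0, 400, 4)
  series <- lin_series(t, rep(0.5, length(t)))
  split <- structure(
    list(pre_train = series[1:5, ], train = series[6:80, ],
         test = series[81:101, ], series = series),
    class = "dataset_split"
  )
  spec <- gated_spec("lstm", n_hidden = 4, n_layers = 1, n_inputs = 1)
  model <- gated_train(split, spec,
                       train_config(max_epochs = 2000,
                                    learning_rate = 5e-2, seed = 2))
  expect_lt(tail(model$loss_history, 1), 1e-6)
  # loss history trends downward
  expect_lt(mean(tail(model$loss_history, 10)),
            mean(head(model$loss_history, 10)))
  # closed loop over the test horizon stays at the constant
  pred <- forecast_recursive(model, split)
  expect_equal(pred$voltage, rep(0.5, 21), tolerance = 0.02)
  # zero-step horizon
  split0 <- split
  split0$test <- series[0, ]
  expect_equal(nrow(forecast_recursive(model, split0)), 0)
})

test_that("gated training is reproducible under a fixed seed", {
  split <- fk_split_small()
  cfg <- train_config(max_epochs = 3, seed = 5)
  m1 <- gated_train(split, gated_spec("gru", 10, 1, 2), cfg)
  m2 <- gated_train(split, gated_spec("gru", 10, 1, 2), cfg)
  expect_identical(m1$loss_history, m2$loss_history)
  expect_identical(forecast_recursive(m1, split)$voltage,
                   forecast_recursive(m2, split)$voltage)
})
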