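test_that("rmse closed forms and properties hold", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(0, 1, 2), c(0, 1, 2) + 0.3), 0.3)
  expect_equal(rmse(c(0, 1), c(1, 1)), sqrt(0.5))
  expect_error(rmse(1:3, 1:4), "mismatch")
  # triangle-type bound on random sequences
  set.seed(2)
  for (i in 1:20) {
    a <- rnorm(30); b <- rnorm(30); c <- rnorm(30)
    expect_lte(rmse(a, c), rmse(a, b) + rmse(b, c) + 1e-12)
  }
})

test_that("APD extraction is exact on analytic pulses", {
  # rectangle: 200 ms at 0.8
  rect <- lin_series(c(0, 99.999, 100, 300, 300.001, 400),
                     c(0, 0, 0.8, 0.8, 0, 0))
  a <- extract_apds(rect, 0.3)
  expect_equal(nrow(a), 1)
  expect_equal(a$apd, 200, tolerance = 0.1)
  # triangle 0 -> 1 -> 0 over 100 ms, threshold 0.5: crossing at 25/75
  tri <- lin_series(c(0, 50, 100), c(0, 1, 0))
  at <- extract_apds(tri, 0.5)
  expect_equal(at$apd, 50, tolerance = 1e-9)
  expect_equal(at$onset, 25, tolerance = 1e-9)
  # no crossings: empty result
  expect_equal(nrow(extract_apds(lin_series(0:5, rep(0.1, 6)), 0.3)), 0)
  # runs touching the series boundary are discarded
  trunc <- lin_series(c(0, 10, 20), c(0.9, 0.8, 0.7))
  expect_equal(nrow(extract_apds(trunc, 0.3)), 0)
})

test_that("APD extraction is stable under trace refinement", {
  set.seed(6)
  t <- seq(0, 2000, 5)
  v <- pmax(0, sin(t / 100))
  coarse <- extract_apds(lin_series(t, v), 0.3)
  # insert midpoints on the same piecewise-linear trace
  tm <- sort(c(t, t[-1] - 2.5))
  vm <- approx(t, v, xout = tm)$y
  fine <- extract_apds(lin_series(tm, vm), 0.3)
  expect_equal(nrow(coarse), nrow(fine))
  expect_lt(max(abs(coarse$apd - fine$apd)), 1)
})

test_that("per-beat APD errors match, shift, and report misses", {
  t <- seq(0, 3000, 1)
  v <- pmax(0, sin(t / 50))       # beats every ~314 ms
  a <- extract_apds(lin_series(t, v), 0.3)
  expect_gt(nrow(a), 5)
  # identical series: zero errors
  e0 <- apd_error(a, a)
  expect_true(all(e0$matched))
  expect_true(all(e0$abs_error == 0))
  # uniform +5 ms APD inflation
  shifted <- a
  shifted$offset <- shifted$offset + 5
  shifted$apd <- shifted$apd + 5
  e5 <- apd_error(a, shifted)
  expect_equal(e5$abs_error, rep(5, nrow(a)))
  # dropping one predicted beat yields one miss, others matched
  dropped <- a[-3, ]
  ed <- apd_error(a, dropped)
  expect_equal(sum(!ed$matched), 1)
  expect_false(ed$matched[3])
  expect_equal(sum(ed$matched), nrow(a) - 1)
})

test_that("evaluation reports carry aligned metrics and tidy output", {
  split <- fk_split_small()
  rep <- forecast_with(split, "esn", n_neurons = 40, seed = 1)
  expect_s3_class(rep, "eval_report")
  expect_gte(rep$rmse, 0)
  td <- tidy(rep)
  expect_equal(nrow(td), nrow(rep$apd))
  gl <- glance(rep)
  expect_equal(gl$rmse, rep$rmse)
  expect_equal(gl$n_beats, nrow(rep$apd))
})

test_that("grid search returns the arg-min and matches brute force", {
  split <- fk_split_small()
  grid <- list(leaking_rate = c(0.3, 0.6), ridge_beta = c(1e-4, 1e-2))
  gs <- grid_search(split, "esn", grid, n_seeds = 2, seed = 1,
                    n_neurons = 30)
  expect_equal(nrow(gs$log), 4)
  # brute-force replay of all four cells
  replay <- apply(expand.grid(grid), 1, function(cell) {
    forecast_seed_averaged(split, "esn", n_seeds = 2, seed = 1,
                           n_neurons = 30,
                           esn_args = as.list(cell))$rmse_mean
  })
  expect_equal(sort(gs$log$score), sort(unname(replay)))
  expect_equal(gs$best_score, min(replay))
  # size-1 grid returns that configuration
  g1 <- grid_search(split, "esn", list(leaking_rate = 0.4), n_seeds = 1,
                    n_neurons = 20)
  expect_equal(g1$best$leaking_rate, 0.4)
  # duplicated cells score identically (determinism under fixed seeds)
  g2 <- grid_search(split, "esn", list(leaking_rate = c(0.4, 0.4)),
                    n_seeds = 1, n_neurons = 20)
  expect_equal(g2$log$score[1], g2$log$score[2])
})

test_that("compare_methods emits one tidy row per method and size", {
  split <- fk_split_small()
  tab <- compare_methods(split, methods = c("esn", "clustered_esn"),
                         sizes = c(20, 40), n_seeds = 2)
  expect_equal(nrow(tab), 4)
  expect_true(all(c("method", "n_neurons", "rmse_mean", "apd_mae",
                    "wall_time") %in% names(tab)))
  expect_true(all(is.finite(tab$rmse_mean)))
  one <- compare_methods(split, methods = "esn", sizes = 30, n_seeds = 1)
  expect_equal(nrow(one), 1)
})
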