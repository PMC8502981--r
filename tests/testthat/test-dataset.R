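test_that("unit rescaling builds the affine map and round-trips", {
  s <- lin_series(0:3, c(-80, -20, 40, -80))
  r <- rescale_unit_interval(s)
  expect_equal(range(r$voltage), c(0, 1))
  m <- attr(r, "rescale_map")
  expect_equal(m$offset, -80)
  expect_equal(m$scale, 120)
  expect_equal(r$voltage, (s$voltage + 80) / 120)
  expect_equal(unrescale(r)$voltage, s$voltage, tolerance = 1e-12)

  # already-[0,1] voltages map through the identity when flagged pre-scaled
  q <- lin_series(0:2, c(0, 1, 0.5))
  rq <- rescale_unit_interval(q, prescaled = TRUE)
  expect_identical(rq$voltage, q$voltage)
  expect_equal(attr(rq, "rescale_map"), list(offset = 0, scale = 1))

  expect_error(rescale_unit_interval(lin_series(0:2, rep(1, 3))),
               "constant")
})

test_that("resampling with a zero threshold is the identity", {
  s <- lin_series(seq(0, 100, 0.5), sin(seq(0, 100, 0.5) / 5))
  expect_equal(resample_series(s, 0, 20), s)
})

test_that("constant-voltage input is kept at the time threshold only", {
  s <- lin_series(seq(0, 1000, 1), rep(0.5, 1001))
  r <- resample_series(s, dv_threshold = 0.1, dt_max = 50)
  gaps <- diff(r$time)
  expect_true(all(gaps == 51))  # first time the gap exceeds 50
})

test_that("every kept pair satisfies the voltage-or-time rule and output
           points are input points", {
  set.seed(4)
  s <- lin_series(cumsum(runif(500, 0.1, 2)), cumsum(rnorm(500, 0, 0.05)))
  cfg <- list(dv = 0.08, dtm = 15)
  r <- resample_series(s, cfg$dv, cfg$dtm)
  dv <- abs(diff(r$voltage))
  dtv <- diff(r$time)
  expect_true(all(dv >= cfg$dv | dtv > cfg$dtm))
  expect_true(all(r$time %in% s$time))
  expect_true(all(r$voltage %in% s$voltage))
  # idempotence
  expect_equal(resample_series(r, cfg$dv, cfg$dtm), r)
})

test_that("resampled size is non-increasing in the voltage threshold", {
  set.seed(8)
  s <- lin_series(seq(0, 200, 0.5), cumsum(rnorm(401, 0, 0.05)))
  sizes <- vapply(c(0, 0.02, 0.05, 0.1, 0.2),
                  function(dv) nrow(resample_series(s, dv, 30)),
                  numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("beat onsets match the pacing protocol on simulated data", {
  p <- tiny_protocol(6, cl = 400)
  s <- simulate_fk(p, t_end = 2600)
  onsets <- detect_beat_onsets(s, 0.15)
  expect_length(onsets, 6)
  expect_true(all(onsets > p$pulse_times & onsets < p$pulse_times + 10))

  expect_identical(detect_beat_onsets(lin_series(0:10, rep(0, 11))),
                   numeric(0))
  tri <- lin_series(c(0, 10, 20, 30), c(0, 1, 0, 0))
  expect_length(detect_beat_onsets(tri, 0.5), 1)
})

test_that("stimulus-channel reconstruction stamps pulses on the grid", {
  grid <- seq(0, 300, 0.1)
  ch <- reconstruct_stimulus_channel(100, grid)
  expect_equal(sum(ch > 0), 20)           # 2 ms at 0.1 ms spacing
  expect_true(all(ch[ch > 0] == 0.2))
  expect_equal(reconstruct_stimulus_channel(numeric(0), grid),
               rep(0, length(grid)))
  # onsets recovered within one grid step by re-detection of pulse starts
  on2 <- grid[which(diff(c(0, ch)) > 0)]
  expect_equal(on2, 100, tolerance = 0.1)
  # adversarial coarse grid: a pulse falling between grid points warns
  coarse <- c(0, 50, 103, 200)
  expect_warning(reconstruct_stimulus_channel(100, coarse), "no grid")
  expect_error(reconstruct_stimulus_channel(c(100, 101), grid),
               "overlap")
})

test_that("spline artifact removal restores a known-clean trace", {
  t <- seq(0, 100, 0.5)
  clean <- sin(t / 8)
  dirty <- clean
  dirty[t >= 40 & t <= 44] <- 3   # injected stimulus-artifact spike
  s <- lin_series(t, dirty)
  fixed <- remove_artifacts_spline(s, list(c(40, 44)))
  expect_lt(max(abs(fixed$voltage - clean)), 0.01)
  # untouched outside the window
  out <- t < 40 | t > 44
  expect_identical(fixed$voltage[out], dirty[out])
  # empty window list is the identity; disjoint windows commute
  expect_identical(remove_artifacts_spline(s, list()), s)
  w2 <- list(c(20, 24), c(60, 64))
  expect_equal(remove_artifacts_spline(s, w2),
               remove_artifacts_spline(s, rev(w2)))
  expect_error(remove_artifacts_spline(s, list(c(-5, 10))), "start")
})

test_that("train/test splitting partitions at beat boundaries", {
  split <- fk_split_small()
  expect_equal(split$n_test_beats,
               length(split$beat_onsets) - 4 - 20)
  # contiguous partition recovers the series
  expect_equal(
    dplyr::bind_rows(split$pre_train, split$train, split$test)$voltage,
    split$series$voltage
  )
  # boundaries fall at detected onsets
  expect_gte(min(split$train$time), split$beat_onsets[5] - 1e-9)
  expect_gte(min(split$test$time), split$beat_onsets[25] - 1e-9)
  expect_error(split_train_test(split$series, split$beat_onsets,
                                20, 20), "beats")
})
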