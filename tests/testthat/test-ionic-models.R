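test_that("unstimulated FK cell stays at rest", {
  p <- stim_protocol(10, duration = 2, amplitude = 0)
  s <- simulate_fk(p, t_end = 500)
  expect_lt(max(s$voltage), 0.05)
})

test_that("each suprathreshold FK pulse elicits one action potential", {
  p <- tiny_protocol(5, cl = 400)
  s <- simulate_fk(p, t_end = 2200)
  a <- extract_apds(s, 0.3)
  expect_equal(nrow(a), 5)
  expect_gte(max(s$voltage), 0.95)
})

test_that("FK integration is adequate: halving dt moves APDs < 2 ms", {
  p <- tiny_protocol(4, cl = 350)
  a1 <- extract_apds(simulate_fk(p, t_end = 1500, dt = 0.1), 0.3)
  a2 <- extract_apds(simulate_fk(p, t_end = 1500, dt = 0.05), 0.3)
  expect_equal(nrow(a1), nrow(a2))
  expect_lt(max(abs(a1$apd - a2$apd)), 2)
})

test_that("simulated stimulus channel integrates to the delivered charge", {
  p <- tiny_protocol(4, cl = 300)
  s <- simulate_fk(p, t_end = 1400)
  dt <- attr(s, "dt")
  expect_equal(sum(s$stimulus) * dt, 4 * 0.4 * 2,
               tolerance = 0.4 * dt * 4 / (4 * 0.4 * 2))
})

test_that("FK simulation is bit-reproducible and divergence is caught", {
  p <- tiny_protocol(2)
  expect_identical(simulate_fk(p, t_end = 700), simulate_fk(p, t_end = 700))
  # a absurdly large step blows up the explicit integration
  strong <- stim_protocol(10, duration = 50, amplitude = 10)
  expect_error(simulate_fk(strong, t_end = 300, dt = 20), "diverged")
})

test_that("Mitchell-Schaeffer cell rests without stimulus and fires with one", {
  p0 <- stim_protocol(10, duration = 2, amplitude = 0)
  s0 <- simulate_ms(p0, t_end = 400)
  expect_lt(max(s0$voltage), 1e-6)

  p1 <- stim_protocol(10, duration = 2, amplitude = 0.3)
  s1 <- simulate_ms(p1, t_end = 600)
  a1 <- extract_apds(s1, 0.3)
  expect_equal(nrow(a1), 1)
  # self-consistency against a refined-step integration
  a2 <- extract_apds(simulate_ms(p1, t_end = 600, dt = 0.02), 0.3)
  expect_lt(abs(a1$apd - a2$apd), 2)
})

test_that("MS with v_gate = 1 gives no regenerative upstroke", {
  p <- stim_protocol(10, duration = 2, amplitude = 0.3)
  s <- simulate_ms(p, t_end = 300, params = ms_params(v_gate = 1))
  # voltage never exceeds what the stimulus alone can deposit
  expect_lt(max(s$voltage), 0.3 * 2 + 1e-6)
  expect_equal(nrow(extract_apds(s, 0.65)), 0)
})

test_that("Noble-Lorenz fires aperiodically and is seed-reproducible", {
  s <- simulate_noble_lorenz(t_end = 5000, seed = 2, burn_in = 1000)
  r <- rescale_unit_interval(s)
  a <- extract_apds(r, 0.3)
  expect_gt(nrow(a), 3)
  cls <- diff(a$onset)
  expect_gt(sd(cls), 1)   # not a fixed cycle length
  expect_identical(
    simulate_noble_lorenz(t_end = 2000, seed = 9, burn_in = 500)$voltage,
    simulate_noble_lorenz(t_end = 2000, seed = 9, burn_in = 500)$voltage
  )
})

test_that("decoupled Noble (zero anionic slope) runs autonomously", {
  pars <- noble_lorenz_params(g_an_slope = 0)
  s <- simulate_noble_lorenz(t_end = 4000, params = pars, seed = 1,
                             burn_in = 500)
  # the Purkinje cell is self-oscillatory; periods are now near-constant
  a <- extract_apds(rescale_unit_interval(s), 0.3)
  expect_gt(nrow(a), 2)
  expect_lt(sd(diff(a$onset)), 5)
})

test_that("nearby Lorenz initial states diverge (chaotic forcing)", {
  base <- c(1, 1, 25)
  s1 <- simulate_noble_lorenz(t_end = 20000, lorenz_init = base,
                              seed = 1, burn_in = 0)
  s2 <- simulate_noble_lorenz(t_end = 20000,
                              lorenz_init = base + c(0, 0, 1e-6),
                              seed = 1, burn_in = 0)
  d <- abs(s1$voltage - s2$voltage)
  early <- max(d[s1$time < 2000])
  late <- max(d[s1$time > 15000])
  expect_lt(early, 1)
  expect_gt(late, 10 * max(early, 1e-6))
})

test_that("gating variables stay within [0, 1]", {
  p <- tiny_protocol(3, cl = 250)
  s <- simulate_fk(p, t_end = 900)   # would abort internally otherwise
  expect_true(all(is.finite(s$voltage)))
  sm <- simulate_ms(tiny_protocol(3, cl = 250), t_end = 900)
  expect_true(all(is.finite(sm$voltage)))
})
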