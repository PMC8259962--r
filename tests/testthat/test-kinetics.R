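# Peak measurement, exponential decay fitting and steady-state fraction.

test_that("peak measurement finds the largest-magnitude extremum", {
  # triangular inward pulse peaking at -100 pA at 5 ms
  y <- c(seq(0, -100, length.out = 51), seq(-98, 0, length.out = 50))
  sw <- ep_sweep(y, dt = 0.1, onset = 0)
  pk <- measure_peak(sw)
  expect_equal(pk$peak, -100)
  expect_equal(pk$time, 5)
  expect_false(pk$degenerate)
  # all-zero trace is flagged degenerate
  expect_true(measure_peak(ep_sweep(numeric(100), 0.1))$degenerate)
  expect_error(measure_peak(sw, window = c(50, 60)), "empty")
})

test_that("difference-of-exponentials peak matches the closed form", {
  taur <- 0.5; taud <- 5
  tpk <- taur * taud / (taud - taur) * log(taud / taur)
  shape_pk <- exp(-tpk / taud) - exp(-tpk / taur)
  a <- -50 / shape_pk
  t <- seq(0, 40, by = 0.01)
  sw <- ep_sweep(a * (exp(-t / taud) - exp(-t / taur)), dt = 0.01, onset = 0)
  pk <- measure_peak(sw)
  expect_equal(pk$peak, -50, tolerance = 1e-4)
  expect_equal(pk$time, tpk, tolerance = 0.02)
})

test_that("single-exponential identity: tau recovered exactly, tau_w = tau1", {
  sw <- exp_decay_sweep(100, 5)
  f <- fit_decay(sw)
  expect_equal(f$n_components, 1)
  expect_equal(f$weighted_tau, 5, tolerance = 1e-6)
  expect_equal(f$components$tau[1], f$weighted_tau)
  expect_equal(f$components$amplitude[1], 100, tolerance = 1e-4)
})

test_that("noiseless bi-exponential recovered with tau_w = 4.4 ms", {
  sw <- exp_decay_sweep(c(70, 30), c(2, 10))
  f <- fit_decay(sw)
  expect_equal(f$n_components, 2)
  expect_equal(f$weighted_tau, 4.4, tolerance = 1e-3)
  expect_equal(sort(f$components$tau), c(2, 10), tolerance = 1e-3)
  expect_equal(f$components$amplitude[order(f$components$tau)], c(70, 30),
               tolerance = 1e-3)
})

test_that("three separated components are recovered within 0.1%", {
  sw <- exp_decay_sweep(c(60, 30, 10), c(1, 5, 25), dt = 0.02, t_max = 150)
  f <- fit_decay(sw, max_components = 3)
  expect_equal(f$n_components, 3)
  o <- order(f$components$tau)
  expect_equal(f$components$tau[o], c(1, 5, 25), tolerance = 1e-3)
  expect_equal(f$components$amplitude[o], c(60, 30, 10), tolerance = 1e-3)
})

test_that("noisy bi-exponential: median tau_w within 5% over repeats", {
  set.seed(99)
  tws <- vapply(1:60, function(k) {
    sw <- exp_decay_sweep(c(70, 30), c(2, 10), noise_sd = 2)
    fit_decay(sw)$weighted_tau
  }, 0)
  expect_lt(abs(median(tws) - 4.4) / 4.4, 0.05)
})

test_that("fits are scale invariant and report scaled amplitudes", {
  sw <- exp_decay_sweep(c(70, 30), c(2, 10))
  f1 <- fit_decay(sw)
  sw2 <- sw; sw2$current <- 3.5 * sw$current
  f2 <- fit_decay(sw2)
  expect_equal(f2$weighted_tau, f1$weighted_tau, tolerance = 1e-6)
  expect_equal(f2$components$tau, f1$components$tau, tolerance = 1e-5)
  expect_equal(f2$components$amplitude, 3.5 * f1$components$amplitude,
               tolerance = 1e-4)
  # steady-state fraction is scale invariant too
  o <- mean_occupancy(build_scheme("gof"), make_stimulus("desensitization"))
  swd <- ep_sweep(-100 * o$open, 0.01, onset = 20, offset = 520)
  swd3 <- swd; swd3$current <- 3 * swd$current
  expect_equal(steady_state_fraction(swd3), steady_state_fraction(swd),
               tolerance = 1e-10)
})

test_that("exp_fit behaves like a model object", {
  sw <- exp_decay_sweep(c(70, 30), c(2, 10))
  f <- fit_decay(sw)
  expect_named(coef(f), c("a1", "a2", "tau1", "tau2", "offset"))
  expect_equal(length(residuals(f)), length(f$data$y))
  expect_lt(max(abs(residuals(f))), 1e-6)
  pred <- predict(f)
  expect_equal(pred, f$data$y, tolerance = 1e-6)
  expect_output(print(f), "weighted tau")
  expect_output(summary(f), "RSS")
})

test_that("steady-state fraction is the plateau/peak percentage", {
  # constructed trace: peak -100 pA then plateau -28 pA
  y <- c(numeric(2000), seq(0, -100, length.out = 101),
         seq(-100, -28, length.out = 400), rep(-28, 47500))
  sw <- ep_sweep(y, dt = 0.01, onset = 20, offset = 500)
  expect_equal(steady_state_fraction(sw, pulse_end = 500), 28)
  # full decay to zero
  y0 <- c(numeric(2000), seq(0, -100, length.out = 101),
          -100 * exp(-(1:47900) * 0.01 / 5))
  sw0 <- ep_sweep(y0, dt = 0.01, onset = 20, offset = 500)
  expect_lt(steady_state_fraction(sw0, pulse_end = 500), 1e-8)
  expect_error(steady_state_fraction(sw, pulse_end = 30), "before the pulse")
  expect_error(
    steady_state_fraction(ep_sweep(numeric(100) , 0.01, onset = 0),
                          pulse_end = 0.9, steady_window = 0.5),
    "zero peak|degenerate|cannot")
})

test_that("decay window shorter than 10 samples is rejected", {
  sw <- exp_decay_sweep(100, 5, dt = 1, t_max = 30)
  expect_error(fit_decay(sw, end = 5), "10 samples")
})
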