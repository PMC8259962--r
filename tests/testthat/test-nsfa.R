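# Variance-mean construction and parabola inversion.

test_that("noiseless analytic parabola is inverted exactly", {
  I <- seq(1, 30, length.out = 12)
  vc <- variance_curve(I, 1.2 * I - I^2 / 50, sigma0_sq = 0)
  ft <- fit_nsfa(vc)
  expect_equal(ft$i, 1.2, tolerance = 1e-9)
  expect_equal(ft$n_channels, 50, tolerance = 1e-9)
  expect_length(ft$flags, 0)
  # free-background mode recovers sigma0^2 too
  vc2 <- variance_curve(I, 1.2 * I - I^2 / 50 + 0.8)
  ft2 <- fit_nsfa(vc2, fix_background = FALSE)
  expect_equal(ft2$i, 1.2, tolerance = 1e-9)
  expect_equal(ft2$n_channels, 50, tolerance = 1e-9)
  expect_equal(ft2$sigma0_sq, 0.8, tolerance = 1e-9)
})

test_that("derived conductance and open probability follow their definitions", {
  # gamma = i / (Vh - Vr), Vr assumed 0: 1.176 pA at -70 mV -> 16.8 pS
  I <- seq(1, 37.6, length.out = 10)
  vc <- variance_curve(I, 1.176 * I - I^2 / 64, vh = -70, vr = 0)
  ft <- fit_nsfa(vc)
  expect_equal(ft$gamma, 16.8, tolerance = 1e-6)
  # Popen = I_peak / (i N) with I_peak = 37.6, i = 1.176, N = 64
  expect_equal(ft$popen_peak, 37.6 / (1.176 * 64), tolerance = 1e-6)
})

test_that("degenerate curves are flagged, not inverted", {
  I <- seq(1, 20, length.out = 8)
  flat <- fit_nsfa(variance_curve(I, rep(3, 8), sigma0_sq = 0))
  expect_true(any(c("nonconcave", "degenerate") %in% flat$flags))
  expect_true(is.na(flat$i))
  convex <- fit_nsfa(variance_curve(I, 0.1 * I + I^2 / 40))
  expect_true("nonconcave" %in% convex$flags)
  expect_error(fit_nsfa(variance_curve(1:4, rep(1, 4))), ">= 5 bins")
})

test_that("identical sweeps give a zero-variance curve", {
  base <- -c(numeric(200), seq(0, 30, length.out = 50),
             30 * exp(-(1:800) * 0.1 / 4))
  ens <- trace_ensemble(matrix(rep(base, 25), ncol = 25), dt = 0.1,
                        meta = list(onset = 20, vh = -70, vr = 0))
  suppressWarnings(vc <- variance_mean(ens))
  expect_equal(max(vc$variance), 0)
  expect_equal(vc$sigma0_sq, 0)
})

test_that("binned curve from a noiseless binomial ensemble lies on i*I - I^2/N", {
  N <- 80; gamma <- 16.8
  ens <- simulate_ensemble(build_scheme("gof"), make_stimulus("deactivation"),
                           channel_params(N, gamma), noise_model(0), 300,
                           seed = 31)
  ens <- baseline_correct(ens, c(1, 19))
  vc <- variance_mean(ens, n_bins = 12)
  i_true <- abs(ens$meta$unit_current)
  pred <- i_true * vc$mean - vc$mean^2 / N
  expect_lt(max(abs(vc$variance - pred)) / max(pred), 0.2)
  expect_lt(median(abs(vc$variance - pred) / pred), 0.1)
})

test_that("parameter recovery from simulated ensembles (i, N, gamma)", {
  # 200 sweeps, N = 64, gamma = 16.8 pS at -70 mV, 1 pA baseline noise;
  # the 10-seed version is in the acceptance suite
  ens <- nsfa_ensemble(seed = 101)
  ft <- fit_nsfa(variance_mean(ens))
  i_true <- abs(ens$meta$unit_current)
  expect_lt(abs(ft$i - i_true) / i_true, 0.10)
  expect_lt(abs(ft$n_channels - 64) / 64, 0.15)
  expect_lt(abs(ft$gamma - 16.8) / 16.8, 0.10)
  expect_true(ft$popen_peak <= 1.05)
})

test_that("gamma estimate is insensitive to doubling N at fixed gamma", {
  g1 <- fit_nsfa(variance_mean(nsfa_ensemble(seed = 55, n_channels = 64)))
  g2 <- fit_nsfa(variance_mean(nsfa_ensemble(seed = 55, n_channels = 128)))
  expect_lt(abs(g2$gamma - g1$gamma) / g1$gamma, 0.1)
})

test_that("successive-difference estimator resists rundown", {
  sch <- build_scheme("gof")
  stim <- make_stimulus("desensitization")
  ch <- channel_params(64, 16.8)
  run <- baseline_correct(simulate_ensemble(sch, stim, ch,
                                            noise_model(1, rundown = 0.997),
                                            200, seed = 77), c(1, 19))
  f_sd <- fit_nsfa(variance_mean(run, estimator = "successive_difference"))
  f_plain <- fit_nsfa(variance_mean(run))
  # the plain across-sweep variance is swamped by the amplitude drift
  # (an extra quadratic term exceeding 1/N): the inversion fails
  expect_gt(length(f_plain$flags), 0)
  # the pairwise estimator still recovers the channel count; its unitary
  # current is scaled by the rundown moment ratio E[f^2]/E[f]
  expect_lt(abs(f_sd$n_channels - 64) / 64, 0.25)
  rf <- run$meta$rundown
  expect_equal(f_sd$i / 1.176, mean(rf^2) / mean(rf), tolerance = 0.1)
})

test_that("too few sweeps are rejected and < 100 warns", {
  ens <- nsfa_ensemble(seed = 1, n_sweeps = 10)
  expect_error(variance_mean(ens), ">= 20 sweeps")
  ens2 <- nsfa_ensemble(seed = 1, n_sweeps = 30)
  expect_warning(variance_mean(ens2), "fewer than 100")
})
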