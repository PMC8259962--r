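# Event detection, averaging, EPSC decay, charge, PPR and NMDAR readout.

test_that("flat noise yields essentially no detections at 4 sd", {
  set.seed(8)
  rec <- ep_recording(rnorm(600001, 0, 4), dt = 0.1, vh = -70)
  det <- detect_events(rec)
  expect_lte(nrow(det), 1)
})

test_that("detector finds generated events with high precision and recall", {
  g <- generate_mepsc_recording(
    synaptic_gen_params(rate_hz = 1, duration_ms = 120e3, amp_mean = 20,
                        amp_sd = 4, noise_sd = 4, decay_tau = 1.9),
    seed = 42)
  det <- detect_events(g$recording)
  sc <- score_detection(det, g$events, tolerance = 2)
  expect_gte(sc$precision, 0.9)
  expect_gte(sc$recall, 0.9)
})

test_that("template-based detection works too", {
  g <- generate_mepsc_recording(
    synaptic_gen_params(rate_hz = 1, duration_ms = 30e3, decay_tau = 1.9),
    seed = 7)
  kern <- -20 * amparkinetics:::epsc_kernel(0.1, 0.3, 1.9)
  det <- detect_events(g$recording, template = kern)
  sc <- score_detection(det, g$events, tolerance = 2)
  expect_gte(sc$recall, 0.85)
  expect_gte(sc$precision, 0.85)
})

test_that("recordings must be long enough and thresholds positive", {
  expect_error(ep_recording(rnorm(500), dt = 0.1), ">= 1 s")
  rec <- ep_recording(rnorm(20000), dt = 0.1)
  expect_error(detect_events(rec, threshold_sd = 0), "> 0")
  expect_error(detect_events(ep_recording(rep(0, 20000), dt = 0.1)),
               "noise SD")
})

test_that("detection scoring implements greedy one-to-one matching", {
  tr <- event_list(onset = c(10, 50, 90), amplitude = c(1, 1, 1))
  same <- score_detection(tr, tr)
  expect_equal(same$precision, 1)
  expect_equal(same$recall, 1)
  # all detections shifted +1 ms still match at 2 ms tolerance
  sh <- event_list(onset = c(11, 51, 91), amplitude = c(1, 1, 1))
  shifted <- score_detection(sh, tr, tolerance = 2)
  expect_equal(shifted$tp, 3L)
  # empty detections: recall 0, precision 1 by convention (flagged)
  none <- score_detection(event_list(numeric(0), numeric(0), numeric(0)), tr)
  expect_equal(none$recall, 0)
  expect_equal(none$precision, 1)
  expect_true("no_detections" %in% none$flags)
  expect_error(score_detection(tr, tr, tolerance = -1), "tolerance")
})

test_that("averaging identical noise-free events returns the kernel", {
  dt <- 0.1
  kern <- amparkinetics:::epsc_kernel(dt, 0.3, 1.9)
  n <- 100001
  x <- numeric(n)
  onsets <- seq(1000, 9000, by = 500)
  for (t0 in onsets) {
    i0 <- round(t0 / dt) + 1
    x[i0:(i0 + length(kern) - 1)] <- x[i0:(i0 + length(kern) - 1)] - 15 * kern
  }
  rec <- ep_recording(x, dt)
  tpk <- (which.max(kern) - 1) * dt
  ev <- event_list(onset = onsets, peak_time = onsets + tpk,
                   amplitude = rep(15, length(onsets)))
  avg <- average_events(rec, ev, window = c(5, 20), align = "onset")
  i_on <- round(5 / dt) + 1
  got <- avg$current[i_on:(i_on + length(kern) - 1)]
  expect_equal(got, -15 * kern[seq_along(got)], tolerance = 1e-10)
  expect_equal(avg$annotations$n_used, length(onsets))
  # averaging noise shrinks ~ 1/sqrt(n)
  set.seed(3)
  recn <- ep_recording(x + rnorm(n, 0, 4), dt)
  avgn <- average_events(recn, ev, window = c(5, 20), align = "onset")
  resid <- avgn$current[i_on:(i_on + length(kern) - 1)] + 15 * kern[seq_along(got)]
  expect_lt(sd(resid), 3 * 4 / sqrt(length(onsets)))
})

test_that("overlapping events are excluded from the average", {
  dt <- 0.1
  onsets <- c(1000, 1010, 3000, 5000, 7000)   # first two overlap
  ev <- event_list(onset = onsets, amplitude = rep(10, 5))
  x <- numeric(100001)
  rec <- ep_recording(x - 0, dt)
  # only 3 usable events remain
  avg <- average_events(rec, ev, window = c(5, 20), align = "onset")
  expect_equal(avg$annotations$n_used, 3)
  expect_equal(avg$annotations$n_excluded, 2)
  ev2 <- event_list(onset = c(1000, 1010, 3000), amplitude = rep(10, 3))
  expect_error(average_events(rec, ev2, window = c(5, 20)), "fewer than 3")
})

test_that("charge transfer integrates |I| and is additive and linear", {
  # rectangle: 100 pA for 10 ms -> 1000 pA ms
  sw <- ep_sweep(c(numeric(100), rep(-100, 101), numeric(100)), dt = 0.1)
  expect_equal(charge_transfer(sw, c(10, 20)), 1000)
  # single exponential a = 100, tau = 12.5: integral ~ a tau
  t <- seq(0, 125, by = 0.01)
  swe <- ep_sweep(-100 * exp(-t / 12.5), dt = 0.01)
  expect_equal(charge_transfer(swe, c(0, 125)), 1250, tolerance = 1e-3)
  # additivity over disjoint windows
  expect_equal(charge_transfer(swe, c(0, 50)) + charge_transfer(swe, c(50, 125)),
               charge_transfer(swe, c(0, 125)), tolerance = 1e-9)
  # linearity
  swe2 <- swe; swe2$current <- 2 * swe$current
  expect_equal(charge_transfer(swe2, c(0, 125)),
               2 * charge_transfer(swe, c(0, 125)))
  expect_equal(charge_transfer(ep_sweep(numeric(100), 0.1), c(0, 5)), 0)
  expect_error(charge_transfer(swe, c(100, 200)), "window")
})

test_that("PPR: decay subtraction removes the superposition bias", {
  pair <- generate_eepsc_pair(100, 1.5, 50, decay_tau = 12.5)
  sw <- get_sweep(pair, 1)
  corr <- paired_pulse_ratio(sw, correction = "decay_subtraction")
  uncorr <- paired_pulse_ratio(sw, correction = "none")
  expect_equal(corr$ppr, 1.5, tolerance = 0.01)
  expect_equal(uncorr$ppr, 1.5 + exp(-4), tolerance = 1e-6)
  # no overlap: both conventions agree at 1.0
  far <- get_sweep(generate_eepsc_pair(100, 1, 300, decay_tau = 5), 1)
  expect_equal(paired_pulse_ratio(far, correction = "none")$ppr, 1,
               tolerance = 1e-6)
  # zero first peak errors
  flat <- ep_sweep(numeric(5000), 0.1, stim_times = c(50, 100))
  expect_error(paired_pulse_ratio(flat), "zero first peak")
})

test_that("PPR recovery holds across ratios and intervals >= 2 tau", {
  for (ppr in c(0.7, 1.2, 1.8)) {
    for (iv in c(25, 50)) {
      sw <- get_sweep(generate_eepsc_pair(80, ppr, iv, decay_tau = 12.5), 1)
      got <- paired_pulse_ratio(sw, correction = "decay_subtraction")$ppr
      expect_equal(got, ppr, tolerance = 0.01)
    }
  }
})

test_that("NMDAR late component is the 150 ms window mean", {
  # fast tau 10 ms decays to nothing; slow amp 20 pA, tau 100 ms
  t <- seq(0, 400, by = 0.1)
  y <- 60 * exp(-pmax(t - 50, 0) / 10) + 20 * exp(-pmax(t - 50, 0) / 100)
  y[t < 50] <- 0
  sw <- ep_sweep(y, dt = 0.1, vh = 40, onset = 50)
  expect_equal(nmdar_amplitude(sw), 20 * exp(-1.5), tolerance = 0.01)
  expect_equal(nmdar_amplitude(ep_sweep(numeric(5001), 0.1, vh = 40,
                                        onset = 50)), 0)
  # too-short sweep and wrong holding annotation are errors
  expect_error(nmdar_amplitude(ep_sweep(y[t <= 100], 0.1, vh = 40,
                                        onset = 50)), "extend")
  expect_error(nmdar_amplitude(ep_sweep(y, 0.1, vh = -70, onset = 50)),
               "vh = 40")
})

test_that("mEPSC pipeline preserves kernel decay ordering across seeds", {
  # wild-type-like (fast) vs slowed kernel: recovered tau_w ordering
  # matches the generating ordering for every seed
  for (s in 1:5) {
    taus <- vapply(c(1.2, 1.8), function(tau_d) {
      g <- generate_mepsc_recording(
        synaptic_gen_params(rate_hz = 2, duration_ms = 30e3,
                            decay_tau = tau_d, noise_sd = 3), seed = s)
      det <- detect_events(g$recording)
      avg <- average_events(g$recording, det, window = c(5, 20))
      epsc_decay_tau(avg, max_components = 2)$weighted_tau
    }, 0)
    expect_lt(taus[1], taus[2])
  }
})
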