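# Generators: kinetic schemes, stimuli, deterministic oracle, stochastic
# ensembles and synaptic recordings.

test_that("scheme constructor enforces its invariants", {
  expect_s3_class(build_scheme("wt"), "kinetic_scheme")
  expect_error(build_scheme("nonsense"), "arg")
  expect_error(build_scheme("wt", rate_overrides = c(k_des = 1)),
               "nonexistent transition")
  expect_error(build_scheme("wt", rate_overrides = c(kdes = -1)),
               ">= 0")
  # override is applied
  s <- build_scheme("wt", rate_overrides = c(kres = 0.5))
  expect_equal(s$rates["kres", "rate"], 0.5)
  # disconnected graph rejected
  expect_error(kinetic_scheme(
    c("A", "B", "C"), c(FALSE, TRUE, FALSE), "A",
    data.frame(from = "A", to = "B", rate = 1, ligand_dep = FALSE)),
    "not connected")
  # at least one conducting state
  expect_error(kinetic_scheme(
    c("A", "B"), c(FALSE, FALSE), "A",
    data.frame(from = "A", to = "B", rate = 1, ligand_dep = FALSE)),
    "conducting")
})

test_that("stimulus protocols have the standard pulse shapes", {
  de <- make_stimulus("deactivation", dt = 0.01, exchange_tau = 0)
  expect_equal(max(de$conc), 10)
  expect_equal(de$offset - de$onset, 1)
  # square pulse: only two concentration levels
  expect_setequal(unique(de$conc), c(0, 10))
  ds <- make_stimulus("desensitization", dt = 0.01, exchange_tau = 0)
  expect_equal(ds$offset - ds$onset, 500)
  iv <- make_stimulus("iv_step", dt = 0.01, exchange_tau = 0)
  expect_equal(iv$offset - iv$onset, 200)
  expect_true(de$onset >= 20)                       # pre-pulse baseline
  expect_error(make_stimulus("deactivation", dt = -1), "dt")
  expect_error(make_stimulus("deactivation", exchange_tau = -0.1),
               "exchange_tau")
})

test_that("exchange smoothing gives the first-order 10-90% time tau*ln(9)", {
  s <- make_stimulus("desensitization", dt = 0.01, exchange_tau = 0.1)
  t_rel <- s$time - s$onset
  up <- s$conc[t_rel >= 0]
  t10 <- t_rel[t_rel >= 0][which(up >= 1)[1]]
  t90 <- t_rel[t_rel >= 0][which(up >= 9)[1]]
  expect_equal(t90 - t10, 0.1 * log(9), tolerance = 0.1)
  expect_equal(t90, 0.1 * log(10), tolerance = 0.1)
})

test_that("custom all-zero stimulus is valid and leaves the channel at rest", {
  s <- make_stimulus("custom", dt = 0.01, exchange_tau = 0,
                     custom_conc = rep(0, 500))
  expect_true(all(s$conc == 0))
  tr <- mean_occupancy(build_scheme("wt"), s)
  expect_true(all(tr$p[, "R"] == 1))
})

test_that("mean occupancy matches the two-state closed form to < 1e-4", {
  kon <- 0.3; koff <- 0.5; conc <- 2
  sch <- two_state_scheme(kon, koff)
  stim <- make_stimulus("custom", dt = 0.01, exchange_tau = 0,
                        custom_conc = rep(conc, 3000))
  tr <- mean_occupancy(sch, stim)
  t <- tr$time - stim$onset
  k1 <- kon * conc
  closed <- ifelse(t < 0, 0, k1 / (k1 + koff) * (1 - exp(-(k1 + koff) * t)))
  expect_lt(max(abs(tr$open - closed)), 1e-4)
})

test_that("occupancies are conserved and bounded for both presets", {
  for (p in c("wt", "gof")) {
    tr <- mean_occupancy(build_scheme(p), make_stimulus("deactivation"))
    expect_lt(max(abs(rowSums(tr$p) - 1)), 1e-9)
    expect_true(all(tr$p >= -1e-12 & tr$p <= 1 + 1e-12))
  }
})

test_that("stiff scheme/dt combinations are rejected", {
  sch <- build_scheme("wt", rate_overrides = c(koff = 50))
  expect_error(mean_occupancy(sch, make_stimulus("deactivation")),
               "stiffness")
  expect_error(simulate_ensemble(sch, make_stimulus("deactivation"),
                                 channel_params(10), noise_model(0), 2,
                                 seed = 1),
               "stiffness")
})

test_that("ensembles are pure functions of (params, seed)", {
  sch <- build_scheme("wt")
  stim <- make_stimulus("deactivation")
  ch <- channel_params(32)
  a <- simulate_ensemble(sch, stim, ch, noise_model(1), 5, seed = 11)
  b <- simulate_ensemble(sch, stim, ch, noise_model(1), 5, seed = 11)
  d <- simulate_ensemble(sch, stim, ch, noise_model(1), 5, seed = 12)
  expect_identical(a$current, b$current)
  expect_false(identical(a$current, d$current))
  expect_error(simulate_ensemble(sch, stim, ch, noise_model(1), 5),
               "seed")
  expect_identical(a$meta$seed, 11L)
})

test_that("zero channels give pure baseline noise", {
  ens <- simulate_ensemble(build_scheme("wt"), make_stimulus("deactivation"),
                           channel_params(0, 16.8), noise_model(2), 10,
                           seed = 3)
  expect_lt(abs(mean(ens$current)), 3 * 2 / sqrt(length(ens$current)))
})

test_that("pooled stochastic open fraction converges to the oracle", {
  # moderate size here; the full 1e5-channel check lives in the
  # acceptance suite
  sch <- build_scheme("gof")
  stim <- make_stimulus("deactivation")
  ens <- simulate_ensemble(sch, stim, channel_params(1000, 16.8, vh = -70),
                           noise_model(0), 40, seed = 7)
  p_sim <- rowMeans(ens$current) / (1000 * ens$meta$unit_current)
  oracle <- mean_occupancy(sch, stim)$open
  expect_lt(max(abs(p_sim - oracle)) / max(oracle), 0.03)
})

test_that("noiseless ensemble variance follows the binomial identity", {
  sch <- build_scheme("gof")
  stim <- make_stimulus("deactivation")
  N <- 80
  ens <- simulate_ensemble(sch, stim, channel_params(N, 16.8), noise_model(0),
                           400, seed = 21)
  i_u <- abs(ens$meta$unit_current)
  p <- mean_occupancy(sch, stim)$open
  v_pred <- i_u^2 * N * p * (1 - p)
  v_obs <- apply(ens$current, 1, var)
  sel <- p > 0.05
  # relative agreement where the signal lives; MC error ~ sqrt(2/399)
  expect_lt(median(abs(v_obs[sel] - v_pred[sel]) / v_pred[sel]), 0.15)
})

test_that("mEPSC generator: Poisson counts, truth list, determinism", {
  p <- synaptic_gen_params(rate_hz = 2, duration_ms = 60e3)
  counts <- vapply(1:40, function(s)
    nrow(generate_mepsc_recording(p, seed = s)$events), 0)
  expect_lt(abs(mean(counts) - 120), 3 * sqrt(120 / 40) + 3)
  g1 <- generate_mepsc_recording(p, seed = 5)
  g2 <- generate_mepsc_recording(p, seed = 5)
  expect_identical(g1$recording$current, g2$recording$current)
  expect_identical(g1$events, g2$events)
  # zero rate: flat noise, empty truth
  g0 <- generate_mepsc_recording(
    synaptic_gen_params(rate_hz = 0, duration_ms = 5e3), seed = 1)
  expect_identical(nrow(g0$events), 0L)
  expect_lt(max(abs(g0$recording$current)), 6 * 4)
  expect_error(synaptic_gen_params(rate_hz = -1, duration_ms = 1000),
               "rate")
  expect_error(synaptic_gen_params(rate_hz = 1, duration_ms = -5),
               "duration")
})

test_that("evoked pair superposition matches the analytic form", {
  # amp1 100 pA, tau 12.5 ms, interval 50 ms, true PPR 1.5:
  # raw second-peak excursion = 150 + 100 exp(-4)
  pair <- generate_eepsc_pair(100, 1.5, 50, decay_tau = 12.5, dt = 0.1)
  sw <- get_sweep(pair, 1)
  t <- trace_time(sw)
  st <- pair$meta$stim_times
  expect_equal(min(sw$current[t >= st[1] & t < st[2]]), -100)
  expect_equal(min(sw$current[t >= st[2]]), -(150 + 100 * exp(-4)),
               tolerance = 1e-10)
  # true_ppr = 1, no noise: identical underlying peaks
  p1 <- generate_eepsc_pair(80, 1, 200, decay_tau = 5)
  sw1 <- get_sweep(p1, 1)
  expect_equal(min(sw1$current[trace_time(sw1) < 250]),
               min(sw1$current[trace_time(sw1) >= 250]), tolerance = 1e-6)
  expect_error(generate_eepsc_pair(100, 1.5, -2), "interval")
  expect_error(generate_eepsc_pair(-1, 1.5, 50), "amp1")
})
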