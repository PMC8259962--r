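# shared fixtures built in code

# simple two-state R = O scheme with known closed-form relaxation
two_state_scheme <- function(kon = 0.3, koff = 0.5) {
  kinetic_scheme(
    states = c("R", "O"), conducting = c(FALSE, TRUE), resting = "R",
    rates = data.frame(from = c("R", "O"), to = c("O", "R"),
                       rate = c(kon, koff), ligand_dep = c(TRUE, FALSE),
                       row.names = c("kon", "koff")))
}

# noiseless multi-exponential decay sweep (positive-going magnitudes
# flipped to inward-negative), starting at its peak
exp_decay_sweep <- function(amps, taus, dt = 0.05, t_max = 60, offset = 0,
                            noise_sd = 0, sign = -1) {
  t <- seq(0, t_max, by = dt)
  y <- rowSums(vapply(seq_along(amps),
                      function(i) amps[i] * exp(-t / taus[i]),
                      numeric(length(t)))) + offset
  if (noise_sd > 0) y <- y + rnorm(length(y), 0, noise_sd)
  ep_sweep(sign * y, dt, onset = 0)
}

# standard NSFA-style simulated ensemble; the recovery checks use the
# 500 ms protocol of the slowly-desensitizing phenotype, whose response
# sweeps the widest open-probability range (most informative curve)
nsfa_ensemble <- function(seed, n_sweeps = 200, n_channels = 64,
                          gamma = 16.8, noise_sd = 1, preset = "gof",
                          protocol = "desensitization") {
  ens <- simulate_ensemble(build_scheme(preset),
                           make_stimulus(protocol),
                           channel_params(n_channels, gamma),
                           noise_model(noise_sd), n_sweeps, seed)
  baseline_correct(ens, c(1, 19))
}
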