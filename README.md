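# amparkinetics

Quantitative electrophysiology of fast ligand-gated ion channels in R:
the complete analysis chain used to classify an AMPA-receptor variant as
gain-of-function, together with a stochastic simulator that makes every
stage checkable by parameter recovery.

## Who this is for

Patch-clamp labs (and their analysts) measuring AMPA-receptor-style
currents: outside-out patch responses to fast glutamate application,
current–voltage families, and miniature or evoked synaptic currents.
Raw recordings from such studies are rarely deposited, so the package
pairs every analysis with a generator whose ground truth is known —
if an analysis cannot recover the parameters of data it fully
understands, its output on real data is not trustworthy.

## What it computes

* **Decay kinetics** — multi-exponential fits of deactivation (1 ms
  pulse), desensitization (500 ms pulse) and EPSC decays via
  `fit_decay()`, reporting the amplitude-weighted time constant
  `tau_w = sum(a_i tau_i) / sum(a_i)`, plus the steady-state
  (non-desensitizing) current as a percentage of peak.
* **Non-stationary fluctuation analysis** — `variance_mean()` +
  `fit_nsfa()` invert the across-sweep variance–mean parabola
  `sigma^2 = i I − I^2/N + sigma0^2` to unitary current *i*, channel
  count *N*, conductance `gamma = i/(Vh − Vr)` (Vr assumed 0 mV) and
  peak open probability `Popen = I_peak/(iN)`.
* **I–V and rectification** — `build_iv()` normalizes peak currents by
  |I(−100 mV)|; `rectification_index()` is |I(+60)|/|I(−60)|.
* **Synaptic currents** — `detect_events()` (validated against
  generator ground truth by `score_detection()`), `average_events()`,
  `epsc_decay_tau()`, `charge_transfer()`, `paired_pulse_ratio()` with
  superposition correction, `nmdar_amplitude()`.
* **Group statistics** — `compare_groups()` (classical t tests) and
  `anova_oneway()`, reporting mean ± SEM.
* **Simulation** — a four-state Markov gating scheme (`build_scheme()`
  with calibrated `"wt"` and `"gof"` presets), a deterministic
  master-equation oracle (`mean_occupancy()`), stochastic sweep
  ensembles (`simulate_ensemble()`), and synaptic-recording generators
  (`generate_mepsc_recording()`, `generate_eepsc_pair()`), all pure
  functions of (parameters, seed).
* **Orchestration** — `run_config()` + `run_protocol()` run the whole
  simulate → analyze → report cycle deterministically; a thin CLI
  (`inst/cli/ampar-kinetics`) wraps the same functions for shell use.

The methods vignette (`vignettes/amparkinetics-methods.Rmd`) documents
the gating model, the estimator design decisions and their rationale,
and known limitations.

## Worked example

Simulate a gain-of-function-like patch, measure its desensitization and
run fluctuation analysis:

```r
library(amparkinetics)

sch  <- build_scheme("gof")
stim <- make_stimulus("desensitization")        # 500 ms of 10 mM glutamate
ens  <- simulate_ensemble(sch, stim, channel_params(64, gamma = 16.8),
                          noise_model(baseline_sd = 1),
                          n_sweeps = 200, seed = 7)
ens  <- baseline_correct(ens, c(1, 19))
avg  <- average_sweeps(ens)

fit_decay(decimate_sweep(avg, 5), end = 520, max_components = 3)
#> Exponential decay fit: 1 component(s), weighted tau = 13.02 ms
#>   a1 = -30.91 pA, tau1 = 13.02 ms
#>   offset -11.8 pA, window 21.80-520.00 ms, residual sd 0.257 pA
steady_state_fraction(avg)
#> [1] 28.0977

fit_nsfa(variance_mean(ens, n_bins = 10))
#> Non-stationary fluctuation analysis
#>   i = 1.175 pA   N = 64.6   sigma0^2 = 0.9997 pA^2 (fixed)
#>   gamma = 16.79 pS (Vh = -70 mV, Vr = 0 mV)   peak Popen = 0.5576
```

Read: the simulated mutant-like patch desensitizes with a weighted tau
of ~13 ms to a sustained plateau of ~28% of peak (the offset term is
the plateau current), and the fluctuation analysis recovers the
generating single-channel parameters — 1.176 pA unitary current through
64 channels of 16.8 pS at −70 mV — within a few percent, with peak open
probability ~0.56. A `"wt"` patch analyzed identically gives tau_w near
4.7 ms and a steady state below 1%, the fingerprint the package's
reports contrast.

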