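---
title: "Models and methods behind amparkinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind amparkinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(amparkinetics)
```

amparkinetics analyzes fast ligand-gated ion-channel currents — AMPA-type
glutamate receptor responses to rapid agonist application, and the
synaptic currents those receptors carry — and ships a stochastic
simulator that generates such data with known ground truth. The package
exists for a practical reason: the quantitative readouts that
distinguish a wild-type receptor from a gain-of-function variant
(slowed deactivation and desensitization, a non-desensitizing
steady-state current, unchanged single-channel conductance and open
probability, slowed synaptic decays) are all *derived* quantities, and
each derivation has failure modes that are invisible without data whose
true parameters are known. Every analysis stage here can therefore be
validated by parameter recovery against the generator.

Units are fixed everywhere: time in ms, current in pA, voltage in mV,
conductance in pS, concentration in mM. Inward current is negative;
analysis functions work on magnitudes after baseline subtraction and
restore the sign only in reports.

## The gating model

The generative model is a four-state kinetic scheme

    R  <-kon*c / koff->  B  <-beta / alpha->  O  <-kdes / kres->  D

with resting (R), agonist-bound closed (B), open (O) and desensitized
(D) states; only O conducts, and binding R→B scales with the agonist
concentration c. This is the smallest scheme that gives three
separately tunable phenomena: deactivation (decay after agonist
removal, set mainly by `alpha`, `koff`, `beta`), desensitization during
sustained agonist (set by the slow O⇄D exchange), and a non-zero
steady-state current (set by the `kdes`/`kres` balance). It is a
deliberately phenomenological stand-in — real AMPA receptors have
multiple bound and desensitized states — but it is sufficient to
produce every readout the analysis modules measure, which is all a
ground-truth generator must do.

Two presets ship with the package. The `"wt"` preset emulates a fast,
almost completely desensitizing wild-type-like receptor (weighted
desensitization constant near 4.7 ms, steady state below ~1% of peak,
deactivation below 1 ms). The `"gof"` preset emulates a
gain-of-function phenotype: roughly three-fold slower desensitization
(~13 ms), a sustained current near 28% of peak, and slowed
deactivation, with peak open probability 0.43 (wt) and 0.56 (gof). The
rate
constants were calibrated by Nelder-Mead against the deterministic
model's own responses, measured with the same `fit_decay()` and
`steady_state_fraction()` the package applies to data; starting points
came from the detailed-balance algebra of the chain (the scheme has no
cycles, so state ratios at saturating agonist follow directly from rate
ratios). The calibration script is shipped in
`inst/scripts/calibrate-presets.R` and the frozen constants in
`scheme_presets`. Because both integration engines step on the sample
grid with the precondition `max total exit rate x dt < 0.1`, the
calibration constrained every state's total exit rate at 10 mM below
10 ms^-1 (dt = 0.01 ms, i.e. 100 kHz).

```{r scheme}
build_scheme("gof")
```

## Stimuli and integration engines

`make_stimulus()` builds the standard fast-perfusion protocols: 1 ms
and 500 ms pulses of 10 mM agonist (deactivation and desensitization)
and a 200 ms pulse for voltage families, each with a 20 ms pre-pulse
baseline. Pulse edges pass through a first-order solution-exchange
filter; its time constant defaults to 0.1 ms (10–90% exchange
~0.22 ms), a typical figure for piezo-driven theta-glass application
onto excised patches — the package's choice, since exchange speed is
rig-specific. Concentrations below 1 nM are snapped to zero; the
recursive filter otherwise decays through subnormals forever, which is
physically meaningless and multiplies the number of distinct generator
matrices.

`mean_occupancy()` integrates the master equation dp/dt = p Q(c(t))
treating c as constant over each sample: within such an interval the
propagator is the exact matrix exponential, computed spectrally
(eigendecomposition, with `Matrix::expm` as fallback for
ill-conditioned cases), and long constant-concentration runs are
evaluated in one vectorized step. The integration is therefore exact
for piecewise-constant agonist; the only discretization is the sampling
of c(t) itself. Against the two-state closed form the error is at
machine precision.

`simulate_ensemble()` is the stochastic counterpart: per sweep,
`n_channels` independent channels step on the same grid as a
discrete-time Markov chain whose one-step transition probabilities are
the rows of the same exact propagator `expm(Q dt)` the oracle uses
(aggregated as binomial draws per state, which is
distribution-identical to per-channel simulation for exchangeable
channels and vastly faster). Using the exact kernel rather than the
common first-order approximation `1 - exp(-K dt)` with proportional
route splitting matters: the approximation ignores multi-hop
transitions within a step and biases the pooled open fraction by up to
~`K dt/2` (1.5–2.5% here) during the fast binding rise, whereas the
exact kernel leaves only Monte-Carlo noise. The chain remains
fixed-step and grid-aligned — an event-driven (Gillespie) engine is
deliberately out of scope since samples must land on the trace grid
anyway — and the `K dt < 0.1` stiffness guard is still enforced so
that the per-step kernels stay well conditioned. Current is
`n_open * gamma * (Vh - Vr) / 1000` plus Gaussian baseline noise;
optional multiplicative per-sweep rundown exercises the robust
fluctuation-analysis path. Everything is a pure function of
(parameters, seed).

```{r engines}
sch <- build_scheme("gof")
stim <- make_stimulus("desensitization")
oracle <- mean_occupancy(sch, stim)
ens <- simulate_ensemble(sch, stim, channel_params(64, gamma = 16.8),
                         noise_model(baseline_sd = 1), n_sweeps = 40,
                         seed = 1)
plot(ens, n_show = 10, main = "gof preset, 500 ms pulse")
lines(oracle$time, 64 * ens$meta$unit_current * oracle$open,
      col = 2, lwd = 2)
```

## Decay fitting

`fit_decay()` fits `sum(a_i exp(-(t - t0)/tau_i)) + offset` from the
peak sample (the convention for fast-application currents; a
percent-of-peak start is available) by Levenberg–Marquardt with
amplitudes bounded non-negative and time constants bounded in
[1e-3, 1e4] ms. Initial time constants are log-spaced over 0.2–100 ms
and the whole fit restarts five times with the grid rescaled (1/9x to
9x); given candidate time constants, starting amplitudes come from a
linear solve, so each restart begins at the best least-squares point of
its basin. Component counts 1..3 are tried in order and k+1 replaces k
only if it cuts the residual sum of squares by more than 5% — the
number of exponentials behind a "weighted tau" is rarely identifiable
more finely than that, and the amplitude-weighted
`sum(a tau)/sum(a)` is deliberately the headline readout because it is
stable under component splitting. On noiseless sums of up to three
separated exponentials the generating parameters are recovered to
better than 0.1%; under 2 pA of noise the weighted tau of the standard
70/30 bi-exponential (true 4.4 ms) stays within 5% in median.

`steady_state_fraction()` reports the mean current over the last 50 ms
of a long pulse (window configurable; the choice of 50 ms is the
package's, made once) as a percentage of peak.

## Non-stationary fluctuation analysis

With independent identical channels the across-sweep variance at each
time obeys `sigma^2 = i I - I^2/N + sigma0^2`; inverting that parabola
yields the unitary current i, the channel count N, and from them the
unitary conductance `gamma = i/(Vh - Vr)` (reversal assumed 0 mV) and
the peak open probability `Popen = I_peak/(i N)`.

`variance_mean()` builds the curve from the decay phase (peak down to
5% of peak) with the plain ensemble estimator by default; a
successive-difference estimator (half the mean squared difference of
consecutive sweeps) is offered for recordings with slow rundown. Three
estimator details were driven by simulation studies during development,
because the naive construction is measurably biased:

* **Binning key.** Samples are binned into 10 equal-count bins by a
  1 ms-smoothed copy of the mean current, not the raw mean. Binning by
  the raw mean selects on the same noise that enters the variance
  estimates; since a binomial's sample mean and variance are
  correlated, that selection tilts the curve wherever the true mean is
  flat (plateaus), biasing i up and N down.
* **Two bin moments.** A bin spanning a range of mean currents sits
  *below* the parabola drawn through its mean (Jensen's inequality), so
  wide bins masquerade as extra curvature and N comes out ~20–30% low
  on slowly decaying responses. Expectation is linear, so the fit in
  `fit_nsfa()` regresses the bin variance on both `mean(|I|)` and
  `mean(I^2)` (the latter debiased for sampling noise), which is exact
  for arbitrarily wide bins.
* **Effective sample size.** Channel gating correlates neighbouring
  samples over ~1/(sum of rates) — far beyond 0.01 ms — so bin weights
  estimate the variance-of-the-variance with an effective sample size
  from the lag-1 autocorrelation of the per-time variances, rather than
  the raw sample count.

On noiseless analytic parabola points the inversion is exact to
machine precision. On simulated ensembles, precision depends on how
much of the open-probability range the response visits and for how
long: a 1 ms pulse of the fast phenotype contains only a handful of
independent decay epochs, and no estimator can pin N from it to better
than ~20% with 200 sweeps. The recovery validation therefore uses
500 ms responses of the slow phenotype (Popen swept from ~0.55 to the
~15% plateau across many independent epochs), where 200 sweeps recover
i and gamma within ±10% and N within ±15% in nearly every seed. The
reporting pipeline still analyzes 1 ms-pulse ensembles — the
conventional protocol — and its per-patch gamma scatter of 10–20%
mirrors what patch-to-patch scatter looks like in practice.

Whether the background variance is fixed from the pre-stimulus baseline
or fitted as an intercept is unspecified in common practice; both modes
exist (`fix_background`), with the fixed mode the default.

```{r nsfa}
ens <- baseline_correct(ens, c(1, 19))
fit <- fit_nsfa(variance_mean(ens, n_bins = 10))
plot(fit, main = "variance-mean parabola")
fit
```

(With only 40 sweeps this example is noisy by design — `variance_mean()`
warns below 100 sweeps.)

## Current–voltage analysis

`build_iv()` measures the signed peak of each per-voltage average sweep
inside the application window and normalizes by |I(-100 mV)|, so the
reference point is -1 for inward reference currents.
`rectification_index()` is defined in this package as
`|I(+60)|/|I(-60)|`, linearly interpolated if those voltages were not
sampled: the ratio at symmetric voltages is the least-assumptive
quantification of I-V asymmetry, equals 1 exactly for any
odd-symmetric curve, and is scale invariant. The simulator's channels
are ohmic (conductance independent of voltage), so simulated families
give linear I-V curves with RI = 1; genuinely rectifying curves (e.g.
polyamine block of homomeric receptors) are analyzed when supplied but
are not generated — rectification biophysics is out of scope.

## Synaptic currents

`generate_mepsc_recording()` lays homogeneous-Poisson event onsets on a
noisy baseline; each event is a peak-normalized bi-exponential kernel
scaled by a truncated-Gaussian amplitude, and the ground-truth event
list is returned with the recording. Defaults (20 +/- 5 pA amplitudes,
0.3 ms rise, ~2 ms decay, 4 pA noise at 10 kHz, -70 mV) emulate
miniature EPSCs in small neurons. What the generator does *not*
emulate: overlapping multi-quantal bursts beyond Poisson coincidence,
slow baseline wander, series-resistance filtering, or amplitude
rundown — so a detector that scores well here is validated for
threshold logic and timing, not for every pathology of real recordings.

`detect_events()` thresholds a 1 kHz low-pass copy at `threshold_sd`
(default 4) times the robust noise SD (median absolute deviation, which
sparse events barely perturb). Two guards make the 4-SD default usable:
excursions must stay above threshold for at least 0.5 ms — a
band-limited Gaussian process crosses 4 SD far too often (Rice rate
~0.2/s at 1 kHz bandwidth) but almost never stays there longer than
its ~0.23 ms correlation time — and peaks closer than 5 ms are merged,
keeping the larger. Onsets are refined to the last baseline crossing
before the peak. A matched-filter mode (mean-subtracted template
correlation) accepts an event template. At the validation condition
(SNR 5, 1 Hz, 120 s) precision and recall both exceed 0.9 in every
tested seed; `score_detection()` implements the greedy one-to-one
time-ordered matching behind those numbers, reporting precision 1 with
a flag when there are no detections (and recall 1 when the truth is
empty).

`average_events()` aligns on peaks (or onsets), excludes events whose
windows overlap another event rather than deconvolving them (the count
is reported), subtracts per-event baselines and averages;
`epsc_decay_tau()` then delegates to `fit_decay()` without an offset
term, since synaptic currents decay to baseline.

`paired_pulse_ratio()` measures peak2/peak1 of a two-pulse response.
At intervals comparable to the decay constant the second peak rides on
the first response's tail; with `correction = "decay_subtraction"` the
first decay is fitted over the inter-pulse window, extrapolated under
the second response and subtracted, which recovers the true ratio
within 1% for intervals >= 2 decay constants (the uncorrected bias is
the analytic residual `exp(-interval/tau)`). `charge_transfer()` is
the trapezoidal integral of |I|, and `nmdar_amplitude()` reads the
late (NMDAR) component as the mean current in a 5 ms window 150 ms
after stimulation at +40 mV, where the fast AMPAR component has fully
decayed.

```{r ppr}
pair <- generate_eepsc_pair(amp1 = 100, true_ppr = 1.5, interval = 50,
                            decay_tau = 12.5)
sw <- get_sweep(pair, 1)
paired_pulse_ratio(sw, correction = "decay_subtraction")
paired_pulse_ratio(sw, correction = "none")
```

## Group comparisons

`compare_groups()` (pooled-variance unpaired or paired two-sided t,
Welch available but off by default) and `anova_oneway()` (classical
one-way F) mirror the comparison layer conventional for this kind of
study, reporting mean +/- SEM per group. No multiple-testing correction
is applied anywhere, and no post-hoc procedure is claimed beyond the
omnibus F plus optional pairwise t. Degenerate ANOVA inputs are handled
explicitly: identical groups give F = 0, p = 1; zero within-group
variance with differing means gives an infinite F with a flag (the
standard `aov` route returns NaN for both).

## The orchestration layer

`run_config()` + `run_protocol()` drive the full simulate → analyze →
report cycle: per preset, replicate deactivation/desensitization
ensembles with decay fits and steady-state fractions (fitted on a
20 kHz-decimated grid — the decays of interest are slower than 2 ms, so
the full 100 kHz grid adds cost but no information), 200-sweep
fluctuation-analysis ensembles under both the 1 ms and the 500 ms
protocol (the latter is the validated high-information condition; both
are reported, labeled by protocol), an 11-voltage I-V family with
rectification index, mEPSC recordings with detection scored against
ground truth, and evoked paired-pulse responses with charge transfer.
Default problem sizes (4 cells x 30 sweeps for kinetics, 200 sweeps for
NSFA, 5 sweeps x 11 voltages, 60 s of mEPSCs) are chosen as realistic
single-study sizes that keep a full two-preset run in the low minutes
on one core. Between-preset unpaired t tests are reported for the
per-cell kinetics readouts. Every stochastic stage derives its own seed
from the single configuration seed, so a configuration determines the
report byte-for-byte; the run log records the package version, a
configuration hash and one line per stage. A thin command-line wrapper
(`inst/cli/ampar-kinetics`) exposes `simulate`, `kinetics`, `nsfa`,
`iv`, `mepsc`, `eepsc`, `compare` and `run` subcommands over the same
functions, with ensembles and recordings exchanged as tab-separated
text plus a JSON metadata sidecar.

## Numerical choices and known limitations

* Stiffness guard: both engines refuse `max exit rate x dt >= 0.1`
  rather than silently losing transitions.
* The exponential fitter flags time constants that land on the search
  bounds, and refuses decay windows of fewer than 10 samples.
* The parabola fit flags non-concave solutions (i <= 0 or N <= 0) and a
  peak open probability outside [0, 1] instead of returning them as
  estimates.
* Recovery-from-desensitization (two-pulse agonist) protocols, TARP or
  cornichon auxiliary-subunit kinetics (representable only as
  alternative rate presets), polyamine rectification mechanics,
  stationary noise analysis and single-channel idealization are out of
  scope.
* Absolute mEPSC frequencies and amplitudes depend on detector settings
  that differ between laboratories; within-package contrasts (wild-type
  vs gain-of-function kernels) are the meaningful outputs.
* The text + JSON trace dialect is the only storage format; vendor
  formats (ABF, NWB) are intentionally not parsed.
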