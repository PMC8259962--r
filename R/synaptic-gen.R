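# Generators for synaptic recordings: Poisson trains of miniature EPSCs
# on a noisy baseline, and two-pulse evoked responses with a known
# paired-pulse ratio.

# Bi-exponential synaptic conductance kernel, peak-normalized to 1.
# rise_tau = 0 gives an instantaneous-rise single/multi-exponential decay.
epsc_kernel <- function(dt, rise_tau, decay_tau, decay_amp = NULL,
                        length_ms = NULL) {
  if (any(decay_tau <= 0)) stop("decay tau values must be > 0")
  if (rise_tau < 0) stop("rise tau must be >= 0")
  if (is.null(decay_amp)) decay_amp <- rep(1, length(decay_tau))
  if (length(decay_amp) != length(decay_tau) || any(decay_amp <= 0))
    stop("decay_amp must be positive weights matching decay_tau")
  if (is.null(length_ms)) length_ms <- 8 * max(decay_tau) + 5 * max(rise_tau, dt)
  t <- seq(0, length_ms, by = dt)
  dec <- rowSums(vapply(seq_along(decay_tau),
                        function(i) decay_amp[i] * exp(-t / decay_tau[i]),
                        numeric(length(t))))
  k <- if (rise_tau > 0) dec * (1 - exp(-t / rise_tau)) else dec
  k / max(k)
}

#' Parameters of a synthetic miniature-EPSC recording
#'
#' @param rate_hz Event rate in Hz (>= 0, homogeneous Poisson).
#' @param duration_ms Recording duration in ms (> 0).
#' @param amp_mean,amp_sd Mean and sd (pA) of the truncated-Gaussian
#'   (> 0) event peak-amplitude distribution.
#' @param rise_tau Kernel rise time constant in ms (> 0).
#' @param decay_tau Kernel decay time constant(s) in ms (> 0).
#' @param decay_amp Relative weights of the decay components.
#' @param noise_sd Baseline Gaussian noise sd in pA.
#' @param dt Sample interval in ms (default 0.1, i.e. 10 kHz).
#' @param vh Holding potential annotation in mV (default -70; events are
#'   inward, i.e. negative-going).
#' @return Object of class `synaptic_gen_params`.
#' @export
synaptic_gen_params <- function(rate_hz, duration_ms, amp_mean = 20,
                                amp_sd = 5, rise_tau = 0.3, decay_tau = 1.9,
                                decay_amp = NULL, noise_sd = 4, dt = 0.1,
                                vh = -70) {
  if (rate_hz < 0) stop("event rate must be >= 0")
  if (duration_ms <= 0) stop("duration must be > 0")
  if (amp_mean <= 0 || amp_sd < 0) stop("amplitude distribution invalid")
  if (rise_tau <= 0) stop("rise tau must be > 0")
  if (any(decay_tau <= 0)) stop("decay tau values must be > 0")
  if (noise_sd < 0 || dt <= 0) stop("noise_sd >= 0 and dt > 0 required")
  structure(as.list(environment()), class = "synaptic_gen_params")
}

#' Ground-truth or detected synaptic event list
#'
#' @param onset Event onset times in ms (strictly increasing).
#' @param peak_time Event peak times in ms.
#' @param amplitude Event peak amplitudes in pA (magnitudes, > 0).
#' @param provenance `"ground truth"` or a description of the detector.
#' @return A data frame of class `event_list`.
#' @export
event_list <- function(onset, peak_time = onset, amplitude,
                       provenance = "ground truth") {
  if (length(onset) && is.unsorted(onset, strictly = TRUE))
    stop("event times must be strictly increasing")
  if (any(amplitude <= 0)) stop("event amplitudes are magnitudes, > 0")
  structure(data.frame(onset = as.numeric(onset),
                       peak_time = as.numeric(peak_time),
                       amplitude = as.numeric(amplitude)),
            provenance = provenance,
            class = c("event_list", "data.frame"))
}

# truncated-at-zero Gaussian draws
rtruncnorm_pos <- function(n, mean, sd) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x <= 0)) x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}

#' Generate a gap-free recording containing miniature EPSCs
#'
#' Event onsets follow a homogeneous Poisson process; each event adds a
#' peak-normalized bi-exponential kernel scaled by a truncated-Gaussian
#' amplitude (inward, negative-going).  The ground-truth event list is
#' returned alongside the recording, so detector performance can be
#' scored exactly.
#'
#' @param params A [synaptic_gen_params()].
#' @param seed Integer seed (required).
#' @return List with elements `recording` (an [ep_recording()]) and
#'   `events` (ground-truth [event_list()]).
#' @examples
#' g <- generate_mepsc_recording(
#'   synaptic_gen_params(rate_hz = 1, duration_ms = 10e3), seed = 1)
#' nrow(g$events)
#' @export
generate_mepsc_recording <- function(params, seed) {
  stopifnot(inherits(params, "synaptic_gen_params"))
  if (missing(seed) || is.null(seed)) stop("seed must be supplied")
  set.seed(as.integer(seed))
  p <- params
  n <- round(p$duration_ms / p$dt) + 1
  x <- if (p$noise_sd > 0) stats::rnorm(n, 0, p$noise_sd) else numeric(n)
  kern <- epsc_kernel(p$dt, p$rise_tau, p$decay_tau, p$decay_amp)
  tpeak_off <- (which.max(kern) - 1) * p$dt
  n_ev <- stats::rpois(1, p$rate_hz * p$duration_ms / 1000)
  if (n_ev > 0) {
    onsets <- sort(stats::runif(n_ev, 0, p$duration_ms - 1))
    # keep onsets distinct on the sample grid
    oi <- round(onsets / p$dt) + 1
    dup <- duplicated(oi)
    onsets <- (oi[!dup] - 1) * p$dt
    oi <- oi[!dup]
    amps <- rtruncnorm_pos(length(oi), p$amp_mean, p$amp_sd)
    for (e in seq_along(oi)) {
      idx <- oi[e]:min(n, oi[e] + length(kern) - 1)
      x[idx] <- x[idx] - amps[e] * kern[seq_along(idx)]
    }
    ev <- event_list(onset = onsets, peak_time = onsets + tpeak_off,
                     amplitude = amps)
  } else {
    ev <- event_list(numeric(0), numeric(0), numeric(0))
  }
  list(recording = ep_recording(x, p$dt, vh = p$vh, protocol = "mepsc",
                                seed = as.integer(seed)),
       events = ev)
}

#' Generate a two-pulse evoked-EPSC sweep ensemble
#'
#' Two kernel-shaped inward responses at `t1` and `t1 + interval` whose
#' underlying peak amplitudes are `amp1` and `amp1 * true_ppr`; the second
#' response superimposes on the decaying tail of the first, as in a real
#' paired-pulse experiment.  With `rise_tau = 0` (the default) each
#' response is an instantaneous-rise exponential decay, making the
#' superposition analytically tractable.
#'
#' @param amp1 First-response peak amplitude in pA (> 0).
#' @param true_ppr True paired-pulse ratio (> 0).
#' @param interval Inter-pulse interval in ms (> 0).
#' @param decay_tau,rise_tau Kernel time constants in ms.
#' @param t1 Time of the first stimulus in ms (default 50).
#' @param tail_ms Trace duration after the second response, ms.
#' @param noise_sd Gaussian noise sd in pA.
#' @param n_sweeps Number of sweeps.
#' @param dt Sample interval in ms (default 0.1).
#' @param seed Integer seed (required when `noise_sd > 0`).
#' @return A [trace_ensemble()]; `meta$stim_times` records both stimulus
#'   times and `meta$true_ppr` the generating ratio.
#' @export
generate_eepsc_pair <- function(amp1, true_ppr, interval, decay_tau = 12.5,
                                rise_tau = 0, t1 = 50, tail_ms = NULL,
                                noise_sd = 0, n_sweeps = 1, dt = 0.1,
                                seed = NULL) {
  if (amp1 <= 0) stop("amp1 must be > 0")
  if (interval <= 0) stop("interval must be > 0")
  if (true_ppr <= 0) stop("true_ppr must be > 0")
  if (noise_sd > 0 && is.null(seed)) stop("seed must be supplied for noisy sweeps")
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (is.null(tail_ms)) tail_ms <- 10 * max(decay_tau)
  kern <- epsc_kernel(dt, rise_tau, decay_tau)
  n <- round((t1 + interval + tail_ms) / dt) + 1
  base <- numeric(n)
  add_at <- function(x, t0, amp) {
    i0 <- round(t0 / dt) + 1
    idx <- i0:min(n, i0 + length(kern) - 1)
    x[idx] <- x[idx] - amp * kern[seq_along(idx)]
    x
  }
  base <- add_at(base, t1, amp1)
  base <- add_at(base, t1 + interval, amp1 * true_ppr)
  cur <- matrix(rep(base, n_sweeps), ncol = n_sweeps)
  if (noise_sd > 0)
    cur <- cur + matrix(stats::rnorm(n * n_sweeps, 0, noise_sd), n, n_sweeps)
  trace_ensemble(cur, dt, meta = list(
    protocol = "eepsc_pair", vh = -70, vr = 0,
    stim_times = c(t1, t1 + interval), onset = t1,
    true_ppr = true_ppr, amp1 = amp1, decay_tau = decay_tau,
    rise_tau = rise_tau, noise_sd = noise_sd,
    seed = if (is.null(seed)) NA_integer_ else as.integer(seed)))
}
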