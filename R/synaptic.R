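# Synaptic-current analysis: mEPSC detection and averaging, EPSC decay,
# charge transfer, paired-pulse ratio and late NMDAR-component readout.

#' Detect synaptic events in a gap-free recording
#'
#' Threshold detector on a low-pass-filtered copy of the recording:
#' inward (negative-going) deflections crossing `threshold_sd` times the
#' robust noise SD, sustained for at least `min_width` ms (rejecting
#' noise excursions shorter than the filter correlation time), separated
#' by at least `min_interval` ms.  Event onsets are refined to the last
#' baseline crossing before the peak.  When a `template` kernel is
#' supplied, detection runs on the matched-filter (sliding
#' mean-subtracted template correlation) output with the same threshold
#' logic.
#'
#' The noise SD is the median absolute deviation of the detection trace,
#' which is insensitive to sparse events (duty cycle of a few percent).
#'
#' @param rec An [ep_recording()] (>= 1 s).
#' @param threshold_sd Detection threshold as a multiple of the noise SD
#'   (> 0, default 4).
#' @param min_interval Minimum separation between event peaks in ms
#'   (default 5); the larger-amplitude event of a closer pair is kept.
#' @param template Optional event kernel (numeric vector, same dt as the
#'   recording) for matched-filter detection.
#' @param lowpass_hz Low-pass corner for the detection copy (default
#'   1000 Hz).
#' @param min_width Minimum time above threshold in ms (default 0.5).
#' @return An [event_list()] (onset, peak time, amplitude in pA measured
#'   on the filtered trace) with detector parameters in the
#'   `"provenance"` attribute.
#' @export
detect_events <- function(rec, threshold_sd = 4, min_interval = 5,
                          template = NULL, lowpass_hz = 1000,
                          min_width = 0.5) {
  stopifnot(inherits(rec, "ep_recording"))
  if (threshold_sd <= 0) stop("threshold must be > 0")
  dt <- rec$dt
  fs <- 1000 / dt                       # Hz
  x <- rec$current - stats::median(rec$current)
  if (is.null(template)) {
    bf <- signal::butter(2, min(lowpass_hz / (fs / 2), 0.99))
    det <- -as.numeric(signal::filtfilt(bf, x))   # inward events positive
    scale_amp <- 1
  } else {
    # sliding correlation with the mean-subtracted template; positive at
    # alignment whatever the template's sign, in units of template scale
    w <- template - mean(template)
    det <- as.numeric(stats::filter(c(x, numeric(length(w) - 1)), rev(w),
                                    method = "convolution", sides = 1))
    det <- det[length(w):(length(w) + length(x) - 1)] / sum(w^2)
    scale_amp <- max(abs(template))
  }
  sdn <- stats::mad(det)
  if (sdn == 0) stop("cannot estimate noise SD (zero spread)")
  thr <- threshold_sd * sdn

  above <- det > thr
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & r$lengths >= max(1, round(min_width / dt))
  if (!any(keep)) {
    out <- event_list(numeric(0), numeric(0), numeric(0),
                      provenance = "detector")
    attr(out, "noise_sd") <- sdn
    return(out)
  }
  starts <- starts[keep]; ends <- ends[keep]
  pk_idx <- mapply(function(s, e) s - 1 + which.max(det[s:e]), starts, ends)
  pk_amp <- det[pk_idx]

  # enforce minimum inter-event interval, keeping the larger event
  o <- order(pk_idx)
  pk_idx <- pk_idx[o]; pk_amp <- pk_amp[o]
  keep <- rep(TRUE, length(pk_idx))
  last <- 1
  for (k in seq_along(pk_idx)[-1]) {
    if ((pk_idx[k] - pk_idx[last]) * dt < min_interval) {
      if (pk_amp[k] > pk_amp[last]) { keep[last] <- FALSE; last <- k }
      else keep[k] <- FALSE
    } else last <- k
  }
  pk_idx <- pk_idx[keep]; pk_amp <- pk_amp[keep]

  # onset: last baseline (zero) crossing of the detection trace before peak
  onset_idx <- vapply(pk_idx, function(i) {
    j <- i
    lim <- max(1, i - round(20 / dt))
    while (j > lim && det[j] > 0) j <- j - 1
    j
  }, 0)
  # close event pairs can walk back to the same baseline crossing; keep
  # onsets strictly ordered and after the preceding peak
  if (length(onset_idx) > 1) {
    for (k in 2:length(onset_idx)) {
      onset_idx[k] <- max(onset_idx[k], pk_idx[k - 1] + 1,
                          onset_idx[k - 1] + 1)
    }
  }
  t <- trace_time(rec)
  # in template mode the correlation peaks at the window-start alignment
  # (the event onset); shift reported peaks by the template's own peak lag
  pk_lag <- if (is.null(template)) 0
            else (which.max(abs(template)) - 1) * dt
  out <- event_list(onset = t[onset_idx], peak_time = t[pk_idx] + pk_lag,
                    amplitude = pk_amp * scale_amp, provenance = "detector")
  attr(out, "noise_sd") <- sdn
  attr(out, "detector") <- list(threshold_sd = threshold_sd,
                                min_interval = min_interval,
                                lowpass_hz = lowpass_hz,
                                min_width = min_width,
                                template = !is.null(template))
  out
}

#' Score detected events against ground truth
#'
#' Greedy one-to-one matching by increasing time: a detected and a true
#' event match if their peak times differ by at most `tolerance` ms.
#' Precision with no detections (and recall with empty truth) are
#' reported as 1 by convention, with a flag.
#'
#' @param detected,truth [event_list()] objects (sorted by time).
#' @param tolerance Matching tolerance in ms (>= 0, default 2).
#' @return Object of class `detection_score`: counts of true positives,
#'   false positives and false negatives, precision, recall, tolerance
#'   and flags.
#' @export
score_detection <- function(detected, truth, tolerance = 2) {
  if (tolerance < 0) stop("tolerance must be >= 0")
  td <- detected$peak_time
  tt <- truth$peak_time
  i <- 1L; j <- 1L; tp <- 0L
  while (i <= length(td) && j <= length(tt)) {
    d <- td[i] - tt[j]
    if (abs(d) <= tolerance) { tp <- tp + 1L; i <- i + 1L; j <- j + 1L }
    else if (d < 0) i <- i + 1L
    else j <- j + 1L
  }
  fp <- length(td) - tp
  fn <- length(tt) - tp
  flags <- character(0)
  precision <- if (length(td) == 0) { flags <- c(flags, "no_detections"); 1 }
               else tp / (tp + fp)
  recall <- if (length(tt) == 0) { flags <- c(flags, "empty_truth"); 1 }
            else tp / (tp + fn)
  structure(list(tp = tp, fp = fp, fn = fn, precision = precision,
                 recall = recall, tolerance = tolerance, flags = flags),
            class = "detection_score")
}

#' @exportS3Method base::print
print.detection_score <- function(x, ...) {
  cat(sprintf(
    "Detection score: TP %d, FP %d, FN %d; precision %.3f, recall %.3f (tolerance %g ms)%s\n",
    x$tp, x$fp, x$fn, x$precision, x$recall, x$tolerance,
    if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]") else ""))
  invisible(x)
}

#' Average aligned synaptic events
#'
#' Extracts a window around each event, drops events whose windows
#' overlap another event or fall outside the recording, subtracts a
#' per-event baseline (mean of the first half of the pre window) and
#' returns the pointwise mean event.
#'
#' @param rec An [ep_recording()].
#' @param events An [event_list()].
#' @param window `c(pre, post)` in ms around the alignment point.
#' @param align `"peak"` (default) or `"onset"`.
#' @return An [ep_sweep()]; annotations record `n_used` and
#'   `n_excluded`, and `onset` is set to `pre` (the alignment point).
#' @export
average_events <- function(rec, events, window = c(5, 20),
                           align = c("peak", "onset")) {
  stopifnot(inherits(rec, "ep_recording"))
  align <- match.arg(align)
  at <- if (align == "peak") events$peak_time else events$onset
  pre <- window[1]; post <- window[2]
  dur <- (length(rec$current) - 1) * rec$dt
  inside <- at - pre >= 0 & at + post <= dur
  overlap <- vapply(seq_along(at), function(k)
    any(abs(at[-k] - at[k]) < pre + post), TRUE)
  use <- which(inside & !overlap)
  if (length(use) < 3)
    stop("fewer than 3 usable events after exclusions (",
         length(use), " usable of ", length(at), ")")
  n_pre <- round(pre / rec$dt)
  n_post <- round(post / rec$dt)
  segs <- vapply(at[use], function(tk) {
    i0 <- round(tk / rec$dt) + 1
    s <- rec$current[(i0 - n_pre):(i0 + n_post)]
    s - mean(s[seq_len(max(2, floor(n_pre / 2)))])
  }, numeric(n_pre + n_post + 1))
  ep_sweep(rowMeans(segs), rec$dt, onset = pre, protocol = "averaged_event",
           align = align, n_used = length(use),
           n_excluded = length(at) - length(use),
           vh = rec$annotations$vh)
}

#' Weighted decay time constant of an averaged event or evoked EPSC
#'
#' Thin wrapper around [fit_decay()] (fit from the peak, offset-free by
#' default since synaptic currents decay to baseline).
#'
#' @param x An [ep_sweep()], e.g. from [average_events()].
#' @param ... Passed to [fit_decay()].
#' @return An `exp_fit`.
#' @export
epsc_decay_tau <- function(x, ...) {
  args <- list(...)
  if (is.null(args$offset)) args$offset <- FALSE
  do.call(fit_decay, c(list(x = x), args))
}

#' Charge transfer over a window
#'
#' Trapezoidal integral of the current magnitude, in pA*ms.
#'
#' @param x A baseline-corrected [ep_sweep()].
#' @param window `c(t0, t1)` in ms.
#' @return Charge in pA*ms.
#' @export
charge_transfer <- function(x, window) {
  stopifnot(inherits(x, "ep_sweep"))
  t <- trace_time(x)
  if (window[1] < 0 || window[2] > max(t) || window[2] <= window[1])
    stop("window outside sweep")
  idx <- which(t >= window[1] & t <= window[2])
  pracma::trapz(t[idx], abs(x$current[idx]))
}

#' Paired-pulse ratio of a two-pulse evoked response
#'
#' `PPR = peak2 / peak1` (magnitudes).  With
#' `correction = "decay_subtraction"` the decay of the first response is
#' fitted over the inter-pulse window, extrapolated under the second
#' response and subtracted before measuring the second peak, removing
#' the superposition bias at short intervals.
#'
#' @param x An [ep_sweep()] (baseline-corrected); if `t1`/`t2` are
#'   missing they are taken from a `stim_times` annotation.
#' @param t1,t2 Stimulus times in ms, `t2 > t1`.
#' @param correction `"none"` or `"decay_subtraction"`.
#' @param fit_gap Time in ms left between the fitted decay window and
#'   `t2` (default 1).
#' @return List of class `ppr_measure`: `ppr`, `peak1`, `peak2`
#'   (magnitudes, pA), `correction` and (when corrected) the first-pulse
#'   decay fit.
#' @export
paired_pulse_ratio <- function(x, t1 = NULL, t2 = NULL,
                               correction = c("none", "decay_subtraction"),
                               fit_gap = 1) {
  stopifnot(inherits(x, "ep_sweep"))
  correction <- match.arg(correction)
  st <- x$annotations$stim_times
  if (is.null(t1)) t1 <- st[1]
  if (is.null(t2)) t2 <- st[2]
  if (is.null(t1) || is.null(t2)) stop("two stimulus times required")
  if (t2 <= t1) stop("t2 must be after t1")
  t <- trace_time(x)
  pk1 <- measure_peak(x, window = c(t1, t2 - x$dt))
  if (pk1$degenerate || pk1$peak == 0) stop("zero first peak")
  fit1 <- NULL
  if (correction == "decay_subtraction") {
    ipk1 <- which.min(abs(t - pk1$time))
    iend <- max(which(t <= t2 - fit_gap))
    if (iend - ipk1 + 1 >= 10) {
      sub <- ep_sweep(x$current[ipk1:iend], x$dt, onset = 0)
      fit1 <- fit_decay(sub, max_components = 2, offset = FALSE)
      later <- t >= t2
      y2 <- x$current
      ts <- t[later] - pk1$time
      pred <- rowSums(vapply(seq_len(fit1$n_components), function(i)
        fit1$components$amplitude[i] * exp(-ts / fit1$components$tau[i]),
        numeric(sum(later)))) * fit1$sign
      y2[later] <- y2[later] - pred
      x2 <- x; x2$current <- y2
      pk2 <- measure_peak(x2, window = c(t2, max(t)))
    } else {
      warning("inter-pulse window too short to fit the first decay; uncorrected")
      pk2 <- measure_peak(x, window = c(t2, max(t)))
    }
  } else {
    pk2 <- measure_peak(x, window = c(t2, max(t)))
  }
  structure(list(ppr = abs(pk2$peak) / abs(pk1$peak),
                 peak1 = abs(pk1$peak), peak2 = abs(pk2$peak),
                 correction = correction, decay_fit = fit1),
            class = "ppr_measure")
}

#' @exportS3Method base::print
print.ppr_measure <- function(x, ...) {
  cat(sprintf("Paired-pulse ratio %.4f (peak1 %.2f pA, peak2 %.2f pA, %s)\n",
              x$ppr, x$peak1, x$peak2, x$correction))
  invisible(x)
}

#' Late NMDAR-component amplitude at +40 mV
#'
#' Mean current in a 5 ms window centered 150 ms after the stimulus, the
#' conventional time at which the fast AMPAR component has fully decayed
#' and only the slow NMDAR component remains.
#'
#' @param x An [ep_sweep()] annotated with `vh = 40`; must extend at
#'   least 160 ms past the stimulus.
#' @param stim_time Stimulus time in ms (default: annotated `onset`).
#' @param at Delay after the stimulus in ms (default 150).
#' @param width Averaging window width in ms (default 5).
#' @return Mean current in pA (signed; outward positive at +40 mV).
#' @export
nmdar_amplitude <- function(x, stim_time = NULL, at = 150, width = 5) {
  stopifnot(inherits(x, "ep_sweep"))
  vh <- x$annotations$vh
  if (is.null(vh) || vh != 40)
    stop("sweep must be annotated with vh = 40 (holding +40 mV)")
  if (is.null(stim_time)) stim_time <- x$annotations$onset
  if (is.null(stim_time)) stop("stimulus time required")
  t <- trace_time(x)
  if (max(t) < stim_time + at + 10)
    stop("sweep must extend >= ", at + 10, " ms past the stimulus")
  idx <- which(t >= stim_time + at - width / 2 & t <= stim_time + at + width / 2)
  mean(x$current[idx])
}
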