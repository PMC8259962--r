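# Current-voltage relation and rectification index.

#' Build a current-voltage curve from per-voltage ensembles
#'
#' Takes one baseline-corrected ensemble per holding potential, measures
#' the signed peak of the average sweep within the agonist application
#' window, and normalizes by the magnitude of the peak at the -100 mV
#' reference (so the reference point has normalized current -1 for inward
#' reference currents).
#'
#' @param ensembles Named list of [trace_ensemble()] objects; names (or
#'   `voltages`) give the holding potential in mV.  Must include the
#'   reference voltage.
#' @param voltages Optional numeric holding potentials overriding the
#'   list names.
#' @param reference Reference voltage in mV (default -100).
#' @param window Optional peak-search window `c(t0, t1)` ms; default is
#'   the annotated application window (onset to offset).
#' @return Object of class `iv_curve`: a data frame with columns
#'   `voltage`, `current` (signed peak pA) and `normalized`, with the
#'   reference voltage as an attribute.
#' @export
build_iv <- function(ensembles, voltages = NULL, reference = -100,
                     window = NULL) {
  if (is.null(voltages)) voltages <- as.numeric(names(ensembles))
  if (length(voltages) != length(ensembles) || anyNA(voltages))
    stop("each ensemble needs a numeric holding voltage")
  peaks <- vapply(seq_along(ensembles), function(k) {
    avg <- average_sweeps(ensembles[[k]])
    w <- window
    if (is.null(w)) {
      on <- avg$annotations$onset
      off <- avg$annotations$offset
      if (is.null(on) || is.null(off))
        stop("no application window annotated; supply 'window'")
      w <- c(on, off)
    }
    pk <- measure_peak(avg, window = w)
    if (pk$degenerate) 0 else pk$peak
  }, 0)
  o <- order(voltages)
  voltages <- voltages[o]; peaks <- peaks[o]
  if (anyDuplicated(voltages)) stop("duplicate holding voltages")
  if (!any(voltages == reference))
    stop("missing reference voltage ", reference, " mV")
  iref <- abs(peaks[voltages == reference])
  if (iref == 0) stop("zero current at the reference voltage")
  structure(data.frame(voltage = voltages, current = peaks,
                       normalized = peaks / iref),
            reference = reference,
            class = c("iv_curve", "data.frame"))
}

#' Construct an I-V curve from measured peak currents
#'
#' @param voltage Holding potentials in mV (strictly increasing after
#'   sorting).
#' @param current Signed peak currents in pA.
#' @param reference Normalization reference voltage (default -100 mV).
#' @return An `iv_curve`.
#' @export
iv_curve <- function(voltage, current, reference = -100) {
  o <- order(voltage)
  voltage <- voltage[o]; current <- current[o]
  if (anyDuplicated(voltage)) stop("voltages must be distinct")
  if (!any(voltage == reference)) stop("missing reference voltage")
  iref <- abs(current[voltage == reference])
  if (iref == 0) stop("zero current at the reference voltage")
  structure(data.frame(voltage = voltage, current = current,
                       normalized = current / iref),
            reference = reference,
            class = c("iv_curve", "data.frame"))
}

#' Rectification index of an I-V curve
#'
#' `RI = |I(+60)| / |I(-60)|`, with the two currents linearly
#' interpolated from neighboring voltages when +/-60 mV were not sampled.
#' 1 for a symmetric (e.g. linear through the origin) relation; < 1 for
#' inward rectification.
#'
#' @param curve An `iv_curve`.
#' @param v_test Test voltage magnitude in mV (default 60).
#' @return The rectification index (dimensionless).
#' @export
rectification_index <- function(curve, v_test = 60) {
  stopifnot(inherits(curve, "iv_curve"))
  if (v_test > max(curve$voltage) || -v_test < min(curve$voltage))
    stop("test voltages outside the sampled range")
  ip <- stats::approx(curve$voltage, curve$current, xout = v_test)$y
  im <- stats::approx(curve$voltage, curve$current, xout = -v_test)$y
  if (abs(im) == 0) stop("zero current at -", v_test, " mV")
  abs(ip) / abs(im)
}

#' @export
plot.iv_curve <- function(x, normalized = TRUE, ...) {
  y <- if (normalized) x$normalized else x$current
  graphics::plot(x$voltage, y, type = "b", xlab = "voltage (mV)",
                 ylab = if (normalized) "normalized current" else "current (pA)",
                 ...)
  graphics::abline(h = 0, v = 0, col = "grey70")
  invisible(x)
}
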