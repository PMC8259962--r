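# Trace containers shared by every analysis stage: single sweeps,
# sweep ensembles and gap-free recordings.  Units are fixed throughout
# the package: time ms, current pA, voltage mV, conductance pS.

#' Construct a single current sweep
#'
#' @param current Numeric samples in pA (inward current negative).
#' @param dt Sample interval in ms.
#' @param ... Annotations stored with the sweep, e.g. `protocol`, `vh`
#'   (holding potential, mV), `onset` (stimulus onset, ms),
#'   `stim_times` (vector of stimulus times for paired-pulse sweeps).
#'
#' @return Object of class `ep_sweep` with fields `current`, `dt`,
#'   `annotations`.
#' @export
ep_sweep <- function(current, dt, ...) {
  if (!is.numeric(current) || length(current) < 2)
    stop("a sweep needs >= 2 numeric samples")
  if (!is.numeric(dt) || dt <= 0) stop("dt must be > 0")
  structure(list(current = as.numeric(current), dt = dt,
                 annotations = list(...)),
            class = "ep_sweep")
}

#' Time base of a sweep or ensemble
#' @param x An `ep_sweep`, `ep_recording` or `trace_ensemble`.
#' @return Numeric vector of sample times in ms starting at 0.
#' @export
trace_time <- function(x) {
  n <- if (inherits(x, "trace_ensemble")) nrow(x$current) else length(x$current)
  (seq_len(n) - 1) * x$dt
}

#' Construct a sweep ensemble
#'
#' @param current Numeric matrix, samples x sweeps, in pA.
#' @param dt Shared sample interval in ms.
#' @param meta Named list of protocol metadata (protocol, vh, vr, onset,
#'   seed, scheme/channel/noise parameters, ...).
#'
#' @return Object of class `trace_ensemble`.
#' @export
trace_ensemble <- function(current, dt, meta = list()) {
  current <- as.matrix(current)
  if (nrow(current) < 2 || ncol(current) < 1)
    stop("ensemble needs >= 2 samples and >= 1 sweep")
  if (!is.numeric(dt) || dt <= 0) stop("dt must be > 0")
  structure(list(current = current, dt = dt, meta = meta),
            class = "trace_ensemble")
}

#' Number of sweeps in an ensemble
#' @param x A `trace_ensemble`.
#' @export
n_sweeps <- function(x) ncol(x$current)

#' Extract one sweep from an ensemble
#' @param x A `trace_ensemble`.
#' @param i Sweep index.
#' @return An `ep_sweep` carrying the ensemble metadata as annotations.
#' @export
get_sweep <- function(x, i) {
  stopifnot(inherits(x, "trace_ensemble"), i >= 1, i <= n_sweeps(x))
  do.call(ep_sweep, c(list(current = x$current[, i], dt = x$dt),
                      x$meta[!vapply(x$meta, is.list, TRUE)]))
}

#' Construct a gap-free recording
#'
#' A continuous single-channel-of-data recording used for synaptic event
#' detection; must be at least 1 s long.
#'
#' @param current Numeric samples in pA.
#' @param dt Sample interval in ms (default 0.1, i.e. 10 kHz).
#' @param ... Annotations (e.g. `vh`).
#' @return Object of class `ep_recording` (also an `ep_sweep`).
#' @export
ep_recording <- function(current, dt = 0.1, ...) {
  x <- ep_sweep(current, dt, ...)
  if ((length(current) - 1) * dt < 1000)
    stop("recording must be >= 1 s long for event analysis")
  class(x) <- c("ep_recording", class(x))
  x
}

#' Average the sweeps of an ensemble
#'
#' Pointwise mean across sweeps; the returned sweep's annotations record
#' the number averaged.
#'
#' @param x A `trace_ensemble` with >= 1 sweep.
#' @return An `ep_sweep`.
#' @export
average_sweeps <- function(x) {
  stopifnot(inherits(x, "trace_ensemble"))
  if (n_sweeps(x) < 1) stop("empty ensemble")
  ann <- x$meta[!vapply(x$meta, is.list, TRUE)]
  out <- do.call(ep_sweep, c(list(current = rowMeans(x$current), dt = x$dt), ann))
  out$annotations$n_averaged <- n_sweeps(x)
  out
}

#' Decimate a sweep by an integer factor
#'
#' Keeps every `factor`-th sample (dt grows accordingly).  Useful before
#' fitting slow decays sampled at 100 kHz, where the full grid adds cost
#' but no information.
#'
#' @param x An `ep_sweep`.
#' @param factor Positive integer decimation factor.
#' @return An `ep_sweep` with `dt * factor`.
#' @export
decimate_sweep <- function(x, factor) {
  stopifnot(inherits(x, "ep_sweep"), factor >= 1, factor == round(factor))
  if (factor == 1) return(x)
  out <- x
  out$current <- x$current[seq(1, length(x$current), by = factor)]
  out$dt <- x$dt * factor
  out
}

#' Baseline-correct a sweep, recording or ensemble
#'
#' Subtracts the mean current over a pre-stimulus window.  The window must
#' lie before the annotated stimulus onset (when present) and be at least
#' 1 ms long.  The subtracted offset is recorded in the annotations
#' (per-sweep offsets in `meta$baseline_offsets` for ensembles).
#'
#' @param x An `ep_sweep`, `ep_recording` or `trace_ensemble`.
#' @param window Numeric `c(t0, t1)` in ms.
#' @return Object of the same class.
#' @export
baseline_correct <- function(x, window) UseMethod("baseline_correct")

.baseline_idx <- function(dt, n, window, onset) {
  if (length(window) != 2 || window[2] <= window[1])
    stop("window must be c(t0, t1) with t1 > t0")
  if (window[2] - window[1] < 1) stop("baseline window must be >= 1 ms")
  if (window[1] < 0 || window[2] > (n - 1) * dt)
    stop("baseline window outside trace")
  if (!is.null(onset) && window[2] > onset)
    stop("baseline window must precede the stimulus onset")
  idx <- which((seq_len(n) - 1) * dt >= window[1] &
                 (seq_len(n) - 1) * dt <= window[2])
  if (length(idx) < 2) stop("baseline window too short for this dt")
  idx
}

#' @export
baseline_correct.ep_sweep <- function(x, window) {
  idx <- .baseline_idx(x$dt, length(x$current), window, x$annotations$onset)
  off <- mean(x$current[idx])
  x$current <- x$current - off
  x$annotations$baseline_offset <- off
  x$annotations$baseline_window <- window
  x
}

#' @export
baseline_correct.trace_ensemble <- function(x, window) {
  idx <- .baseline_idx(x$dt, nrow(x$current), window, x$meta$onset)
  off <- colMeans(x$current[idx, , drop = FALSE])
  x$current <- sweep(x$current, 2, off)
  x$meta$baseline_offsets <- off
  x$meta$baseline_window <- window
  x
}

#' @exportS3Method base::print
print.ep_sweep <- function(x, ...) {
  cat(sprintf("Sweep: %d samples at dt = %g ms (%.1f ms), range [%.2f, %.2f] pA\n",
              length(x$current), x$dt, (length(x$current) - 1) * x$dt,
              min(x$current), max(x$current)))
  ann <- x$annotations[!vapply(x$annotations, is.list, TRUE)]
  if (length(ann))
    cat("  ", paste(names(ann), vapply(ann, function(a)
      paste(format(a, digits = 4), collapse = ","), ""),
      sep = "=", collapse = "  "), "\n")
  invisible(x)
}

#' @exportS3Method base::print
print.trace_ensemble <- function(x, ...) {
  cat(sprintf("Trace ensemble: %d sweeps x %d samples at dt = %g ms\n",
              n_sweeps(x), nrow(x$current), x$dt))
  m <- x$meta[!vapply(x$meta, function(e) is.list(e) || length(e) > 4, TRUE)]
  if (length(m))
    cat("  ", paste(names(m), vapply(m, function(a)
      paste(format(a, digits = 4), collapse = ","), ""),
      sep = "=", collapse = "  "), "\n")
  invisible(x)
}

#' @export
plot.ep_sweep <- function(x, ...) {
  graphics::plot(trace_time(x), x$current, type = "l",
                 xlab = "time (ms)", ylab = "current (pA)", ...)
  invisible(x)
}

#' @export
plot.trace_ensemble <- function(x, n_show = 20, ...) {
  i <- seq_len(min(n_show, n_sweeps(x)))
  graphics::matplot(trace_time(x), x$current[, i, drop = FALSE], type = "l",
                    lty = 1, col = grDevices::grey(0.7),
                    xlab = "time (ms)", ylab = "current (pA)", ...)
  graphics::lines(trace_time(x), rowMeans(x$current), lwd = 2)
  invisible(x)
}
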