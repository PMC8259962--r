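# Peak, steady-state and multi-exponential decay measurements.
#
# All decay analysis works on current magnitudes after baseline
# correction: the sign at the peak is detected once, the trace is flipped
# to positive-going, and the sign is restored only in reports.

#' Measure the peak of a baseline-corrected sweep
#'
#' Finds the extremum of largest magnitude in the search window and the
#' 10-90% rise time from baseline to that peak.
#'
#' @param x An [ep_sweep()] (baseline-corrected).
#' @param window Optional `c(t0, t1)` ms search window; default is from
#'   the annotated stimulus onset (if any) to the end of the trace.
#' @return Object of class `peak_measure`: `peak` (signed pA), `time`
#'   (ms), `rise_10_90` (ms) and a `degenerate` flag (all-zero trace).
#' @export
measure_peak <- function(x, window = NULL) {
  stopifnot(inherits(x, "ep_sweep"))
  t <- trace_time(x)
  if (is.null(window))
    window <- c(if (!is.null(x$annotations$onset)) x$annotations$onset else 0,
                max(t))
  idx <- which(t >= window[1] & t <= window[2])
  if (!length(idx)) stop("empty search window")
  y <- x$current[idx]
  if (all(y == 0))
    return(structure(list(peak = 0, time = NA_real_, rise_10_90 = NA_real_,
                          degenerate = TRUE), class = "peak_measure"))
  ipk <- idx[which.max(abs(y))]
  pk <- x$current[ipk]
  # 10-90% rise time on the magnitude, walking back from the peak
  m <- abs(x$current)
  apk <- abs(pk)
  pre <- idx[idx <= ipk]
  cross <- function(level) {
    below <- pre[m[pre] <= level]
    if (!length(below)) return(t[pre[1]])
    i0 <- max(below)
    if (i0 == ipk) return(t[i0])
    # linear interpolation between the last sample below and the next one
    t[i0] + x$dt * (level - m[i0]) / (m[i0 + 1] - m[i0])
  }
  rise <- cross(0.9 * apk) - cross(0.1 * apk)
  structure(list(peak = pk, time = t[ipk], rise_10_90 = max(rise, 0),
                 degenerate = FALSE),
            class = "peak_measure")
}

#' @exportS3Method base::print
print.peak_measure <- function(x, ...) {
  if (x$degenerate) cat("Peak measure: degenerate (all-zero trace)\n")
  else cat(sprintf("Peak %.3f pA at %.3f ms, 10-90%% rise %.4f ms\n",
                   x$peak, x$time, x$rise_10_90))
  invisible(x)
}

#' Amplitude-weighted time constant
#'
#' `sum(a_i * tau_i) / sum(a_i)` over the fitted exponential components.
#'
#' @param amplitude,tau Component amplitudes and time constants.
#' @export
weighted_tau <- function(amplitude, tau) sum(amplitude * tau) / sum(amplitude)

# linear solve of amplitudes (+ offset) for fixed taus; returns list or NULL
.lin_amps <- function(ts, ys, taus, offset) {
  X <- vapply(taus, function(tau) exp(-ts / tau), numeric(length(ts)))
  if (offset) X <- cbind(X, 1)
  b <- tryCatch(qr.coef(qr(X), ys), error = function(e) NULL)
  if (is.null(b) || anyNA(b)) return(NULL)
  list(a = pmax(b[seq_along(taus)], 0),
       c0 = if (offset) b[length(b)] else 0)
}

# Levenberg-Marquardt fit of k exponentials (+ optional offset) with
# analytic Jacobian, driven through minpack.lm::nls.lm directly.
# Parameter vector: (a_1..a_k, tau_1..tau_k[, c0]).
.fit_k_exp <- function(ts, ys, k, offset, n_restarts, tau_range) {
  model <- function(p) {
    y <- if (offset) rep(p[2 * k + 1], length(ts)) else numeric(length(ts))
    for (i in seq_len(k)) y <- y + p[i] * exp(-ts / p[k + i])
    y
  }
  resid_fn <- function(p) ys - model(p)
  jac_fn <- function(p) {
    J <- matrix(0, length(ts), length(p))
    for (i in seq_len(k)) {
      e <- exp(-ts / p[k + i])
      J[, i] <- -e
      J[, k + i] <- -p[i] * ts * e / p[k + i]^2
    }
    if (offset) J[, 2 * k + 1] <- -1
    J
  }
  base_tau <- exp(seq(log(tau_range[1]), log(tau_range[2]), length.out = k + 2))
  base_tau <- base_tau[seq_len(k) + 1]
  shifts <- c(1, 1 / 3, 3, 1 / 9, 9)[seq_len(n_restarts)]
  lower <- c(rep(0, k), rep(1e-3, k), if (offset) -Inf)
  upper <- c(rep(Inf, k), rep(1e4, k), if (offset) Inf)
  best <- NULL
  for (s in shifts) {
    taus <- pmin(pmax(base_tau * s, 2e-3), 5e3)
    lin <- .lin_amps(ts, ys, taus, offset)
    if (is.null(lin)) next
    p0 <- c(pmax(lin$a, 1e-9 * max(abs(ys))), taus, if (offset) lin$c0)
    out <- tryCatch(
      suppressWarnings(
        minpack.lm::nls.lm(par = p0, fn = resid_fn, jac = jac_fn,
                           lower = lower, upper = upper,
                           control = minpack.lm::nls.lm.control(
                             maxiter = 200, ftol = 1e-12, ptol = 1e-12))),
      error = function(e) NULL)
    if (is.null(out)) next
    rss <- out$deviance
    if (!is.finite(rss)) next
    if (is.null(best) || rss < best$rss) {
      best <- list(par = out$par, rss = rss, fitted = model(out$par))
    }
  }
  if (!is.null(best))
    names(best$par) <- c(paste0("a", seq_len(k)), paste0("tau", seq_len(k)),
                         if (offset) "c0")
  best
}

#' Fit a multi-exponential decay
#'
#' Least-squares fit of `sum(a_i * exp(-(t - t0)/tau_i)) + offset` over a
#' decay window, used for deactivation, desensitization and EPSC decays.
#' The window starts at the peak sample by default (or where the
#' magnitude first falls to `start_percent` of peak) and runs to `end`.
#' 1 to `max_components` components are tried with log-spaced multi-start
#' initial time constants; a model with one more component is accepted
#' only if it reduces the residual sum of squares by more than 5%.  The
#' amplitude-weighted time constant `sum(a*tau)/sum(a)` is the headline
#' readout.
#'
#' @param x An [ep_sweep()] (baseline-corrected).
#' @param start `"peak"` (default) or `"percent"`.
#' @param start_percent Percent-of-peak level used when
#'   `start = "percent"`.
#' @param end End of the fit window in ms (default: end of trace).
#' @param max_components Maximum number of exponential components (1-3).
#' @param offset Fit a constant offset (default `TRUE`; needed for
#'   non-desensitizing plateaus).
#' @param n_restarts Multi-start restarts per component count (default 5,
#'   initial time constants log-spaced over 0.2-100 ms and rescaled per
#'   restart).
#' @param peak_window Optional search window passed to [measure_peak()].
#'
#' @return An object of class `exp_fit` with components (amplitude pA,
#'   tau ms), offset, `weighted_tau`, fit window, residual norm, number of
#'   components and convergence flags.  Amplitudes are magnitudes; the
#'   decay sign is in `$sign`.
#' @examples
#' sw <- ep_sweep(100 * exp(-(0:500) * 0.1 / 5), dt = 0.1, onset = 0)
#' fit_decay(sw)
#' @export
fit_decay <- function(x, start = c("peak", "percent"), start_percent = 100,
                      end = NULL, max_components = 3, offset = TRUE,
                      n_restarts = 5, peak_window = NULL) {
  stopifnot(inherits(x, "ep_sweep"))
  start <- match.arg(start)
  if (max_components < 1 || max_components > 3)
    stop("max_components must be between 1 and 3")
  pk <- measure_peak(x, window = peak_window)
  if (pk$degenerate) stop("cannot fit a decay to an all-zero trace")
  t <- trace_time(x)
  sgn <- sign(pk$peak)
  m <- x$current * sgn                       # positive-going magnitude
  ipk <- which(t == pk$time)[1]
  i0 <- ipk
  if (start == "percent" && start_percent < 100) {
    after <- which(t > pk$time & m <= start_percent / 100 * abs(pk$peak))
    if (length(after)) i0 <- after[1]
  }
  iend <- if (is.null(end)) length(t) else max(which(t <= end))
  if (iend - i0 + 1 < 10) stop("decay window must contain >= 10 samples")
  ts <- t[i0:iend] - t[i0]
  ys <- m[i0:iend]

  fits <- list()
  rss <- rep(NA_real_, max_components)
  chosen <- 1
  tol0 <- 1e-12 * sum(ys^2)
  for (k in seq_len(max_components)) {
    fk <- .fit_k_exp(ts, ys, k, offset, n_restarts, tau_range = c(0.2, 100))
    if (is.null(fk)) {
      if (k == 1) stop("exponential fit failed to converge after restarts")
      break
    }
    fits[[k]] <- fk
    rss[k] <- fk$rss
    if (k > 1) {
      if (rss[k] < 0.95 * rss[chosen]) chosen <- k else break
    }
    if (rss[k] <= tol0) break                 # already at numerical noise
  }
  cf <- fits[[chosen]]$par
  a <- cf[paste0("a", seq_len(chosen))]
  tau <- cf[paste0("tau", seq_len(chosen))]
  c0 <- if (offset) unname(cf["c0"]) else 0
  keep <- a > 1e-9 * max(abs(ys))             # drop numerically-zero components
  if (!any(keep)) keep[which.max(a)] <- TRUE
  ord <- order(tau[keep])
  a <- unname(a[keep][ord]); tau <- unname(tau[keep][ord])
  at_bounds <- any(tau <= 1.1e-3) || any(tau >= 0.9e4)
  structure(list(
    components = data.frame(amplitude = a, tau = tau),
    offset = c0,
    weighted_tau = weighted_tau(a, tau),
    n_components = length(a),
    window = c(t[i0], t[iend]),
    rss = fits[[chosen]]$rss,
    sigma = sqrt(fits[[chosen]]$rss / max(length(ys) - length(cf), 1)),
    sign = sgn,
    rss_path = rss,
    at_bounds = at_bounds,
    peak = pk,
    t0 = t[i0],
    data = list(time = ts + t[i0], y = ys * sgn,
                fitted = fits[[chosen]]$fitted * sgn)),
    class = "exp_fit")
}

#' @exportS3Method base::print
print.exp_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Exponential decay fit: %d component(s), weighted tau = %s ms\n",
              x$n_components, format(x$weighted_tau, digits = digits)))
  comps <- x$components
  cat(sprintf("  a%d = %s pA, tau%d = %s ms\n", seq_len(nrow(comps)),
              format(comps$amplitude * x$sign, digits = digits),
              seq_len(nrow(comps)), format(comps$tau, digits = digits)),
      sep = "")
  cat(sprintf("  offset %s pA, window %.2f-%.2f ms, residual sd %s pA%s\n",
              format(x$offset * x$sign, digits = digits),
              x$window[1], x$window[2], format(x$sigma, digits = 3),
              if (x$at_bounds) " [tau at bounds]" else ""))
  invisible(x)
}

#' @exportS3Method base::summary
summary.exp_fit <- function(object, ...) {
  print(object, ...)
  cat("  RSS by component count:",
      paste(format(object$rss_path[!is.na(object$rss_path)], digits = 4),
            collapse = " "), "\n")
  invisible(object)
}

#' @export
coef.exp_fit <- function(object, ...) {
  k <- object$n_components
  stats::setNames(
    c(object$components$amplitude, object$components$tau, object$offset),
    c(paste0("a", seq_len(k)), paste0("tau", seq_len(k)), "offset"))
}

#' Predicted decay at given times
#' @param object An `exp_fit`.
#' @param times Times in ms on the sweep's own time base (default: the
#'   fitted window).
#' @param ... Unused.
#' @export
predict.exp_fit <- function(object, times = NULL, ...) {
  if (is.null(times)) times <- object$data$time
  ts <- times - object$t0
  y <- rowSums(vapply(seq_len(object$n_components), function(i)
    object$components$amplitude[i] * exp(-ts / object$components$tau[i]),
    numeric(length(ts)))) + object$offset
  y * object$sign
}

#' @export
residuals.exp_fit <- function(object, ...) object$data$y - object$data$fitted

#' @export
plot.exp_fit <- function(x, ...) {
  graphics::plot(x$data$time, x$data$y, type = "l", col = "grey50",
                 xlab = "time (ms)", ylab = "current (pA)", ...)
  graphics::lines(x$data$time, x$data$fitted, col = 2, lwd = 2)
  graphics::legend("topright", c("data", "fit"), col = c("grey50", 2),
                   lwd = c(1, 2), bty = "n")
  invisible(x)
}

#' Steady-state current as a percentage of peak
#'
#' Mean current magnitude over a window at the end of a long agonist
#' pulse, divided by the peak amplitude, times 100.  Quantifies the
#' non-desensitizing current fraction.
#'
#' @param x An [ep_sweep()] (baseline-corrected) from a long-pulse
#'   protocol.
#' @param pulse_end End of the agonist pulse in ms (default: annotated
#'   `offset`).
#' @param steady_window Window length in ms ending at `pulse_end`
#'   (default 50).
#' @return Percentage (0-100 scale).
#' @export
steady_state_fraction <- function(x, pulse_end = NULL, steady_window = 50) {
  stopifnot(inherits(x, "ep_sweep"))
  if (is.null(pulse_end)) pulse_end <- x$annotations$offset
  if (is.null(pulse_end)) stop("pulse_end required (no 'offset' annotation)")
  t <- trace_time(x)
  onset <- x$annotations$onset
  if (!is.null(onset) && pulse_end - steady_window < onset)
    stop("steady window extends before the pulse")
  if (pulse_end > max(t)) stop("steady window outside trace")
  pk <- measure_peak(x, window = c(if (is.null(onset)) 0 else onset, pulse_end))
  if (pk$degenerate || pk$peak == 0) stop("zero peak; cannot normalize")
  idx <- which(t >= pulse_end - steady_window & t <= pulse_end)
  100 * mean(x$current[idx] * sign(pk$peak)) / abs(pk$peak)
}
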