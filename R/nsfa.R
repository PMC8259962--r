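# Non-stationary fluctuation analysis: build the variance-mean relation
# across repeated sweeps and invert the parabola
#
#   sigma^2 = i * I - I^2 / N + sigma0^2
#
# to the single-channel current i, the number of available channels N and
# the background variance sigma0^2; derived quantities are the unitary
# conductance gamma = i / (Vh - Vr) and the peak open probability
# Popen = I_peak / (i * N).

#' Construct a variance-mean curve directly
#'
#' Mostly used for analytic test points and for re-fitting saved curves;
#' [variance_mean()] builds curves from ensembles.
#'
#' @param mean_current Mean current per bin (pA; magnitudes or signed,
#'   magnitudes are taken).
#' @param variance Ensemble variance per bin (pA^2, >= 0).
#' @param sigma0_sq Background variance estimate in pA^2.
#' @param weights Optional positive fit weights (default equal).
#' @param mean_sq Optional per-bin mean of the squared mean current
#'   (pA^2).  For bins pooling a range of mean currents the parabola is
#'   linear in (mean |I|, mean I^2), so carrying the second moment keeps
#'   the fit exact for arbitrarily wide bins; defaults to
#'   `mean_current^2` (point bins).
#' @param i_peak Peak mean current magnitude in pA (default:
#'   `max(abs(mean_current))`); used for the Popen readout.
#' @param vh,vr Holding and reversal potentials in mV (for the
#'   conductance readout).
#' @param n_sweeps_used Number of sweeps behind the curve (diagnostics).
#' @param estimator Estimator label.
#' @return Object of class `variance_curve`.
#' @export
variance_curve <- function(mean_current, variance, sigma0_sq = 0,
                           weights = NULL, mean_sq = NULL, i_peak = NULL,
                           vh = -70, vr = 0, n_sweeps_used = NA_integer_,
                           estimator = "ensemble") {
  if (length(mean_current) != length(variance))
    stop("mean_current and variance must have equal length")
  if (any(variance < 0)) stop("variances must be >= 0")
  m <- abs(mean_current)
  if (max(m) <= 0) stop("zero dynamic range in mean current")
  if (is.null(weights)) weights <- rep(1, length(m))
  if (any(weights <= 0)) stop("weights must be > 0")
  if (is.null(mean_sq)) mean_sq <- m^2
  if (is.null(i_peak)) i_peak <- max(m)
  structure(list(mean = m, variance = as.numeric(variance),
                 mean_sq = as.numeric(mean_sq),
                 sigma0_sq = sigma0_sq, weights = weights,
                 i_peak = i_peak, vh = vh, vr = vr,
                 n_sweeps_used = n_sweeps_used, estimator = estimator),
            class = "variance_curve")
}

#' @exportS3Method base::print
print.variance_curve <- function(x, ...) {
  cat(sprintf(
    "Variance-mean curve: %d bins (%s estimator), |I| up to %.2f pA, sigma0^2 = %.3f pA^2\n",
    length(x$mean), x$estimator, max(x$mean), x$sigma0_sq))
  invisible(x)
}

#' @export
plot.variance_curve <- function(x, ...) {
  graphics::plot(x$mean, x$variance, xlab = "|mean current| (pA)",
                 ylab = expression(sigma^2 ~ (pA^2)), ...)
  invisible(x)
}

#' Variance-mean relation of a sweep ensemble
#'
#' Computes the per-time mean and across-sweep variance of a
#' baseline-corrected ensemble, restricts to the decay phase (from the
#' peak of the mean current down to 5% of peak) by default, and bins the
#' (|mean|, variance) pairs into equal-count bins ordered by |mean|.
#' Background variance is estimated from the pre-stimulus baseline.
#'
#' Three estimator details matter for unbiased inversion and are applied
#' here:
#' * the binning key is a lightly smoothed copy of the mean current
#'   (`key_smooth` ms running mean), so that bin membership in flat
#'   stretches does not select on the same noise that enters the
#'   variance estimates (the binomial mean-variance correlation
#'   otherwise tilts the curve);
#' * each bin carries both moments of the mean current (mean |I| and
#'   mean I^2, debiased for sampling noise), because the parabola is
#'   linear in those moments, which keeps wide bins exact;
#' * bin weights use an effective sample size from the lag-1
#'   autocorrelation of the per-time variances, since channel gating
#'   correlates neighbouring samples far beyond the sampling interval.
#'
#' Two variance estimators are offered: `"ensemble"` (plain across-sweep
#' variance at each time) and `"successive_difference"` (half the mean
#' squared difference of consecutive sweeps, robust to slow rundown of
#' the response amplitude).
#'
#' @param x A [trace_ensemble()] with >= 20 sweeps (a warning is issued
#'   below 100, the conventional floor for stable curves).
#' @param phase `"decay"` (default) or `"full"` (all samples from onset).
#' @param estimator `"ensemble"` or `"successive_difference"`.
#' @param n_bins Number of equal-count bins (default 10).
#' @param baseline_window Window for the background-variance estimate;
#'   default is from 1 ms after trace start to 1 ms before onset.
#' @param key_smooth Running-mean window (ms) for the binning key.
#' @return A [variance_curve()]; bin weights are inverse estimated
#'   variances of the bin variances.
#' @export
variance_mean <- function(x, phase = c("decay", "full"),
                          estimator = c("ensemble", "successive_difference"),
                          n_bins = 10, baseline_window = NULL,
                          key_smooth = 1) {
  stopifnot(inherits(x, "trace_ensemble"))
  phase <- match.arg(phase)
  estimator <- match.arg(estimator)
  M <- n_sweeps(x)
  if (M < 20) stop("need >= 20 sweeps for fluctuation analysis")
  if (M < 100) warning("fewer than 100 sweeps; variance-mean curve may be unstable")
  t <- trace_time(x)
  onset <- if (!is.null(x$meta$onset)) x$meta$onset else 0
  if (is.null(baseline_window)) baseline_window <- c(1, max(onset - 1, 2))

  mu <- rowMeans(x$current)
  if (estimator == "ensemble") {
    v <- apply(x$current, 1, stats::var)
    pairs_used <- M
  } else {
    d <- x$current[, -1, drop = FALSE] - x$current[, -M, drop = FALSE]
    v <- rowMeans(d^2) / 2
    pairs_used <- M - 1
  }

  bidx <- which(t >= baseline_window[1] & t <= baseline_window[2] & t < onset)
  if (length(bidx) < 2) stop("baseline window too short")
  sigma0_sq <- mean(v[bidx])

  am <- abs(mu)
  # smoothed binning key: used only for ordering samples into bins, so
  # that bin membership does not select on per-sample noise; the phase
  # window and the peak current come from the raw ensemble mean
  w_n <- max(1L, round(key_smooth / x$dt))
  key <- abs(as.numeric(stats::filter(mu, rep(1 / w_n, w_n), sides = 2)))
  key[is.na(key)] <- am[is.na(key)]
  ipk <- which.max(am)
  if (am[ipk] <= 0) stop("zero dynamic range: no response in the ensemble mean")
  if (phase == "decay") {
    below <- which(t > t[ipk] & key <= 0.05 * am[ipk])
    iend <- if (length(below)) below[1] else length(t)
    sel <- ipk:iend
  } else {
    sel <- which(t >= onset)
  }
  if (length(sel) < n_bins) stop("too few samples in the analysis phase")

  # equal-width bins over the key range: a response that dwells at one
  # amplitude (a plateau) must not absorb all bins, or the fit loses its
  # leverage along the parabola; unequal occupancy is absorbed by the
  # effective-sample-size weights below
  kr <- range(key[sel])
  cuts <- cut(key[sel], breaks = seq(kr[1], kr[2], length.out = n_bins + 1),
              include.lowest = TRUE, labels = FALSE)
  bins <- split(sel, cuts)
  bins <- bins[lengths(bins) > 0]
  bm <- vapply(bins, function(i) mean(am[i]), 0)
  # second moment of the true mean current: subtract the sampling
  # variance of the sample mean, var(x_bar) = sigma^2 / M
  bm2 <- vapply(bins, function(i) max(mean(am[i]^2 - v[i] / M), 0), 0)
  bv <- vapply(bins, function(i) mean(v[i]), 0)
  # effective number of independent variance samples per bin from the
  # lag-1 autocorrelation of v(t) (channel gating correlates neighbours)
  neff <- vapply(bins, function(i) {
    vi <- v[sort(i)]
    n <- length(vi)
    if (n < 4) return(as.numeric(n))
    r1 <- suppressWarnings(stats::cor(vi[-1], vi[-n]))
    if (!is.finite(r1)) r1 <- 0
    r1 <- min(max(r1, 0), 0.999)
    n * (1 - r1) / (1 + r1)
  }, 0)
  vov <- 2 * (bv + sigma0_sq + 1e-12)^2 / (pmax(neff, 1) * (pairs_used - 1))
  variance_curve(bm, bv, sigma0_sq = sigma0_sq, weights = 1 / vov,
                 mean_sq = bm2,
                 i_peak = max(am[sel]),
                 vh = if (!is.null(x$meta$vh)) x$meta$vh else -70,
                 vr = if (!is.null(x$meta$vr)) x$meta$vr else 0,
                 n_sweeps_used = M, estimator = estimator)
}

#' Fit the variance-mean parabola
#'
#' Weighted least-squares fit of `sigma^2 = i|I| - I^2/N + sigma0^2` to a
#' [variance_curve()], using the curve's two mean-current moments as
#' regressors (exact for wide bins).  With `fix_background = TRUE`
#' (default) the background variance is fixed at the curve's baseline
#' estimate and subtracted; otherwise it is a free intercept.  Derived
#' readouts:
#' unitary conductance `gamma = 1000 * i / |vh - vr|` (pS) and peak open
#' probability `popen_peak = I_peak / (i N)`.
#'
#' @param curve A [variance_curve()] with >= 5 bins.
#' @param fix_background Fix sigma0^2 at the baseline estimate instead of
#'   fitting it.
#' @return Object of class `nsfa_fit`: `i` (pA), `n_channels`,
#'   `sigma0_sq` (pA^2), `gamma` (pS), `popen_peak`, residual norm and
#'   `flags` (character vector; `"nonconcave"` marks a failed inversion,
#'   `"popen_out_of_range"` a Popen outside [0, 1]).
#' @examples
#' I <- seq(1, 30, length.out = 10)
#' fit_nsfa(variance_curve(I, 1.2 * I - I^2 / 50))
#' @export
fit_nsfa <- function(curve, fix_background = TRUE) {
  stopifnot(inherits(curve, "variance_curve"))
  if (length(curve$mean) < 5) stop("need >= 5 bins to fit the parabola")
  x <- curve$mean
  x2 <- curve$mean_sq
  if (is.null(x2)) x2 <- x^2
  w <- curve$weights
  flags <- character(0)
  if (fix_background) {
    y <- curve$variance - curve$sigma0_sq
    fit <- stats::lm(y ~ 0 + x + x2, weights = w)
    b <- stats::coef(fit)
    i_hat <- unname(b["x"]); q <- unname(b["x2"])
    s0 <- curve$sigma0_sq
  } else {
    y <- curve$variance
    fit <- stats::lm(y ~ x + x2, weights = w)
    b <- stats::coef(fit)
    i_hat <- unname(b["x"]); q <- unname(b["x2"])
    s0 <- unname(b["(Intercept)"])
  }
  n_hat <- if (is.finite(q) && q < 0) -1 / q else NA_real_
  # a curve with no structure in |I| is degenerate: the parabola must
  # explain the variance better than a constant does
  rss_fit <- sum(w * stats::resid(fit)^2)
  rss_const <- sum(w * (y - stats::weighted.mean(y, w))^2)
  degenerate <- rss_fit > 0.5 * rss_const + 1e-10 * sum(w * y^2)
  if (!is.finite(i_hat) || !is.finite(q) || i_hat <= 0 || q >= 0 ||
      degenerate) {
    flags <- c(flags, if (degenerate) "degenerate" else "nonconcave")
    return(structure(list(i = NA_real_, n_channels = NA_real_,
                          sigma0_sq = s0, gamma = NA_real_,
                          popen_peak = NA_real_, rss = NA_real_,
                          flags = flags, fit = fit, curve = curve,
                          fix_background = fix_background),
                     class = "nsfa_fit"))
  }
  gamma <- 1000 * i_hat / abs(curve$vh - curve$vr)
  popen <- curve$i_peak / (i_hat * n_hat)
  if (!is.na(popen) && (popen < 0 || popen > 1))
    flags <- c(flags, "popen_out_of_range")
  structure(list(i = i_hat, n_channels = n_hat, sigma0_sq = s0,
                 gamma = gamma, popen_peak = popen,
                 rss = sum(w * stats::resid(fit)^2),
                 flags = flags, fit = fit, curve = curve,
                 fix_background = fix_background),
            class = "nsfa_fit")
}

#' @exportS3Method base::print
print.nsfa_fit <- function(x, digits = 4, ...) {
  cat("Non-stationary fluctuation analysis\n")
  if (any(c("nonconcave", "degenerate") %in% x$flags)) {
    cat("  FAILED: variance-mean relation is not a concave parabola (",
        paste(x$flags, collapse = ", "), ")\n", sep = "")
    return(invisible(x))
  }
  cat(sprintf("  i = %s pA   N = %s   sigma0^2 = %s pA^2%s\n",
              format(x$i, digits = digits),
              format(x$n_channels, digits = digits),
              format(x$sigma0_sq, digits = digits),
              if (x$fix_background) " (fixed)" else " (fitted)"))
  cat(sprintf("  gamma = %s pS (Vh = %g mV, Vr = %g mV)   peak Popen = %s%s\n",
              format(x$gamma, digits = digits), x$curve$vh, x$curve$vr,
              format(x$popen_peak, digits = digits),
              if (length(x$flags)) paste0("  [", paste(x$flags, collapse = ", "), "]")
              else ""))
  invisible(x)
}

#' @exportS3Method base::summary
summary.nsfa_fit <- function(object, ...) {
  print(object, ...)
  if (!any(c("nonconcave", "degenerate") %in% object$flags))
    cat(sprintf("  %d bins, %s sweeps, weighted RSS %s\n",
                length(object$curve$mean),
                format(object$curve$n_sweeps_used),
                format(object$rss, digits = 3)))
  invisible(object)
}

#' @export
coef.nsfa_fit <- function(object, ...) {
  c(i = object$i, n_channels = object$n_channels,
    sigma0_sq = object$sigma0_sq, gamma = object$gamma,
    popen_peak = object$popen_peak)
}

#' Predicted parabola variance at given mean currents
#' @param object An `nsfa_fit`.
#' @param mean_current Mean-current magnitudes in pA (default: the
#'   fitted bin means).
#' @param ... Unused.
#' @export
predict.nsfa_fit <- function(object, mean_current = NULL, ...) {
  if (is.null(mean_current)) mean_current <- object$curve$mean
  m <- abs(mean_current)
  object$i * m - m^2 / object$n_channels + object$sigma0_sq
}

#' @export
plot.nsfa_fit <- function(x, ...) {
  plot(x$curve, ...)
  if (!any(c("nonconcave", "degenerate") %in% x$flags)) {
    xx <- seq(0, max(x$curve$mean), length.out = 200)
    graphics::lines(xx, predict(x, xx), col = 2, lwd = 2)
  }
  invisible(x)
}
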