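# Agonist application waveforms for the fast-perfusion protocols.

#' Build an agonist concentration waveform
#'
#' Standard fast-application protocols: a 1 ms pulse of 10 mM glutamate
#' (`"deactivation"`), a 500 ms pulse (`"desensitization"`), a 200 ms pulse
#' used for voltage-step families (`"iv_step"`), or a user-supplied
#' concentration trace (`"custom"`).  Pulse edges are smoothed with a
#' first-order solution-exchange filter of time constant `exchange_tau`
#' (10-90% exchange time = `exchange_tau * log(9)`), emulating the finite
#' speed of piezo-driven theta-glass perfusion.  Every protocol includes a
#' pre-pulse baseline (default 20 ms).
#'
#' @param protocol One of `"deactivation"`, `"desensitization"`,
#'   `"iv_step"`, `"custom"`.
#' @param dt Sample interval in ms (default 0.01, i.e. 100 kHz).
#' @param exchange_tau Solution-exchange time constant in ms (>= 0, default
#'   0.1; 0 gives square pulses).
#' @param conc Pulse concentration in mM (default 10).
#' @param baseline Pre-pulse baseline duration in ms (>= 20).
#' @param tail Post-pulse duration in ms.
#' @param custom_conc Numeric concentration samples (mM), required for
#'   `protocol = "custom"`; used as-is (plus exchange smoothing).
#'
#' @return An object of class `stimulus` with fields `dt`, `conc`
#'   (mM samples), `time` (ms), `onset` and `offset` (pulse edges, ms)
#'   and `exchange_tau`.
#' @examples
#' s <- make_stimulus("deactivation", dt = 0.01, exchange_tau = 0)
#' range(s$conc)
#' @export
make_stimulus <- function(protocol = c("deactivation", "desensitization",
                                       "iv_step", "custom"),
                          dt = 0.01, exchange_tau = 0.1, conc = 10,
                          baseline = 20, tail = 30, custom_conc = NULL) {
  protocol <- match.arg(protocol)
  if (!is.numeric(dt) || dt <= 0) stop("dt must be > 0")
  if (exchange_tau < 0) stop("exchange_tau must be >= 0")
  if (baseline < 20) stop("pre-pulse baseline must be >= 20 ms")
  if (protocol == "custom") {
    if (is.null(custom_conc)) stop("custom protocol requires custom_conc")
    if (length(custom_conc) < 2) stop("custom_conc needs length >= 2")
    if (any(custom_conc < 0)) stop("concentrations must be >= 0")
    c_raw <- c(rep(0, round(baseline / dt)), as.numeric(custom_conc))
    onset <- baseline
    offset <- baseline + (length(custom_conc) - 1) * dt
  } else {
    pulse <- switch(protocol, deactivation = 1, desensitization = 500,
                    iv_step = 200)
    n_base <- round(baseline / dt)
    n_pulse <- round(pulse / dt)
    n_tail <- round(tail / dt)
    c_raw <- c(rep(0, n_base), rep(conc, n_pulse), rep(0, n_tail + 1))
    onset <- baseline
    offset <- baseline + pulse
  }
  if (exchange_tau > 0) {
    a <- exp(-dt / exchange_tau)
    c_sm <- as.numeric(stats::filter(c_raw * (1 - a), a, method = "recursive"))
    # the filter tail decays geometrically forever; concentrations below
    # 1 nM are physically zero
    c_sm[c_sm < 1e-6] <- 0
  } else {
    c_sm <- c_raw
  }
  structure(list(dt = dt,
                 conc = c_sm,
                 time = (seq_along(c_sm) - 1) * dt,
                 onset = onset, offset = offset,
                 exchange_tau = exchange_tau,
                 protocol = protocol),
            class = "stimulus")
}

#' @exportS3Method base::print
print.stimulus <- function(x, ...) {
  cat(sprintf(
    "Stimulus '%s': %d samples at dt = %g ms (%.1f ms), peak %g mM, pulse %g-%g ms, exchange tau %g ms\n",
    x$protocol, length(x$conc), x$dt, (length(x$conc) - 1) * x$dt,
    max(x$conc), x$onset, x$offset, x$exchange_tau))
  invisible(x)
}
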