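# Stochastic ensemble simulator: independent channels stepping through a
# kinetic scheme on the sample grid of the stimulus.

#' Channel population parameters
#'
#' @param n_channels Number of channels N in the patch (integer >= 0).
#' @param gamma Unitary conductance in pS (> 0).
#' @param vh Holding potential in mV.
#' @param vr Reversal potential in mV (default 0, the conventional AMPAR
#'   assumption); must differ from `vh`.
#' @return Object of class `channel_params`.
#' @export
channel_params <- function(n_channels, gamma = 16.8, vh = -70, vr = 0) {
  if (n_channels < 0 || n_channels != round(n_channels))
    stop("n_channels must be a non-negative integer")
  if (gamma <= 0) stop("gamma must be > 0")
  if (vh == vr) stop("holding potential must differ from reversal potential")
  structure(list(n_channels = as.integer(n_channels), gamma = gamma,
                 vh = vh, vr = vr),
            class = "channel_params")
}

#' Recording-noise model
#'
#' Gaussian baseline noise plus an optional multiplicative per-sweep
#' rundown schedule scaling the channel current (not the noise), to
#' emulate slow loss of responsiveness over a long recording session.
#'
#' @param baseline_sd Baseline noise standard deviation in pA (>= 0).
#' @param rundown Either `NULL` (off), a single per-sweep decay factor
#'   `f` (sweep k scaled by `f^(k-1)`), or a vector of positive per-sweep
#'   scale factors.
#' @return Object of class `noise_model`.
#' @export
noise_model <- function(baseline_sd = 0, rundown = NULL) {
  if (baseline_sd < 0) stop("baseline_sd must be >= 0")
  if (!is.null(rundown) && any(rundown <= 0))
    stop("rundown factors must be > 0")
  structure(list(baseline_sd = baseline_sd, rundown = rundown),
            class = "noise_model")
}

rundown_factors <- function(noise, n_sweeps) {
  if (is.null(noise$rundown)) return(rep(1, n_sweeps))
  if (length(noise$rundown) == 1) return(noise$rundown^(seq_len(n_sweeps) - 1))
  if (length(noise$rundown) != n_sweeps)
    stop("rundown schedule length must equal n_sweeps")
  noise$rundown
}

#' Simulate a stochastic sweep ensemble
#'
#' Each sweep is an independent realization of `n_channels` channels, all
#' starting in the resting state, stepped on the stimulus grid as a
#' discrete-time Markov chain whose one-step transition probabilities are
#' the rows of `expm(Q dt)` at the current agonist concentration — exact
#' for piecewise-constant agonist, so the pooled channel statistics are
#' unbiased against [mean_occupancy()] at any rate the stiffness guard
#' admits.  The recorded current is
#'
#'   I(t) = n_open(t) * gamma * (vh - vr) * 1e-3   (pA)
#'
#' so inward current is negative at hyperpolarized holding potentials,
#' plus Gaussian baseline noise.  Identical seeds give bit-identical
#' ensembles.
#'
#' @param scheme A [kinetic_scheme()].
#' @param stim A [make_stimulus()] waveform.
#' @param channels A [channel_params()].
#' @param noise A [noise_model()].
#' @param n_sweeps Number of sweeps (>= 1).
#' @param seed Integer seed; required, every simulation is a pure
#'   function of (parameters, seed).
#'
#' @return A [trace_ensemble()] whose `meta` records the protocol,
#'   holding/reversal potentials, onset, seed, scheme label and rates,
#'   channel and noise parameters, and the per-sweep mean open-channel
#'   count trace (`open_mean`, the simulated ground truth).
#' @examples
#' ens <- simulate_ensemble(build_scheme("wt"),
#'                          make_stimulus("deactivation"),
#'                          channel_params(64), noise_model(1),
#'                          n_sweeps = 20, seed = 1)
#' ens
#' @export
simulate_ensemble <- function(scheme, stim, channels,
                              noise = noise_model(0), n_sweeps, seed) {
  stopifnot(inherits(scheme, "kinetic_scheme"), inherits(stim, "stimulus"),
            inherits(channels, "channel_params"), inherits(noise, "noise_model"))
  if (missing(seed) || is.null(seed)) stop("seed must be supplied")
  if (n_sweeps < 1) stop("n_sweeps must be >= 1")
  dt <- stim$dt
  if (max_exit_rate(scheme, max(stim$conc)) * dt >= 0.1)
    stop("stiffness: max total exit rate * dt must be < 0.1; reduce dt")
  set.seed(as.integer(seed))

  states <- scheme$states
  ns <- length(states)
  conc <- stim$conc
  uc <- unique(conc)
  ci <- match(conc, uc)
  # per concentration level, per origin state: destination indices and
  # exact per-channel one-step transition probabilities, taken from the
  # rows of expm(Q dt) so that multiple transitions within a step are
  # accounted for and the chain is unbiased against the master equation
  trans <- vector("list", length(uc))
  for (k in seq_along(uc)) {
    Q <- rate_matrix(scheme, uc[k])
    P <- tryCatch({
      e <- eigen(Q)
      P1 <- Re(e$vectors %*% (exp(e$values * dt) * solve(e$vectors)))
      if (any(!is.finite(P1)) || max(abs(rowSums(P1) - 1)) > 1e-10)
        stop("ill-conditioned")
      P1
    }, error = function(e) as.matrix(Matrix::expm(Q * dt)))
    P <- pmax(P, 0)
    P <- P / rowSums(P)
    lv <- vector("list", ns)
    for (j in seq_len(ns)) {
      dest <- setdiff(seq_len(ns), j)
      p <- P[j, dest]
      keep <- p > 1e-15
      if (!any(keep)) { lv[[j]] <- NULL; next }
      lv[[j]] <- list(dest = dest[keep], p = unname(p[keep]))
    }
    trans[[k]] <- lv
  }

  nt <- length(conc)
  counts <- matrix(0L, n_sweeps, ns)
  counts[, match(scheme$resting, states)] <- channels$n_channels
  cond <- which(scheme$conducting)
  open <- matrix(0L, nt, n_sweeps)
  open[1, ] <- as.integer(rowSums(counts[, cond, drop = FALSE]))
  for (t in 2:nt) {
    tp <- trans[[ci[t - 1L]]]
    moved <- matrix(0L, n_sweeps, ns)
    for (j in seq_len(ns)) {
      if (is.null(tp[[j]])) next
      n_j <- counts[, j]
      if (!any(n_j > 0L)) next
      remaining <- n_j
      pr_left <- 1
      for (m in seq_along(tp[[j]]$dest)) {
        p_m <- min(tp[[j]]$p[m] / pr_left, 1)
        x <- stats::rbinom(n_sweeps, remaining, p_m)
        moved[, tp[[j]]$dest[m]] <- moved[, tp[[j]]$dest[m]] + x
        moved[, j] <- moved[, j] - x
        remaining <- remaining - x
        pr_left <- pr_left - tp[[j]]$p[m]
      }
    }
    counts <- counts + moved
    open[t, ] <- as.integer(rowSums(counts[, cond, drop = FALSE]))
  }

  unit_i <- channels$gamma * (channels$vh - channels$vr) * 1e-3  # pA
  cur <- open * unit_i
  rf <- rundown_factors(noise, n_sweeps)
  if (any(rf != 1)) cur <- sweep(cur, 2, rf, `*`)
  if (noise$baseline_sd > 0)
    cur <- cur + matrix(stats::rnorm(nt * n_sweeps, 0, noise$baseline_sd),
                        nt, n_sweeps)
  trace_ensemble(cur, dt, meta = list(
    protocol = stim$protocol, onset = stim$onset, offset = stim$offset,
    vh = channels$vh, vr = channels$vr, gamma = channels$gamma,
    n_channels = channels$n_channels, unit_current = unit_i,
    baseline_sd = noise$baseline_sd, rundown = rf,
    seed = as.integer(seed), scheme = scheme$label,
    scheme_rates = stats::setNames(scheme$rates$rate, rownames(scheme$rates)),
    open_mean = rowMeans(open)))
}
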