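# Deterministic master-equation solution of a kinetic scheme driven by an
# agonist waveform.  Serves as the analytic oracle against which the
# stochastic simulator is checked.

#' Mean state occupancies under an agonist waveform
#'
#' Integrates the master equation dp/dt = p Q(c(t)) with the resting state
#' fully occupied at t = 0.  The concentration is treated as constant over
#' each sample interval and the solution propagated with the exact matrix
#' exponential of the corresponding generator, so the integration itself
#' is exact for piecewise-constant agonist; the only discretization error
#' is the sampling of c(t).  Propagators are cached per unique
#' concentration value.
#'
#' The fixed-step precondition `max total exit rate * dt < 0.1` shared
#' with the stochastic simulator is enforced so that trajectories from
#' both engines are always comparable on the same grid.
#'
#' @param scheme A [kinetic_scheme()].
#' @param stim A [make_stimulus()] waveform.
#'
#' @return An object of class `state_trajectory`: list with `time` (ms),
#'   `p` (samples x states occupancy matrix), `open` (summed occupancy of
#'   conducting states) and `stim`.
#' @examples
#' tr <- mean_occupancy(build_scheme("wt"),
#'                      make_stimulus("deactivation", exchange_tau = 0))
#' max(tr$open)
#' @export
mean_occupancy <- function(scheme, stim) {
  stopifnot(inherits(scheme, "kinetic_scheme"), inherits(stim, "stimulus"))
  dt <- stim$dt
  if (max_exit_rate(scheme, max(stim$conc)) * dt >= 0.1)
    stop("stiffness: max total exit rate * dt must be < 0.1; reduce dt")
  conc <- stim$conc
  uc <- unique(conc)
  ci <- match(conc, uc)
  ns <- length(scheme$states)
  props <- vector("list", length(uc))
  eigs <- vector("list", length(uc))
  for (k in seq_along(uc)) {
    Q <- rate_matrix(scheme, uc[k])
    # spectral propagator: one-step matrix and, for long
    # constant-concentration runs, p(t0 + k dt) = p(t0) V exp(Lambda k dt) V^-1
    eg <- tryCatch({
      e <- eigen(Q)
      W <- solve(e$vectors)
      P1 <- Re(e$vectors %*% (exp(e$values * dt) * W))
      if (any(!is.finite(P1)) || max(abs(rowSums(P1) - 1)) > 1e-10)
        stop("ill-conditioned")
      list(lam = e$values, V = e$vectors, W = W, P1 = P1)
    }, error = function(e) NULL)
    eigs[k] <- list(eg)          # may be NULL: fall back to expm stepping
    props[[k]] <- if (!is.null(eg)) eg$P1
                  else as.matrix(Matrix::expm(Q * dt))
  }
  nt <- length(conc)
  p <- matrix(0, nt, ns, dimnames = list(NULL, scheme$states))
  p[1, scheme$resting] <- 1
  cur <- p[1, , drop = FALSE]
  runs <- rle(ci[-nt])
  pos <- 1L                      # index of the last filled sample
  for (r in seq_along(runs$lengths)) {
    L <- runs$lengths[r]
    lev <- runs$values[r]
    eg <- eigs[[lev]]
    done <- FALSE
    if (!is.null(eg) && L > 8) {
      a <- as.vector(cur %*% eg$V)
      Et <- exp(outer((1:L) * dt, eg$lam))      # L x ns
      blk <- Re(Et %*% (a * eg$W))              # rows: p(pos + 1..L)
      if (all(is.finite(blk)) &&
          max(abs(rowSums(blk) - 1)) < 1e-9) {
        p[pos + (1:L), ] <- blk
        cur <- blk[L, , drop = FALSE]
        done <- TRUE
      }
    }
    if (!done) {
      Pstep <- props[[lev]]
      for (t in pos + (1:L)) {
        cur <- cur %*% Pstep
        p[t, ] <- cur
      }
    }
    pos <- pos + L
  }
  structure(list(time = stim$time,
                 p = p,
                 open = as.numeric(p[, scheme$conducting, drop = FALSE] %*%
                                     rep(1, sum(scheme$conducting))),
                 stim = stim, scheme_label = scheme$label),
            class = "state_trajectory")
}

#' @exportS3Method base::print
print.state_trajectory <- function(x, ...) {
  cat(sprintf(
    "State trajectory (%s): %d samples, states %s, peak open fraction %.4f\n",
    x$scheme_label, nrow(x$p), paste(colnames(x$p), collapse = " "),
    max(x$open)))
  invisible(x)
}

#' @export
plot.state_trajectory <- function(x, ...) {
  graphics::matplot(x$time, x$p, type = "l", lty = 1,
                    xlab = "time (ms)", ylab = "occupancy", ...)
  graphics::legend("topright", legend = colnames(x$p), lty = 1,
                   col = seq_len(ncol(x$p)), bty = "n")
  invisible(x)
}
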