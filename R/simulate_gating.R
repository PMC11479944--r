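#' Aligned set of current sweeps
#'
#' Container for one or more current sweeps sampled on a common uniform
#' time base, with the protocol that generated them.
#'
#' @param time sample times, ms (uniform, strictly increasing).
#' @param sweeps numeric matrix, `n_sweeps x n_samples`, pA.
#' @param protocol the [gating_protocol()] (or `NULL`).
#' @param baseline_window integer index range of the pre-stimulus baseline.
#' @export
sweep_set <- function(time, sweeps, protocol = NULL,
                      baseline_window = integer(0)) {
  if (is.vector(sweeps)) sweeps <- matrix(sweeps, nrow = 1)
  if (ncol(sweeps) != length(time))
    stop("sweeps must have one column per time sample")
  dt <- diff(time)
  if (length(dt) && (any(dt <= 0) ||
      max(abs(dt - dt[1])) > 1e-6 * max(dt[1], 1e-12)))
    stop("'time' must be strictly increasing and uniform")
  structure(list(time = time, sweeps = sweeps, protocol = protocol,
                 baseline_window = as.integer(baseline_window)),
            class = "sweep_set")
}

#' @export
print.sweep_set <- function(x, ...) {
  cat("Sweep set:", nrow(x$sweeps), "sweep(s) x", ncol(x$sweeps),
      "samples (", round(max(x$time) - min(x$time), 3), "ms )\n")
  cat("  peak |current|:", round(max(abs(x$sweeps)), 2), "pA\n")
  invisible(x)
}

#' @export
dim.sweep_set <- function(x) dim(x$sweeps)

# per-step single-channel transition matrices P_k = expm(Q(c_k, pH) * dt)
# over the protocol sample grid, using the mid-step filtered concentration.
# Cached by concentration value: after the exchange transient settles the
# same matrix is reused, so only O(exchange_tau/dt) exponentials are paid.
step_matrices <- function(scheme, protocol, pH) {
  dt <- protocol$sample_interval
  total <- sum(protocol$segments$duration)
  time <- seq(0, total, by = dt)
  n_step <- length(time) - 1L
  cmid <- agonist_concentration(protocol, time[-length(time)] + dt / 2)
  # snap the exchange-filter tail to its target so the matrix cache closes
  cmax <- max(protocol$segments$conc, 1)
  cmid[cmid < 1e-9 * cmax] <- 0
  key <- as.character(signif(cmid, 9))
  uniq <- !duplicated(key)
  mats <- vector("list", sum(uniq))
  names(mats) <- key[uniq]
  for (k in key[uniq]) {
    Q <- rate_matrix(scheme, as.numeric(k), pH)
    mats[[k]] <- as.matrix(Matrix::expm(Q * dt))
  }
  list(time = time, index = match(key, names(mats)), mats = mats,
       n_step = n_step)
}

# single-channel current of each open state, pA (pS * mV * 1e-3)
open_currents <- function(scheme, voltage)
  scheme$conductance_open * voltage * 1e-3

#' Deterministic macroscopic current from the master equation
#'
#' Solves the master equation dp/dt = Q(t)' p piecewise over the sampled
#' protocol (agonist concentration low-pass filtered by the solution
#' exchange), propagating the state occupancy with the exact interval
#' matrix exponential.  The macroscopic current is
#' `n_channels * sum_open p_open * g_open * V`.
#'
#' @param scheme a [kinetic_scheme()].
#' @param protocol a [gating_protocol()].
#' @param pH solution pH.
#' @param n_channels number of channels in the patch.
#' @param return_occupancy if `TRUE` the per-state occupancy matrix is
#'   attached as attribute `"occupancy"`.
#' @return a one-sweep [sweep_set()].
#' @export
simulate_macroscopic <- function(scheme, protocol, pH = scheme$reference_pH,
                                 n_channels = 100,
                                 return_occupancy = FALSE) {
  stopifnot(inherits(scheme, "kinetic_scheme"),
            inherits(protocol, "gating_protocol"))
  sm <- step_matrices(scheme, protocol, pH)
  nm <- names(scheme$states)
  p <- matrix(0, length(sm$time), length(nm), dimnames = list(NULL, nm))
  p[1, scheme$resting] <- 1
  for (k in seq_len(sm$n_step))
    p[k + 1, ] <- p[k, ] %*% sm$mats[[sm$index[k]]]
  bad <- abs(rowSums(p) - 1) > 1e-9
  if (any(bad))
    stop("occupancy conservation violated (|sum - 1| > 1e-9)")
  if (min(p) < -1e-9) stop("negative occupancy beyond tolerance")
  p[p < 0] <- 0
  iopen <- open_currents(scheme, protocol$holding_voltage)
  current <- n_channels *
    as.numeric(p[, names(iopen), drop = FALSE] %*% iopen)
  out <- sweep_set(sm$time, matrix(current, nrow = 1), protocol,
                   baseline_window_of(protocol, sm$time))
  if (return_occupancy) attr(out, "occupancy") <- p
  out
}

#' Stochastic channel-ensemble current sweeps
#'
#' Simulates `n_channels` independent channels per sweep as continuous-time
#' Markov chains with rates frozen per sample interval (the filtered
#' agonist concentration at mid-step).  Identical channels are aggregated
#' by state counts and propagated with multinomial draws from the exact
#' interval transition matrix, which is distributionally equivalent to
#' simulating each channel separately and far cheaper.  Gaussian background
#' noise is added per sample.
#'
#' @inheritParams simulate_macroscopic
#' @param n_sweeps number of successive sweeps (>= 2).
#' @param noise_sigma background noise s.d., pA.
#' @param seed integer seed; required (reproducibility is part of the
#'   contract).
#' @return a [sweep_set()] with `n_sweeps` rows.
#' @export
simulate_stochastic <- function(scheme, protocol, pH = scheme$reference_pH,
                                n_channels, n_sweeps, noise_sigma = 0,
                                seed) {
  stopifnot(inherits(scheme, "kinetic_scheme"),
            inherits(protocol, "gating_protocol"))
  stopifnot_scalar(n_channels, "n_channels", positive = TRUE,
                   integerish = TRUE)
  stopifnot_scalar(n_sweeps, "n_sweeps", positive = TRUE, integerish = TRUE)
  if (n_sweeps < 2) stop("'n_sweeps' must be >= 2")
  if (missing(seed)) stop("'seed' is required")
  sm <- step_matrices(scheme, protocol, pH)
  nm <- names(scheme$states)
  S <- length(nm)
  iopen <- open_currents(scheme, protocol$holding_voltage)
  open_idx <- match(names(iopen), nm)
  with_seed(seed, {
    counts <- matrix(0L, n_sweeps, S)
    counts[, match(scheme$resting, nm)] <- as.integer(n_channels)
    cur <- matrix(0, n_sweeps, length(sm$time))
    cur[, 1] <- counts[, open_idx, drop = FALSE] %*% iopen
    for (k in seq_len(sm$n_step)) {
      P <- sm$mats[[sm$index[k]]]
      new <- matrix(0L, n_sweeps, S)
      for (j in seq_len(S)) {
        rem <- counts[, j]
        if (all(rem == 0L)) next
        pleft <- 1
        for (s in seq_len(S)) {
          pr <- if (pleft > 0) P[j, s] / pleft else 1
          if (s == S || pr >= 1) {
            new[, s] <- new[, s] + rem
            break
          }
          draw <- stats::rbinom(n_sweeps, rem, max(pr, 0))
          new[, s] <- new[, s] + draw
          rem <- rem - draw
          pleft <- pleft - P[j, s]
        }
      }
      counts <- new
      cur[, k + 1] <- counts[, open_idx, drop = FALSE] %*% iopen
    }
    if (noise_sigma > 0)
      cur <- cur + matrix(stats::rnorm(length(cur), 0, noise_sigma),
                          nrow(cur), ncol(cur))
    sweep_set(sm$time, cur, protocol, baseline_window_of(protocol, sm$time))
  })
}

#' Steady-state occupancy under constant agonist
#'
#' Null vector of the transposed generator, normalized to sum 1 —
#' the infinite-time solution of the master equation.
#'
#' @inheritParams rate_matrix
#' @return named occupancy vector.
#' @export
steady_state <- function(scheme, conc, pH = scheme$reference_pH) {
  Q <- rate_matrix(scheme, conc, pH)
  # null space of Q' via the smallest right singular vector
  s <- svd(t(Q))
  v <- s$v[, ncol(s$v)]
  v <- v / sum(v)
  if (min(v) < -1e-10) stop("steady state has negative components")
  stats::setNames(pmax(v, 0) / sum(pmax(v, 0)), names(scheme$states))
}

#' Slowest relaxation eigenvalue of the liganded (bound-state) sub-generator
#'
#' Eigen-decomposition of the generator restricted to the states occupied
#' during a sustained saturating pulse (all states except the resting,
#' unbound one).  The slowest nonzero relaxation rate sets the dominant
#' macroscopic desensitization time constant; its reciprocal is returned
#' in ms.
#'
#' @inheritParams rate_matrix
#' @return named numeric: sorted relaxation time constants (ms), slowest
#'   first.
#' @export
desensitization_eigen_tau <- function(scheme, conc, pH = scheme$reference_pH) {
  Q <- rate_matrix(scheme, conc, pH)
  keep <- setdiff(names(scheme$states), scheme$resting)
  Qb <- Q[keep, keep]
  diag(Qb) <- 0
  diag(Qb) <- -rowSums(Qb)          # re-close the sub-chain on itself
  ev <- eigen(t(Qb), only.values = TRUE)$values
  ev <- Re(ev[abs(Re(ev)) > 1e-12])
  sort(-1 / ev[order(-Re(ev))], decreasing = TRUE)
}
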