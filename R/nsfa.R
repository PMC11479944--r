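#' Ensemble mean and variance of successive current responses
#'
#' Pointwise mean and unbiased variance across sweeps over the analysis
#' window — the first step of nonstationary fluctuation analysis, applied
#' to the desensitizing phase of repeated macroscopic responses.
#'
#' @param sweepset a [sweep_set()] with at least 2 (ideally >= 30) sweeps.
#' @param phase_window index range to analyse; defaults to peak-to-end of
#'   the agonist pulse (the desensitizing phase) when a protocol is
#'   present, else all samples.
#' @param min_sweeps floor below which a warning is issued (default 30,
#'   the lower end of the usual 30-100 successive responses).
#' @param successive_differences if `TRUE`, the variance is computed from
#'   scaled successive sweep differences instead of the plain ensemble
#'   variance — an option for drift-affected recordings (off by default).
#' @return object of class `ensemble_stats`: list with `time`, `mean`,
#'   `variance` (pA, pA^2) and `n_sweeps`.
#' @export
ensemble_variance <- function(sweepset, phase_window = NULL,
                              min_sweeps = 30,
                              successive_differences = FALSE) {
  stopifnot(inherits(sweepset, "sweep_set"))
  n <- nrow(sweepset$sweeps)
  if (n < 2) stop("at least 2 sweeps are required")
  if (n < min_sweeps)
    warning(sprintf("only %d sweeps; NSFA normally uses >= %d", n,
                    min_sweeps))
  if (is.null(phase_window)) {
    phase_window <- if (!is.null(sweepset$protocol)) {
      pw <- try(segment_window(sweepset$protocol, sweepset$time, "pulse"),
                silent = TRUE)
      if (inherits(pw, "try-error")) seq_along(sweepset$time) else {
        mtr <- colMeans(sweepset$sweeps[, pw, drop = FALSE])
        pw[which.max(abs(mtr)):length(pw)]
      }
    } else seq_along(sweepset$time)
  }
  sw <- sweepset$sweeps[, phase_window, drop = FALSE]
  mu <- colMeans(sw)
  v <- if (successive_differences) {
    d <- sw[-1, , drop = FALSE] - sw[-n, , drop = FALSE]
    colMeans(d^2) / 2
  } else {
    colSums(sweep(sw, 2, mu)^2) / (n - 1)
  }
  structure(list(time = sweepset$time[phase_window], mean = mu,
                 variance = v, n_sweeps = n), class = "ensemble_stats")
}

#' Parabolic variance-mean fit (nonstationary fluctuation analysis)
#'
#' Groups the ensemble variance into `n_bins` equal-width mean-current
#' amplitude bins and fits the variance-mean parabola
#' `sigma^2 = i * I - I^2 / N + sigma_B^2`,
#' where `i` is the single-channel current, `I` the mean current, `N` the
#' channel count and `sigma_B^2` the background variance.  The fit is
#' linear in `(i, 1/N, sigma_B^2)` and solved by weighted least squares;
#' bins are weighted by the inverse sampling variance of the variance
#' estimator (chi-squared based, `2 sigma^4 / (n_sweeps - 1)` per sample).
#' The weighted-mean single-channel conductance is `gamma = i / V`.
#'
#' @param stats an `ensemble_stats` object from [ensemble_variance()], or
#'   a list with `mean`, `variance` and `n_sweeps`.
#' @param n_bins number of amplitude bins (default 10).
#' @param voltage holding potential, mV (default -60).
#' @param sigma_b if given, the background variance is fixed at this value
#'   (pA^2, e.g. from the pre-pulse baseline) instead of fitted.
#' @param min_per_bin bins with fewer samples are dropped with a warning.
#' @return object of class `nsfa_fit` with `i` (pA), `N`, `sigma_b_sq`
#'   (pA^2), `gamma` (pS), binned `mean_bins` / `variance_bins`, and
#'   `valid` / `flag`.
#' @export
fit_parabola <- function(stats, n_bins = 10, voltage = -60,
                         sigma_b = NULL, min_per_bin = 3) {
  mu <- stats$mean; v <- stats$variance
  n_sweeps <- stats$n_sweeps
  if (is.null(n_sweeps)) n_sweeps <- 30
  if (diff(range(mu)) == 0)
    stop("mean trace spans no current range: cannot bin")
  br <- seq(min(mu), max(mu), length.out = n_bins + 1)
  bin <- findInterval(mu, br, rightmost.closed = TRUE)
  bin[bin > n_bins] <- n_bins
  cnt <- tabulate(bin, n_bins)
  keep <- cnt >= min_per_bin
  if (any(!keep & cnt > 0))
    warning(sprintf("%d bin(s) with < %d samples dropped",
                    sum(!keep & cnt > 0), min_per_bin))
  if (sum(keep) < 3) stop("fewer than 3 usable amplitude bins")
  mb <- as.numeric(tapply(mu, bin, mean)[as.character(which(keep))])
  # within-bin mean of I^2: binning must not distort the parabola's
  # curvature (E[I^2] != E[I]^2 inside a bin)
  m2b <- as.numeric(tapply(mu^2, bin, mean)[as.character(which(keep))])
  vb <- as.numeric(tapply(v, bin, mean)[as.character(which(keep))])
  # chi^2 sampling variance of a variance estimate, averaged within bin
  wraw <- tapply(2 * v^2 / max(n_sweeps - 1, 1), bin, mean)
  wraw <- as.numeric(wraw[as.character(which(keep))]) / cnt[keep]
  w <- if (any(wraw > 0))
    ifelse(wraw > 0, 1 / wraw, max(1 / wraw[wraw > 0]))
  else rep(1, length(wraw))

  if (is.null(sigma_b)) {
    X <- cbind(I = mb, I2 = m2b, const = 1)
    cf <- stats::lm.wfit(X, vb, w)$coefficients
    i_hat <- unname(cf["I"]); b <- unname(cf["I2"]); s_b <- unname(cf["const"])
  } else {
    X <- cbind(I = mb, I2 = m2b)
    cf <- stats::lm.wfit(X, vb - sigma_b, w)$coefficients
    i_hat <- unname(cf["I"]); b <- unname(cf["I2"]); s_b <- sigma_b
  }
  N <- if (b < 0) -1 / b else NA_real_
  flag <- NULL
  cur_sign <- sign(mb[which.max(abs(mb))])
  if (!is.finite(N) || is.na(N) || N <= 0)
    flag <- "fitted curvature non-negative: channel count undefined"
  if (is.finite(i_hat) && cur_sign != 0 && sign(i_hat) != cur_sign)
    flag <- c(flag, "single-channel current sign inconsistent with current")
  if (abs(i_hat) < 1e-12)
    flag <- c(flag, "no channel noise detected (i ~ 0)")
  structure(list(
    i = i_hat, N = N, sigma_b_sq = s_b,
    gamma = 1000 * i_hat / voltage,   # pA/mV -> pS
    holding_voltage = voltage, n_sweeps = n_sweeps,
    mean_bins = unname(mb), variance_bins = unname(vb),
    weights = unname(w), n_bins = n_bins,
    valid = is.null(flag), flag = flag), class = "nsfa_fit")
}

#' @export
print.nsfa_fit <- function(x, ...) {
  cat("Nonstationary fluctuation analysis (parabolic fit)\n")
  cat(sprintf("  i = %.4g pA, N = %.4g channels, sigma_B^2 = %.4g pA^2\n",
              x$i, x$N, x$sigma_b_sq))
  cat(sprintf("  gamma = i/V = %.4g pS at %g mV (%d sweeps, %d bins)\n",
              x$gamma, x$holding_voltage, x$n_sweeps,
              length(x$mean_bins)))
  if (!x$valid) cat("  INVALID:", paste(x$flag, collapse = "; "), "\n")
  invisible(x)
}

#' @export
coef.nsfa_fit <- function(object, ...)
  c(i = object$i, N = object$N, sigma_b_sq = object$sigma_b_sq,
    gamma = object$gamma)

#' @export
predict.nsfa_fit <- function(object, newdata = NULL, ...) {
  I <- if (is.null(newdata)) object$mean_bins else
    if (is.list(newdata)) newdata$mean else newdata
  object$i * I - I^2 / object$N + object$sigma_b_sq
}

#' @export
plot.nsfa_fit <- function(x, ...) {
  plot(x$mean_bins, x$variance_bins, pch = 16,
       xlab = "mean current (pA)", ylab = "variance (pA^2)",
       main = sprintf("i = %.3g pA, N = %.3g, gamma = %.3g pS",
                      x$i, x$N, x$gamma), ...)
  I <- seq(0, max(abs(x$mean_bins)) * sign(x$i), length.out = 200)
  graphics::lines(I, predict(x, I), col = "red", lwd = 2)
  invisible(x)
}
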