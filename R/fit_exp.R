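#' Exponential fit of a current decay with amplitude-weighted tau
#'
#' Fits `offset + sum_i A_i * exp(-(t - t0) / tau_i)` to the desensitizing
#' (or deactivating) phase of a current sweep, starting where the current
#' has decayed to 90% of its peak and ending at the end of the agonist
#' pulse.  With two components the amplitude-weighted time constant
#' `tau_w = tau_f * A_f/(A_f + A_s) + tau_s * A_s/(A_f + A_s)` is reported
#' (weights use absolute amplitudes, so inward currents work unchanged).
#'
#' @param x a [sweep_set()] (first sweep used unless `sweep` says
#'   otherwise) or a numeric current vector (then `time` is required).
#' @param time sample times, ms (only when `x` is a bare vector).
#' @param n_components 1, 2, or `NULL` to select by BIC (the second
#'   component must improve BIC by at least `delta_bic`).
#' @param pulse_window index range of the agonist pulse.  Defaults to the
#'   protocol segment labelled `"pulse"` (or `"conditioning"`).
#' @param baseline_window index range for baseline estimation; defaults to
#'   the sweep set's stored window.
#' @param blank_ms initial blanking after pulse onset to skip the
#'   solution-exchange artifact (default 0.2 ms).
#' @param delta_bic BIC margin required to accept the biexponential fit.
#' @param sweep row of the sweep matrix to fit.
#' @return an object of class `exp_fit` with components `tau` (ms, fast
#'   first), `amp` (pA), `offset`, `tau_weighted`, `n_components`,
#'   `fit_window`, `goodness` (residual variance) and `converged`.
#' @export
fit_decay <- function(x, time = NULL, n_components = NULL,
                      pulse_window = NULL, baseline_window = NULL,
                      blank_ms = 0.2, delta_bic = 10, sweep = 1L) {
  d <- as_sweep_data(x, time, sweep, pulse_window, baseline_window)
  y <- d$current; t <- d$time
  base <- if (length(d$baseline_window))
    mean(y[d$baseline_window]) else 0
  pw <- d$pulse_window
  blank <- t[pw[1]] + blank_ms
  cand <- pw[t[pw] >= blank]
  if (!length(cand)) stop("pulse window shorter than the blanking period")
  dev <- abs(y[cand] - base)
  if (max(dev) <= .Machine$double.eps^0.5 * max(abs(y), 1))
    stop("no identifiable peak: trace is flat within the pulse window")
  pk <- cand[which.max(dev)]
  peak_amp <- y[pk] - base
  # decay onset: first sample after the peak at or below 90% of the peak
  after <- cand[cand >= pk]
  below <- after[abs(y[after] - base) <= 0.9 * abs(peak_amp)]
  start <- if (length(below)) below[1] else after[min(2, length(after))]
  win <- start:pw[length(pw)]
  if (length(win) < 10)
    stop("decay window has fewer than 10 samples")
  tw <- t[win] - t[win[1]]
  yw <- y[win]
  if (diff(range(yw)) == 0) stop("no decay: constant trace in fit window")

  fits <- list()
  ks <- if (is.null(n_components)) c(1L, 2L) else as.integer(n_components)
  for (k in ks) fits[[as.character(k)]] <-
    try(fit_exp_sum(tw, yw, k), silent = TRUE)
  ok <- !vapply(fits, inherits, TRUE, "try-error")
  if (!any(ok)) stop("exponential fit did not converge")
  fits <- fits[ok]; ks <- ks[ok]
  pick <- 1L
  if (length(fits) == 2L) {
    n <- length(yw)
    bic <- vapply(seq_along(fits), function(i)
      n * log(fits[[i]]$rss / n) + log(n) * (2 * ks[i] + 1), 0)
    # a second component must be real: clearly better BIC, both
    # amplitudes decaying in the same direction, separated time scales
    f2 <- fits[[2]]
    sane <- all(sign(f2$amp) == sign(sum(f2$amp))) &&
      max(f2$tau) / min(f2$tau) > 1.5
    pick <- if (sane && bic[2] <= bic[1] - delta_bic) 2L else 1L
  }
  f <- fits[[pick]]
  ord <- order(f$tau)
  tau <- f$tau[ord]; amp <- f$amp[ord]
  structure(list(
    n_components = ks[pick], tau = tau, amp = amp, offset = f$offset,
    tau_weighted = weighted_tau(tau, amp),
    fit_window = range(win), t0 = t[win[1]],
    goodness = f$rss / max(length(yw) - (2 * ks[pick] + 1), 1),
    converged = f$converged, phase = "decay",
    time = t[win], current = yw), class = "exp_fit")
}

#' Exponential fit of the current rising phase
#'
#' Fits a single saturating exponential from the 20%-of-peak crossing to
#' the peak, the standard measure of activation speed under fast agonist
#' application.
#'
#' @inheritParams fit_decay
#' @return an `exp_fit` object (`phase = "rise"`); `tau` holds the rise
#'   time constant in ms.
#' @export
fit_rise <- function(x, time = NULL, pulse_window = NULL,
                     baseline_window = NULL, sweep = 1L) {
  d <- as_sweep_data(x, time, sweep, pulse_window, baseline_window)
  y <- d$current; t <- d$time
  base <- if (length(d$baseline_window))
    mean(y[d$baseline_window]) else 0
  pw <- d$pulse_window
  dev <- abs(y[pw] - base)
  if (max(dev) <= .Machine$double.eps^0.5 * max(abs(y), 1))
    stop("no identifiable peak in the pulse window")
  pk <- pw[which.max(dev)]
  peak_amp <- y[pk] - base
  pre <- pw[pw <= pk]
  above <- abs(y[pre] - base) >= 0.2 * abs(peak_amp)
  if (!any(above)) stop("no rising phase found before the peak")
  start <- pre[which(above)[1]]
  win <- start:pk
  if (length(win) < 4)
    stop("rise faster than the sampling interval: too few samples ",
         "between 20% of peak and peak")
  tw <- t[win] - t[win[1]]
  yw <- y[win]
  # y(t) = yinf + (y0 - yinf) exp(-t/tau), all three free
  p0 <- c(yinf = y[pk], y0 = yw[1],
          tau = max(tw[length(tw)] / 3, diff(t)[1]))
  resid_fn <- function(p)
    yw - (p[1] + (p[2] - p[1]) * exp(-tw / p[3]))
  fit <- lm_multistart(
    scaled_starts(p0, "tau"),
    lower = c(-Inf, -Inf, 1e-6), upper = c(Inf, Inf, Inf), resid_fn)
  tau <- unname(fit$par[3])
  flag <- if (tau < diff(t)[1])
    "rise time constant below one sample interval" else NULL
  structure(list(
    n_components = 1L, tau = tau, amp = unname(fit$par[2] - fit$par[1]),
    offset = unname(fit$par[1]), tau_weighted = tau,
    fit_window = range(win), t0 = t[win[1]],
    goodness = fit$deviance / max(length(yw) - 3, 1),
    converged = fit$info %in% 1:4, flag = flag, phase = "rise",
    time = t[win], current = yw), class = "exp_fit")
}

# core sum-of-exponentials least squares on (t, y), t starting at 0
fit_exp_sum <- function(t, y, k) {
  offset0 <- mean(y[t >= stats::quantile(t, 0.9)])
  a0 <- y[1] - offset0
  # crude tau from the 1/e crossing of |y - offset|
  dev <- abs(y - offset0)
  cross <- which(dev <= dev[1] / exp(1))
  tau0 <- if (length(cross)) max(t[cross[1]], diff(t)[1]) else max(t) / 3
  if (k == 1L) {
    p0 <- c(offset0, a0, tau0)
    lower <- c(-Inf, -Inf, 1e-9); upper <- rep(Inf, 3)
    model <- function(p) p[1] + p[2] * exp(-t / p[3])
    tau_ix <- 3
  } else {
    p0 <- c(offset0, 0.5 * a0, tau0 / 3, 0.5 * a0, tau0 * 3)
    lower <- c(-Inf, -Inf, 1e-9, -Inf, 1e-9); upper <- rep(Inf, 5)
    model <- function(p) p[1] + p[2] * exp(-t / p[3]) + p[4] * exp(-t / p[5])
    tau_ix <- c(3, 5)
  }
  fit <- lm_multistart(scaled_starts(p0, tau_ix), lower, upper,
                       function(p) y - model(p))
  p <- fit$par
  list(offset = p[1],
       amp = p[setdiff(seq_along(p), c(1, tau_ix))],
       tau = p[tau_ix], rss = fit$deviance,
       converged = fit$info %in% 1:4)
}

# resolve sweep input into time/current plus windows
as_sweep_data <- function(x, time, sweep, pulse_window, baseline_window) {
  if (inherits(x, "sweep_set")) {
    cur <- x$sweeps[sweep, ]
    t <- x$time
    if (is.null(baseline_window)) baseline_window <- x$baseline_window
    if (is.null(pulse_window) && !is.null(x$protocol)) {
      lab <- x$protocol$segments$label
      use <- if ("pulse" %in% lab) "pulse" else
        if ("conditioning" %in% lab) "conditioning" else
          x$protocol$segments$label[which.max(x$protocol$segments$conc)]
      pulse_window <- segment_window(x$protocol, t, use)
    }
  } else {
    if (is.null(time)) stop("'time' is required for a bare current vector")
    cur <- as.numeric(x); t <- as.numeric(time)
    if (length(cur) != length(t)) stop("time/current length mismatch")
  }
  if (is.null(pulse_window)) pulse_window <- seq_along(t)
  if (is.null(baseline_window)) baseline_window <- integer(0)
  list(time = t, current = cur, pulse_window = pulse_window,
       baseline_window = baseline_window)
}

#' @export
print.exp_fit <- function(x, ...) {
  cat(sprintf("Exponential %s fit (%d component%s)\n", x$phase,
              x$n_components, if (x$n_components > 1) "s" else ""))
  for (i in seq_along(x$tau))
    cat(sprintf("  tau%d = %.4g ms  (amplitude %.4g pA)\n",
                i, x$tau[i], x$amp[i]))
  cat(sprintf("  weighted tau = %.4g ms, offset = %.4g pA\n",
              x$tau_weighted, x$offset))
  if (!is.null(x$flag)) cat("  FLAG:", x$flag, "\n")
  if (!x$converged) cat("  WARNING: optimiser did not report convergence\n")
  invisible(x)
}

#' @export
coef.exp_fit <- function(object, ...) {
  out <- c(object$offset, object$amp, object$tau, object$tau_weighted)
  names(out) <- c("offset",
                  paste0("A", seq_along(object$amp)),
                  paste0("tau", seq_along(object$tau)), "tau_w")
  out
}

#' @export
predict.exp_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$time else
    if (is.list(newdata)) newdata$time else newdata
  tt <- t - object$t0
  if (object$phase == "rise")
    object$offset + object$amp * exp(-tt / object$tau)
  else
    object$offset +
      as.numeric(exp(-outer(tt, object$tau, "/")) %*% object$amp)
}

#' @export
residuals.exp_fit <- function(object, ...)
  object$current - predict(object)

#' @export
plot.exp_fit <- function(x, ...) {
  plot(x$time, x$current, pch = 16, cex = 0.4, col = "grey40",
       xlab = "time (ms)", ylab = "current (pA)",
       main = sprintf("%s fit, tau_w = %.3g ms", x$phase, x$tau_weighted),
       ...)
  graphics::lines(x$time, predict(x), col = "red", lwd = 2)
  invisible(x)
}
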