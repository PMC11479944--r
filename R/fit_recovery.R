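#' Recovery curve from a paired-pulse sweep series
#'
#' For each interpulse interval, the recovered fraction is
#' `(test-pulse peak - baseline) / (conditioning peak - baseline)`, each
#' peak measured against its own pre-pulse baseline (the leading baseline
#' segment for the conditioning pulse; the tail of the interpulse gap for
#' the test pulse).
#'
#' @param sweeps a list of one-sweep [sweep_set()] objects whose protocols
#'   contain segments labelled `"conditioning"`, `"gap"` and `"test"`
#'   (e.g. from [paired_pulse_protocol()] + [simulate_macroscopic()]).
#' @param blank_ms exchange-artifact blanking after each pulse onset, ms.
#' @return an object of class `recovery_curve`: data frame columns
#'   `interval` (ms) and `fraction`, plus attribute
#'   `conditioning_duration`.
#' @export
extract_recovery <- function(sweeps, blank_ms = 0.2) {
  if (inherits(sweeps, "sweep_set")) sweeps <- list(sweeps)
  rows <- lapply(sweeps, function(s) {
    if (!inherits(s, "sweep_set") || is.null(s$protocol))
      stop("each element must be a sweep_set with a protocol")
    lab <- s$protocol$segments$label
    if (!all(c("conditioning", "test", "gap") %in% lab))
      stop("protocol must annotate 'conditioning', 'gap' and 'test' segments")
    t <- s$time; y <- s$sweeps[1, ]
    cw <- segment_window(s$protocol, t, "conditioning")
    gw <- segment_window(s$protocol, t, "gap")
    tw <- segment_window(s$protocol, t, "test")
    base_c <- if (length(s$baseline_window))
      mean(y[s$baseline_window]) else 0
    # test baseline: final stretch of the gap, after the conditioning tail
    ntail <- max(3L, ceiling(length(gw) * 0.2))
    base_t <- mean(y[gw[(length(gw) - ntail + 1):length(gw)]])
    pk <- function(win, base) {
      keep <- win[t[win] >= t[win[1]] + blank_ms]
      if (!length(keep)) keep <- win
      y[keep[which.max(abs(y[keep] - base))]] - base
    }
    c(interval = sum(s$protocol$segments$duration[lab == "gap"]),
      fraction = pk(tw, base_t) / pk(cw, base_c),
      cond = sum(s$protocol$segments$duration[lab == "conditioning"]))
  })
  m <- do.call(rbind, rows)
  m <- m[order(m[, "interval"]), , drop = FALSE]
  recovery_curve(m[, "interval"], m[, "fraction"], m[1, "cond"])
}

#' Construct a recovery curve
#'
#' @param intervals interpulse intervals, ms (strictly increasing).
#' @param fractions recovered fractions (test/conditioning peak ratio).
#' @param conditioning_duration conditioning-pulse duration, ms.
#' @export
recovery_curve <- function(intervals, fractions,
                           conditioning_duration = NA_real_) {
  if (length(intervals) != length(fractions))
    stop("intervals and fractions must have equal length")
  if (any(diff(intervals) <= 0))
    stop("'intervals' must be strictly increasing")
  if (any(fractions < 0 | fractions > 1.2))
    stop("recovered fractions must lie in [0, 1.2]")
  structure(data.frame(interval = intervals, fraction = fractions),
            conditioning_duration = conditioning_duration,
            class = c("recovery_curve", "data.frame"))
}

#' Hodgkin-Huxley-type fit of recovery from desensitization
#'
#' Fits `f(t) = y0 + (ymax - y0) * (1 - exp(-k t))^m` to the recovered
#' fractions, with the slope `m` fixed (2 for the steep GluA2 recovery
#' profile, 1 — a plain single exponential — for slower receptors such as
#' GluA1).  The recovery time constant reported is `tau = 1/k`.
#'
#' @param curve a [recovery_curve()] (or data frame with columns
#'   `interval`, `fraction`).
#' @param m fixed slope, 1 or 2 (default 2).
#' @return object of class `hh_fit` with `y0`, `ymax`, `k` (1/ms),
#'   `tau` (ms), `m`, and `converged` / `flag`.
#' @export
fit_recovery_hh <- function(curve, m = 2) {
  if (!m %in% c(1, 2)) stop("'m' must be 1 or 2")
  t <- curve$interval; y <- curve$fraction
  if (length(t) < 4) stop("at least 4 interval points are required")
  k0 <- 1 / max(stats::median(t), 1e-6)
  p0 <- c(y0 = max(min(y), 0), ymax = max(y), k = k0)
  fit <- lm_multistart(
    scaled_starts(p0, "k"),
    lower = c(-Inf, -Inf, 1e-9), upper = c(Inf, Inf, Inf),
    function(p) y - (p[1] + (p[2] - p[1]) * (1 - exp(-p[3] * t))^m))
  p <- fit$par
  flag <- NULL
  if (p["k"] <= 1e-9) flag <- "rate constant pinned at zero: fit failed"
  if (p["ymax"] < p["y0"]) flag <- c(flag, "ymax below y0")
  structure(list(
    y0 = unname(p["y0"]), ymax = unname(p["ymax"]), k = unname(p["k"]),
    tau = unname(1 / p["k"]), m = m,
    goodness = fit$deviance / max(length(y) - 3, 1),
    converged = fit$info %in% 1:4 && is.null(flag), flag = flag,
    curve = curve), class = "hh_fit")
}

#' @export
print.hh_fit <- function(x, ...) {
  cat(sprintf(
    "Hodgkin-Huxley recovery fit (m = %d)\n  tau = 1/k = %.4g ms  (k = %.4g /ms)\n  y0 = %.4g, ymax = %.4g\n",
    x$m, x$tau, x$k, x$y0, x$ymax))
  if (!is.null(x$flag)) cat("  FLAG:", paste(x$flag, collapse = "; "), "\n")
  invisible(x)
}

#' @export
coef.hh_fit <- function(object, ...)
  c(y0 = object$y0, ymax = object$ymax, k = object$k, tau = object$tau)

#' @export
predict.hh_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$curve$interval else
    if (is.list(newdata)) newdata$interval else newdata
  object$y0 + (object$ymax - object$y0) *
    (1 - exp(-object$k * t))^object$m
}

#' @export
plot.hh_fit <- function(x, ...) {
  plot(x$curve$interval, x$curve$fraction, pch = 16,
       xlab = "interpulse interval (ms)", ylab = "recovered fraction",
       main = sprintf("recovery, tau = %.3g ms (m = %d)", x$tau, x$m), ...)
  tt <- seq(0, max(x$curve$interval), length.out = 200)
  graphics::lines(tt, predict(x, tt), col = "red", lwd = 2)
  invisible(x)
}
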