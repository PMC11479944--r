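#' FRAP trace container
#'
#' Raw fluorescence time series of the bleached ROI, a distant
#' non-photobleached reference ROI, and the background, with the index of
#' the first post-bleach frame.
#'
#' @param time acquisition times, s (increasing).
#' @param roi,reference,background fluorescence, arbitrary units.
#' @param bleach_index index of the first post-bleach frame (> 1, so at
#'   least one pre-bleach frame exists).
#' @param normalized optional normalized vector (filled by
#'   [normalize_frap()]).
#' @export
frap_trace <- function(time, roi, reference, background,
                       bleach_index, normalized = NULL) {
  n <- length(time)
  if (any(lengths(list(roi, reference, background)) != n))
    stop("all channels must have the same length as 'time'")
  if (any(diff(time) <= 0)) stop("'time' must be increasing")
  stopifnot_scalar(bleach_index, "bleach_index", positive = TRUE,
                   integerish = TRUE)
  if (bleach_index < 2 || bleach_index > n)
    stop("'bleach_index' must leave >= 1 pre-bleach frame")
  structure(list(time = time, roi = roi, reference = reference,
                 background = background,
                 bleach_index = as.integer(bleach_index),
                 normalized = normalized), class = "frap_trace")
}

#' @export
print.frap_trace <- function(x, ...) {
  cat("FRAP trace:", x$bleach_index - 1L, "pre- and",
      length(x$time) - x$bleach_index + 1L, "post-bleach frames\n")
  if (!is.null(x$normalized)) cat("  (normalized)\n")
  invisible(x)
}

#' Synthetic FRAP trace with acquisition bleaching
#'
#' Emulates a spine FRAP acquisition: `pre_frames` images, a bleach event,
#' then `post_frames` images at fixed intervals.  The ROI recovers as
#' `plateau * (1 - exp(-t/tau))` (t from the first post-bleach frame);
#' every acquired image additionally bleaches all fluorophores by
#' `acquisition_bleach_rate`, which affects the ROI and the reference
#' identically and is what the double normalization must remove.  Gaussian
#' noise is added per channel.
#'
#' @param plateau recovery plateau (mobile-fraction proxy), in \[0, 1\].
#' @param tau recovery time constant, s.
#' @param pre_frames,post_frames frames before/after the bleach
#'   (defaults 3 and 20).
#' @param frame_interval s between frames (default 30).
#' @param acquisition_bleach_rate per-frame fractional fluorescence loss
#'   from imaging.
#' @param noise_sigma noise s.d. on the normalized (pre-bleach = 1) scale.
#' @param seed integer seed (required when `noise_sigma > 0`).
#' @param scale fluorescence units per normalized unit (arbitrary).
#' @param background constant background level, same units as `scale`.
#' @return a [frap_trace()].
#' @export
generate_frap_trace <- function(plateau, tau, pre_frames = 3,
                                post_frames = 20, frame_interval = 30,
                                acquisition_bleach_rate = 0,
                                noise_sigma = 0, seed = NULL,
                                scale = 1000, background = 100) {
  if (plateau < 0 || plateau > 1) stop("'plateau' must be in [0, 1]")
  stopifnot_scalar(tau, "tau", positive = TRUE)
  n <- pre_frames + post_frames
  time <- (seq_len(n) - 1) * frame_interval
  t_post <- (seq_len(post_frames) - 1) * frame_interval
  ideal <- c(rep(1, pre_frames), plateau * (1 - exp(-t_post / tau)))
  decay <- (1 - acquisition_bleach_rate)^(seq_len(n) - 1)
  roi <- ideal * decay
  ref <- decay
  bg <- rep(0, n)
  if (noise_sigma > 0) {
    noise <- with_seed(seed,
      matrix(stats::rnorm(3 * n, 0, noise_sigma), n, 3))
    roi <- roi + noise[, 1]; ref <- ref + noise[, 2]; bg <- bg + noise[, 3]
  }
  frap_trace(time, scale * roi + background, scale * ref + background,
             scale * bg + background, bleach_index = pre_frames + 1L)
}

#' Double normalization of a FRAP trace
#'
#' Background-subtracts the ROI and reference, divides the ROI by the
#' reference (removing acquisition bleaching, which hits both equally),
#' and scales by the pre-bleach mean so the normalized pre-bleach level is
#' exactly 1.  `method = "fullscale"` additionally pins the first
#' post-bleach frame to 0 (full-scale normalization), so the curve reads
#' directly as recovered fraction of the bleached signal.
#'
#' @param trace a [frap_trace()].
#' @param method `"double"` (default) or `"fullscale"`.
#' @return the trace with `normalized` filled.
#' @export
normalize_frap <- function(trace, method = c("double", "fullscale")) {
  stopifnot(inherits(trace, "frap_trace"))
  method <- match.arg(method)
  ref <- trace$reference - trace$background
  if (any(ref <= 0))
    stop("reference minus background is non-positive at frame(s) ",
         paste(which(ref <= 0), collapse = ", "))
  norm <- (trace$roi - trace$background) / ref
  pre <- seq_len(trace$bleach_index - 1L)
  norm <- norm / mean(norm[pre])
  if (method == "fullscale") {
    f0 <- norm[trace$bleach_index]
    if (abs(1 - f0) < .Machine$double.eps^0.5)
      stop("no bleach depth: full-scale normalization undefined")
    norm <- (norm - f0) / (1 - f0)
  }
  trace$normalized <- norm
  trace$normalization <- method
  trace
}

#' Single-exponential FRAP recovery fit
#'
#' Fits `F(t) = F0 + (plateau - F0) * (1 - exp(-t/tau))` to the
#' normalized post-bleach frames, with t measured from the first
#' post-bleach frame and `F0` free (not pinned to the noisy first frame).
#' The plateau approximates the mobile fraction.
#'
#' @param trace a normalized [frap_trace()] (run [normalize_frap()]
#'   first; a trace with `normalized` absent is normalized with defaults).
#' @param readout_times times (s after bleach) at which the fitted
#'   recovered fraction is reported (default 630 s).
#' @return object of class `frap_fit` with `plateau`, `tau` (s), `F0`,
#'   `recovery_at` (named vector) and `converged` / `flag`.
#' @export
fit_frap <- function(trace, readout_times = 630) {
  stopifnot(inherits(trace, "frap_trace"))
  if (is.null(trace$normalized)) trace <- normalize_frap(trace)
  post <- trace$bleach_index:length(trace$time)
  if (length(post) < 5) stop("at least 5 post-bleach frames are required")
  t <- trace$time[post] - trace$time[trace$bleach_index]
  y <- trace$normalized[post]
  p0 <- c(F0 = y[1], plateau = mean(y[max(1, length(y) - 3):length(y)]),
          tau = max(t[length(t)] / 3, diff(t)[1]))
  fit <- lm_multistart(
    scaled_starts(p0, "tau"),
    lower = c(-Inf, -Inf, 1e-9), upper = c(Inf, Inf, Inf),
    function(p) y - (p[1] + (p[2] - p[1]) * (1 - exp(-t / p[3]))))
  p <- fit$par
  flag <- NULL
  if (abs(p["plateau"] - p["F0"]) < 1e-6 * max(abs(y), 1))
    flag <- "no recovery amplitude: tau unidentifiable"
  if (p["plateau"] < 0 || p["plateau"] > 1.2)
    flag <- c(flag, "plateau outside [0, 1.2]")
  ra <- p["F0"] + (p["plateau"] - p["F0"]) *
    (1 - exp(-readout_times / p["tau"]))
  structure(list(
    plateau = unname(p["plateau"]), tau = unname(p["tau"]),
    F0 = unname(p["F0"]),
    recovery_at = stats::setNames(unname(ra), readout_times),
    goodness = fit$deviance / max(length(y) - 3, 1),
    converged = fit$info %in% 1:4 && is.null(flag), flag = flag,
    time = t, normalized = y), class = "frap_fit")
}

#' @export
print.frap_fit <- function(x, ...) {
  cat(sprintf(
    "FRAP exponential fit\n  plateau (mobile fraction) = %.3g, tau = %.4g s, F0 = %.3g\n",
    x$plateau, x$tau, x$F0))
  for (nm in names(x$recovery_at))
    cat(sprintf("  recovery at %s s: %.3g\n", nm, x$recovery_at[[nm]]))
  if (!is.null(x$flag)) cat("  FLAG:", paste(x$flag, collapse = "; "), "\n")
  invisible(x)
}

#' @export
coef.frap_fit <- function(object, ...)
  c(plateau = object$plateau, tau = object$tau, F0 = object$F0)

#' @export
predict.frap_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$time else
    if (is.list(newdata)) newdata$time else newdata
  object$F0 + (object$plateau - object$F0) * (1 - exp(-t / object$tau))
}

#' @export
plot.frap_fit <- function(x, ...) {
  plot(x$time, x$normalized, pch = 16,
       xlab = "time after bleach (s)", ylab = "normalized fluorescence",
       main = sprintf("plateau = %.3g, tau = %.3g s", x$plateau, x$tau),
       ...)
  tt <- seq(0, max(x$time), length.out = 200)
  graphics::lines(tt, predict(x, tt), col = "red", lwd = 2)
  invisible(x)
}
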