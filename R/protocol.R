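#' Fast-application stimulation protocol
#'
#' A protocol is a sequence of solution segments (duration, agonist
#' concentration) applied to a patch held at a fixed voltage.  The finite
#' speed of the theta-tube solution exchange is modelled as a first-order
#' low-pass on the concentration with time constant `exchange_tau`
#' (default 0.12 ms, i.e. a ~120 us exchange).
#'
#' @param segments data frame with columns `duration` (ms), `conc` (mM) and
#'   optionally `label` (e.g. `"conditioning"`, `"test"` for paired-pulse
#'   protocols).
#' @param holding_voltage membrane potential, mV (default -60).
#' @param exchange_tau solution-exchange time constant, ms.
#' @param sample_interval sampling interval of the simulated current, ms.
#' @return an object of class `gating_protocol`.
#' @export
gating_protocol <- function(segments, holding_voltage = -60,
                            exchange_tau = 0.12, sample_interval = 0.05) {
  segments <- as.data.frame(segments)
  if (!all(c("duration", "conc") %in% names(segments)))
    stop("'segments' needs columns duration and conc")
  if (is.null(segments$label)) segments$label <- ""
  if (any(segments$duration <= 0)) stop("segment durations must be > 0")
  if (any(segments$conc < 0)) stop("concentrations must be >= 0")
  stopifnot_scalar(sample_interval, "sample_interval", positive = TRUE)
  if (exchange_tau < 0) stop("'exchange_tau' must be >= 0")
  structure(list(segments = segments, holding_voltage = holding_voltage,
                 exchange_tau = exchange_tau,
                 sample_interval = sample_interval),
            class = "gating_protocol")
}

#' Single agonist pulse protocol
#'
#' Baseline / pulse / wash, the protocol used for desensitization (200-ms
#' pulses) and deactivation (1-ms pulses) measurements.
#'
#' @param pre,pulse,post segment durations, ms.
#' @param conc pulse glutamate concentration, mM.
#' @param ... passed to [gating_protocol()].
#' @export
pulse_protocol <- function(pre = 10, pulse = 200, post = 50, conc = 10, ...) {
  gating_protocol(data.frame(
    duration = c(pre, pulse, post), conc = c(0, conc, 0),
    label = c("baseline", "pulse", "wash")), ...)
}

#' Paired-pulse recovery protocol
#'
#' A conditioning glutamate pulse followed, after a variable interpulse
#' interval, by a brief test pulse — the standard two-pulse protocol for
#' measuring recovery from desensitization.  One protocol is returned per
#' interval.
#'
#' @param intervals interpulse intervals, ms.
#' @param conditioning conditioning-pulse duration, ms (default 200).
#' @param test test-pulse duration, ms (default 15).
#' @param conc glutamate concentration, mM (default 10).
#' @param pre baseline before the conditioning pulse, ms.
#' @param post wash after the test pulse, ms.
#' @param ... passed to [gating_protocol()].
#' @return a list of `gating_protocol` objects, one per interval, each
#'   with segments labelled `conditioning` and `test`.
#' @export
paired_pulse_protocol <- function(intervals, conditioning = 200, test = 15,
                                  conc = 10, pre = 10, post = 20, ...) {
  if (any(intervals <= 0)) stop("intervals must be > 0")
  lapply(intervals, function(iv)
    gating_protocol(data.frame(
      duration = c(pre, conditioning, iv, test, post),
      conc = c(0, conc, 0, conc, 0),
      label = c("baseline", "conditioning", "gap", "test", "wash")), ...))
}

#' Agonist concentration seen by the patch
#'
#' Piecewise-analytic solution of the first-order exchange filter applied
#' to the command concentration steps.
#'
#' @param protocol a [gating_protocol()].
#' @param t times, ms (from protocol start).
#' @return concentrations, mM, at `t`.
#' @export
agonist_concentration <- function(protocol, t) {
  seg <- protocol$segments
  tau <- protocol$exchange_tau
  bounds <- c(0, cumsum(seg$duration))
  # concentration at each segment start (filter state), then analytic decay
  c0 <- numeric(nrow(seg) + 1)
  c0[1] <- seg$conc[1]    # assume equilibrated at the first segment's level
  for (k in seq_len(nrow(seg)))
    c0[k + 1] <- if (tau > 0)
      seg$conc[k] + (c0[k] - seg$conc[k]) * exp(-seg$duration[k] / tau)
    else seg$conc[k]
  out <- numeric(length(t))
  idx <- findInterval(t, bounds, rightmost.closed = TRUE)
  idx[idx < 1] <- 1; idx[idx > nrow(seg)] <- nrow(seg)
  for (k in unique(idx)) {
    sel <- idx == k
    dt <- t[sel] - bounds[k]
    out[sel] <- if (tau > 0)
      seg$conc[k] + (c0[k] - seg$conc[k]) * exp(-dt / tau)
    else seg$conc[k]
  }
  out
}

#' @export
print.gating_protocol <- function(x, ...) {
  cat("Gating protocol:", nrow(x$segments), "segments,",
      sum(x$segments$duration), "ms total\n")
  cat("  holding", x$holding_voltage, "mV; exchange tau",
      x$exchange_tau, "ms; sampled every", x$sample_interval, "ms\n")
  print(x$segments, row.names = FALSE)
  invisible(x)
}

# index range of the pre-pulse baseline (all samples in the leading
# zero-concentration segment, if any)
baseline_window_of <- function(protocol, time) {
  seg <- protocol$segments
  if (seg$conc[1] != 0) return(integer(0))
  which(time < seg$duration[1])
}

# sample-index window of a labelled segment (label match, first occurrence
# unless which= selects another)
segment_window <- function(protocol, time, label, which = 1L) {
  seg <- protocol$segments
  bounds <- c(0, cumsum(seg$duration))
  hits <- which(seg$label == label)
  if (length(hits) < which)
    stop(sprintf("protocol has no segment labelled '%s' (#%d)", label, which))
  k <- hits[which]
  which(time >= bounds[k] & time < bounds[k + 1])
}
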