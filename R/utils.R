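# internal helpers shared across modules

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards so seeded generators are pure
#' functions of (inputs, seed) and never perturb the global stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed) || !is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("a single integer 'seed' is required for every stochastic generator",
         call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

stopifnot_scalar <- function(x, name, positive = FALSE, integerish = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  if (integerish && abs(x - round(x)) > 1e-8)
    stop(sprintf("'%s' must be a whole number", name), call. = FALSE)
  invisible(x)
}

#' Amplitude-weighted mean of exponential time constants
#'
#' `tau_w = tau_f * A_f/(A_f + A_s) + tau_s * A_s/(A_f + A_s)`, the
#' standard way a biexponential desensitization (or deactivation) decay
#' is condensed to one number.  Absolute amplitudes are used, so inward
#' (negative) currents need no sign handling; with a single component (or
#' one amplitude equal to 0) it collapses to that component's tau.
#'
#' @param taus time constants, ms.
#' @param amps corresponding amplitudes (any common unit).
#' @return weighted time constant, ms.
#' @export
weighted_tau <- function(taus, amps) {
  if (length(taus) != length(amps))
    stop("'taus' and 'amps' must have equal length")
  w <- abs(amps)
  if (sum(w) == 0) return(NA_real_)
  sum(taus * w) / sum(w)
}
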