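# shared nonlinear least-squares machinery: bounded Levenberg-Marquardt
# (minpack.lm) with a small deterministic multi-start to dodge local minima

lm_multistart <- function(starts, lower, upper, resid_fn, ftol = 1e-10) {
  best <- NULL
  for (p0 in starts) {
    p0 <- pmin(pmax(p0, lower), upper)
    fit <- try(minpack.lm::nls.lm(
      par = p0, lower = lower, upper = upper, fn = resid_fn,
      control = minpack.lm::nls.lm.control(
        ftol = ftol, ptol = 1e-12, maxiter = 500)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) stop("least-squares optimisation failed from all starts")
  best
}

# scale a base start by factors to obtain deterministic multi-starts on
# selected (positive) parameters
scaled_starts <- function(p0, which, factors = c(1, 0.3, 3)) {
  lapply(factors, function(f) { p <- p0; p[which] <- p[which] * f; p })
}
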