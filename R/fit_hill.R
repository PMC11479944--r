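#' Hill fit of a dose-response relationship
#'
#' Fits `I = Imax * [A]^nH / ([A]^nH + EC50^nH)` to peak responses at a
#' series of agonist concentrations, optionally after normalizing all
#' responses to the response at a stated concentration (the convention
#' used for pooling cells).
#'
#' @param doses agonist concentrations, mM (>= 4 values spanning the
#'   half-maximal region).
#' @param responses peak responses, pA (or normalized units).
#' @param normalize_to if not `NULL`, divide all responses by the response
#'   at this concentration (must be one of `doses`).
#' @return object of class `hill_fit` with `I_max`, `EC50` (mM), `n_H`,
#'   standard errors, and `flag` when the dose range identifies EC50
#'   poorly.
#' @export
fit_dose_response <- function(doses, responses, normalize_to = NULL) {
  if (length(doses) != length(responses))
    stop("doses and responses must have equal length")
  if (length(doses) < 4) stop("at least 4 dose points are required")
  if (any(doses <= 0)) stop("doses must be > 0")
  if (!is.null(normalize_to)) {
    i <- which(abs(doses - normalize_to) < 1e-12)
    if (!length(i)) stop("'normalize_to' must be one of the doses")
    responses <- responses / responses[i[1]]
  }
  if (diff(range(responses)) == 0)
    stop("responses show no dose dependence: Hill fit is degenerate")
  sgn <- sign(responses[which.max(abs(responses))])
  y <- responses * sgn   # fit on positive scale, restore sign afterwards
  p0 <- c(Imax = max(y), EC50 = exp(mean(log(range(doses)))), nH = 1)
  hill <- function(p) p[1] * doses^p[3] / (doses^p[3] + p[2]^p[3])
  fit <- lm_multistart(
    scaled_starts(p0, "EC50"),
    lower = c(1e-12, 1e-9, 1e-3), upper = c(Inf, Inf, 20),
    function(p) y - hill(p))
  p <- fit$par
  # asymptotic standard errors from the LM Jacobian
  se <- rep(NA_real_, 3)
  cv <- try({
    s2 <- fit$deviance / max(length(y) - 3, 1)
    sqrt(diag(s2 * solve(fit$hessian)))
  }, silent = TRUE)
  if (!inherits(cv, "try-error")) se <- cv
  flag <- NULL
  if (p["EC50"] < min(doses) || p["EC50"] > max(doses))
    flag <- "EC50 outside the tested dose range"
  if (is.finite(se[2]) && se[2] > 0.5 * p["EC50"])
    flag <- c(flag, "EC50 poorly constrained (SE > 50%)")
  structure(list(
    I_max = unname(sgn * p["Imax"]), EC50 = unname(p["EC50"]),
    n_H = unname(p["nH"]), se = stats::setNames(se, c("I_max", "EC50", "n_H")),
    doses = doses, responses = responses,
    goodness = fit$deviance / max(length(y) - 3, 1),
    converged = fit$info %in% 1:4, flag = flag), class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("Hill fit\n  EC50 = %.4g mM, n_H = %.3g, I_max = %.4g\n",
              x$EC50, x$n_H, x$I_max))
  if (!is.null(x$flag)) cat("  FLAG:", paste(x$flag, collapse = "; "), "\n")
  invisible(x)
}

#' @export
coef.hill_fit <- function(object, ...)
  c(I_max = object$I_max, EC50 = object$EC50, n_H = object$n_H)

#' @export
predict.hill_fit <- function(object, newdata = NULL, ...) {
  a <- if (is.null(newdata)) object$doses else
    if (is.list(newdata)) newdata$doses else newdata
  object$I_max * a^object$n_H / (a^object$n_H + object$EC50^object$n_H)
}

#' @export
plot.hill_fit <- function(x, ...) {
  plot(x$doses, x$responses, log = "x", pch = 16,
       xlab = "[glutamate] (mM)", ylab = "response",
       main = sprintf("EC50 = %.3g mM, nH = %.3g", x$EC50, x$n_H), ...)
  a <- exp(seq(log(min(x$doses)), log(max(x$doses)), length.out = 200))
  graphics::lines(a, predict(x, a), col = "red", lwd = 2)
  invisible(x)
}
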