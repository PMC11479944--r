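test_that("noiseless exponential decays are recovered exactly", {
  d <- make_decay(14.3, -100)
  f <- fit_decay(d$current, d$time)
  expect_equal(f$n_components, 1L)
  expect_equal(f$tau_weighted, 14.3, tolerance = 1e-6)

  # biexponential: both taus recovered; reported tau_w is consistent with
  # the amplitude-weighted formula applied to the fitted coefficients
  d2 <- make_decay(c(4, 20), c(-0.6, -0.4))
  f2 <- fit_decay(d2$current, d2$time)
  expect_equal(f2$n_components, 2L)
  expect_equal(sort(f2$tau), c(4, 20), tolerance = 1e-6)
  expect_equal(f2$tau_weighted, weighted_tau(f2$tau, f2$amp),
               tolerance = 1e-12)
})

test_that("the weighted-tau formula matches hand evaluation", {
  expect_equal(weighted_tau(c(4, 20), c(0.6, 0.4)), 10.4)
  expect_equal(weighted_tau(c(4, 20), c(-0.6, -0.4)), 10.4)  # inward sign
  # collapses to the single tau when one amplitude vanishes
  expect_equal(weighted_tau(c(4, 20), c(0.6, 0)), 4)
  expect_equal(weighted_tau(14.3, -250), 14.3)
})

test_that("degenerate decay inputs raise errors", {
  t <- seq(0, 50, by = 0.1)
  expect_error(fit_decay(rep(5, length(t)), t), "peak|decay")
  expect_error(fit_decay(exp(-t / 5), t[-1]), "length mismatch")
  d <- make_decay(5, -10, dt = 1, t_end = 5)
  expect_error(fit_decay(d$current, d$time), "fewer than 10")
})

test_that("fitters are invariant to uniform current rescaling", {
  d <- make_decay(c(4, 20), c(-0.6, -0.4))
  f1 <- fit_decay(d$current, d$time)
  f2 <- fit_decay(100 * d$current, d$time)
  expect_equal(f2$tau, f1$tau, tolerance = 1e-8)
  expect_equal(f2$tau_weighted, f1$tau_weighted, tolerance = 1e-8)
  expect_equal(f2$amp, 100 * f1$amp, tolerance = 1e-6)
})

test_that("rise time constant is recovered, and a step input is degenerate", {
  t <- seq(0, 3, by = 0.01)
  y <- -80 * (1 - exp(-t / 0.2))
  f <- fit_rise(y, t)
  expect_equal(f$tau, 0.2, tolerance = 1e-6)
  step <- c(rep(0, 5), rep(-80, 200))
  ts <- seq_along(step) * 0.01
  expect_error(fit_rise(step, ts), "too few samples|rising")
})

test_that("rise fitting tolerates 1% noise within 10% median error", {
  t <- seq(0, 3, by = 0.01)
  errs <- vapply(1:100, function(i) {
    set.seed(i)
    y <- -80 * (1 - exp(-t / 0.2)) + rnorm(length(t), 0, 0.8)
    f <- try(fit_rise(y, t), silent = TRUE)
    if (inherits(f, "try-error")) return(NA_real_)
    abs(f$tau - 0.2) / 0.2
  }, 0)
  expect_lt(median(errs, na.rm = TRUE), 0.10)
})

test_that("Hodgkin-Huxley recovery fit round-trips noiseless data", {
  t <- c(5, 10, 15, 20, 30, 40, 60, 80, 120, 200, 300)
  k <- 1 / 15.6
  y <- (1 - exp(-k * t))^2
  f <- fit_recovery_hh(recovery_curve(t, y), m = 2)
  expect_equal(f$tau, 15.6, tolerance = 1e-6)
  expect_equal(f$y0, 0, tolerance = 1e-6)
  expect_equal(f$ymax, 1, tolerance = 1e-6)
  # limits of the fitted function
  expect_equal(predict(f, 0), f$y0, tolerance = 1e-12)
  expect_equal(predict(f, 1e9), f$ymax, tolerance = 1e-9)
  # analytic identity: normalized f(1/k) = (1 - 1/e)^m
  expect_equal((predict(f, 1 / f$k) - f$y0) / (f$ymax - f$y0),
               (1 - exp(-1))^2, tolerance = 1e-9)
})

test_that("slope-1 recovery fit equals an independent single-exponential fit", {
  t <- c(5, 10, 20, 40, 80, 150, 300)
  set.seed(42)
  y <- 0.1 + 0.85 * (1 - exp(-t / 30)) + rnorm(length(t), 0, 0.01)
  f <- fit_recovery_hh(recovery_curve(t, pmin(pmax(y, 0), 1.2)), m = 1)
  ref <- stats::nls(y ~ y0 + (ymax - y0) * (1 - exp(-t / tau)),
                    start = list(y0 = 0, ymax = 1, tau = 20))
  expect_equal(f$tau, unname(coef(ref)["tau"]), tolerance = 1e-4)
})

test_that("Hill fit round-trips and honors the half-maximum identity", {
  doses <- exp(seq(log(0.01), log(10), length.out = 6))
  y <- 900 * doses^1.3 / (doses^1.3 + 0.27^1.3)
  f <- fit_dose_response(doses, y)
  expect_equal(f$EC50, 0.27, tolerance = 1e-6)
  expect_equal(f$n_H, 1.3, tolerance = 1e-6)
  expect_equal(predict(f, f$EC50), f$I_max / 2, tolerance = 1e-9)
  # normalization to the 10 mM response
  fn <- fit_dose_response(doses, y, normalize_to = 10)
  expect_equal(fn$EC50, 0.27, tolerance = 1e-6)
  # flat responses are degenerate
  expect_error(fit_dose_response(doses, rep(1, 6)), "no dose dependence")
})
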