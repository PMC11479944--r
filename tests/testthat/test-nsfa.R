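test_that("ensemble statistics behave on degenerate and pure-noise inputs", {
  t <- seq(0, 10, by = 0.1)
  one <- sin(t) * 5
  ss <- sweep_set(t, matrix(rep(one, 40), nrow = 40, byrow = TRUE))
  st <- ensemble_variance(ss, min_sweeps = 30)
  expect_true(all(st$variance == 0))
  expect_equal(st$mean, one)

  set.seed(5)
  noise <- matrix(rnorm(100 * length(t), 0, 2), nrow = 100)
  stn <- ensemble_variance(sweep_set(t, noise))
  expect_equal(mean(stn$variance), 4, tolerance = 0.1)
  expect_true(all(abs(stn$variance - 4) / 4 < 0.8))

  expect_error(ensemble_variance(sweep_set(t, matrix(one, nrow = 1))),
               "at least 2 sweeps")
})

test_that("closed-form binomial variance bins are recovered exactly", {
  i <- -1.2; N <- 64; sb <- 0.5
  p <- seq(0.002, 0.6, length.out = 400)
  mu <- N * i * p
  v <- N * i^2 * p * (1 - p) + sb
  fit <- fit_parabola(list(mean = mu, variance = v, n_sweeps = 100),
                      voltage = -60)
  expect_true(fit$valid)
  expect_equal(fit$i, i, tolerance = 1e-8)
  expect_equal(fit$N, N, tolerance = 1e-8)
  expect_equal(fit$sigma_b_sq, sb, tolerance = 1e-8)
  # conductance identity gamma * V = i (gamma in pS, V in mV, i in pA)
  expect_equal(fit$gamma * fit$holding_voltage * 1e-3, fit$i,
               tolerance = 1e-12)
  expect_equal(fit$gamma, 20, tolerance = 1e-8)
})

test_that("constant variance (no channel noise) is flagged invalid", {
  mu <- seq(-60, -1, length.out = 200)
  v <- rep(0.5, 200)
  fit <- fit_parabola(list(mean = mu, variance = v, n_sweeps = 50),
                      voltage = -60)
  expect_false(fit$valid)
  expect_lt(abs(fit$i), 1e-6)
})

test_that("stochastic ensembles recover single-channel parameters", {
  scheme <- glua2_scheme()      # 20 pS; -60 mV gives i = -1.2 pA
  p <- pulse_protocol(pre = 5, pulse = 200, post = 5,
                      sample_interval = 0.1)
  sw <- simulate_stochastic(scheme, p, n_channels = 64, n_sweeps = 100,
                            noise_sigma = 0.7, seed = 202)
  fit <- fit_parabola(ensemble_variance(sw), voltage = -60)
  expect_true(fit$valid)
  expect_lt(abs(fit$i - (-1.2)) / 1.2, 0.2)
  expect_lt(abs(fit$N - 64) / 64, 0.35)
})

test_that("variance traces follow the binomial parabola on simulated data", {
  scheme <- glua2_scheme()
  p <- pulse_protocol(pre = 2, pulse = 120, post = 2,
                      sample_interval = 0.1)
  sw <- simulate_stochastic(scheme, p, n_channels = 64, n_sweeps = 300,
                            noise_sigma = 0, seed = 99)
  st <- ensemble_variance(sw)
  # oracle: binomial variance from the master-equation open probability
  m <- simulate_macroscopic(scheme, p, n_channels = 1,
                            return_occupancy = TRUE)
  po <- attr(m, "occupancy")[, "O"]
  keep <- match(signif(st$time, 9), signif(m$time, 9))
  i1 <- -1.2
  pred <- 64 * i1^2 * po[keep] * (1 - po[keep])
  sel <- po[keep] > 0.05
  expect_lt(median(abs(st$variance[sel] - pred[sel]) / pred[sel]), 0.2)
})
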