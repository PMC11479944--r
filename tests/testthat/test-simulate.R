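scheme <- glua2_scheme()

test_that("macroscopic simulation conserves occupancy and is deterministic", {
  p <- pulse_protocol(pulse = 50, post = 20, sample_interval = 0.1)
  m1 <- simulate_macroscopic(scheme, p, n_channels = 100,
                             return_occupancy = TRUE)
  occ <- attr(m1, "occupancy")
  expect_lt(max(abs(rowSums(occ) - 1)), 1e-9)
  expect_gte(min(occ), 0)
  m2 <- simulate_macroscopic(scheme, p, n_channels = 100)
  expect_identical(m1$sweeps, m2$sweeps)  # bitwise determinism
})

test_that("zero agonist throughout gives an identically zero current", {
  p <- gating_protocol(data.frame(duration = c(10, 50), conc = c(0, 0)),
                       sample_interval = 0.1)
  m <- simulate_macroscopic(scheme, p, n_channels = 100)
  expect_true(all(m$sweeps == 0))
})

test_that("long constant agonist relaxes to the independent null-vector steady state", {
  p <- gating_protocol(data.frame(duration = c(2000), conc = 10,
                                  label = "pulse"),
                       exchange_tau = 0, sample_interval = 0.5)
  m <- simulate_macroscopic(scheme, p, n_channels = 1,
                            return_occupancy = TRUE)
  occ_end <- attr(m, "occupancy")[nrow(attr(m, "occupancy")), ]
  ss <- steady_state(scheme, 10)
  expect_lt(max(abs(occ_end - ss)), 1e-8)
})

test_that("fitted decay matches the slowest bound-state relaxation eigenvalue", {
  p <- pulse_protocol(sample_interval = 0.05)
  m <- simulate_macroscopic(scheme, p, n_channels = 100)
  f <- fit_decay(m)
  tau_eig <- desensitization_eigen_tau(scheme, 10)[1]
  expect_lt(abs(f$tau_weighted - tau_eig) / tau_eig, 0.02)
})

test_that("stochastic simulation is reproducible and requires a seed", {
  p <- pulse_protocol(pulse = 20, post = 10, sample_interval = 0.1)
  s1 <- simulate_stochastic(scheme, p, n_channels = 50, n_sweeps = 5,
                            seed = 11)
  s2 <- simulate_stochastic(scheme, p, n_channels = 50, n_sweeps = 5,
                            seed = 11)
  expect_identical(s1$sweeps, s2$sweeps)
  s3 <- simulate_stochastic(scheme, p, n_channels = 50, n_sweeps = 5,
                            seed = 12)
  expect_false(identical(s1$sweeps, s3$sweeps))
  expect_error(simulate_stochastic(scheme, p, n_channels = 50,
                                   n_sweeps = 5), "seed")
})

test_that("a permanently open channel yields zero across-sweep variance", {
  s <- kinetic_scheme(
    c(C = "closed", O = "open"), "C",
    data.frame(from = "C", to = "O", rate = 1000, ligand_order = 0),
    conductance_open = 20)
  p <- gating_protocol(data.frame(duration = 10, conc = 0),
                       sample_interval = 0.1)
  sw <- simulate_stochastic(s, p, n_channels = 30, n_sweeps = 10,
                            noise_sigma = 0, seed = 3)
  late <- sw$time > 2   # past the opening transient
  expect_true(all(apply(sw$sweeps[, late, drop = FALSE], 2, var) == 0))
})

test_that("stochastic ensemble mean converges on the master-equation trace", {
  p <- pulse_protocol(pre = 2, pulse = 40, post = 5, sample_interval = 0.1)
  m <- simulate_macroscopic(scheme, p, n_channels = 500)
  sw <- simulate_stochastic(scheme, p, n_channels = 500, n_sweeps = 100,
                            seed = 7)
  peak <- max(abs(m$sweeps))
  err <- max(abs(colMeans(sw$sweeps) - m$sweeps[1, ])) / peak
  expect_lt(err, 0.05)   # 5e4 events: looser than the full-budget check
})
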