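quiet_spec <- function(...)
  rupture_trajectory_spec(thermal_sigma = 0, breathing_amplitude = 0, ...)

test_that("Henderson-Hasselbalch fractions and states are assigned correctly", {
  tab <- data.frame(residue = c("H208", "H229", "E42"),
                    pKa = c(6.5, 5.5, 4.2))
  out <- assign_protonation(tab, pH = 5.5)
  expect_equal(out$fraction[out$residue == "H208"], 10 / 11,
               tolerance = 1e-12)
  expect_true(out$protonated[out$residue == "H208"])
  # pH = pKa gives exactly one half
  expect_equal(out$fraction[out$residue == "H229"], 0.5)
  out8 <- assign_protonation(tab, pH = 8.0)
  expect_equal(out8$fraction[out8$residue == "H208"],
               1 / (1 + 10^1.5), tolerance = 1e-12)
  expect_false(out8$protonated[out8$residue == "H208"])
  expect_error(assign_protonation(tab, 7, residues = c("H208", "K12")),
               "K12")
})

test_that("rmsd trace is zero for static and rigidly transformed frames", {
  traj <- generate_rupture_trajectory(quiet_spec(n_frames = 20,
                                                 rupture_frame = NULL))
  r <- rmsd_trace(traj)
  expect_true(all(r$rmsd < 1e-8))
  # frames that are rigid transforms of the reference
  rt <- random_rigid(17)
  moved <- apply_rigid_traj(traj, rt)
  expect_true(all(rmsd_trace(moved, reference = traj$xyz[1, ])$rmsd < 1e-8))
})

test_that("rupture rmsd step matches a brute-force superposition oracle", {
  traj <- generate_rupture_trajectory(quiet_spec(
    n_frames = 300, rupture_frame = 200, rupture_displacement = 30))
  r <- rmsd_trace(traj)
  ref <- matrix(traj$xyz[1, ], ncol = 3, byrow = TRUE)
  post <- matrix(traj$xyz[250, ], ncol = 3, byrow = TRUE)
  expect_equal(r$rmsd[250], oracle_kabsch_rmsd(ref, post),
               tolerance = 1e-8)
  expect_lt(max(r$rmsd[1:200]), 1e-8)
  expect_gt(r$rmsd[201], 5)
})

test_that("distance metrics are invariant under seeded rigid transforms", {
  spec <- rupture_trajectory_spec(n_frames = 60, thermal_sigma = 0.2,
                                  rupture_frame = 40,
                                  rupture_displacement = 25, seed = 5)
  traj <- generate_rupture_trajectory(spec)
  moved <- apply_rigid_traj(traj, random_rigid(23))
  cs <- default_contacts()
  expect_equal(contact_evolution(moved, cs), contact_evolution(traj, cs),
               tolerance = 1e-8)
  ra <- list(chain = "A", resno = c(201, 208))
  rb <- list(chain = "B", resno = c(201, 208))
  expect_equal(distance_sd_matrix(moved, ra, rb),
               distance_sd_matrix(traj, ra, rb), tolerance = 1e-8)
  expect_equal(rupture_onset(moved, cs, sustain = 0.5),
               rupture_onset(traj, cs, sustain = 0.5))
})

test_that("contact evolution reports window minima and handles wide windows", {
  traj <- generate_rupture_trajectory(quiet_spec(
    n_frames = 500, rupture_frame = 200, rupture_displacement = 30))
  cs <- default_contacts(window = 1)           # 10 frames per window
  ce <- contact_evolution(traj, cs)
  expect_equal(ncol(ce), 50)
  # interface pairs sit at the constructed 3.5 A before the rupture
  expect_equal(unname(ce["A201-B201", 1:19]), rep(3.5, 19),
               tolerance = 1e-8)
  expect_true(all(ce[, 21:50] > cs$cutoff))
  # one window spanning everything returns the global minimum
  wide <- contact_evolution(traj, default_contacts(window = 1e6))
  expect_equal(ncol(wide), 1)
  expect_equal(unname(wide["A201-B201", 1]), 3.5, tolerance = 1e-8)
})

test_that("pairwise distance s.d. captures oscillation amplitude A/sqrt(2)", {
  traj <- generate_rupture_trajectory(quiet_spec(n_frames = 400))
  # static: all s.d. zero
  sdm0 <- distance_sd_matrix(traj, list(chain = "A", resno = 201),
                             list(chain = "B", resno = 201))
  expect_true(all(sdm0 < 1e-10))
  # sinusoidal breathing of amplitude A along the separation axis
  A <- 2
  tr2 <- generate_rupture_trajectory(rupture_trajectory_spec(
    n_frames = 400, breathing_amplitude = A, breathing_period = 100,
    thermal_sigma = 0))
  sdm <- distance_sd_matrix(tr2, list(chain = "A", resno = 201),
                            list(chain = "B", resno = 201))
  expect_equal(sdm[1, 1], A / sqrt(2), tolerance = 0.01)
  expect_error(distance_sd_matrix(
    generate_rupture_trajectory(quiet_spec(n_frames = 1)),
    list(chain = "A", resno = 201), list(chain = "B", resno = 201)),
    "2 frames")
})

test_that("encounter statistics are exact on planted contact patterns", {
  traj <- generate_rupture_trajectory(quiet_spec(n_frames = 100))
  cs <- default_contacts()
  et <- encounter_times(traj, cs)
  on <- et[et$pair == "A201-B201", ]
  expect_equal(on$fraction_in_contact, 1)
  expect_equal(on$mean_duration, 100 * 0.1)     # total trajectory span
  # never in contact after full displacement
  tr_off <- generate_rupture_trajectory(quiet_spec(
    n_frames = 100, rupture_frame = 0, rupture_displacement = 50))
  et0 <- encounter_times(tr_off, cs)
  expect_true(all(et0$fraction_in_contact == 0))
  expect_true(all(et0$mean_duration == 0))
  # alternating 10-on / 10-off planted by interleaving frames
  base <- generate_rupture_trajectory(quiet_spec(n_frames = 100))
  alt <- base
  blocks <- rep(rep(c(TRUE, FALSE), each = 10), 5)
  alt$xyz[!blocks, ] <- tr_off$xyz[!blocks, ]
  eta <- encounter_times(alt, cs)
  expect_equal(eta[eta$pair == "A201-B201", "mean_duration"], 10 * 0.1)
  expect_equal(eta[eta$pair == "A201-B201", "fraction_in_contact"], 0.5)
})

test_that("rupture onset is found at the planted frame and flicker is ignored", {
  traj <- generate_rupture_trajectory(quiet_spec(
    n_frames = 500, rupture_frame = 200, rupture_displacement = 30))
  cs <- default_contacts()
  expect_equal(rupture_onset(traj, cs, sustain = 1), 20.0)
  # intact interface: no rupture reported
  intact <- generate_rupture_trajectory(quiet_spec(n_frames = 200))
  expect_true(is.na(rupture_onset(intact, cs, sustain = 1)))
  # a 0.5-ns excursion does not count with sustain = 1 ns
  flick <- intact
  ruptured <- generate_rupture_trajectory(quiet_spec(
    n_frames = 200, rupture_frame = 0, rupture_displacement = 30))
  ex <- 101:105
  flick$xyz[ex, ] <- ruptured$xyz[ex, ]
  expect_true(is.na(rupture_onset(flick, cs, sustain = 1)))
  expect_equal(rupture_onset(flick, cs, sustain = 0.5), 10.0)
})

test_that("trajectory generation is deterministic and ruptures shift the COM", {
  spec <- rupture_trajectory_spec(n_frames = 300, thermal_sigma = 0.1,
                                  rupture_frame = 200,
                                  rupture_displacement = 30, seed = 9)
  t1 <- generate_rupture_trajectory(spec)
  t2 <- generate_rupture_trajectory(spec)
  expect_identical(t1$xyz, t2$xyz)
  com_sep <- function(traj, f) {
    co <- matrix(traj$xyz[f, ], ncol = 3, byrow = TRUE)
    a <- traj$atoms$chain == "A"
    sqrt(sum((colMeans(co[a, ]) - colMeans(co[!a, ]))^2))
  }
  pre <- mean(vapply(1:200, com_sep, 0, traj = t1))
  post <- mean(vapply(201:300, com_sep, 0, traj = t1))
  expect_equal(post - pre, 30, tolerance = 0.5)
})
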