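# small synthetic models built in code
toy_model <- function() {
  atoms <- data.frame(
    chain = c("A", "A", "B", "B"),
    resno = c(1L, 2L, 1L, 2L),
    resid = "GLY",
    elety = c("CA", "CA", "CA", "CA"),
    elesy = "C")
  xyz <- c(0, 0, 0,  0, 0, 4,  3, 4, 0,  3, 4, 4)
  list(atom = atoms, xyz = xyz)
}

test_that("center-of-mass distances follow plain geometry", {
  m <- toy_model()
  # two single atoms at (0,0,0) and (3,4,0): distance 5
  expect_equal(com_distance(m, 1, 3), 5)
  expect_equal(com_distance(m, 1, 3, mass_weighted = FALSE), 5)
  # identical selections give zero
  expect_equal(com_distance(m, list(chain = "A"), list(chain = "A")), 0)
  # equal-mass two-atom selections average their positions
  expect_equal(com_distance(m, list(chain = "A"), list(chain = "B")), 5)
  expect_error(com_distance(m, list(chain = "Z"), list(chain = "B")),
               "empty")
})

test_that("measurements are invariant under global rigid transforms", {
  m <- toy_model()
  rt <- random_rigid(31)
  co <- matrix(m$xyz, ncol = 3, byrow = TRUE)
  m2 <- m
  m2$xyz <- as.numeric(t(sweep(co %*% t(rt$R), 2, rt$t, "+")))
  expect_equal(com_distance(m2, list(chain = "A"), list(chain = "B")),
               com_distance(m, list(chain = "A"), list(chain = "B")),
               tolerance = 1e-10)
  expect_equal(terminus_distance(m2, "A", "B"),
               terminus_distance(m, "A", "B"), tolerance = 1e-10)
})

test_that("terminus distances use the terminal CA atoms", {
  m <- toy_model()
  expect_equal(terminus_distance(m, "A", "B", "N"), 5)         # (0,0,0)-(3,4,0)
  expect_equal(terminus_distance(m, "A", "B", "C"), 5)         # (0,0,4)-(3,4,4)
  expect_equal(terminus_distance(m, "A", "A", "N"), 0)
  noCA <- m; noCA$atom$elety <- "CB"
  expect_error(terminus_distance(noCA, "A", "B"), "no CA atom")
})

test_that("interface residues are detected, sorted and chain-symmetric", {
  spec <- rupture_trajectory_spec(n_frames = 1, thermal_sigma = 0,
                                  breathing_amplitude = 0)
  traj <- generate_rupture_trajectory(spec)
  m <- list(atom = traj$atoms, xyz = traj$xyz[1, ])
  ir <- interface_residues(m, "A", "B", cutoff = 4.5)
  expect_equal(nrow(ir), 3)       # the three facing residue pairs at 3.5 A
  expect_equal(ir$min_dist, rep(3.5, 3), tolerance = 1e-8)
  expect_true(!is.unsorted(ir$min_dist))
  # symmetry under chain swap
  ir2 <- interface_residues(m, "B", "A", cutoff = 4.5)
  expect_equal(ir2$resno_a, ir$resno_b)
  expect_equal(ir2$min_dist, ir$min_dist)
  # far apart: empty result
  far <- m
  co <- matrix(far$xyz, ncol = 3, byrow = TRUE)
  co[far$atom$chain == "B", 1] <- co[far$atom$chain == "B", 1] + 100
  far$xyz <- as.numeric(t(co))
  expect_equal(nrow(interface_residues(far, "A", "B", 4.5)), 0)
})

test_that("two-fold tetramer construction is an involution with fresh chains", {
  m <- toy_model()
  expect_warning(tet <- build_twofold_tetramer(m, axis = c(0, 0, 1)),
                 "renamed")
  expect_equal(nrow(tet$atom), 2 * nrow(m$atom))
  expect_setequal(unique(tet$atom$chain), c("A", "B", "C", "D"))
  # metadata preserved per atom
  expect_equal(tet$atom$resno[1:4], m$atom$resno)
  expect_equal(tet$atom$elety, rep(m$atom$elety, 2))
  # the copy equals a hand-applied 180-degree rotation about the axis
  co <- matrix(m$xyz, ncol = 3, byrow = TRUE)
  w <- rep(12.011, 4)
  ctr <- colSums(co * w) / sum(w)
  R <- diag(c(-1, -1, 1))                     # 180 degrees about z
  hand <- sweep(sweep(co, 2, ctr) %*% t(R), 2, ctr, "+")
  got <- matrix(as.numeric(tet$xyz), ncol = 3, byrow = TRUE)[5:8, ]
  expect_equal(got, hand, tolerance = 1e-10)
  # applying the rotation twice restores the original coordinates
  back <- sweep(sweep(hand, 2, ctr) %*% t(R), 2, ctr, "+")
  expect_equal(back, co, tolerance = 1e-8)
})
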