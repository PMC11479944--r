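# independent oracles used across tests; deliberately written without the
# package's own code paths

# brute-force Kabsch superposition rmsd via SVD
oracle_kabsch_rmsd <- function(a, b) {
  # a, b: n x 3 coordinate matrices
  ca <- sweep(a, 2, colMeans(a))
  cb <- sweep(b, 2, colMeans(b))
  s <- svd(crossprod(cb, ca))
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  rot <- cb %*% R
  sqrt(mean(rowSums((rot - ca)^2)))
}

# matrix-exponential propagation of the master equation at constant
# concentration (no exchange filter) — independent of step_matrices()
oracle_propagate <- function(Q, p0, t_points) {
  t(vapply(t_points, function(t)
    as.numeric(p0 %*% as.matrix(Matrix::expm(Q * t))),
    numeric(length(p0))))
}

# random rigid transform (rotation + translation), seeded
random_rigid <- function(seed) {
  set.seed(seed)
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  th <- runif(1, 0, 2 * pi)
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
  list(R = R, t = rnorm(3, 0, 20))
}

apply_rigid_traj <- function(traj, rt) {
  for (f in seq_len(nrow(traj$xyz))) {
    co <- matrix(traj$xyz[f, ], ncol = 3, byrow = TRUE)
    traj$xyz[f, ] <- as.numeric(t(sweep(co %*% t(rt$R), 2, rt$t, "+")))
  }
  traj
}

# noiseless multi-exponential decay sweep on a bare time grid
make_decay <- function(taus, amps, offset = 0, dt = 0.05, t_end = 150) {
  t <- seq(0, t_end, by = dt)
  y <- offset + as.numeric(exp(-outer(t, taus, "/")) %*% amps)
  list(time = t, current = y)
}

# default small contact spec matching the synthetic rupture domains
default_contacts <- function(cutoff = 4.5, window = NULL)
  contact_spec(list(chain = "A", resno = c(201, 204, 208)),
               list(chain = "B", resno = c(201, 204, 208)),
               cutoff = cutoff, window = window)
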