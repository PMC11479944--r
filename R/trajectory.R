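#' Molecular-dynamics trajectory container
#'
#' Frames of atomic coordinates on a common atom set, with per-atom
#' metadata in the bio3d column convention.
#'
#' @param xyz numeric matrix, `n_frames x (3 * n_atoms)`, coordinates in
#'   Angstrom ordered x1,y1,z1,x2,...
#' @param times frame times, ns (nondecreasing).
#' @param atoms data frame with at least `chain`, `resno`, `resid`,
#'   `elety` (atom name) and `elesy` (element) columns.
#' @export
md_trajectory <- function(xyz, times, atoms) {
  if (is.vector(xyz)) xyz <- matrix(xyz, nrow = 1)
  atoms <- as.data.frame(atoms)
  need <- c("chain", "resno", "resid", "elety", "elesy")
  if (!all(need %in% names(atoms)))
    stop("'atoms' needs columns ", paste(need, collapse = ", "))
  if (ncol(xyz) != 3 * nrow(atoms))
    stop("xyz width must be 3 * n_atoms")
  if (length(times) != nrow(xyz))
    stop("one time stamp per frame is required")
  if (any(diff(times) < 0)) stop("'times' must be nondecreasing")
  structure(list(xyz = xyz, times = as.numeric(times), atoms = atoms),
            class = "md_trajectory")
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat("MD trajectory:", nrow(x$xyz), "frames x", nrow(x$atoms), "atoms,",
      round(diff(range(x$times)), 3), "ns\n")
  cat("  chains:", paste(unique(x$atoms$chain), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.md_trajectory <- function(x) c(nrow(x$xyz), nrow(x$atoms))

#' Specification of a synthetic two-domain rupture trajectory
#'
#' Describes two rigid domains facing each other across an interface, a
#' harmonic breathing motion of their separation, isotropic thermal
#' noise, and an optional planted rupture event after which domain B is
#' displaced along the separation axis — a controllable stand-in for an
#' NTD-interface rupture.
#'
#' @param n_frames number of frames.
#' @param frame_interval ns between frames.
#' @param domain_a,domain_b lists with `xyz` (`n_atoms x 3` matrix, A)
#'   and `atoms` metadata (as in [md_trajectory()]); defaults are two
#'   three-residue mini-domains whose interface residues sit ~3.5 A
#'   apart (chains A and B, residues 201/204/208).
#' @param breathing_amplitude amplitude of the separation breathing, A.
#' @param breathing_period breathing period, frames (default 100).
#' @param thermal_sigma per-coordinate thermal noise s.d., A.
#' @param rupture_frame 0-based frame index at which the rupture occurs,
#'   or `NULL` for no rupture.
#' @param rupture_displacement displacement of domain B along the
#'   separation axis from the rupture frame on, A.
#' @param seed integer seed (required when `thermal_sigma > 0`).
#' @export
rupture_trajectory_spec <- function(n_frames, frame_interval = 0.1,
                                    domain_a = NULL, domain_b = NULL,
                                    breathing_amplitude = 0.5,
                                    breathing_period = 100,
                                    thermal_sigma = 0.1,
                                    rupture_frame = NULL,
                                    rupture_displacement = 30,
                                    seed = NULL) {
  stopifnot_scalar(n_frames, "n_frames", positive = TRUE,
                   integerish = TRUE)
  stopifnot_scalar(frame_interval, "frame_interval", positive = TRUE)
  if (breathing_amplitude < 0 || thermal_sigma < 0)
    stop("amplitudes must be >= 0")
  if (!is.null(rupture_frame)) {
    stopifnot_scalar(rupture_frame, "rupture_frame", integerish = TRUE)
    if (rupture_frame < 0 || rupture_frame >= n_frames)
      stop("'rupture_frame' must lie in [0, n_frames)")
  }
  if (is.null(domain_a)) domain_a <- default_domain("A", side = -1)
  if (is.null(domain_b)) domain_b <- default_domain("B", side = +1)
  structure(list(n_frames = as.integer(n_frames),
                 frame_interval = frame_interval,
                 domain_a = domain_a, domain_b = domain_b,
                 breathing_amplitude = breathing_amplitude,
                 breathing_period = breathing_period,
                 thermal_sigma = thermal_sigma,
                 rupture_frame = rupture_frame,
                 rupture_displacement = rupture_displacement,
                 seed = seed), class = "rupture_trajectory_spec")
}

# a small rigid three-residue domain; interface atoms end up ~3.5 A from
# the mirrored partner domain (gap between x = -1.75 and x = +1.75)
default_domain <- function(chain, side) {
  res <- c(201L, 204L, 208L)
  xyz <- NULL; meta <- NULL
  for (k in seq_along(res)) {
    # four heavy atoms per residue: backbone-ish triangle + side chain tip
    local <- rbind(c(-4, 0, 0), c(-3, 1.2, 0), c(-3, -1.2, 0.8),
                   c(-1.75, 0, 0))
    local[, 3] <- local[, 3] + (k - 2) * 6   # stack residues along z
    xyz <- rbind(xyz, local)
    meta <- rbind(meta, data.frame(
      chain = chain, resno = res[k], resid = "ALA",
      elety = c("N", "CA", "C", "CB"), elesy = c("N", "C", "C", "C")))
  }
  xyz[, 1] <- side * abs(xyz[, 1])  # mirror for the facing domain
  list(xyz = xyz, atoms = meta)
}

#' Generate a synthetic two-domain trajectory with a plantable rupture
#'
#' Pre-rupture frames carry a harmonic breathing of the inter-domain
#' separation; from the rupture frame on, domain B is additionally
#' displaced by `rupture_displacement` along the separation axis.
#' Isotropic Gaussian thermal noise is applied to every atom of every
#' frame.  Deterministic for a fixed spec (including seed).
#'
#' @param spec a [rupture_trajectory_spec()].
#' @return an [md_trajectory()].
#' @export
generate_rupture_trajectory <- function(spec) {
  stopifnot(inherits(spec, "rupture_trajectory_spec"))
  xa <- spec$domain_a$xyz; xb <- spec$domain_b$xyz
  coma <- colMeans(xa); comb <- colMeans(xb)
  u <- comb - coma
  nu <- sqrt(sum(u^2))
  u <- if (nu > 0) u / nu else c(1, 0, 0)
  n <- spec$n_frames
  na <- nrow(xa); nb <- nrow(xb)
  base <- rbind(xa, xb)
  atoms <- rbind(spec$domain_a$atoms, spec$domain_b$atoms)
  frames <- matrix(0, n, 3 * (na + nb))
  gen <- function() {
    for (f in seq_len(n)) {
      off <- spec$breathing_amplitude *
        sin(2 * pi * (f - 1) / spec$breathing_period)
      if (!is.null(spec$rupture_frame) && (f - 1) >= spec$rupture_frame)
        off <- off + spec$rupture_displacement
      fr <- base
      fr[(na + 1):(na + nb), ] <-
        sweep(fr[(na + 1):(na + nb), , drop = FALSE], 2, off * u, "+")
      if (spec$thermal_sigma > 0)
        fr <- fr + matrix(stats::rnorm(length(fr), 0, spec$thermal_sigma),
                          nrow(fr), 3)
      frames[f, ] <<- as.numeric(t(fr))
    }
  }
  if (spec$thermal_sigma > 0) with_seed(spec$seed, gen()) else gen()
  md_trajectory(frames, (seq_len(n) - 1) * spec$frame_interval, atoms)
}
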