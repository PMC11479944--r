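#' Henderson-Hasselbalch protonation assignment
#'
#' For each titratable residue, the protonated fraction at the simulated
#' pH is `1 / (1 + 10^(pH - pKa))` (basic titration, e.g. histidine); a
#' fixed protonation state is assigned by thresholding the fraction, the
#' standard preparation step for fixed-protonation MD.
#'
#' @param pka table of site pKa values: a data frame with columns
#'   `residue` and `pKa`, or a named numeric vector.
#' @param pH simulated pH.
#' @param residues optional subset of residues to assign; an error lists
#'   any residue without a pKa entry.
#' @param threshold protonated-state threshold on the fraction
#'   (default 0.5).
#' @return data frame with `residue`, `pKa`, `fraction`, `protonated`.
#' @export
assign_protonation <- function(pka, pH, residues = NULL, threshold = 0.5) {
  if (is.numeric(pka) && !is.null(names(pka)))
    pka <- data.frame(residue = names(pka), pKa = as.numeric(pka))
  pka <- as.data.frame(pka)
  if (!all(c("residue", "pKa") %in% names(pka)))
    stop("'pka' needs columns residue and pKa")
  if (any(!is.finite(pka$pKa))) stop("all pKa values must be finite")
  stopifnot_scalar(pH, "pH")
  if (!is.null(residues)) {
    missing <- setdiff(residues, pka$residue)
    if (length(missing))
      stop("no pKa entry for residue(s): ",
           paste(missing, collapse = ", "))
    pka <- pka[match(residues, pka$residue), , drop = FALSE]
  }
  fraction <- 1 / (1 + 10^(pH - pka$pKa))
  data.frame(residue = pka$residue, pKa = pka$pKa, fraction = fraction,
             protonated = fraction >= threshold)
}

# atom-index selection on a bio3d-style atoms data frame
select_atoms <- function(atoms, chain = NULL, resno = NULL, elety = NULL,
                         heavy = TRUE) {
  sel <- rep(TRUE, nrow(atoms))
  if (!is.null(chain)) sel <- sel & atoms$chain %in% chain
  if (!is.null(resno)) sel <- sel & atoms$resno %in% resno
  if (!is.null(elety)) sel <- sel & atoms$elety %in% elety
  if (heavy) sel <- sel & toupper(atoms$elesy) != "H"
  which(sel)
}

#' r.m.s.d. trace of a trajectory against a reference frame
#'
#' Per frame, the root-mean-square deviation of the selected atoms from
#' the reference after optimal least-squares rigid superposition
#' (Kabsch), so only internal motion — not global drift — is reported.
#'
#' @param traj an [md_trajectory()].
#' @param reference reference frame index (default 1) or an xyz vector of
#'   matching length.
#' @param selection atom indices, or a list of selection arguments
#'   (e.g. `list(chain = "B")`); default all heavy atoms.
#' @return data frame with `time` (ns) and `rmsd` (A).
#' @export
rmsd_trace <- function(traj, reference = 1, selection = NULL) {
  stopifnot(inherits(traj, "md_trajectory"))
  idx <- resolve_selection(traj$atoms, selection)
  if (!length(idx)) stop("empty atom selection")
  xi <- bio3d::atom2xyz(idx)
  ref <- if (length(reference) == 1)
    traj$xyz[reference, ] else as.numeric(reference)
  if (length(ref) != ncol(traj$xyz))
    stop("reference length does not match the trajectory atoms")
  r <- bio3d::rmsd(ref, traj$xyz, a.inds = xi, b.inds = xi, fit = TRUE)
  data.frame(time = traj$times, rmsd = as.numeric(r))
}

resolve_selection <- function(atoms, selection) {
  if (is.null(selection)) select_atoms(atoms)
  else if (is.numeric(selection)) as.integer(selection)
  else if (is.list(selection)) do.call(select_atoms, c(list(atoms), selection))
  else stop("'selection' must be indices or a list of selection arguments")
}

#' Cross-interface contact specification
#'
#' Two residue groups on opposite sides of an interface (e.g.
#' Q201/T204/H208 of chains B and D), a heavy-atom contact cutoff and a
#' time window for binned summaries.
#'
#' @param group_a,group_b lists with `chain` and `resno` (e.g.
#'   `list(chain = "B", resno = c(201, 204, 208))`).
#' @param cutoff contact cutoff on the minimum heavy-atom distance, A
#'   (default 4.5, a common van-der-Waals contact convention).
#' @param window window length for time-binned summaries, ns (`NULL`:
#'   one window per frame).
#' @export
contact_spec <- function(group_a, group_b, cutoff = 4.5, window = NULL) {
  stopifnot_scalar(cutoff, "cutoff", positive = TRUE)
  for (g in list(group_a, group_b))
    if (!all(c("chain", "resno") %in% names(g)))
      stop("groups need 'chain' and 'resno'")
  ka <- paste(group_a$chain, group_a$resno)
  kb <- paste(group_b$chain, group_b$resno)
  if (length(intersect(ka, kb)))
    stop("contact groups must be disjoint")
  structure(list(group_a = group_a, group_b = group_b, cutoff = cutoff,
                 window = window), class = "contact_spec")
}

# per-frame minimum heavy-atom distance for every cross-interface residue
# pair; rows = pairs, cols = frames
pair_min_distances <- function(traj, spec) {
  a_res <- spec$group_a$resno; b_res <- spec$group_b$resno
  idx_a <- lapply(a_res, function(r)
    select_atoms(traj$atoms, spec$group_a$chain, r))
  idx_b <- lapply(b_res, function(r)
    select_atoms(traj$atoms, spec$group_b$chain, r))
  if (any(lengths(idx_a) == 0) || any(lengths(idx_b) == 0))
    stop("empty residue selection in contact groups")
  n_fr <- nrow(traj$xyz)
  pairs <- expand.grid(a = seq_along(a_res), b = seq_along(b_res))
  out <- matrix(NA_real_, nrow(pairs), n_fr)
  rownames(out) <- paste0(spec$group_a$chain, a_res[pairs$a], "-",
                          spec$group_b$chain, b_res[pairs$b])
  for (f in seq_len(n_fr)) {
    co <- matrix(traj$xyz[f, ], ncol = 3, byrow = TRUE)
    for (p in seq_len(nrow(pairs))) {
      A <- co[idx_a[[pairs$a[p]]], , drop = FALSE]
      B <- co[idx_b[[pairs$b[p]]], , drop = FALSE]
      d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
      out[p, f] <- sqrt(max(min(d2), 0))
    }
  }
  out
}

#' Temporal evolution of cross-interface contact distances
#'
#' For every residue pair across the interface, the minimum heavy-atom
#' distance summarized per time window (window minimum) — the per-pair
#' "contact bar" view of interface integrity over a run.
#'
#' @param traj an [md_trajectory()].
#' @param spec a [contact_spec()].
#' @return matrix, rows = residue pairs, columns = time windows (A);
#'   attribute `"window_start"` holds the window start times (ns).
#' @export
contact_evolution <- function(traj, spec) {
  stopifnot(inherits(traj, "md_trajectory"),
            inherits(spec, "contact_spec"))
  dm <- pair_min_distances(traj, spec)
  if (is.null(spec$window)) {
    attr(dm, "window_start") <- traj$times
    return(dm)
  }
  t0 <- traj$times[1]
  wid <- floor((traj$times - t0) / spec$window)
  ids <- sort(unique(wid))
  out <- matrix(NA_real_, nrow(dm), length(ids),
                dimnames = list(rownames(dm)))
  for (k in seq_along(ids))
    out[, k] <- apply(dm[, wid == ids[k], drop = FALSE], 1, min)
  attr(out, "window_start") <- t0 + ids * spec$window
  out
}

#' Standard deviation of cross-interface residue-pair distances
#'
#' For each residue pair (one residue from each side), the s.d. across
#' frames of the residue centroid (heavy-atom geometric center) distance —
#' large values flag pairs mobilized by interface rupture.
#'
#' @param traj an [md_trajectory()].
#' @param residues_a,residues_b lists with `chain` and `resno`.
#' @return matrix of s.d. (A), rows = residues_a, columns = residues_b.
#' @export
distance_sd_matrix <- function(traj, residues_a, residues_b) {
  stopifnot(inherits(traj, "md_trajectory"))
  if (nrow(traj$xyz) < 2)
    stop("at least 2 frames are required for an s.d.")
  coms <- function(g) lapply(g$resno, function(r) {
    idx <- select_atoms(traj$atoms, g$chain, r)
    if (!length(idx)) stop("no atoms for residue ", g$chain, ":", r)
    xi <- bio3d::atom2xyz(idx)
    t(apply(traj$xyz[, xi, drop = FALSE], 1, function(v)
      colMeans(matrix(v, ncol = 3, byrow = TRUE))))
  })
  ca <- coms(residues_a); cb <- coms(residues_b)
  out <- matrix(NA_real_, length(ca), length(cb),
                dimnames = list(paste0(residues_a$chain, residues_a$resno),
                                paste0(residues_b$chain, residues_b$resno)))
  for (i in seq_along(ca)) for (j in seq_along(cb))
    out[i, j] <- stats::sd(sqrt(rowSums((ca[[i]] - cb[[j]])^2)))
  out
}

#' Residue encounter times across an interface
#'
#' An encounter is a maximal run of consecutive frames in which a residue
#' pair's minimum heavy-atom distance is below the cutoff.  Reported per
#' pair: the mean encounter duration (ns; 0 if never in contact) and the
#' fraction of frames in contact.
#'
#' @param traj an [md_trajectory()] on a uniform time grid.
#' @param spec a [contact_spec()].
#' @return data frame with `pair`, `mean_duration` (ns),
#'   `fraction_in_contact`, `n_encounters`.
#' @export
encounter_times <- function(traj, spec) {
  stopifnot(inherits(traj, "md_trajectory"),
            inherits(spec, "contact_spec"))
  if (nrow(traj$xyz) < 2) stop("at least 2 frames are required")
  dt <- frame_step(traj)
  dm <- pair_min_distances(traj, spec)
  res <- lapply(seq_len(nrow(dm)), function(p) {
    inc <- dm[p, ] < spec$cutoff
    r <- rle(inc)
    runs <- r$lengths[r$values]
    data.frame(pair = rownames(dm)[p],
               mean_duration = if (length(runs)) mean(runs) * dt else 0,
               fraction_in_contact = mean(inc),
               n_encounters = length(runs))
  })
  do.call(rbind, res)
}

#' Rupture-onset time of an interface
#'
#' The earliest frame from which every residue pair of the contact
#' specification stays above the cutoff continuously for at least
#' `sustain` ns (sustained loss suppresses thermal flicker).  Returns
#' `NA` when the interface never ruptures.
#'
#' @param traj an [md_trajectory()] on a uniform time grid.
#' @param spec a [contact_spec()].
#' @param sustain minimum sustained-loss duration, ns (default 2; must be
#'   at least one frame step).
#' @return onset time (ns) or `NA_real_`.
#' @export
rupture_onset <- function(traj, spec, sustain = 2) {
  stopifnot(inherits(traj, "md_trajectory"),
            inherits(spec, "contact_spec"))
  dt <- frame_step(traj)
  if (sustain < dt) stop("'sustain' must cover at least one frame step")
  need <- ceiling(sustain / dt)
  dm <- pair_min_distances(traj, spec)
  apart <- apply(dm > spec$cutoff, 2, all)
  r <- rle(apart)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- which(r$values & r$lengths >= need)
  if (!length(hit)) return(NA_real_)
  traj$times[starts[hit[1]]]
}

frame_step <- function(traj) {
  dt <- diff(traj$times)
  if (!length(dt)) stop("trajectory has a single frame")
  if (max(abs(dt - dt[1])) > 1e-6 * max(dt[1], 1e-12))
    stop("a uniform frame interval is required")
  dt[1]
}
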