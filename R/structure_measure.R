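#' Center-of-mass distance between two atom selections
#'
#' Euclidean distance between the (mass-weighted) centers of two
#' selections of a static model — e.g. the NTDs of the two B/D-position
#' chains of a receptor tetramer.  With `mass_weighted = FALSE` unit
#' masses are used (geometric center); `calpha_only = TRUE` restricts the
#' selections to C-alpha atoms, a common lighter-weight convention.
#'
#' @param model a structure as returned by [read_structure()] (bio3d-style
#'   `$atom` data frame plus `$xyz`).
#' @param selection_a,selection_b atom indices, or lists of selection
#'   arguments (`chain`, `resno`, `elety`), as in [rmsd_trace()].
#' @param mass_weighted use standard atomic masses (default `TRUE`).
#' @param calpha_only restrict to C-alpha atoms.
#' @return distance in Angstrom.
#' @export
com_distance <- function(model, selection_a, selection_b,
                         mass_weighted = TRUE, calpha_only = FALSE) {
  a <- resolve_selection(model$atom, selection_a)
  b <- resolve_selection(model$atom, selection_b)
  if (calpha_only) {
    a <- intersect(a, which(model$atom$elety == "CA"))
    b <- intersect(b, which(model$atom$elety == "CA"))
  }
  if (!length(a) || !length(b)) stop("empty atom selection")
  sqrt(sum((selection_com(model, a, mass_weighted) -
              selection_com(model, b, mass_weighted))^2))
}

selection_com <- function(model, idx, mass_weighted) {
  co <- matrix(model$xyz[bio3d::atom2xyz(idx)], ncol = 3, byrow = TRUE)
  w <- if (mass_weighted) atom_masses(model$atom[idx, , drop = FALSE])
  else rep(1, length(idx))
  colSums(co * w) / sum(w)
}

atom_masses <- function(atoms) {
  el <- atoms$elesy
  if (is.null(el) || all(is.na(el)) || all(!nzchar(el)))
    el <- substr(trimws(atoms$elety), 1, 1)
  m <- try(suppressWarnings(bio3d::atom2mass(el)), silent = TRUE)
  if (inherits(m, "try-error") || any(is.na(m))) {
    tab <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
             P = 30.974)
    m <- tab[toupper(trimws(el))]
    m[is.na(m)] <- 12.011
  }
  as.numeric(m)
}

#' Distance between chain termini
#'
#' Distance between the C-alpha atoms of the first (N-terminus) or last
#' (C-terminus) modeled residues of two chains — e.g. the separation of
#' the B/D N-termini that reports NTD splaying.
#'
#' @param model structure (see [com_distance()]).
#' @param chain_a,chain_b chain identifiers.
#' @param which_terminus `"N"` (first modeled residue) or `"C"` (last).
#' @return distance in Angstrom.
#' @export
terminus_distance <- function(model, chain_a, chain_b,
                              which_terminus = c("N", "C")) {
  which_terminus <- match.arg(which_terminus)
  ca_of <- function(ch) {
    rows <- which(model$atom$chain == ch)
    if (!length(rows)) stop("no atoms in chain ", ch)
    resnos <- model$atom$resno[rows]
    r <- if (which_terminus == "N") min(resnos) else max(resnos)
    i <- rows[model$atom$resno[rows] == r & model$atom$elety == "CA"]
    if (!length(i))
      stop(sprintf("terminal residue %d of chain %s has no CA atom", r, ch))
    matrix(model$xyz[bio3d::atom2xyz(i[1])], ncol = 3, byrow = TRUE)
  }
  sqrt(sum((ca_of(chain_a) - ca_of(chain_b))^2))
}

#' Cross-chain residue pairs in contact
#'
#' All residue pairs (one per chain) whose minimum heavy-atom distance is
#' below the cutoff, sorted by distance — the interface residue list of a
#' dimer contact.
#'
#' @param model structure (see [com_distance()]).
#' @param chain_a,chain_b chain identifiers.
#' @param cutoff heavy-atom distance cutoff, A (default 4.5).
#' @return data frame `resno_a`, `resid_a`, `resno_b`, `resid_b`,
#'   `min_dist`, sorted ascending by `min_dist` (possibly empty).
#' @export
interface_residues <- function(model, chain_a, chain_b, cutoff = 4.5) {
  at <- model$atom
  co <- matrix(model$xyz, ncol = 3, byrow = TRUE)
  heavy <- function(ch) which(at$chain == ch & toupper(at$elesy) != "H")
  ia <- heavy(chain_a); ib <- heavy(chain_b)
  if (!length(ia) || !length(ib)) stop("empty chain selection")
  A <- co[ia, , drop = FALSE]; B <- co[ib, , drop = FALSE]
  d <- sqrt(pmax(outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B), 0))
  ra <- paste(at$resno[ia], at$resid[ia])
  rb <- paste(at$resno[ib], at$resid[ib])
  mind <- tapply(seq_along(d), list(ra[row(d)], rb[col(d)]),
                 function(k) min(d[k]))
  hits <- which(mind < cutoff, arr.ind = TRUE)
  if (!nrow(hits))
    return(data.frame(resno_a = integer(0), resid_a = character(0),
                      resno_b = integer(0), resid_b = character(0),
                      min_dist = numeric(0)))
  split_key <- function(k) {
    parts <- strsplit(k, " ", fixed = TRUE)
    list(resno = as.integer(vapply(parts, `[`, "", 1)),
         resid = vapply(parts, `[`, "", 2))
  }
  ka <- split_key(rownames(mind)[hits[, 1]])
  kb <- split_key(colnames(mind)[hits[, 2]])
  out <- data.frame(resno_a = ka$resno, resid_a = ka$resid,
                    resno_b = kb$resno, resid_b = kb$resid,
                    min_dist = mind[hits])
  out[order(out$min_dist), , drop = FALSE]
}

#' Build a two-fold tetramer from a dimer by a 180-degree rotation
#'
#' Appends to the input dimer a copy rotated 180 degrees about the given
#' axis (through the dimer center of mass), with fresh chain identifiers —
#' the standard construction of a dimer-of-dimers from one asymmetric
#' unit.  Applying the same rotation twice restores the original
#' coordinates (the operation is an involution).
#'
#' @param model structure with (at least) two chains.
#' @param axis rotation axis (length-3 vector; normalized internally).
#' @param center point on the axis; default the model's center of mass.
#' @return a structure (`$atom`, `$xyz`) with doubled atom count; new
#'   chains are renamed to unused identifiers (warning on collision
#'   handling).
#' @export
build_twofold_tetramer <- function(model, axis = c(0, 0, 1),
                                   center = NULL) {
  if (sqrt(sum(axis^2)) == 0) stop("'axis' must be a nonzero vector")
  u <- axis / sqrt(sum(axis^2))
  co <- matrix(model$xyz, ncol = 3, byrow = TRUE)
  if (is.null(center)) {
    w <- atom_masses(model$atom)
    center <- colSums(co * w) / sum(w)
  }
  R <- 2 * tcrossprod(u) - diag(3)   # 180-degree rotation about u
  rot <- sweep(sweep(co, 2, center) %*% t(R), 2, center, "+")
  new_atom <- model$atom
  old <- unique(model$atom$chain)
  pool <- setdiff(c(LETTERS, letters, as.character(0:9)), old)
  if (length(pool) < length(old))
    stop("not enough free chain identifiers")
  map <- stats::setNames(pool[seq_along(old)], old)
  warning("rotated copy renamed to chain(s) ",
          paste(map, collapse = ", "), call. = FALSE)
  new_atom$chain <- unname(map[model$atom$chain])
  atom <- rbind(model$atom, new_atom)
  xyz <- c(model$xyz, as.numeric(t(rot)))
  structure(list(atom = atom, xyz = bio3d::as.xyz(matrix(xyz, nrow = 1)),
                 calpha = atom$elety == "CA",
                 call = match.call()), class = "pdb")
}
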