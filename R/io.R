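#' Write current sweeps to delimited text
#'
#' Tab-separated file with a mandatory unit header (`# units: time=ms
#' current=pA`), a `time` column and one column per sweep.  Round-trips
#' through [read_sweeps()] at full double precision.
#'
#' @param sweepset a [sweep_set()].
#' @param path output file.
#' @export
write_sweeps <- function(sweepset, path) {
  stopifnot(inherits(sweepset, "sweep_set"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# units: time=ms current=pA",
               sprintf("# n_sweeps: %d", nrow(sweepset$sweeps)),
               if (length(sweepset$baseline_window))
                 sprintf("# baseline_window: %d %d",
                         min(sweepset$baseline_window),
                         max(sweepset$baseline_window))), con)
  m <- cbind(time = sweepset$time, t(sweepset$sweeps))
  colnames(m) <- c("time", paste0("sweep", seq_len(nrow(sweepset$sweeps))))
  writeLines(paste(colnames(m), collapse = "\t"), con)
  writeLines(apply(m, 1, function(r)
    paste(sprintf("%.17g", r), collapse = "\t")), con)
  invisible(path)
}

#' Read current sweeps from delimited text
#'
#' Expects the format written by [write_sweeps()]: a `# units:` header
#' declaring ms/pA, a header row, then one row per sample.  Malformed or
#' non-finite samples are reported with their line numbers; a nonuniform
#' time grid is an error.
#'
#' @param path input file.
#' @return a [sweep_set()] (without protocol).
#' @export
read_sweeps <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  units <- grep("^#\\s*units:", lines, value = TRUE)
  if (!length(units))
    stop("missing '# units:' header (expected time=ms current=pA)")
  if (!grepl("time=ms", units) || !grepl("current=pA", units))
    stop("unsupported units: ", units)
  bw <- integer(0)
  bl <- grep("^#\\s*baseline_window:", lines, value = TRUE)
  if (length(bl)) {
    v <- as.integer(strsplit(trimws(sub(".*:", "", bl[1])), "\\s+")[[1]])
    bw <- v[1]:v[2]
  }
  body <- setdiff(seq_along(lines), hdr)
  header_row <- body[1]
  cols <- strsplit(lines[header_row], "\t", fixed = TRUE)[[1]]
  data_rows <- body[-1]
  vals <- lapply(data_rows, function(i) {
    v <- suppressWarnings(
      as.numeric(strsplit(lines[i], "\t", fixed = TRUE)[[1]]))
    if (length(v) != length(cols) || anyNA(v) || any(!is.finite(v)))
      stop("malformed or non-finite sample on line ", i, " of ", path)
    v
  })
  m <- do.call(rbind, vals)
  colnames(m) <- cols
  time <- m[, "time"]
  dt <- diff(time)
  if (any(dt <= 0) || max(abs(dt - dt[1])) > 1e-6 * dt[1])
    stop("nonuniform time grid in ", path)
  sweep_set(unname(time), unname(t(m[, -1, drop = FALSE])),
            baseline_window = bw)
}

#' Read an atomic model from a PDB file
#'
#' Thin wrapper over the bio3d PDB parser keeping the first model only
#' and preferring altloc A: alternate locations other than blank/A are
#' dropped with a warning that counts them.
#'
#' @param path PDB file.
#' @return a bio3d `pdb` object.
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                         verbose = FALSE)
  if (is.null(pdb$atom) || nrow(pdb$atom) == 0)
    stop("no atoms parsed from ", path)
  alt <- pdb$atom$alt
  drop <- !(is.na(alt) | alt == "" | alt == "A")
  if (any(drop)) {
    warning(sum(drop), " alternate-location atom(s) dropped (altloc A kept)")
    pdb <- bio3d::trim.pdb(pdb, inds = list(atom = which(!drop),
                                            xyz = bio3d::atom2xyz(which(!drop))))
  }
  pdb
}

#' Read a multi-model PDB file as a trajectory
#'
#' Each MODEL block becomes one frame; frame times come from
#' `frame_interval` (uniform spacing starting at 0).
#'
#' @param path multi-model PDB file.
#' @param frame_interval ns between frames (default 1).
#' @return an [md_trajectory()].
#' @export
read_trajectory <- function(path, frame_interval = 1) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  if (is.null(pdb$atom) || nrow(pdb$atom) == 0)
    stop("no atoms parsed from ", path)
  xyz <- pdb$xyz
  if (is.vector(xyz)) xyz <- matrix(xyz, nrow = 1)
  md_trajectory(unclass(xyz),
                (seq_len(nrow(xyz)) - 1) * frame_interval,
                pdb$atom[, c("chain", "resno", "resid", "elety", "elesy")])
}

#' Write a trajectory as a multi-model PDB file
#'
#' @param traj an [md_trajectory()].
#' @param path output file.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "md_trajectory"))
  at <- traj$atoms
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(nrow(traj$xyz))) {
    writeLines(sprintf("MODEL     %4d", f), con)
    co <- matrix(traj$xyz[f, ], ncol = 3, byrow = TRUE)
    writeLines(sprintf(
      "ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      seq_len(nrow(at)),
      ifelse(nchar(at$elety) < 4, paste0(" ", at$elety), at$elety),
      at$resid, at$chain, at$resno, co[, 1], co[, 2], co[, 3],
      toupper(at$elesy)), con)
    writeLines(c("TER", "ENDMDL"), con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a kinetic scheme from a plain-text config
#'
#' Declarative key-value + table format with sections `[states]`,
#' `[rates]`, `[conductance]` and optional `[ph_modifiers]`; see the
#' packaged `glua2_scheme.cfg` in `inst/extdata` for the reference file.
#'
#' @param path config file.
#' @return a [kinetic_scheme()].
#' @export
read_scheme_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  section <- ""
  kv <- list(); states <- character(); st_cls <- character()
  rates <- list(); mods <- list(); cond <- c()
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) { section <- gsub("\\[|\\]", "", ln); next }
    tok <- strsplit(ln, "\\s+")[[1]]
    if (section == "") kv[[tok[1]]] <- tok[2]
    else if (section == "states") { states <- c(states, tok[1])
      st_cls <- c(st_cls, tok[2]) }
    else if (section == "rates") {
      if (identical(tok[1], "from")) next
      rates[[length(rates) + 1]] <- data.frame(
        from = tok[1], to = tok[2], rate = as.numeric(tok[3]),
        ligand_order = as.integer(tok[4]))
    } else if (section == "ph_modifiers") {
      if (identical(tok[1], "pH")) next
      mods[[length(mods) + 1]] <- data.frame(
        pH = as.numeric(tok[1]), from = tok[2], to = tok[3],
        factor = as.numeric(tok[4]))
    } else if (section == "conductance")
      cond[tok[1]] <- as.numeric(tok[2])
  }
  kinetic_scheme(
    states = stats::setNames(st_cls, states),
    resting = kv$resting,
    rates = do.call(rbind, rates),
    conductance_open = cond,
    ph_modifiers = if (length(mods)) do.call(rbind, mods) else NULL,
    reference_pH = as.numeric(kv$reference_pH))
}
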