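# Trajectory ingestion and molecular dipole extraction.  Multi-model PDB is
# the native round-trip format (plain text); DCD frames are read through
# bio3d against a PDB topology.  All file I/O is in Angstrom and ps,
# right-handed axes; molecules are expected to be whole (no wrapping across
# periodic boundaries before dipole computation).

#' Trajectory container
#'
#' @param coords numeric array \code{[frame, atom, 3]} (Angstrom).
#' @param atoms data frame with one row per atom: \code{molecule} (integer
#'   id) and \code{site} (label matching the water model, e.g. O/H1/H2/OM;
#'   Drude particles as \code{D<host>}).
#' @param dt frame spacing in ps.
#' @param box cubic box edge (Angstrom) or NA.
#' @param model optional water model name tag.
#' @return a \code{wtraj}.
#' @export
wtraj <- function(coords, atoms, dt, box = NA_real_, model = NULL) {
  stopifnot(is.array(coords), length(dim(coords)) == 3, dim(coords)[3] == 3,
            nrow(atoms) == dim(coords)[2],
            all(c("molecule", "site") %in% names(atoms)))
  if (!is.finite(dt) || dt <= 0) stop("dt must be a positive time step (ps)")
  structure(list(coords = coords, atoms = atoms, dt = dt, box = box,
                 model = model),
            class = "wtraj")
}

#' @export
print.wtraj <- function(x, ...) {
  cat("<wtraj>", dim(x$coords)[1], "frames x", dim(x$coords)[2], "atoms (",
      max(x$atoms$molecule), "molecules ), dt =", x$dt, "ps, box =",
      x$box, "A\n")
  invisible(x)
}

#' Write a trajectory as a multi-model PDB file
#'
#' Plain-text, one MODEL/ENDMDL block per frame, coordinates at the PDB's
#' native 1e-3 A precision; a CRYST1 record carries the (cubic) box.
#'
#' @param traj a [wtraj()].
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_trajectory_pdb <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("REMARK   thzwater trajectory dt_ps=%.9g", traj$dt), con)
  if (is.finite(traj$box))
    writeLines(sprintf(
      "CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
      traj$box, traj$box, traj$box, 90, 90, 90), con)
  elem <- substr(traj$atoms$site, 1, 1)
  for (f in seq_len(dim(traj$coords)[1])) {
    writeLines(sprintf("MODEL     %4d", f), con)
    writeLines(sprintf(
      "ATOM  %5d %-4s%-4s %4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      seq_len(nrow(traj$atoms)), substr(traj$atoms$site, 1, 4), "HOH",
      traj$atoms$molecule, traj$coords[f, , 1], traj$coords[f, , 2],
      traj$coords[f, , 3], elem), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Load a trajectory
#'
#' Reads a multi-model PDB (topology and frames in one file) or a DCD frame
#' file against a PDB topology (via bio3d).  Molecules are resolved from
#' residue numbers; site labels from atom names.  XTC/TRR are not supported
#' (no reader available) and are rejected with a clear error.
#'
#' @param path trajectory file (.pdb or .dcd).
#' @param topology PDB topology path (required for DCD).
#' @param dt frame spacing in ps; required unless the PDB carries the
#'   thzwater REMARK written by [write_trajectory_pdb()].
#' @param stride keep every \code{stride}-th frame (the effective dt is
#'   multiplied accordingly).
#' @return a [wtraj()].
#' @export
load_trajectory <- function(path, topology = NULL, dt = NULL, stride = 1) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("xtc", "trr"))
    stop("XTC/TRR trajectories are not supported; convert to PDB or DCD")
  if (ext == "pdb") {
    first <- readLines(path, n = 5)
    rem <- grep("^REMARK   thzwater trajectory dt_ps=", first, value = TRUE)
    if (is.null(dt) && length(rem))
      dt <- as.numeric(sub(".*dt_ps=", "", rem[1]))
    if (is.null(dt))
      stop("missing dt metadata: supply dt explicitly")
    pdb <- bio3d::read.pdb(path, multi = TRUE)
    xyz <- pdb$xyz                       # frames x 3*natoms
    natoms <- ncol(xyz) / 3
    coords <- array(0, c(nrow(xyz), natoms, 3))
    coords[, , 1] <- xyz[, seq(1, ncol(xyz), 3)]
    coords[, , 2] <- xyz[, seq(2, ncol(xyz), 3)]
    coords[, , 3] <- xyz[, seq(3, ncol(xyz), 3)]
    atoms <- data.frame(molecule = as.integer(pdb$atom$resno),
                        site = trimws(pdb$atom$elety))
    box <- NA_real_
    cr <- grep("^CRYST1", readLines(path), value = TRUE)
    if (length(cr)) box <- as.numeric(substr(cr[1], 7, 15))
  } else if (ext == "dcd") {
    if (is.null(topology)) stop("DCD input needs a PDB topology")
    if (is.null(dt)) stop("missing dt metadata: supply dt explicitly")
    top <- bio3d::read.pdb(topology)
    xyz <- bio3d::read.dcd(path, verbose = FALSE)
    if (ncol(xyz) != 3 * nrow(top$atom))
      stop("atom-count mismatch: topology has ", nrow(top$atom),
           " atoms, DCD frames have ", ncol(xyz) / 3)
    natoms <- nrow(top$atom)
    coords <- array(0, c(nrow(xyz), natoms, 3))
    coords[, , 1] <- xyz[, seq(1, ncol(xyz), 3)]
    coords[, , 2] <- xyz[, seq(2, ncol(xyz), 3)]
    coords[, , 3] <- xyz[, seq(3, ncol(xyz), 3)]
    atoms <- data.frame(molecule = as.integer(top$atom$resno),
                        site = trimws(top$atom$elety))
    box <- NA_real_
  } else stop("unsupported trajectory format: .", ext)
  if (stride > 1) {
    keep <- seq(1, dim(coords)[1], by = stride)
    coords <- coords[keep, , , drop = FALSE]
    dt <- dt * stride
  }
  wtraj(coords, atoms, dt = dt, box = box)
}

# molecule_geometry list for one frame (Drude particles excluded from the
# geometric sites; they are read separately by the induced-dipole channel)
.frame_geometries <- function(traj, frame) {
  drude <- startsWith(traj$atoms$site, "D")
  mols <- sort(unique(traj$atoms$molecule))
  lapply(mols, function(m) {
    sel <- which(traj$atoms$molecule == m & !drude)
    co <- traj$coords[frame, sel, , drop = FALSE]
    co <- matrix(co, length(sel), 3)
    rownames(co) <- traj$atoms$site[sel]
    molecule_geometry(co)
  })
}

#' Extract per-molecule dipoles from a trajectory
#'
#' Computes permanent molecular dipoles per frame (point charges at the
#' frame coordinates, plus lab-frame atomic dipoles for multipole models)
#' and, when Drude particles (sites named \code{D<host>}) are present in
#' the trajectory, the induced dipoles from the Drude pair displacements.
#' Molecules must be whole: a bonded O-H distance above 1.5 A raises an
#' error (unwrap the trajectory first).
#'
#' @param traj a [wtraj()].
#' @param spec the \code{water_model} describing the sites.
#' @return a [dipole_series()].
#' @export
molecular_dipoles <- function(traj, spec) {
  stopifnot(inherits(traj, "wtraj"))
  nfr <- dim(traj$coords)[1]
  mols <- sort(unique(traj$atoms$molecule))
  nm <- length(mols)
  perm <- array(0, c(nfr, nm, 3))
  ind <- array(0, c(nfr, nm, 3))
  drude_host <- if (!is.null(spec$drude)) spec$drude$host else NULL
  has_drude <- !is.null(drude_host) &&
    any(traj$atoms$site == paste0("D", drude_host))
  for (f in seq_len(nfr)) {
    geoms <- .frame_geometries(traj, f)
    for (mi in seq_len(nm)) {
      g <- geoms[[mi]]
      if (all(c("O", "H1") %in% rownames(g$coords)) &&
          sqrt(sum((g$coords["O", ] - g$coords["H1", ])^2)) > 1.5)
        stop("molecule ", mols[mi], " appears broken at frame ", f,
             " (O-H1 > 1.5 A); unwrap the trajectory first")
      perm[f, mi, ] <- permanent_dipole(g, spec)
      if (has_drude) {
        sel_h <- which(traj$atoms$molecule == mols[mi] &
                       traj$atoms$site == drude_host)
        sel_d <- which(traj$atoms$molecule == mols[mi] &
                       traj$atoms$site == paste0("D", drude_host))
        ind[f, mi, ] <- drude_induced(traj$coords[f, sel_h, ],
                                      traj$coords[f, sel_d, ],
                                      spec$drude$charge)
      }
    }
  }
  dipole_series((seq_len(nfr) - 1) * traj$dt, perm, ind)
}
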