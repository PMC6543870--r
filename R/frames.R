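#' Construct a frame series from atom records and coordinates
#'
#' A `frame_series` holds the ordered coordinate frames of one dissociation
#' trajectory together with atom typing for both binding partners. Coordinates
#' are in Angstrom, times in nanoseconds, frames are 0-indexed.
#'
#' @param atoms data.frame with one row per atom: `atom` (name), `resno`,
#'   `resid` (residue name), `role` ("protein" or "ligand"), `element`,
#'   `mass`, `charge` (formal-charge class -1/0/+1), `aromatic`, `donor`,
#'   `acceptor`, `apolar` (logicals), `ring_id` (character or NA).
#' @param xyz numeric matrix, one row per frame, `3 * nrow(atoms)` columns in
#'   x1,y1,z1,x2,... order (the bio3d convention).
#' @param frame_times strictly increasing numeric vector of frame times (ns).
#' @param compound_id,replica_id,trajectory_id identifiers carried through the
#'   pipeline.
#' @return an object of class `frame_series` with the ligand center of mass
#'   per frame (`ligand_com`, mass-weighted) and `initial_com` (frame 0).
#' @export
frame_series <- function(atoms, xyz, frame_times = NULL,
                         compound_id = "cmpd", replica_id = "r1",
                         trajectory_id = "t1") {
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1)
  n_atoms <- nrow(atoms)
  if (ncol(xyz) != 3 * n_atoms)
    stopf("atom-count mismatch: %d atoms in topology but %d coordinates per frame",
          n_atoms, ncol(xyz))
  n_frames <- nrow(xyz)
  if (is.null(frame_times)) frame_times <- (seq_len(n_frames) - 1) * 1e-3
  if (length(frame_times) != n_frames)
    stopf("frame_times length (%d) != number of frames (%d)",
          length(frame_times), n_frames)
  if (n_frames > 1 && any(diff(frame_times) <= 0))
    stopf("frame_times must be strictly increasing")
  if (!any(atoms$role == "ligand")) stopf("empty ligand selection")
  prot <- atoms[atoms$role == "protein", ]
  if (anyDuplicated(unique(prot[, c("resno", "resid")])$resno))
    stopf("protein residue numbers are not unique")

  lig_idx <- which(atoms$role == "ligand")
  com <- ligand_com(xyz, lig_idx, atoms$mass[lig_idx])
  structure(list(compound_id = compound_id, replica_id = replica_id,
                 trajectory_id = trajectory_id,
                 atoms = atoms, xyz = xyz, frame_times = frame_times,
                 ligand_com = com, initial_com = com[1, ]),
            class = "frame_series")
}

# Mass-weighted ligand center of mass, one row per frame.
ligand_com <- function(xyz, lig_idx, masses) {
  w <- masses / sum(masses)
  cols <- function(k) 3 * (lig_idx - 1) + k
  cbind(xyz[, cols(1), drop = FALSE] %*% w,
        xyz[, cols(2), drop = FALSE] %*% w,
        xyz[, cols(3), drop = FALSE] %*% w)
}

#' @export
print.frame_series <- function(x, ...) {
  cat(sprintf("Frame series: compound %s, replica %s, trajectory %s\n",
              x$compound_id, x$replica_id, x$trajectory_id))
  cat(sprintf("  %d frames, %d atoms (%d ligand, %d protein residues)\n",
              nrow(x$xyz), nrow(x$atoms), sum(x$atoms$role == "ligand"),
              length(unique(x$atoms$resno[x$atoms$role == "protein"]))))
  d <- detect_dissociation(x)
  cat(if (is.na(d)) "  dissociation: censored (never moved 30 A)\n" else
        sprintf("  dissociation at frame %d (%.4g ns)\n", d,
                x$frame_times[d + 1]))
  invisible(x)
}

#' Read a dissociation trajectory from a topology and a frame stream
#'
#' The topology is a PDB file; frames are either a DCD file or a multi-model
#' PDB. When `frames_path` is `NULL` the models of the topology PDB itself are
#' used as frames. Protein atoms are typed from built-in standard amino acid
#' dictionaries; ligand atoms from `ligand_types` (a data.frame or CSV path;
#' see [default_ligand_types()] for the element-based fallback).
#'
#' @param topology_path path to a PDB file.
#' @param frames_path optional path to a DCD file or a multi-model PDB.
#' @param ligand_selection residue name identifying the ligand (default "LIG").
#' @param ligand_types ligand typing table (data.frame or CSV path), or `NULL`.
#' @param frame_times numeric vector of frame times in ns, or `NULL` for
#'   `frame_dt`-spaced times starting at 0.
#' @param frame_dt frame spacing in ns when `frame_times` is `NULL`.
#' @param compound_id,replica_id,trajectory_id identifiers.
#' @return a [frame_series()].
#' @export
read_trajectory <- function(topology_path, frames_path = NULL,
                            ligand_selection = "LIG", ligand_types = NULL,
                            frame_times = NULL, frame_dt = 1e-3,
                            compound_id = "cmpd", replica_id = "r1",
                            trajectory_id = "t1") {
  pdb <- bio3d::read.pdb(topology_path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  if (is.null(frames_path)) {
    xyz <- unclass(pdb$xyz)
  } else if (grepl("\\.dcd$", frames_path, ignore.case = TRUE)) {
    xyz <- unclass(bio3d::read.dcd(frames_path, verbose = FALSE))
  } else if (grepl("\\.pdb$", frames_path, ignore.case = TRUE)) {
    xyz <- unclass(bio3d::read.pdb(frames_path, multi = TRUE,
                                   verbose = FALSE)$xyz)
  } else {
    stopf("unreadable frame stream '%s': expected .dcd or .pdb", frames_path)
  }
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1)
  if (ncol(xyz) != 3 * nrow(at))
    stopf("atom-count mismatch: topology has %d atoms, frame stream has %d",
          nrow(at), ncol(xyz) / 3)

  is_lig <- at$resid == ligand_selection
  if (!any(is_lig))
    stopf("empty ligand selection: no atoms with residue name '%s'",
          ligand_selection)
  elem <- at$elesy
  if (is.null(elem) || all(is.na(elem) | elem == ""))
    elem <- element_from_name(at$elety)
  elem <- toupper(trimws(elem))
  elem[is.na(elem) | elem == ""] <- element_from_name(at$elety[is.na(elem) | elem == ""])
  mass <- unname(ELEMENT_MASSES[elem])
  mass[is.na(mass)] <- 12.011

  atoms <- data.frame(atom = trimws(at$elety), resno = at$resno,
                      resid = trimws(at$resid),
                      role = ifelse(is_lig, "ligand", "protein"),
                      element = elem, mass = mass,
                      charge = 0, aromatic = FALSE, donor = FALSE,
                      acceptor = FALSE, apolar = FALSE,
                      ring_id = NA_character_, stringsAsFactors = FALSE)

  pi <- which(!is_lig)
  pt <- type_protein_atoms(atoms$atom[pi], atoms$resid[pi], atoms$resno[pi])
  atoms[pi, c("donor", "acceptor", "apolar", "aromatic", "charge", "ring_id")] <-
    pt[, c("donor", "acceptor", "apolar", "aromatic", "charge", "ring_id")]

  li <- which(is_lig)
  if (is.character(ligand_types)) ligand_types <- utils::read.csv(ligand_types)
  if (is.null(ligand_types)) {
    lt <- default_ligand_types(atoms$atom[li], atoms$element[li])
  } else {
    lt <- validate_ligand_types(ligand_types)
    m <- match(atoms$atom[li], lt$atom)
    if (anyNA(m))
      stopf("missing atom typing for ligand atom(s): %s",
            paste(atoms$atom[li][is.na(m)], collapse = ", "))
    lt <- lt[m, ]
  }
  atoms[li, c("charge", "aromatic", "donor", "acceptor", "apolar", "ring_id")] <-
    lt[, c("charge", "aromatic", "donor", "acceptor", "apolar", "ring_id")]

  if (is.null(frame_times)) frame_times <- (seq_len(nrow(xyz)) - 1) * frame_dt
  frame_series(atoms, xyz, frame_times, compound_id, replica_id, trajectory_id)
}

#' Detect the ligand dissociation event
#'
#' The dissociation frame is the first frame (0-indexed) at which the ligand
#' center of mass has moved at least `threshold` Angstrom from its position in
#' frame 0 — the stopping criterion used when egress trajectories are
#' generated. Trajectories that never reach the threshold are censored.
#'
#' @param series a [frame_series()].
#' @param threshold displacement threshold in Angstrom (default 30).
#' @return integer frame index, or `NA_integer_` if censored.
#' @export
detect_dissociation <- function(series, threshold = 30) {
  stopifnot(inherits(series, "frame_series"))
  d2 <- rowSums(sweep(series$ligand_com, 2, series$initial_com)^2)
  hit <- which(d2 >= threshold^2)
  if (length(hit) == 0) NA_integer_ else as.integer(hit[1] - 1L)
}
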