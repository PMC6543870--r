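# Geometric typing of protein-ligand contacts per frame.
#
# Each contacting residue gets a 7-bit record: hydrophobic, aromatic
# face-to-face, aromatic edge-to-face, H-bond donor (ligand donates), H-bond
# acceptor (ligand accepts), cationic (ligand +), anionic (ligand -).

BIT_NAMES <- c("hydrophobic", "aro_face", "aro_edge", "hb_donor",
               "hb_acceptor", "cationic", "anionic")

stop_typed <- function(msg, class) stop(errorCondition(msg, class = c(class, "tauramd_error")))

frame_coords <- function(series, frame) {
  n <- nrow(series$atoms)
  matrix(series$xyz[frame + 1L, ], nrow = n, ncol = 3, byrow = TRUE)
}

min_pair_dist <- function(a, b) {
  # minimum Euclidean distance between two small coordinate sets
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(max(0, min(d2)))
}

ring_geometry <- function(coords) {
  ctr <- colMeans(coords)
  sv <- svd(sweep(coords, 2, ctr))
  list(center = ctr, normal = sv$v[, 3])
}

plane_angle <- function(n1, n2) {
  ca <- abs(sum(n1 * n2)) / sqrt(sum(n1^2) * sum(n2^2))
  acos(min(1, max(-1, ca))) * 180 / pi
}

# Does any (donor heavy atom, acceptor) pair satisfy the H-bond criterion?
# `dh` are coordinates of hydrogens; a donor's hydrogens are those within
# 1.25 A of it. If a donor carries no explicit hydrogen the distance criterion
# alone applies (heavy-atom topologies).
hb_contact <- function(donors, acceptors, hydrogens, cutoffs) {
  for (i in seq_len(nrow(donors))) {
    d <- donors[i, ]
    hs <- NULL
    if (!is.null(hydrogens) && nrow(hydrogens) > 0) {
      hd <- sqrt(rowSums(sweep(hydrogens, 2, d)^2))
      hs <- hydrogens[hd <= 1.25, , drop = FALSE]
    }
    for (j in seq_len(nrow(acceptors))) {
      a <- acceptors[j, ]
      if (sqrt(sum((d - a)^2)) > cutoffs$hb_dist) next
      if (is.null(hs) || nrow(hs) == 0) return(TRUE)
      for (k in seq_len(nrow(hs))) {
        h <- hs[k, ]
        v1 <- d - h; v2 <- a - h
        ca <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
        ang <- acos(min(1, max(-1, ca))) * 180 / pi
        if (ang >= cutoffs$hb_angle) return(TRUE)
      }
    }
  }
  FALSE
}

#' Type protein-ligand interactions in one frame
#'
#' Assigns the seven geometric interaction flags for every protein residue in
#' contact with the ligand. Residues with no flag set are omitted.
#'
#' @param series a [frame_series()] with atom typing assigned.
#' @param frame 0-based frame index.
#' @param cutoffs a [geometric_cutoffs()] object.
#' @return data.frame with columns `resno`, `resid` and the seven binary
#'   flags `hydrophobic`, `aro_face`, `aro_edge`, `hb_donor`, `hb_acceptor`,
#'   `cationic`, `anionic`; zero rows if the ligand contacts nothing.
#' @export
type_interactions <- function(series, frame = 0L,
                              cutoffs = geometric_cutoffs()) {
  stopifnot(inherits(series, "frame_series"))
  at <- series$atoms
  need <- c("donor", "acceptor", "apolar", "aromatic", "charge", "ring_id")
  if (!all(need %in% names(at)) || anyNA(at$donor) || anyNA(at$apolar))
    stop_typed("atom typing flags missing from frame series",
               "tauramd_typing_error")
  xyz <- frame_coords(series, frame)
  lig <- at$role == "ligand"
  pro <- !lig

  lig_h <- xyz[lig & at$element == "H", , drop = FALSE]
  lig_apolar <- xyz[lig & at$apolar, , drop = FALSE]
  lig_donor <- xyz[lig & at$donor, , drop = FALSE]
  lig_acceptor <- xyz[lig & at$acceptor, , drop = FALSE]
  lig_cation <- xyz[lig & at$charge > 0, , drop = FALSE]
  lig_anion <- xyz[lig & at$charge < 0, , drop = FALSE]
  lig_rings <- lapply(split(which(lig & at$aromatic),
                            at$ring_id[lig & at$aromatic]),
                      function(ix) ring_geometry(xyz[ix, , drop = FALSE]))

  res_rows <- split(which(pro), at$resno[pro])
  out <- list()
  for (rn in names(res_rows)) {
    ix <- res_rows[[rn]]
    rxyz <- xyz[ix, , drop = FALSE]
    rat <- at[ix, ]
    bits <- stats::setNames(integer(7), BIT_NAMES)

    p_apolar <- rxyz[rat$apolar, , drop = FALSE]
    if (nrow(lig_apolar) && nrow(p_apolar) &&
        min_pair_dist(lig_apolar, p_apolar) <= cutoffs$apolar_dist)
      bits["hydrophobic"] <- 1L

    if (length(lig_rings) && any(rat$aromatic)) {
      p_rings <- lapply(split(seq_len(nrow(rat))[rat$aromatic],
                              rat$ring_id[rat$aromatic]),
                        function(jx) ring_geometry(rxyz[jx, , drop = FALSE]))
      for (lr in lig_rings) for (pr in p_rings) {
        d <- sqrt(sum((lr$center - pr$center)^2))
        ang <- plane_angle(lr$normal, pr$normal)
        if (d <= cutoffs$aro_face_dist && ang <= cutoffs$aro_face_angle)
          bits["aro_face"] <- 1L
        if (d <= cutoffs$aro_edge_dist && ang >= cutoffs$aro_edge_angle)
          bits["aro_edge"] <- 1L
      }
    }

    p_h <- rxyz[rat$element == "H", , drop = FALSE]
    p_acceptor <- rxyz[rat$acceptor, , drop = FALSE]
    p_donor <- rxyz[rat$donor, , drop = FALSE]
    if (nrow(lig_donor) && nrow(p_acceptor) &&
        hb_contact(lig_donor, p_acceptor, lig_h, cutoffs))
      bits["hb_donor"] <- 1L
    if (nrow(p_donor) && nrow(lig_acceptor) &&
        hb_contact(p_donor, lig_acceptor, p_h, cutoffs))
      bits["hb_acceptor"] <- 1L

    p_anion <- rxyz[rat$charge < 0, , drop = FALSE]
    p_cation <- rxyz[rat$charge > 0, , drop = FALSE]
    if (nrow(lig_cation) && nrow(p_anion) &&
        min_pair_dist(lig_cation, p_anion) <= cutoffs$ionic_dist)
      bits["cationic"] <- 1L
    if (nrow(lig_anion) && nrow(p_cation) &&
        min_pair_dist(lig_anion, p_cation) <= cutoffs$ionic_dist)
      bits["anionic"] <- 1L

    if (any(bits == 1L))
      out[[length(out) + 1L]] <- data.frame(resno = as.integer(rn),
                                            resid = rat$resid[1],
                                            t(bits))
  }
  if (length(out) == 0)
    return(data.frame(resno = integer(), resid = character(),
                      matrix(integer(), 0, 7,
                             dimnames = list(NULL, BIT_NAMES))))
  res <- do.call(rbind, out)
  res[order(res$resno), , drop = FALSE]
}

#' Collapse a 7-bit interaction record into the four contact categories
#'
#' `HB = hb_donor | hb_acceptor`, `ARO = aro_face | aro_edge`,
#' `IP = cationic | anionic`, `APO = hydrophobic`.
#'
#' @param bits numeric/integer vector of seven 0/1 flags in the order
#'   hydrophobic, aro_face, aro_edge, hb_donor, hb_acceptor, cationic,
#'   anionic (names ignored).
#' @return named integer vector with elements HB, ARO, IP, APO.
#' @export
group_to_categories <- function(bits) {
  bits <- as.integer(bits)
  if (length(bits) != 7 || any(!bits %in% c(0L, 1L)))
    stopf("expected seven 0/1 interaction flags")
  c(HB = as.integer(bits[4] | bits[5]),
    ARO = as.integer(bits[2] | bits[3]),
    IP = as.integer(bits[6] | bits[7]),
    APO = bits[1])
}
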