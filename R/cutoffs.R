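#' Geometric cutoffs for interaction typing
#'
#' Distance and angle criteria used to assign the seven interaction types
#' (hydrophobic, aromatic face-to-face, aromatic edge-to-face, hydrogen-bond
#' donor/acceptor, cationic, anionic) from frame coordinates. The defaults
#' follow widely used structural interaction-fingerprint conventions
#' (Marcou & Rognan style); they are conventions, not fitted values, and every
#' criterion is configurable.
#'
#' @param hb_dist maximum donor-acceptor heavy-atom distance, in Angstrom.
#' @param hb_angle minimum donor-H...acceptor angle, in degrees. Applied only
#'   when an explicit hydrogen is attached to the donor heavy atom; heavy-atom
#'   topologies fall back to the distance criterion alone.
#' @param apolar_dist maximum carbon-carbon distance for a hydrophobic contact.
#' @param aro_face_dist maximum ring centroid-centroid distance for
#'   face-to-face stacking.
#' @param aro_face_angle maximum angle between ring planes for face-to-face
#'   stacking, in degrees.
#' @param aro_edge_dist maximum centroid distance for edge-to-face (T-shaped)
#'   stacking.
#' @param aro_edge_angle minimum plane-plane angle for edge-to-face stacking.
#' @param ionic_dist maximum distance between opposite formal-charge centers.
#' @return an object of class `geometric_cutoffs`.
#' @examples
#' geometric_cutoffs()
#' geometric_cutoffs(hb_dist = 3.2)
#' @export
geometric_cutoffs <- function(hb_dist = 3.5, hb_angle = 120,
                              apolar_dist = 4.5,
                              aro_face_dist = 4.4, aro_face_angle = 30,
                              aro_edge_dist = 5.5, aro_edge_angle = 60,
                              ionic_dist = 4.0) {
  co <- list(hb_dist = hb_dist, hb_angle = hb_angle,
             apolar_dist = apolar_dist,
             aro_face_dist = aro_face_dist, aro_face_angle = aro_face_angle,
             aro_edge_dist = aro_edge_dist, aro_edge_angle = aro_edge_angle,
             ionic_dist = ionic_dist)
  dists <- c(co$hb_dist, co$apolar_dist, co$aro_face_dist, co$aro_edge_dist,
             co$ionic_dist)
  if (any(!is.finite(dists)) || any(dists <= 0))
    stopf("all cutoff distances must be finite and > 0")
  angs <- c(co$hb_angle, co$aro_face_angle, co$aro_edge_angle)
  if (any(angs < 0) || any(angs > 180))
    stopf("all cutoff angles must lie in [0, 180] degrees")
  structure(co, class = "geometric_cutoffs")
}

#' @export
print.geometric_cutoffs <- function(x, ...) {
  cat("Geometric interaction cutoffs\n")
  cat(sprintf("  H-bond:        d <= %.2f A, D-H...A angle >= %.0f deg\n",
              x$hb_dist, x$hb_angle))
  cat(sprintf("  hydrophobic:   C...C <= %.2f A\n", x$apolar_dist))
  cat(sprintf("  aromatic f2f:  centroid <= %.2f A, plane angle <= %.0f deg\n",
              x$aro_face_dist, x$aro_face_angle))
  cat(sprintf("  aromatic e2f:  centroid <= %.2f A, plane angle >= %.0f deg\n",
              x$aro_edge_dist, x$aro_edge_angle))
  cat(sprintf("  ionic:         <= %.2f A\n", x$ionic_dist))
  invisible(x)
}
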