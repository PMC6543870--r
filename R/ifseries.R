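#' Construct an interaction-fingerprint series
#'
#' An `if_series` is the per-frame binary contact matrix of one dissociation
#' trajectory over `(residue, category)` features named
#' `"<one-letter-residue><number>-<category>"` (e.g. `"D93-HB"`), with
#' categories HB, ARO, IP, APO. Frames are 0-indexed.
#'
#' @param frames binary matrix, one row per frame, one column per feature.
#' @param feature_names character vector of feature names (may be taken from
#'   `colnames(frames)`).
#' @param dissociation_frame 0-based frame index of the egress event, or
#'   `NA_integer_` when censored.
#' @param frame_times optional numeric vector of frame times (ns).
#' @param compound_id,replica_id,trajectory_id identifiers.
#' @return an object of class `if_series`.
#' @export
if_series <- function(frames, feature_names = colnames(frames),
                      dissociation_frame = NA_integer_, frame_times = NULL,
                      compound_id = "cmpd", replica_id = "r1",
                      trajectory_id = "t1") {
  frames <- as.matrix(frames)
  if (is.null(feature_names)) {
    if (ncol(frames) > 0) stopf("feature names are required")
    feature_names <- character(0)
  }
  if (length(feature_names) != ncol(frames))
    stopf("frames have %d columns but %d feature names", ncol(frames),
          length(feature_names))
  if (anyDuplicated(feature_names)) stopf("duplicate feature names")
  storage.mode(frames) <- "integer"
  if (length(frames) && any(!frames %in% c(0L, 1L)))
    stopf("fingerprint values must be 0 or 1")
  colnames(frames) <- feature_names
  if (is.null(frame_times)) frame_times <- (seq_len(nrow(frames)) - 1) * 1e-3
  structure(list(compound_id = compound_id, replica_id = replica_id,
                 trajectory_id = trajectory_id,
                 feature_names = feature_names, frames = frames,
                 dissociation_frame = dissociation_frame,
                 frame_times = frame_times),
            class = "if_series")
}

#' @export
print.if_series <- function(x, ...) {
  cat(sprintf("Interaction fingerprints: compound %s, replica %s, trajectory %s\n",
              x$compound_id, x$replica_id, x$trajectory_id))
  cat(sprintf("  %d frames x %d features; dissociation %s\n",
              nrow(x$frames), ncol(x$frames),
              if (is.na(x$dissociation_frame)) "censored"
              else sprintf("at frame %d", x$dissociation_frame)))
  invisible(x)
}

# Canonical feature order: ascending residue number, then HB < ARO < IP < APO.
# Names that do not follow the "<RES><number>-<CAT>" convention keep their
# given order.
order_features <- function(feature_names) {
  if (length(feature_names) == 0) return(integer(0))
  conforms <- grepl("^[A-Za-z]+[0-9]+-(HB|ARO|IP|APO)$", feature_names)
  if (!all(conforms)) return(seq_along(feature_names))
  resno <- as.integer(sub("^[A-Za-z]+([0-9]+)-.*$", "\\1", feature_names))
  cat <- match(sub("^.*-", "", feature_names), CATEGORIES)
  order(resno, cat)
}

#' Extract the interaction-fingerprint series of a whole trajectory
#'
#' Types every frame with [type_interactions()], collapses the 7-bit records
#' to the four contact categories and assembles the per-frame binary matrix
#' over the union of all `(residue, category)` features observed anywhere in
#' the trajectory. The dissociation frame is taken from
#' [detect_dissociation()].
#'
#' @param series a [frame_series()].
#' @param cutoffs a [geometric_cutoffs()] object.
#' @param dissociation_threshold egress displacement threshold in Angstrom.
#' @return an [if_series()].
#' @export
fingerprint_trajectory <- function(series, cutoffs = geometric_cutoffs(),
                                   dissociation_threshold = 30) {
  stopifnot(inherits(series, "frame_series"))
  n_frames <- nrow(series$xyz)
  per_frame <- vector("list", n_frames)
  for (f in seq_len(n_frames) - 1L) {
    ti <- type_interactions(series, f, cutoffs)
    feats <- character(0)
    if (nrow(ti)) {
      for (i in seq_len(nrow(ti))) {
        cats <- group_to_categories(as.integer(ti[i, BIT_NAMES]))
        letter <- AA_321[ti$resid[i]]
        if (is.na(letter)) letter <- "X"
        feats <- c(feats, paste0(letter, ti$resno[i], "-",
                                 names(cats)[cats == 1L]))
      }
    }
    per_frame[[f + 1L]] <- feats
  }
  all_feats <- as.character(unique(unlist(per_frame)))
  all_feats <- all_feats[order_features(all_feats)]
  mat <- matrix(0L, n_frames, length(all_feats),
                dimnames = list(NULL, all_feats))
  for (f in seq_len(n_frames)) mat[f, per_frame[[f]]] <- 1L
  if_series(mat, dissociation_frame =
              detect_dissociation(series, dissociation_threshold),
            frame_times = series$frame_times,
            compound_id = series$compound_id, replica_id = series$replica_id,
            trajectory_id = series$trajectory_id)
}

#' Write an interaction-fingerprint series to CSV with a JSON sidecar
#'
#' The CSV holds one row per frame with feature names as header; the sidecar
#' `<path>.json` records compound/replica/trajectory ids, the dissociation
#' frame and the frame times.
#'
#' @param x an [if_series()].
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_if_series <- function(x, path) {
  stopifnot(inherits(x, "if_series"))
  utils::write.csv(as.data.frame(x$frames, check.names = FALSE), path,
                   row.names = FALSE)
  meta <- list(compound_id = x$compound_id, replica_id = x$replica_id,
               trajectory_id = x$trajectory_id,
               dissociation_frame = if (is.na(x$dissociation_frame)) NULL
                                    else x$dissociation_frame,
               censored = is.na(x$dissociation_frame),
               frame_times = x$frame_times)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read an interaction-fingerprint series written by [write_if_series()]
#'
#' @param path CSV path; the sidecar is looked up at `<path>.json` (absent
#'   sidecar: ids default and the trajectory is treated as censored).
#' @return an [if_series()].
#' @export
read_if_series <- function(path) {
  frames <- as.matrix(utils::read.csv(path, check.names = FALSE))
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side, simplifyVector = TRUE)
          else list()
  gv <- function(k, d) if (!is.null(meta[[k]])) meta[[k]] else d
  dis <- gv("dissociation_frame", NA_integer_)
  if (isTRUE(gv("censored", FALSE))) dis <- NA_integer_
  if_series(frames,
            dissociation_frame = if (is.na(dis)) NA_integer_ else as.integer(dis),
            frame_times = gv("frame_times", NULL),
            compound_id = gv("compound_id", "cmpd"),
            replica_id = gv("replica_id", "r1"),
            trajectory_id = gv("trajectory_id", "t1"))
}
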