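#' Bound-state truncation mode
#'
#' Defines when the bound-state part of a trajectory ends and its transition
#' part begins, counted on the `(residue, category)` features present in the
#' first frame: mode A — at least `n_lost` (default 2) bound-state contacts
#' absent; modes B and C — at least a fraction (20% / 60%, rounded up to whole
#' contacts) of the bound-state contacts absent.
#'
#' @param mode "A", "B" or "C".
#' @param n_lost contact count for mode A.
#' @param frac fraction of bound contacts for modes B (0.20) and C (0.60);
#'   must lie in (0, 1].
#' @return an object of class `truncation_mode`.
#' @export
truncation_mode <- function(mode = c("A", "B", "C"), n_lost = 2,
                            frac = NULL) {
  mode <- match.arg(mode)
  if (is.null(frac)) frac <- switch(mode, A = NA_real_, B = 0.20, C = 0.60)
  if (mode != "A" && (!is.finite(frac) || frac <= 0 || frac > 1))
    stopf("fraction threshold must lie in (0, 1]")
  structure(list(mode = mode, n_lost = n_lost, frac = frac),
            class = "truncation_mode")
}

# Number of absent bound contacts required to start the transition part.
required_losses <- function(tm, n_bound) {
  if (tm$mode == "A") tm$n_lost else ceiling(tm$frac * n_bound)
}

#' Bound-state reference contacts of a trajectory
#'
#' The bound-state contact set is defined as the features present in the
#' first frame of the trajectory.
#'
#' @param series an [if_series()].
#' @return character vector of feature names present in frame 0.
#' @export
bound_reference <- function(series) {
  stopifnot(inherits(series, "if_series"))
  if (nrow(series$frames) < 1) stopf("trajectory has no frames")
  feats <- series$feature_names[series$frames[1, ] == 1L]
  if (length(feats) == 0)
    stopf("no bound contacts: first frame has no interactions")
  feats
}

#' Truncate the bound-state part of a fingerprint series
#'
#' Returns the transition part: frames from the first frame at which the
#' required number of bound-state contacts (see [truncation_mode()]) is
#' simultaneously absent, through the dissociation frame (inclusive; through
#' the last frame when the trajectory is censored). Later re-formation of
#' contacts does not move the truncation point. If the criterion is never met
#' the transition part is empty and the result carries `flagged = TRUE`;
#' such trajectories are excluded from aggregation with a warning.
#'
#' @param series an [if_series()].
#' @param mode a [truncation_mode()] (or the letter "A"/"B"/"C").
#' @return an [if_series()] over the same features, with attributes
#'   `truncation_frame` (0-based, `NA` when never truncated), `n_bound` and
#'   `flagged`.
#' @export
truncate_series <- function(series, mode = truncation_mode("A")) {
  stopifnot(inherits(series, "if_series"))
  if (is.character(mode)) mode <- truncation_mode(mode)
  bound <- bound_reference(series)
  need <- required_losses(mode, length(bound))
  last <- if (is.na(series$dissociation_frame)) nrow(series$frames) - 1L
          else series$dissociation_frame
  absent <- length(bound) -
    rowSums(series$frames[, bound, drop = FALSE])
  hit <- which(absent[seq_len(last + 1L)] >= need)
  if (length(hit) == 0) {
    t0 <- NA_integer_
    keep <- integer(0)
  } else {
    t0 <- as.integer(hit[1] - 1L)
    keep <- (t0 + 1L):(last + 1L)
  }
  out <- if_series(series$frames[keep, , drop = FALSE],
                   feature_names = series$feature_names,
                   dissociation_frame = series$dissociation_frame,
                   frame_times = series$frame_times[keep],
                   compound_id = series$compound_id,
                   replica_id = series$replica_id,
                   trajectory_id = series$trajectory_id)
  attr(out, "truncation_frame") <- t0
  attr(out, "n_bound") <- length(bound)
  attr(out, "flagged") <- length(keep) == 0
  out
}

#' Per-trajectory contact occurrences
#'
#' The occurrence of a feature is the fraction of transition frames in which
#' it is present.
#'
#' @param transition an [if_series()] holding the transition part of a
#'   trajectory (output of [truncate_series()]).
#' @return an object of class `trajectory_profile`: compound/trajectory ids,
#'   named occurrence vector in \[0, 1\] and `n_transition_frames`.
#' @export
trajectory_occurrence <- function(transition) {
  stopifnot(inherits(transition, "if_series"))
  n <- nrow(transition$frames)
  if (n == 0) stopf("empty transition part: no frames to average")
  structure(list(compound_id = transition$compound_id,
                 trajectory_id = transition$trajectory_id,
                 occurrence = colMeans(transition$frames),
                 n_transition_frames = n),
            class = "trajectory_profile")
}

#' Average trajectory occurrences into one compound feature row
#'
#' Unweighted mean over trajectories; a feature absent from a trajectory's
#' feature set contributes 0 for that trajectory.
#'
#' @param profiles list of [trajectory_occurrence()] profiles, all from the
#'   same compound.
#' @return named numeric vector of mean occurrences.
#' @export
aggregate_compound <- function(profiles) {
  stopifnot(length(profiles) >= 1,
            all(vapply(profiles, inherits, TRUE, "trajectory_profile")))
  ids <- unique(vapply(profiles, `[[`, "", "compound_id"))
  if (length(ids) != 1)
    stopf("profiles mix compounds: %s", paste(ids, collapse = ", "))
  feats <- unique(unlist(lapply(profiles, function(p) names(p$occurrence))))
  feats <- feats[order_features(feats)]
  acc <- stats::setNames(numeric(length(feats)), feats)
  for (p in profiles) acc[names(p$occurrence)] <-
    acc[names(p$occurrence)] + p$occurrence
  acc / length(profiles)
}

#' Compound-by-feature occurrence matrix with kinetic labels
#'
#' @param values numeric matrix: rows = compounds, columns = features.
#' @param labels numeric vector of `log10(1/k_off [s])` per compound.
#' @param annotations optional data.frame of per-compound flags (scaffold,
#'   outlier/indazole pool membership, ...), rownames = compound ids.
#' @return an object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, labels, annotations = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stopf("feature matrix needs compound row names and feature column names")
  if (anyDuplicated(rownames(values)) || anyDuplicated(colnames(values)))
    stopf("compound and feature names must be unique")
  if (anyNA(values)) stopf("feature matrix contains missing values")
  if (length(labels) != nrow(values))
    stopf("%d labels for %d compounds", length(labels), nrow(values))
  if (any(!is.finite(labels))) stopf("labels must be finite")
  labels <- stats::setNames(as.numeric(labels), rownames(values))
  if (!is.null(annotations)) {
    annotations <- as.data.frame(annotations)
    if (nrow(annotations) != nrow(values))
      stopf("annotation rows do not match compounds")
    rownames(annotations) <- rownames(values)
  }
  structure(list(values = values, labels = labels, annotations = annotations),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("Feature matrix: %d compounds x %d features\n",
              nrow(x$values), ncol(x$values)))
  cat(sprintf("  labels log10(1/koff) in [%.2f, %.2f]\n",
              min(x$labels), max(x$labels)))
  if (!is.null(x$annotations))
    cat("  annotations:", paste(names(x$annotations), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

#' Build a compound feature matrix from fingerprint series
#'
#' Runs truncation, per-trajectory occurrence averaging and per-compound
#' aggregation over a list of fingerprint series, and attaches kinetic labels.
#' Trajectories whose truncation criterion is never met are excluded with a
#' warning.
#'
#' @param series_list list of [if_series()] (any number of trajectories per
#'   compound).
#' @param kinetics data.frame with columns `compound_id` and `koff` (s^-1),
#'   optionally `out_of_range` (logical; clamped to `koff_floor`) and further
#'   annotation columns.
#' @param mode a [truncation_mode()] or letter.
#' @param koff_floor lower-limit k_off assigned to out-of-range compounds.
#' @return a [feature_matrix()]; the per-trajectory truncation report
#'   (bound-set size, truncation frame, transition length) is attached as
#'   attribute `"truncation_report"`.
#' @export
build_feature_matrix <- function(series_list, kinetics,
                                 mode = truncation_mode("A"),
                                 koff_floor = 1e-4) {
  if (is.character(mode)) mode <- truncation_mode(mode)
  report <- list(); profiles <- list()
  for (s in series_list) {
    tr <- truncate_series(s, mode)
    report[[length(report) + 1L]] <-
      data.frame(compound_id = s$compound_id, trajectory_id = s$trajectory_id,
                 n_bound = attr(tr, "n_bound"),
                 truncation_frame = attr(tr, "truncation_frame"),
                 n_transition_frames = nrow(tr$frames))
    if (attr(tr, "flagged")) {
      warnf("trajectory %s/%s never met the truncation criterion; excluded",
            s$compound_id, s$trajectory_id)
      next
    }
    profiles[[length(profiles) + 1L]] <- trajectory_occurrence(tr)
  }
  if (length(profiles) == 0) stopf("no trajectory survived truncation")
  by_cmpd <- split(profiles, vapply(profiles, `[[`, "", "compound_id"))
  rows <- lapply(by_cmpd, aggregate_compound)
  feats <- unique(unlist(lapply(rows, names)))
  feats <- feats[order_features(feats)]
  values <- matrix(0, length(rows), length(feats),
                   dimnames = list(names(rows), feats))
  for (cid in names(rows)) values[cid, names(rows[[cid]])] <- rows[[cid]]

  m <- match(rownames(values), kinetics$compound_id)
  if (anyNA(m))
    stopf("kinetics table lacks compound(s): %s",
          paste(rownames(values)[is.na(m)], collapse = ", "))
  kin <- kinetics[m, , drop = FALSE]
  koff <- clamp_out_of_range(kin$koff,
                             out_of_range = isTRUE_vec(kin$out_of_range),
                             floor = koff_floor)
  ann_cols <- setdiff(names(kin), c("compound_id", "koff"))
  ann <- if (length(ann_cols)) kin[, ann_cols, drop = FALSE] else NULL
  fm <- feature_matrix(values, labels = log10(1 / koff), annotations = ann)
  attr(fm, "truncation_report") <- do.call(rbind, report)
  fm
}

isTRUE_vec <- function(x) if (is.null(x)) FALSE else !is.na(x) & as.logical(x)

#' Drop features that are rare in every compound
#'
#' A feature is kept if and only if its mean occurrence reaches
#' `min_occurrence` in at least one compound (maximum over compounds);
#' the boundary is inclusive.
#'
#' @param fm a [feature_matrix()] (or plain matrix).
#' @param min_occurrence occurrence threshold (default 0.05).
#' @return the filtered object, same class as the input.
#' @export
filter_rare <- function(fm, min_occurrence = 0.05) {
  v <- if (inherits(fm, "feature_matrix")) fm$values else as.matrix(fm)
  keep <- apply(v, 2, max) >= min_occurrence
  if (!any(keep)) stopf("rare-feature filter removed every feature")
  subset_features(fm, keep)
}

#' Prune strongly correlated features
#'
#' Greedy scan in canonical feature order (ascending residue number, then
#' category order HB < ARO < IP < APO; non-conforming names keep the given
#' order): a feature is dropped when its squared Pearson correlation with any
#' already-kept feature exceeds `r2_max`. Zero-variance columns have undefined
#' correlation and are treated as uncorrelated (kept).
#'
#' @param fm a [feature_matrix()] (or plain matrix).
#' @param r2_max maximum allowed pairwise R^2 among kept features.
#' @return the pruned object, same class as the input.
#' @export
prune_correlated <- function(fm, r2_max = 0.9) {
  v <- if (inherits(fm, "feature_matrix")) fm$values else as.matrix(fm)
  if (ncol(v) < 2) return(fm)
  ord <- order_features(colnames(v))
  sds <- apply(v, 2, stats::sd)
  kept <- integer(0)
  for (j in ord) {
    drop <- FALSE
    if (sds[j] > 0) {
      for (k in kept) {
        if (sds[k] == 0) next
        r <- stats::cor(v[, j], v[, k])
        if (is.finite(r) && r^2 > r2_max) { drop <- TRUE; break }
      }
    }
    if (!drop) kept <- c(kept, j)
  }
  keep <- logical(ncol(v)); keep[kept] <- TRUE
  subset_features(fm, keep)
}

#' Min-max normalize each feature to \[0, 1\]
#'
#' Per feature, `x' = (x - min) / (max - min)` over all compounds; constant
#' columns map to 0. Idempotent on already-normalized matrices.
#'
#' @param fm a [feature_matrix()] (or plain matrix).
#' @return the normalized object, same class as the input.
#' @export
minmax_normalize <- function(fm) {
  v <- if (inherits(fm, "feature_matrix")) fm$values else as.matrix(fm)
  lo <- apply(v, 2, min); hi <- apply(v, 2, max)
  rng <- hi - lo
  out <- sweep(v, 2, lo)
  nz <- rng > 0
  out[, nz] <- sweep(out[, nz, drop = FALSE], 2, rng[nz], "/")
  out[, !nz] <- 0
  if (inherits(fm, "feature_matrix")) { fm$values <- out; fm } else out
}

subset_features <- function(fm, keep) {
  if (inherits(fm, "feature_matrix")) {
    fm$values <- fm$values[, keep, drop = FALSE]
    fm
  } else {
    as.matrix(fm)[, keep, drop = FALSE]
  }
}

#' Write a feature matrix as CSV
#'
#' Rows are compounds; columns are `compound_id`, the features, `label`
#' (`log10(1/k_off)`) and any annotation columns.
#'
#' @param fm a [feature_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(fm, path) {
  stopifnot(inherits(fm, "feature_matrix"))
  df <- data.frame(compound_id = rownames(fm$values),
                   fm$values, label = unname(fm$labels),
                   check.names = FALSE)
  if (!is.null(fm$annotations)) df <- cbind(df, fm$annotations)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a feature matrix written by [write_feature_matrix()]
#'
#' Also reads externally prepared occurrence tables in the same layout
#' (compound id column, feature columns, a `label` column, trailing
#' annotation columns).
#'
#' @param path CSV path.
#' @param id_col,label_col column names for compound ids and labels.
#' @return a [feature_matrix()].
#' @export
read_feature_matrix <- function(path, id_col = "compound_id",
                                label_col = "label") {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!all(c(id_col, label_col) %in% names(df)))
    stopf("expected columns '%s' and '%s'", id_col, label_col)
  ids <- as.character(df[[id_col]])
  li <- match(label_col, names(df))
  ii <- match(id_col, names(df))
  feat_cols <- seq_len(li - 1L)
  feat_cols <- setdiff(feat_cols, ii)
  values <- as.matrix(df[, feat_cols, drop = FALSE])
  rownames(values) <- ids
  ann_cols <- setdiff(seq_along(df), c(ii, feat_cols, li))
  ann <- if (length(ann_cols)) df[, ann_cols, drop = FALSE] else NULL
  feature_matrix(values, df[[label_col]], ann)
}
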