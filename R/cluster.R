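#' Fit a Gaussian mixture model with per-component full covariance
#'
#' Maximum-likelihood Gaussian mixture (via mclust, model "VVV": each
#' component has its own full covariance matrix) with hard assignments by
#' maximum responsibility. The EM run is initialized from a random seeded
#' subset, so repeated fits with different seeds explore different local
#' optima.
#'
#' @param x numeric matrix, rows = compounds, features normalized to \[0,1\].
#' @param k number of mixture components (`nrow(x) > k`).
#' @param seed integer seed for the initialization subset.
#' @param model_name mclust covariance model (default "VVV", one full
#'   covariance matrix per component).
#' @param regularize apply a light conjugate prior on means and covariances
#'   (MAP-EM, [mclust::priorControl()] defaults). Prevents the degenerate
#'   near-singular components that otherwise inflate the likelihood of
#'   over-fitted mixtures; on by default.
#' @return list with `assignments` (integer vector), `means` (k x features),
#'   `covariances`, `loglik`, `df`, `aic`, `model_name`.
#' @importFrom mclust Mclust mclustBIC adjustedRandIndex priorControl
#' @export
fit_gmm <- function(x, k, seed = 1L, model_name = "VVV", regularize = TRUE) {
  x <- as.matrix(x)
  if (nrow(x) <= k) stopf("need more compounds (%d) than clusters (%d)",
                          nrow(x), k)
  prior <- if (regularize) mclust::priorControl() else NULL
  fit <- with_seed(seed, {
    sub <- sample.int(nrow(x), max(k + 1L, ceiling(nrow(x) / 2)))
    suppressWarnings(
      mclust::Mclust(x, G = k, modelNames = model_name, verbose = FALSE,
                     prior = prior,
                     initialization = list(subset = sub)))
  })
  if (is.null(fit))
    stopf("GMM with %d components did not converge (n = %d, d = %d)",
          k, nrow(x), ncol(x))
  means <- t(fit$parameters$mean)
  colnames(means) <- colnames(x)
  list(assignments = as.integer(fit$classification),
       means = means,
       covariances = fit$parameters$variance$sigma,
       loglik = fit$loglik, df = fit$df,
       aic = -2 * fit$loglik + 2 * fit$df,
       model_name = fit$modelName)
}

#' Select the number of clusters by the Akaike information criterion
#'
#' Fits mixtures over a range of component counts with several seeded
#' restarts each and returns the count minimizing AIC (best restart per
#' count). Counts for which no fit converges are dropped.
#'
#' @param x feature matrix (rows = compounds).
#' @param k_range candidate cluster counts (default 2:10).
#' @param n_restarts seeded restarts per count (default 10).
#' @param seed master seed.
#' @param ... passed to [fit_gmm()].
#' @return the selected count, with the AIC scan table in attribute
#'   `"scan"`.
#' @export
select_k_aic <- function(x, k_range = 2:10, n_restarts = 10, seed = 1L, ...) {
  if (length(k_range) == 0) stopf("empty cluster-count range")
  aics <- vapply(k_range, function(k) {
    vals <- vapply(seq_len(n_restarts), function(j) {
      f <- tryCatch(fit_gmm(x, k, seed = substream_seed(seed, "aic", k * 1000 + j),
                            ...),
                    error = function(e) NULL)
      if (is.null(f)) NA_real_ else f$aic
    }, 0)
    if (all(is.na(vals))) NA_real_ else min(vals, na.rm = TRUE)
  }, 0)
  if (all(is.na(aics))) stopf("no mixture fit converged in the scan range")
  kstar <- k_range[which.min(aics)]
  attr(kstar, "scan") <- data.frame(k = k_range, aic = aics)
  kstar
}

#' Repeated mixture clustering ordered by residence time
#'
#' Performs independent seeded clustering repeats; within each repeat the
#' clusters are relabelled in order of increasing mean label (log residence
#' time) and the component mean vectors are stored as the cluster feature
#' weights. Across repeats, clusters are matched by rank: the ensemble
#' per-cluster residence time `tau_c` is the mean over repeats of the
#' rank-matched cluster averages. Stability is reported as the mean pairwise
#' adjusted Rand index between repeat assignments.
#'
#' @param x feature matrix (rows = compounds, normalized).
#' @param labels numeric `log10(tau)` labels aligned with rows.
#' @param k number of clusters.
#' @param repeats number of independent clustering repeats (default 50).
#' @param seed master seed.
#' @param ... passed to [fit_gmm()].
#' @return an object of class `cluster_ensemble`: `tau_c` (mean per ordered
#'   cluster), `tau_c_sd`, `sizes` (mean cluster sizes), `feature_weights`
#'   (features x clusters, mean component means), `assignments` (repeats x
#'   compounds, rank-ordered labels), `stability`.
#' @export
repeat_cluster <- function(x, labels, k, repeats = 50, seed = 1L, ...) {
  x <- as.matrix(x)
  stopifnot(length(labels) == nrow(x))
  n <- nrow(x)
  assign_mat <- matrix(NA_integer_, repeats, n)
  tau_mat <- matrix(NA_real_, repeats, k)
  size_mat <- matrix(NA_real_, repeats, k)
  w_acc <- array(0, dim = c(repeats, ncol(x), k))
  for (r in seq_len(repeats)) {
    f <- fit_gmm(x, k, seed = substream_seed(seed, "repeat", r), ...)
    cl_tau <- tapply(labels, f$assignments, mean)
    # order clusters by increasing mean residence time
    present <- as.integer(names(cl_tau))
    ord <- present[order(cl_tau)]
    rank_of <- stats::setNames(seq_along(ord), ord)
    assign_mat[r, ] <- unname(rank_of[as.character(f$assignments)])
    tau_mat[r, seq_along(ord)] <- sort(cl_tau)
    size_mat[r, ] <- tabulate(assign_mat[r, ], nbins = k)
    for (j in seq_along(ord)) w_acc[r, , j] <- f$means[ord[j], ]
  }
  stability <- ensemble_stability(assign_mat)
  fw <- apply(w_acc, c(2, 3), mean, na.rm = TRUE)
  dimnames(fw) <- list(colnames(x), paste0("cluster", seq_len(k)))
  structure(list(k = k, repeats = repeats,
                 tau_c = colMeans(tau_mat, na.rm = TRUE),
                 tau_c_sd = apply(tau_mat, 2, stats::sd, na.rm = TRUE),
                 sizes = colMeans(size_mat),
                 feature_weights = fw,
                 assignments = assign_mat,
                 compound_ids = rownames(x),
                 labels = labels,
                 stability = stability),
            class = "cluster_ensemble")
}

ensemble_stability <- function(assign_mat) {
  r <- nrow(assign_mat)
  if (r < 2) return(NA_real_)
  pairs <- utils::combn(r, 2)
  mean(apply(pairs, 2, function(p)
    mclust::adjustedRandIndex(assign_mat[p[1], ], assign_mat[p[2], ])))
}

#' @export
print.cluster_ensemble <- function(x, ...) {
  cat(sprintf("Cluster ensemble: k = %d, %d repeats (stability ARI %.2f)\n",
              x$k, x$repeats, x$stability))
  for (j in seq_len(x$k))
    cat(sprintf("  cluster %d: mean log10(tau) %+0.2f (SD %.2f), mean size %.1f\n",
                j, x$tau_c[j], x$tau_c_sd[j], x$sizes[j]))
  invisible(x)
}

#' Per-cluster fragment occupancy
#'
#' For each ordered cluster and each fragment class, the number of member
#' compounds carrying the fragment divided by the cluster size. With an
#' ensemble, occupancies are computed per repeat on the rank-ordered clusters
#' and averaged; a single repeat can be selected with `repeat_index`.
#'
#' @param ensemble a [repeat_cluster()] result.
#' @param fragments data.frame with a `compound_id` column and one or more
#'   fragment-class columns (factors/characters from a controlled
#'   vocabulary, e.g. exposed R1 and buried R2 classes).
#' @param repeat_index optional single repeat to evaluate.
#' @return matrix of occupancies in \[0,1\]: rows = `<column>:<class>`
#'   fragment labels, columns = ordered clusters.
#' @export
fragment_occupancy <- function(ensemble, fragments, repeat_index = NULL) {
  stopifnot(inherits(ensemble, "cluster_ensemble"))
  ids <- ensemble$compound_ids
  if (is.null(ids)) ids <- as.character(seq_len(ncol(ensemble$assignments)))
  m <- match(ids, fragments$compound_id)
  if (anyNA(m))
    stopf("missing fragment annotations for compound(s): %s",
          paste(ids[is.na(m)], collapse = ", "))
  frag <- fragments[m, setdiff(names(fragments), "compound_id"), drop = FALSE]
  # expand to indicator columns "<column>:<class>"
  ind <- do.call(cbind, lapply(names(frag), function(cn) {
    cls <- sort(unique(as.character(frag[[cn]])))
    sapply(cls, function(cl) as.integer(frag[[cn]] == cl))
  }))
  colnames(ind) <- unlist(lapply(names(frag), function(cn)
    paste0(cn, ":", sort(unique(as.character(frag[[cn]]))))))
  reps <- if (is.null(repeat_index)) seq_len(nrow(ensemble$assignments))
          else repeat_index
  acc <- array(NA_real_, dim = c(length(reps), ncol(ind), ensemble$k))
  for (ri in seq_along(reps)) {
    a <- ensemble$assignments[reps[ri], ]
    for (j in seq_len(ensemble$k)) {
      mem <- a == j
      acc[ri, , j] <- if (any(mem)) colSums(ind[mem, , drop = FALSE]) / sum(mem)
                      else 0
    }
  }
  occ <- apply(acc, c(2, 3), mean)
  dimnames(occ) <- list(colnames(ind), paste0("cluster", seq_len(ensemble$k)))
  occ
}
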