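#' Run the trajectory-to-model pipeline from a configuration
#'
#' Orchestrates the stages fingerprint (trajectories to per-frame contact
#' tables), featurize (truncation, aggregation, filtering, normalization),
#' tau (egress-time residence estimates and scaling), train (repeated-split
#' regression evaluation) and cluster (mixture clustering). Stages run only
#' when their inputs are configured. Every output directory carries a
#' `report.json` with the configuration hash, the master seed and per-stage
#' record counts; re-running with identical configuration and seed reproduces
#' the outputs byte for byte.
#'
#' Configuration fields (a named list, or a YAML file path):
#' \describe{
#'   \item{output_dir}{output directory (required).}
#'   \item{seed}{master seed (default 1); all stage randomness is derived
#'     from it via named substreams.}
#'   \item{trajectories}{list of entries with `topology`, optional `frames`,
#'     optional `ligand_types`, `compound_id`, `replica_id`, `trajectory_id`.}
#'   \item{if_files}{character vector of fingerprint CSVs (alternative to
#'     `trajectories`).}
#'   \item{kinetics}{CSV with `compound_id`, `koff`, optional `out_of_range`
#'     and annotation columns.}
#'   \item{modes}{truncation data sets to build (default `c("A","B","C")`).}
#'   \item{min_occurrence, r2_max}{filter thresholds (defaults 0.05, 0.9).}
#'   \item{normalize}{min-max normalize matrices (default TRUE).}
#'   \item{egress}{egress-time CSV for the tau stage.}
#'   \item{train}{list: `rounds`, `models`, optional `mode`, optional
#'     `constraints` (fields of [split_constraints()]).}
#'   \item{cluster}{list: `k` or `k_range`, `repeats`, optional `mode`.}
#'   \item{fragments}{fragment-annotation CSV (`compound_id` + class
#'     columns) for per-cluster occupancy.}
#' }
#'
#' @param config named list or path to a YAML file.
#' @return the run report (invisibly written to `report.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$output_dir)) stopf("config: output_dir is required")
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  out <- config$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  report <- list(config_hash = config_hash(config), seed = seed,
                 stages = list())
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("stage %s: %s", name, conditionMessage(e)))
  }
  log_msg <- function(...) message(sprintf(...))

  if_files <- config$if_files
  if (!is.null(config$trajectories)) {
    if_files <- stage("fingerprint", {
      dir.create(file.path(out, "if"), showWarnings = FALSE)
      paths <- vapply(config$trajectories, function(tr) {
        fs <- read_trajectory(tr$topology, tr$frames,
                              ligand_types = tr$ligand_types,
                              compound_id = tr$compound_id,
                              replica_id = if (is.null(tr$replica_id)) "r1"
                                           else tr$replica_id,
                              trajectory_id = if (is.null(tr$trajectory_id))
                                "t1" else tr$trajectory_id)
        ifs <- fingerprint_trajectory(fs)
        write_if_series(ifs, file.path(out, "if",
          sprintf("%s_%s_%s.csv", ifs$compound_id, ifs$replica_id,
                  ifs$trajectory_id)))
      }, "")
      log_msg("fingerprint: %d trajectories", length(paths))
      report$stages$fingerprint <- list(n_trajectories = length(paths))
      paths
    })
  }

  matrices <- list()
  if (!is.null(if_files) && !is.null(config$kinetics)) {
    stage("featurize", {
      series <- lapply(if_files, read_if_series)
      kinetics <- utils::read.csv(config$kinetics)
      modes <- if (is.null(config$modes)) c("A", "B", "C") else config$modes
      min_occ <- if (is.null(config$min_occurrence)) 0.05
                 else config$min_occurrence
      r2 <- if (is.null(config$r2_max)) 0.9 else config$r2_max
      counts <- list()
      for (m in modes) {
        fm <- build_feature_matrix(series, kinetics, mode = m)
        n_raw <- ncol(fm$values)
        fm <- filter_rare(fm, min_occ)
        n_rare <- ncol(fm$values)
        fm <- prune_correlated(fm, r2)
        if (is.null(config$normalize) || isTRUE(config$normalize))
          fm <- minmax_normalize(fm)
        path <- file.path(out, sprintf("matrix_%s.csv", m))
        write_feature_matrix(fm, path)
        rep <- attr(fm, "truncation_report")
        utils::write.csv(rep, file.path(out, sprintf("truncation_%s.csv", m)),
                         row.names = FALSE)
        counts[[m]] <- list(n_compounds = nrow(fm$values),
                            n_features_raw = n_raw,
                            n_features_rare_filtered = n_rare,
                            n_features_final = ncol(fm$values),
                            transition_frames = sum(rep$n_transition_frames))
        matrices[[m]] <- fm
        log_msg("featurize[%s]: %d x %d (raw %d)", m, nrow(fm$values),
                ncol(fm$values), n_raw)
      }
      report$stages$featurize <- counts
    })
  }

  if (!is.null(config$egress)) {
    stage("tau", {
      eg <- read_egress_times(config$egress)
      est <- lapply(eg, tau_ramd)
      fit <- NULL
      if (!is.null(config$kinetics)) {
        kin <- utils::read.csv(config$kinetics)
        m <- match(names(est), kin$compound_id)
        if (!anyNA(m)) {
          koff <- clamp_out_of_range(kin$koff[m],
                                     isTRUE_vec(kin$out_of_range[m]))
          lik <- log10(1 / koff)
          excl <- if (!is.null(kin$outlier))
            kin$compound_id[isTRUE_vec(kin$outlier)] else character(0)
          fit <- fit_scaling(est, lik, exclude = excl)
          for (i in seq_along(est))
            est[[i]]$scaled_log_tau <- predict(fit, est[[i]]$tau_ramd)
        }
      }
      payload <- list(
        estimates = lapply(est, function(e)
          list(compound_id = e$compound_id, tau_ramd_ns = e$tau_ramd,
               replica_sd_ns = e$replica_sd, n_replicas = e$n_replicas,
               scaled_log_tau = if (is.na(e$scaled_log_tau)) NULL
                                else e$scaled_log_tau)),
        scaling_fit = if (is.null(fit)) NULL else
          list(slope = fit$slope, intercept = fit$intercept,
               n_fit = fit$n_fit, r_squared = fit$r_squared,
               excluded_outliers = fit$excluded_outliers))
      jsonlite::write_json(payload, file.path(out, "tau_estimates.json"),
                           auto_unbox = TRUE, digits = NA)
      report$stages$tau <- list(n_compounds = length(est),
                                 scaled = !is.null(fit))
      log_msg("tau: %d compounds", length(est))
    })
  }

  get_matrix <- function(mode_pref) {
    if (length(matrices)) {
      m <- if (!is.null(mode_pref) && mode_pref %in% names(matrices))
        mode_pref else names(matrices)[1]
      return(matrices[[m]])
    }
    if (!is.null(config$matrix)) return(read_feature_matrix(config$matrix))
    stopf("no feature matrix available (configure 'matrix' or featurize inputs)")
  }

  if (!is.null(config$train)) {
    stage("train", {
      tc <- config$train
      fm <- get_matrix(tc$mode)
      constraints <- if (is.null(tc$constraints))
        constraints_from_annotations(fm)
      else do.call(split_constraints, tc$constraints)
      re <- repeated_evaluation(
        fm,
        n_rounds = if (is.null(tc$rounds)) 200 else tc$rounds,
        models = if (is.null(tc$models)) c("LR", "SVR", "Dummy")
                 else tc$models,
        constraints = constraints,
        seed = substream_seed(seed, "train"))
      utils::write.csv(re$results, file.path(out, "round_results.csv"),
                       row.names = FALSE)
      utils::write.csv(summary(re), file.path(out, "model_summary.csv"),
                       row.names = FALSE)
      if (!is.null(re$coefficients))
        utils::write.csv(coefficient_summary(re),
                         file.path(out, "lr_coefficients.csv"),
                         row.names = FALSE)
      report$stages$train <- list(n_rounds_done =
                                     length(unique(re$results$round)),
                                   n_failures = length(re$failures))
      log_msg("train: %d rounds", length(unique(re$results$round)))
    })
  }

  if (!is.null(config$cluster)) {
    stage("cluster", {
      cc <- config$cluster
      fm <- get_matrix(cc$mode)
      x <- fm$values
      k <- cc$k
      if (is.null(k)) {
        kr <- if (is.null(cc$k_range)) 2:10 else cc$k_range[1]:cc$k_range[2]
        k <- select_k_aic(x, kr, seed = substream_seed(seed, "cluster.k"))
      }
      ens <- repeat_cluster(x, fm$labels, k,
                            repeats = if (is.null(cc$repeats)) 50
                                      else cc$repeats,
                            seed = substream_seed(seed, "cluster"))
      utils::write.csv(data.frame(feature = rownames(ens$feature_weights),
                                  ens$feature_weights, check.names = FALSE),
                       file.path(out, "cluster_feature_weights.csv"),
                       row.names = FALSE)
      payload <- list(k = ens$k, repeats = ens$repeats,
                      tau_c = ens$tau_c, tau_c_sd = ens$tau_c_sd,
                      sizes = ens$sizes, stability = ens$stability)
      jsonlite::write_json(payload, file.path(out, "cluster_ensemble.json"),
                           auto_unbox = TRUE, digits = NA)
      if (!is.null(config$fragments)) {
        frag <- utils::read.csv(config$fragments)
        occ <- fragment_occupancy(ens, frag)
        utils::write.csv(data.frame(fragment = rownames(occ), occ,
                                    check.names = FALSE),
                         file.path(out, "fragment_occupancy.csv"),
                         row.names = FALSE)
      }
      report$stages$cluster <- list(k = as.integer(k),
                                     stability = ens$stability)
      log_msg("cluster: k = %d", k)
    })
  }

  jsonlite::write_json(report, file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(report)
}
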