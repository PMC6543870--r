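#' Replica-structured egress times
#'
#' Container for the dissociation (egress) times of one compound: one or more
#' equilibration replicas, each with the egress times (ns) of its dissociation
#' trajectories and censoring flags for trajectories that never dissociated.
#'
#' @param compound_id compound identifier.
#' @param replicas named list; each element a list with `times` (numeric, ns)
#'   and optional `censored` (logical, same length; default all `FALSE`).
#' @return an object of class `egress_times`.
#' @export
egress_times <- function(compound_id, replicas) {
  if (length(replicas) < 1) stopf("at least one replica is required")
  if (is.null(names(replicas)))
    names(replicas) <- paste0("r", seq_along(replicas))
  replicas <- lapply(replicas, function(r) {
    if (is.numeric(r)) r <- list(times = r)
    if (is.null(r$censored)) r$censored <- rep(FALSE, length(r$times))
    if (length(r$censored) != length(r$times))
      stopf("censored flags do not match times")
    if (length(r$times) < 1) stopf("each replica needs at least one trajectory")
    if (any(r$times[!r$censored] <= 0)) stopf("egress times must be positive")
    r
  })
  structure(list(compound_id = compound_id, replicas = replicas),
            class = "egress_times")
}

#' Replica-level relative residence time (t50)
#'
#' The time by which a dissociation event has been observed in 50% of a
#' replica's trajectories: the interpolated median of the egress times, with
#' censored trajectories counted as longer than every observed time. At least
#' half the trajectories must have dissociated; otherwise the sample is
#' insufficient and an error is raised (the remedy is to simulate more
#' trajectories).
#'
#' @param times numeric egress times (ns).
#' @param censored logical censoring flags (default none).
#' @return the t50 in ns.
#' @export
replica_t50 <- function(times, censored = rep(FALSE, length(times))) {
  stopifnot(length(times) == length(censored))
  if (!any(!censored)) stopf("no uncensored egress times")
  if (mean(censored) >= 0.5)
    stopf("insufficient sampling: %.0f%% of trajectories censored",
          100 * mean(censored))
  x <- times
  x[censored] <- Inf  # censored egress is later than every observed time
  unname(stats::median(x))
}

#' Relative residence time of a compound from replica egress times
#'
#' The compound-level relative residence time is the mean of the per-replica
#' t50 values; its uncertainty is their sample standard deviation (0 for a
#' single replica).
#'
#' @param e an [egress_times()] object.
#' @return an object of class `residence_estimate` with fields `compound_id`,
#'   `tau_ramd` (ns), `replica_sd` (ns), `n_replicas` and `replica_t50s`.
#' @export
tau_ramd <- function(e) {
  stopifnot(inherits(e, "egress_times"))
  t50 <- vapply(e$replicas, function(r) replica_t50(r$times, r$censored), 0)
  sdv <- if (length(t50) > 1) stats::sd(t50) else 0
  structure(list(compound_id = e$compound_id,
                 tau_ramd = mean(t50), replica_sd = sdv,
                 n_replicas = length(t50), replica_t50s = t50,
                 scaled_log_tau = NA_real_),
            class = "residence_estimate")
}

#' @export
print.residence_estimate <- function(x, ...) {
  cat(sprintf("tau(RAMD) %s: %.4g ns (SD %.3g over %d replicas)\n",
              x$compound_id, x$tau_ramd, x$replica_sd, x$n_replicas))
  if (!is.na(x$scaled_log_tau))
    cat(sprintf("  scaled log10 tau: %.3f log10(s)\n", x$scaled_log_tau))
  invisible(x)
}

#' Fit the scaling of relative residence times to experimental off-rates
#'
#' Ordinary least squares of `log10(tau_RAMD [ns])` on the experimental
#' `log10(1/k_off [s])`, excluding a declared outlier list. The fitted line
#' converts relative residence times to the experimental scale.
#'
#' @param taus list of [tau_ramd()] estimates (or a numeric vector of
#'   tau_RAMD values in ns, named by compound).
#' @param log_inv_koff numeric vector of `log10(1/k_off)` aligned with `taus`.
#' @param exclude character vector of compound ids excluded as outliers.
#' @return an object of class `scaling_fit` with `slope`, `intercept`,
#'   `excluded_outliers` and `n_fit`.
#' @export
fit_scaling <- function(taus, log_inv_koff, exclude = character(0)) {
  if (is.list(taus)) {
    ids <- vapply(taus, `[[`, "", "compound_id")
    tau <- stats::setNames(vapply(taus, `[[`, 0, "tau_ramd"), ids)
  } else {
    tau <- taus
    ids <- names(tau)
    if (is.null(ids)) ids <- as.character(seq_along(tau))
  }
  if (length(tau) != length(log_inv_koff))
    stopf("tau and k_off vectors differ in length")
  keep <- !(ids %in% exclude) & is.finite(log_inv_koff) & is.finite(tau) &
    tau > 0
  if (sum(keep) < 3) stopf("scaling fit needs at least 3 compounds")
  x <- log_inv_koff[keep]; y <- log10(tau[keep])
  if (stats::var(x) == 0) stopf("degenerate fit: no variance in log10(1/koff)")
  fit <- stats::lm(y ~ x)
  r2 <- if (stats::var(y) == 0) 1 else stats::cor(x, y)^2
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 excluded_outliers = exclude, n_fit = sum(keep),
                 r_squared = r2),
            class = "scaling_fit")
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat(sprintf("Scaling fit (n = %d%s):\n", x$n_fit,
              if (length(x$excluded_outliers))
                sprintf(", %d outliers excluded", length(x$excluded_outliers))
              else ""))
  cat(sprintf("  log10(tau_RAMD) = %.3f * log10(1/koff) %+.3f   (R2 = %.3f)\n",
              x$slope, x$intercept, x$r_squared))
  invisible(x)
}

#' Convert relative residence times to the experimental log10 scale
#'
#' Inverts the [fit_scaling()] line: predicted
#' `log10(tau [s]) = (log10(tau_RAMD) - intercept) / slope`.
#'
#' @param object a `scaling_fit`.
#' @param tau_ramd numeric vector of relative residence times (ns).
#' @param ... unused.
#' @return predicted `log10(tau)` in log10 seconds.
#' @export
predict.scaling_fit <- function(object, tau_ramd, ...) {
  (log10(tau_ramd) - object$intercept) / object$slope
}

#' Agreement between scaled predictions and experimental residence times
#'
#' @param predicted predicted `log10(tau)` (log10 s).
#' @param observed experimental `log10(1/k_off)` (log10 s), same length.
#' @param bin_edges_s residence-time bin edges in seconds for the per-range
#'   MAE (defaults 1, 2, 3 s).
#' @return list with `mae`, `r_squared` (squared Pearson correlation) and
#'   `per_range_mae` (named by bin).
#' @export
evaluate_tau <- function(predicted, observed, bin_edges_s = c(1, 2, 3)) {
  if (length(predicted) != length(observed))
    stopf("prediction and observation vectors differ in length")
  edges <- log10(bin_edges_s)
  bins <- cut(observed, c(-Inf, edges, Inf),
              labels = c(sprintf("<%gs", bin_edges_s[1]),
                         sprintf("%gs-%gs", utils::head(bin_edges_s, -1),
                                 utils::tail(bin_edges_s, -1)),
                         sprintf(">%gs", utils::tail(bin_edges_s, 1))))
  ae <- abs(predicted - observed)
  list(mae = mean(ae),
       r_squared = suppressWarnings(stats::cor(predicted, observed))^2,
       per_range_mae = tapply(ae, bins, mean))
}

#' Clamp out-of-measurement-range off-rates to a lower-limit value
#'
#' Compounds whose affinity and residence time fall outside the measurement
#' range are assigned a lower-limit `k_off` (default 1e-4 s^-1).
#'
#' @param koff numeric off-rates (s^-1).
#' @param out_of_range logical flags, recycled to `length(koff)`.
#' @param floor lower-limit value assigned to flagged compounds.
#' @return clamped off-rates, with attribute `"clamped"` holding the flags.
#' @export
clamp_out_of_range <- function(koff, out_of_range = FALSE, floor = 1e-4) {
  out_of_range <- rep_len(out_of_range, length(koff))
  if (any(!out_of_range & (!is.finite(koff) | koff <= 0)))
    stopf("in-range koff values must be positive and finite")
  koff[out_of_range] <- floor
  attr(koff, "clamped") <- out_of_range
  koff
}

#' Read an egress-time table
#'
#' Expected CSV columns: `compound_id`, `replica_id`, `trajectory_id`,
#' `time_ns`, optional `censored`.
#'
#' @param path CSV path.
#' @return named list of [egress_times()] objects, one per compound.
#' @export
read_egress_times <- function(path) {
  df <- utils::read.csv(path)
  need <- c("compound_id", "replica_id", "time_ns")
  if (!all(need %in% names(df)))
    stopf("egress table lacks column(s): %s",
          paste(setdiff(need, names(df)), collapse = ", "))
  if (is.null(df$censored)) df$censored <- FALSE
  lapply(split(df, df$compound_id), function(d) {
    reps <- lapply(split(d, d$replica_id), function(r)
      list(times = r$time_ns, censored = as.logical(r$censored)))
    egress_times(d$compound_id[1], reps)
  })
}

#' Write egress times to a CSV table
#'
#' @param x a single [egress_times()] object or a list of them.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_egress_times <- function(x, path) {
  if (inherits(x, "egress_times")) x <- list(x)
  rows <- lapply(x, function(e) {
    do.call(rbind, lapply(names(e$replicas), function(rn) {
      r <- e$replicas[[rn]]
      data.frame(compound_id = e$compound_id, replica_id = rn,
                 trajectory_id = paste0("t", seq_along(r$times)),
                 time_ns = r$times, censored = r$censored)
    }))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
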