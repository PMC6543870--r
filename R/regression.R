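#' Constraints for stratified train/test splitting
#'
#' The evaluation protocol holds out 20% of compounds as an external test set
#' while forcing it to contain a fixed number of compounds from a declared
#' outlier pool (compounds whose residence time is poorly estimated from
#' trajectory lengths alone) and a minimum share of the dominant congeneric
#' series (the indazole pool), which would otherwise dominate training.
#'
#' @param test_fraction fraction of compounds held out (default 0.20).
#' @param n_outlier_in_test number of test compounds drawn from the outlier
#'   pool (default 2).
#' @param outlier_pool,indazole_pool character vectors of compound ids; either
#'   may be empty (`character(0)`), in which case that constraint is skipped.
#'   Overlap is resolved with outlier priority.
#' @param min_indazole_in_test minimum indazole compounds in the test set;
#'   default `ceiling(0.2 * |pool|)`, raised to 9 when the pool has at least
#'   45 members.
#' @return an object of class `split_constraints`.
#' @export
split_constraints <- function(test_fraction = 0.20, n_outlier_in_test = 2,
                              outlier_pool = character(0),
                              indazole_pool = character(0),
                              min_indazole_in_test = NULL) {
  indazole_pool <- setdiff(indazole_pool, outlier_pool)  # outlier priority
  if (is.null(min_indazole_in_test)) {
    min_indazole_in_test <- ceiling(0.2 * length(indazole_pool))
    if (length(indazole_pool) >= 45)
      min_indazole_in_test <- max(min_indazole_in_test, 9L)
  }
  structure(list(test_fraction = test_fraction,
                 n_outlier_in_test = n_outlier_in_test,
                 outlier_pool = outlier_pool,
                 indazole_pool = indazole_pool,
                 min_indazole_in_test = as.integer(min_indazole_in_test)),
            class = "split_constraints")
}

#' Build split constraints from feature-matrix annotations
#'
#' Looks for logical annotation columns `outlier` and `indazole`.
#'
#' @param fm a [feature_matrix()].
#' @param ... passed to [split_constraints()].
#' @return a `split_constraints` object.
#' @export
constraints_from_annotations <- function(fm, ...) {
  ann <- fm$annotations
  pool <- function(col) {
    if (is.null(ann) || is.null(ann[[col]])) character(0)
    else rownames(fm$values)[isTRUE_vec(ann[[col]])]
  }
  split_constraints(outlier_pool = pool("outlier"),
                    indazole_pool = pool("indazole"), ...)
}

#' Constrained train/test split
#'
#' @param compound_ids character vector of all compound ids.
#' @param constraints a [split_constraints()] object.
#' @param seed integer seed; splits are deterministic given the seed.
#' @return list with `train` and `test` id vectors (disjoint, covering all
#'   compounds).
#' @export
split_train_test <- function(compound_ids,
                             constraints = split_constraints(), seed = 1L) {
  co <- constraints
  n <- length(compound_ids)
  n_test <- round(co$test_fraction * n)
  out_pool <- intersect(co$outlier_pool, compound_ids)
  ind_pool <- intersect(co$indazole_pool, compound_ids)
  n_out <- if (length(out_pool)) co$n_outlier_in_test else 0L
  n_ind <- if (length(ind_pool)) co$min_indazole_in_test else 0L
  if (n_out > length(out_pool))
    stopf("outlier pool (%d) too small for %d test outliers",
          length(out_pool), n_out)
  if (n_ind > length(ind_pool))
    stopf("indazole pool (%d) too small for %d test indazoles",
          length(ind_pool), n_ind)
  rest_pool <- setdiff(compound_ids, c(out_pool, ind_pool))
  n_rest <- n_test - n_out - n_ind
  if (n_rest < 0)
    stopf("test set of %d cannot hold %d constrained compounds", n_test,
          n_out + n_ind)
  if (n_rest > length(rest_pool))
    stopf("unconstrained pool (%d) too small for %d test compounds",
          length(rest_pool), n_rest)
  test <- with_seed(seed, c(
    sample_ids(out_pool, n_out),
    sample_ids(ind_pool, n_ind),
    sample_ids(rest_pool, n_rest)))
  list(train = setdiff(compound_ids, test), test = test)
}

# sample() without the length-1 surprise
sample_ids <- function(x, k) if (k == 0) character(0) else x[sample.int(length(x), k)]

#' Mean absolute error
#'
#' @param pred,obs numeric vectors of equal length.
#' @return `mean(abs(pred - obs))`.
#' @export
mae <- function(pred, obs) {
  if (length(pred) != length(obs)) stopf("length mismatch in mae()")
  mean(abs(pred - obs))
}

#' External-validation determination coefficient Q2F3
#'
#' `1 - (sum((obs_test - pred_test)^2) / n_test) /
#'      (sum((obs_train - mean(obs_train))^2) / n_train)`.
#' Scales the test-set prediction error by the training-set label variance,
#' making values comparable across test sets of different sizes; the
#' training-mean (null) predictor scores 0 in expectation.
#'
#' @param pred_test,obs_test test-set predictions and observations.
#' @param obs_train training-set observations.
#' @return the Q2F3 value (1 = perfect; <= 0 = no better than the null).
#' @export
q2f3 <- function(pred_test, obs_test, obs_train) {
  if (length(pred_test) != length(obs_test)) stopf("length mismatch in q2f3()")
  denom <- sum((obs_train - mean(obs_train))^2) / length(obs_train)
  if (denom == 0) stopf("zero training variance in q2f3()")
  1 - (sum((obs_test - pred_test)^2) / length(obs_test)) / denom
}

# ---- model fitting -------------------------------------------------------

# Closed-form ridge regression with an unpenalized intercept:
# features and labels are centered on training means, coefficients solve
# (Xc'Xc + alpha I) b = Xc'y.
ridge_fit <- function(x, y, alpha) {
  xbar <- colMeans(x); ybar <- mean(y)
  xc <- sweep(x, 2, xbar)
  b <- solve(crossprod(xc) + diag(alpha, ncol(x)), crossprod(xc, y - ybar))
  list(coefficients = drop(b), intercept = ybar - sum(xbar * b),
       predict = function(newx) drop(newx %*% b) + (ybar - sum(xbar * b)))
}

#' Default hyperparameter grids
#'
#' LR: regularization strength, 13 log-spaced values over 1e-3..1e3.
#' SVR (RBF kernel): error-term weight `cost` 1e-1..1e3, loss epsilon
#' \{0.01, 0.05, 0.1, 0.2\}, kernel width `gamma` 1e-3..10.
#'
#' @return named list of grids (`LR`, `SVR`, `Dummy`).
#' @export
default_grids <- function() {
  list(LR = list(alpha = 10^seq(-3, 3, length.out = 13)),
       SVR = list(cost = 10^seq(-1, 3), epsilon = c(0.01, 0.05, 0.1, 0.2),
                  gamma = 10^seq(-3, 1)),
       Dummy = list())
}

#' Fit a regression model and predict
#'
#' `LR` is ridge regression solved in closed form (unpenalized intercept);
#' `SVR` is epsilon-insensitive support vector regression with an RBF kernel
#' (via e1071); `Dummy` predicts the training-label mean (the null
#' hypothesis).
#'
#' @param model_kind "LR", "SVR" or "Dummy".
#' @param train_x,train_y training features (already normalized) and labels
#'   (`log10(1/k_off)`).
#' @param test_x features to predict.
#' @param hyper named list of hyperparameters (`alpha` for LR; `cost`,
#'   `epsilon`, `gamma` for SVR).
#' @return list with `predictions` and, for LR, per-feature `coefficients`.
#' @export
fit_predict <- function(model_kind, train_x, train_y, test_x,
                        hyper = list()) {
  switch(model_kind,
    LR = {
      alpha <- if (is.null(hyper$alpha)) 1 else hyper$alpha
      fit <- ridge_fit(train_x, train_y, alpha)
      list(predictions = fit$predict(test_x),
           coefficients = stats::setNames(fit$coefficients,
                                          colnames(train_x)))
    },
    SVR = {
      fit <- tryCatch(
        e1071::svm(x = train_x, y = train_y, type = "eps-regression",
                   kernel = "radial",
                   cost = if (is.null(hyper$cost)) 1 else hyper$cost,
                   epsilon = if (is.null(hyper$epsilon)) 0.1
                             else hyper$epsilon,
                   gamma = if (is.null(hyper$gamma)) 1 / ncol(train_x)
                           else hyper$gamma,
                   scale = FALSE),
        error = function(e) {
          # degenerate case: every training point inside the epsilon tube
          # leaves no support vectors; any constant in the tube is optimal
          if (grepl("empty", conditionMessage(e), ignore.case = TRUE)) NULL
          else stop(e)
        })
      pred <- if (is.null(fit) || fit$tot.nSV == 0)
        rep(mean(train_y), nrow(test_x))
      else unname(stats::predict(fit, test_x))
      list(predictions = pred, coefficients = NULL)
    },
    Dummy = list(predictions = rep(mean(train_y), nrow(test_x)),
                 coefficients = NULL),
    stopf("unknown model kind '%s'", model_kind))
}

# 10 random-permutation validation splits at the given fraction.
shuffle_splits <- function(n, n_folds = 10, val_fraction = 0.2) {
  n_val <- max(1L, round(val_fraction * n))
  lapply(seq_len(n_folds), function(j) {
    val <- sample.int(n, n_val)
    list(train = setdiff(seq_len(n), val), val = val)
  })
}

#' Grid-search hyperparameter selection
#'
#' Exhaustive search minimizing the mean validation MAE over repeated
#' random-permutation cross-validation folds (default 10 folds, 20%
#' validation each).
#'
#' @param model_kind "LR" or "SVR" ("Dummy" has no hyperparameters).
#' @param x,y training features and labels.
#' @param grid named list of parameter value vectors; defaults to
#'   [default_grids()] for the model kind.
#' @param seed integer seed for the fold permutations.
#' @param n_folds,val_fraction cross-validation layout.
#' @return named list: the selected parameter combination, with the search
#'   table in attribute `"search"`.
#' @export
grid_search <- function(model_kind, x, y, grid = NULL, seed = 1L,
                        n_folds = 10, val_fraction = 0.2) {
  if (is.null(grid)) grid <- default_grids()[[model_kind]]
  if (model_kind == "Dummy" || length(grid) == 0) return(list())
  combos <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE)
  if (nrow(combos) == 0) stopf("empty hyperparameter grid")
  folds <- with_seed(seed, shuffle_splits(nrow(x), n_folds, val_fraction))
  score <- numeric(nrow(combos))
  if (model_kind == "LR") {
    # one normal-equation factorization pass per fold, reused across alphas
    pre <- lapply(folds, function(f) {
      xt <- x[f$train, , drop = FALSE]; yt <- y[f$train]
      xbar <- colMeans(xt); ybar <- mean(yt)
      xc <- sweep(xt, 2, xbar)
      list(xtx = crossprod(xc), xty = crossprod(xc, yt - ybar),
           xbar = xbar, ybar = ybar, xv = x[f$val, , drop = FALSE],
           yv = y[f$val])
    })
    for (i in seq_len(nrow(combos))) {
      a <- combos$alpha[i]
      score[i] <- mean(vapply(pre, function(p) {
        b <- solve(p$xtx + diag(a, ncol(x)), p$xty)
        pred <- drop(p$xv %*% b) + (p$ybar - sum(p$xbar * b))
        mae(pred, p$yv)
      }, 0))
    }
  } else {
    for (i in seq_len(nrow(combos))) {
      hyper <- as.list(combos[i, , drop = FALSE])
      score[i] <- mean(vapply(folds, function(f) {
        fp <- fit_predict(model_kind, x[f$train, , drop = FALSE],
                          y[f$train], x[f$val, , drop = FALSE], hyper)
        mae(fp$predictions, y[f$val])
      }, 0))
    }
  }
  best <- as.list(combos[which.min(score), , drop = FALSE])
  attr(best, "search") <- cbind(combos, mean_val_mae = score)
  best
}

# ---- repeated evaluation -------------------------------------------------

#' Repeated-split model evaluation
#'
#' The full evaluation protocol: for each round, (i) a constrained train/test
#' split, (ii) grid-search hyperparameter selection on the internal training
#' set, (iii) cross-validation runs in which each model is trained on a
#' sub-training set and scored (MAE, Q2F3) on the sub-training, validation and
#' external test subsets. Relative residence times from trajectory lengths,
#' when supplied as scaled predictions, are scored on the identical subsets.
#'
#' @param fm a [feature_matrix()]; features should be normalized (see
#'   [minmax_normalize()]).
#' @param n_rounds number of independent train/test splits (default 200).
#' @param models subset of `c("LR", "SVR", "Dummy")`.
#' @param constraints a [split_constraints()]; default derived from the
#'   matrix annotations.
#' @param seed master seed; per-round seeds are derived substreams.
#' @param grids hyperparameter grids, as [default_grids()].
#' @param n_cv cross-validation runs per round (default 10).
#' @param val_fraction validation fraction within the training set.
#' @param tau_predictions optional named vector of scaled `log10(tau)`
#'   predictions (see [predict.scaling_fit()]) evaluated as model "tauRAMD".
#' @param refit_hyper re-run the grid search every round (`TRUE`, default) or
#'   once on the first round.
#' @return an object of class `repeated_eval`: `results` (one row per round,
#'   model and subset), `coefficients` (rounds x features, LR), `hyper`,
#'   `failures`.
#' @export
repeated_evaluation <- function(fm, n_rounds = 200,
                                models = c("LR", "SVR", "Dummy"),
                                constraints = NULL, seed = 1L,
                                grids = default_grids(), n_cv = 10,
                                val_fraction = 0.2,
                                tau_predictions = NULL,
                                refit_hyper = TRUE) {
  stopifnot(inherits(fm, "feature_matrix"), n_rounds >= 1)
  models <- match.arg(models, c("LR", "SVR", "Dummy"), several.ok = TRUE)
  if (is.null(constraints)) constraints <- constraints_from_annotations(fm)
  x <- fm$values; y <- fm$labels
  ids <- rownames(x)
  res <- list(); coefs <- list(); hist_hyper <- list(); failures <- list()
  cached_hyper <- NULL
  for (r in seq_len(n_rounds)) {
    round_out <- tryCatch({
      sp <- split_train_test(ids, constraints,
                             seed = substream_seed(seed, "split", r))
      tr_i <- match(sp$train, ids); te_i <- match(sp$test, ids)
      hyper <- cached_hyper
      if (refit_hyper || is.null(hyper)) {
        hyper <- lapply(stats::setNames(models, models), function(mk)
          grid_search(mk, x[tr_i, , drop = FALSE], y[tr_i],
                      grid = grids[[mk]],
                      seed = substream_seed(seed, paste0("grid.", mk), r)))
        if (!refit_hyper) cached_hyper <- hyper
      }
      folds <- with_seed(substream_seed(seed, "cv", r),
                         shuffle_splits(length(tr_i), n_cv, val_fraction))
      all_models <- c(models, if (!is.null(tau_predictions)) "tauRAMD")
      metrics <- array(NA_real_,
                       dim = c(length(all_models), 3, 2, n_cv),
                       dimnames = list(all_models,
                                       c("train", "validation", "test"),
                                       c("mae", "q2f3"), NULL))
      coef_acc <- NULL
      for (j in seq_len(n_cv)) {
        st <- tr_i[folds[[j]]$train]; va <- tr_i[folds[[j]]$val]
        for (mk in models) {
          fp_tr <- fit_predict(mk, x[st, , drop = FALSE], y[st],
                               x[st, , drop = FALSE], hyper[[mk]])
          fp_va <- fit_predict(mk, x[st, , drop = FALSE], y[st],
                               x[va, , drop = FALSE], hyper[[mk]])
          fp_te <- fit_predict(mk, x[st, , drop = FALSE], y[st],
                               x[te_i, , drop = FALSE], hyper[[mk]])
          metrics[mk, "train", "mae", j] <- mae(fp_tr$predictions, y[st])
          metrics[mk, "validation", "mae", j] <- mae(fp_va$predictions, y[va])
          metrics[mk, "test", "mae", j] <- mae(fp_te$predictions, y[te_i])
          metrics[mk, "train", "q2f3", j] <-
            q2f3(fp_tr$predictions, y[st], y[st])
          metrics[mk, "validation", "q2f3", j] <-
            q2f3(fp_va$predictions, y[va], y[st])
          metrics[mk, "test", "q2f3", j] <-
            q2f3(fp_te$predictions, y[te_i], y[st])
          if (mk == "LR")
            coef_acc <- rbind(coef_acc, fp_te$coefficients)
        }
        if (!is.null(tau_predictions)) {
          tp <- tau_predictions[ids]
          metrics["tauRAMD", "train", "mae", j] <- mae(tp[st], y[st])
          metrics["tauRAMD", "validation", "mae", j] <- mae(tp[va], y[va])
          metrics["tauRAMD", "test", "mae", j] <- mae(tp[te_i], y[te_i])
          metrics["tauRAMD", "train", "q2f3", j] <- q2f3(tp[st], y[st], y[st])
          metrics["tauRAMD", "validation", "q2f3", j] <-
            q2f3(tp[va], y[va], y[st])
          metrics["tauRAMD", "test", "q2f3", j] <- q2f3(tp[te_i], y[te_i], y[st])
        }
      }
      per_round <- expand.grid(model = all_models,
                               subset = c("train", "validation", "test"),
                               stringsAsFactors = FALSE)
      per_round$round <- r
      per_round$mae <- mapply(function(m, s)
        mean(metrics[m, s, "mae", ]), per_round$model, per_round$subset)
      per_round$q2f3 <- mapply(function(m, s)
        mean(metrics[m, s, "q2f3", ]), per_round$model, per_round$subset)
      list(res = per_round,
           coefs = if (!is.null(coef_acc)) colMeans(coef_acc),
           hyper = hyper)
    }, error = function(e)
      structure(list(message = conditionMessage(e), round = r),
                class = "round_failure"))
    if (inherits(round_out, "round_failure")) {
      failures[[length(failures) + 1L]] <- round_out
      next
    }
    res[[r]] <- round_out$res
    if (!is.null(round_out$coefs)) coefs[[length(coefs) + 1L]] <- round_out$coefs
    hist_hyper[[r]] <- round_out$hyper
  }
  if (length(failures))
    warnf("%d of %d evaluation rounds failed (first: %s)",
          length(failures), n_rounds, failures[[1]]$message)
  structure(list(results = do.call(rbind, res),
                 coefficients = if (length(coefs)) do.call(rbind, coefs),
                 hyper = hist_hyper, failures = failures,
                 models = models, n_rounds = n_rounds, seed = seed),
            class = "repeated_eval")
}

#' @export
print.repeated_eval <- function(x, ...) {
  cat(sprintf("Repeated evaluation: %d rounds, models %s\n",
              x$n_rounds, paste(x$models, collapse = "/")))
  print(summary(x))
  invisible(x)
}

#' Summarize repeated-split evaluation results
#'
#' @param object a [repeated_evaluation()] result.
#' @param subset which subset to tabulate (default "test").
#' @param ... unused.
#' @return data.frame of per-model MAE and Q2F3 means and SDs.
#' @export
summary.repeated_eval <- function(object, subset = "test", ...) {
  d <- object$results[object$results$subset == subset, ]
  out <- do.call(rbind, lapply(split(d, d$model), function(g)
    data.frame(model = g$model[1], subset = subset,
               mae_mean = mean(g$mae), mae_sd = stats::sd(g$mae),
               q2f3_mean = mean(g$q2f3), q2f3_sd = stats::sd(g$q2f3))))
  rownames(out) <- NULL
  out
}

#' Mean linear-model coefficients over evaluation rounds
#'
#' @param re a [repeated_evaluation()] result that included the LR model.
#' @return data.frame with per-feature mean and SD of the ridge coefficients
#'   across rounds, sorted by decreasing absolute mean.
#' @export
coefficient_summary <- function(re) {
  stopifnot(inherits(re, "repeated_eval"))
  if (is.null(re$coefficients)) stopf("no LR rounds to summarize")
  cm <- colMeans(re$coefficients)
  cs <- if (nrow(re$coefficients) > 1) apply(re$coefficients, 2, stats::sd)
        else rep(0, length(cm))
  out <- data.frame(feature = names(cm), mean = unname(cm), sd = unname(cs))
  out[order(-abs(out$mean)), ]
}
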