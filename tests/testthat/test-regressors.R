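# Constrained splitting, metrics, model fits and the repeated-split protocol.

test_that("constrained splits honor pool quotas on a study-sized set", {
  fm <- gen_compound_set(seed = 5)
  ids <- rownames(fm$values)
  co <- constraints_from_annotations(fm)
  out_pool <- ids[fm$annotations$outlier]
  ind_pool <- setdiff(ids[fm$annotations$indazole], out_pool)
  expect_length(out_pool, 14)   # 8 quinazolines + 6 others
  expect_length(ind_pool, 45)
  expect_equal(co$min_indazole_in_test, 9L)
  # brute-force verification over many seeds
  for (seed in 1:200) {
    sp <- split_train_test(ids, co, seed)
    expect_length(sp$test, 19)  # round(0.2 * 94)
    expect_equal(sum(sp$test %in% out_pool), 2)
    expect_gte(sum(sp$test %in% ind_pool), 9)
    expect_setequal(c(sp$train, sp$test), ids)
    expect_length(intersect(sp$train, sp$test), 0)
  }
  # deterministic under seed
  expect_identical(split_train_test(ids, co, 77),
                   split_train_test(ids, co, 77))
})

test_that("splits without pools fall back to a plain random 20%", {
  ids <- sprintf("c%02d", 1:40)
  sp <- split_train_test(ids, split_constraints(), seed = 2)
  expect_length(sp$test, 8)
  expect_error(split_train_test(ids,
                                split_constraints(outlier_pool = "c01",
                                                  n_outlier_in_test = 2),
                                seed = 1),
               "too small")
})

test_that("mae and q2f3 match their closed forms", {
  expect_equal(mae(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(mae(c(1.5, 2.5), c(1, 2)), 0.5)
  v <- c(0.3, -0.2, 1.1, 0.4)
  w <- c(0.1, 0.2, 0.9, 0.1)
  expect_equal(mae(v, w), sum(abs(v - w)) / 4)
  expect_error(mae(1:3, 1:4), "length mismatch")

  expect_equal(q2f3(c(1, 2), c(1, 2), c(0, 2)), 1)
  expect_equal(q2f3(0.5, 1, c(0, 2)), 0.75)  # 1 - (0.25/1)/1
  expect_error(q2f3(1, 1, c(2, 2)), "zero training variance")
})

test_that("the null predictor has mean Q2F3 near zero on exchangeable labels", {
  set.seed(8)
  n <- 500
  y <- rnorm(n)
  q <- vapply(1:500, function(i) {
    te <- sample(n, n / 5)
    q2f3(rep(mean(y[-te]), n / 5), y[te], y[-te])
  }, 0)
  expect_lt(abs(mean(q)), 0.05)
})

test_that("Dummy predicts the training mean; its test MAE is the MAD closed form", {
  tr_y <- c(0, 2); te_x <- matrix(0, 3, 2)
  fp <- fit_predict("Dummy", matrix(0, 2, 2), tr_y, te_x)
  expect_equal(fp$predictions, rep(1, 3))
  set.seed(3)
  y_tr <- rnorm(30); y_te <- rnorm(10)
  fp2 <- fit_predict("Dummy", matrix(rnorm(60), 30), y_tr,
                     matrix(rnorm(20), 10))
  expect_equal(mae(fp2$predictions, y_te), mean(abs(y_te - mean(y_tr))))
})

test_that("ridge at zero penalty recovers exact linear data (lm oracle)", {
  set.seed(10)
  x <- matrix(runif(200), 40, 5, dimnames = list(NULL, paste0("f", 1:5)))
  w <- c(2, -1, 0.5, 0, 3)
  y <- drop(x %*% w) + 0.7
  fp <- fit_predict("LR", x, y, x, hyper = list(alpha = 0))
  expect_equal(unname(fp$coefficients), w, tolerance = 1e-8)
  expect_equal(fp$predictions, y, tolerance = 1e-8)
  # independent oracle: unregularized least squares via lm()
  ynoisy <- y + rnorm(40, 0, 0.2)
  fp2 <- fit_predict("LR", x, ynoisy, x, hyper = list(alpha = 0))
  ref <- coef(lm(ynoisy ~ x))
  expect_equal(unname(fp2$coefficients), unname(ref[-1]), tolerance = 1e-8)
  # shrinkage: coefficient norm decreases with alpha
  norms <- vapply(c(0, 1, 10, 100), function(a)
    sum(fit_predict("LR", x, ynoisy, x, list(alpha = a))$coefficients^2), 0)
  expect_true(all(diff(norms) < 0))
})

test_that("SVR respects the epsilon-insensitive tube on clean data", {
  set.seed(12)
  x <- matrix(runif(60), 30, 2)
  y <- rep(0.5, 30)  # single cluster, constant target
  fp <- fit_predict("SVR", x, y, x,
                    hyper = list(cost = 10, epsilon = 0.1, gamma = 1))
  expect_lte(mae(fp$predictions, y), 0.1)
})

test_that("grid search selects near-optimal regularization", {
  single <- grid_search("LR", matrix(runif(40), 20), runif(20),
                        grid = list(alpha = 1))
  expect_equal(single$alpha, 1)
  expect_error(grid_search("LR", matrix(runif(40), 20), runif(20),
                           grid = list(alpha = numeric(0))),
               "empty hyperparameter grid")
  set.seed(14)
  x <- matrix(runif(94 * 10), 94, 10, dimnames = list(NULL, paste0("f", 1:10)))
  y <- drop(x %*% rnorm(10)) + rnorm(94, 0, 0.3)
  grid <- list(alpha = 10^seq(-3, 3, length.out = 13))
  sel <- grid_search("LR", x, y, grid, seed = 5)
  # oracle: exhaustive evaluation of the same folds over the full grid
  search <- attr(sel, "search")
  expect_equal(sel$alpha, search$alpha[which.min(search$mean_val_mae)])
  # the selected strength performs within a hair of the brute-force best
  # over an independent ensemble of held-out evaluations
  set.seed(99)
  ho_mae <- rowMeans(vapply(1:50, function(b) {
    ho <- sample(94, 20)
    vapply(grid$alpha, function(a)
      mae(fit_predict("LR", x[-ho, ], y[-ho], x[ho, , drop = FALSE],
                      list(alpha = a))$predictions, y[ho]), 0)
  }, numeric(length(grid$alpha))))
  sel_i <- which(grid$alpha == sel$alpha)
  expect_lte(ho_mae[sel_i], min(ho_mae) + 0.01)
})

test_that("SVR grid selection beats the grid-median parameters out of sample", {
  set.seed(16)
  x <- matrix(runif(80 * 5), 80, 5, dimnames = list(NULL, paste0("f", 1:5)))
  y <- drop(x %*% c(1, -2, 0.5, 1.5, -1)) + rnorm(80, 0, 0.2)
  grid <- list(cost = c(0.1, 1, 10, 100), epsilon = c(0.05, 0.1, 0.2),
               gamma = c(0.01, 0.1, 1))
  tr <- 1:60; ho <- 61:80
  sel <- grid_search("SVR", x[tr, ], y[tr], grid, seed = 6)
  median_hyper <- list(cost = 1, epsilon = 0.1, gamma = 0.1)
  m_sel <- mae(fit_predict("SVR", x[tr, ], y[tr], x[ho, ], sel)$predictions,
               y[ho])
  m_med <- mae(fit_predict("SVR", x[tr, ], y[tr], x[ho, ],
                           median_hyper)$predictions, y[ho])
  expect_lte(m_sel, m_med + 0.02)
})

test_that("a single evaluation round produces one result per model and subset", {
  fm <- minmax_normalize(gen_compound_set(n_compounds = 40, n_features = 8,
                                          seed = 2))
  re <- repeated_evaluation(fm, n_rounds = 1, models = c("LR", "Dummy"),
                            seed = 4)
  expect_s3_class(re, "repeated_eval")
  expect_equal(nrow(re$results), 2 * 3)
  expect_true(all(re$results$mae >= 0))
  expect_equal(nrow(re$coefficients), 1)
  cs <- coefficient_summary(re)
  expect_equal(cs$sd, rep(0, ncol(fm$values)))
})

test_that("permuted labels drive Q2F3 to zero for all models", {
  fm <- gen_compound_set(n_compounds = 60, n_features = 10, seed = 31)
  fm$labels <- with_seed <- local({   # permutation null under a fixed seed
    set.seed(55); sample(fm$labels)
  })
  names(fm$labels) <- rownames(fm$values)
  fm <- minmax_normalize(fm)
  re <- repeated_evaluation(fm, n_rounds = 30, models = c("LR", "Dummy"),
                            seed = 9)
  sm <- summary(re)
  for (m in c("LR", "Dummy"))
    expect_lt(abs(sm$q2f3_mean[sm$model == m]), 0.25)
})

test_that("planted signal: LR beats Dummy and recovers the weight pattern", {
  fm <- minmax_normalize(gen_compound_set(seed = 27))
  re <- repeated_evaluation(fm, n_rounds = 25, models = c("LR", "Dummy"),
                            seed = 12)
  sm <- summary(re)
  expect_lt(sm$mae_mean[sm$model == "LR"], sm$mae_mean[sm$model == "Dummy"])
  cs <- coefficient_summary(re)
  w <- attr(fm, "manifest")$weights
  got <- cs$mean[match(colnames(fm$values), cs$feature)]
  expect_gt(cor(got, w), 0.9)
  # dominant planted feature carries the largest |mean coefficient|
  expect_equal(cs$feature[1], colnames(fm$values)[which.max(abs(w))])
})

test_that("tauRAMD predictions are scored on the identical subsets", {
  fm <- minmax_normalize(gen_compound_set(n_compounds = 40, n_features = 6,
                                          seed = 3))
  tp <- fm$labels + 0.25   # a constant-offset predictor
  re <- repeated_evaluation(fm, n_rounds = 3, models = "Dummy", seed = 8,
                            tau_predictions = tp)
  tau_rows <- re$results[re$results$model == "tauRAMD", ]
  expect_equal(nrow(tau_rows), 9)
  expect_equal(tau_rows$mae, rep(0.25, 9), tolerance = 1e-12)
})
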