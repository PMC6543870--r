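# Bound-state truncation, occurrence aggregation and the feature filters.

test_that("bound_reference is the feature set of the first frame", {
  s <- make_ifs(rbind(c(1, 1, 0), c(0, 1, 1)))
  expect_identical(bound_reference(s), c("a", "b"))
  s5 <- make_ifs(matrix(1L, 2, 5))
  expect_length(bound_reference(s5), 5)
  empty <- make_ifs(rbind(c(0, 0, 0), c(1, 1, 1)))
  expect_error(bound_reference(empty), "no bound contacts")
})

test_that("mode A truncates when two bound contacts are simultaneously absent", {
  # bound = {a,b,c}; presence per frame: (111),(110),(100),(000)
  s <- make_ifs(rbind(c(1, 1, 1), c(1, 1, 0), c(1, 0, 0), c(0, 0, 0)))
  tr <- truncate_series(s, "A")
  expect_identical(attr(tr, "truncation_frame"), 2L)
  expect_identical(unname(tr$frames), rbind(c(1L, 0L, 0L), c(0L, 0L, 0L)))
})

test_that("fractional thresholds round up to whole contacts (modes B and C)", {
  # 10 bound features, one lost per frame: frame t has t features absent
  mat <- t(vapply(0:9, function(t) as.integer(seq_len(10) > t), integer(10)))
  s <- make_ifs(mat)
  trB <- truncate_series(s, "B")  # ceil(0.2 * 10) = 2 absent -> frame 2
  trC <- truncate_series(s, "C")  # ceil(0.6 * 10) = 6 absent -> frame 6
  expect_identical(attr(trB, "truncation_frame"), 2L)
  expect_identical(attr(trC, "truncation_frame"), 6L)
  expect_equal(nrow(trB$frames), 8)
  expect_equal(nrow(trC$frames), 4)
})

test_that("re-forming contacts never un-truncates and no-loss flags", {
  # two contacts drop at frame 1 and re-form at frame 2
  s <- make_ifs(rbind(c(1, 1), c(0, 0), c(1, 1), c(0, 0)))
  tr <- truncate_series(s, "A")
  expect_identical(attr(tr, "truncation_frame"), 1L)
  expect_equal(nrow(tr$frames), 3)
  held <- make_ifs(matrix(1L, 6, 3))
  trh <- truncate_series(held, "A")
  expect_true(attr(trh, "flagged"))
  expect_equal(nrow(trh$frames), 0)
})

test_that("transition parts are nested across modes (property)", {
  # 100 seeded random schedules with bound sets >= 10
  for (seed in 1:100) {
    set.seed(seed)
    nf <- sample(10:25, 1)
    n_frames <- 40
    feats <- sprintf("R%d-HB", seq_len(nf))
    loss <- sample(1:(n_frames - 1), nf, replace = TRUE)
    s <- gen_if_series(contact_schedule(feats, loss_frame =
                                          stats::setNames(loss, feats),
                                        n_frames = n_frames),
                       seed = seed)
    tA <- attr(truncate_series(s, "A"), "truncation_frame")
    tB <- attr(truncate_series(s, "B"), "truncation_frame")
    tC <- attr(truncate_series(s, "C"), "truncation_frame")
    # brute-force oracle: first frame with >= m bound features absent
    brute <- function(m) {
      absent <- rowSums(s$frames[, feats, drop = FALSE] == 0L)
      w <- which(absent >= m)
      if (length(w)) w[1] - 1L else NA_integer_
    }
    expect_identical(tA, brute(2))
    expect_identical(tB, brute(ceiling(0.2 * nf)))
    expect_identical(tC, brute(ceiling(0.6 * nf)))
    expect_true(is.na(tC) || (!is.na(tB) && tB <= tC))
  }
})

test_that("trajectory occurrences are frame fractions", {
  m <- matrix(0L, 12, 1, dimnames = list(NULL, "a"))
  m[1:3, 1] <- 1L
  p <- trajectory_occurrence(make_ifs(m))
  expect_equal(unname(p$occurrence), 0.25)
  expect_equal(unname(trajectory_occurrence(
    make_ifs(matrix(1L, 5, 1, dimnames = list(NULL, "a"))))$occurrence), 1)
  expect_equal(unname(trajectory_occurrence(
    make_ifs(matrix(0L, 5, 1, dimnames = list(NULL, "a"))))$occurrence), 0)
  empty <- make_ifs(matrix(integer(), 0, 1, dimnames = list(NULL, "a")),
                    dis = NA_integer_)
  expect_error(trajectory_occurrence(empty), "empty transition")
})

test_that("compound aggregation averages with implicit zeros", {
  prof <- function(occ, traj) structure(
    list(compound_id = "c1", trajectory_id = traj, occurrence = occ,
         n_transition_frames = 10L), class = "trajectory_profile")
  p1 <- prof(c(a = 0.2), "t1"); p2 <- prof(c(a = 0.4), "t2")
  expect_equal(aggregate_compound(list(p1, p2)), c(a = 0.3))
  expect_equal(aggregate_compound(list(p1)), c(a = 0.2))
  # feature in 1 of 4 trajectories at occurrence 1 -> mean 0.25
  ps <- c(list(prof(c(a = 0.5, b = 1), "t1")),
          lapply(2:4, function(i) prof(c(a = 0.5), paste0("t", i))))
  expect_equal(aggregate_compound(ps), c(a = 0.5, b = 0.25))
  p_other <- structure(list(compound_id = "c2", trajectory_id = "t9",
                            occurrence = c(a = 1),
                            n_transition_frames = 5L),
                       class = "trajectory_profile")
  expect_error(aggregate_compound(list(p1, p_other)), "mix compounds")
})

make_fm <- function(values) {
  feature_matrix(values, labels = seq_len(nrow(values)))
}

test_that("the rare-feature filter keeps features by max occurrence", {
  v <- cbind(low = c(0.04, 0.02, 0.01), edge = c(0.05, 0, 0),
             high = c(1, 0, 0))
  rownames(v) <- paste0("c", 1:3)
  fm <- filter_rare(make_fm(v))
  expect_identical(colnames(fm$values), c("edge", "high"))
  expect_error(filter_rare(make_fm(v[, "low", drop = FALSE])),
               "removed every feature")
})

test_that("correlation pruning keeps a maximal weakly-correlated set", {
  set.seed(9)
  base <- runif(8)
  v <- cbind(x1 = base, x2 = base, y = runif(8),
             z1 = rev(base), z2 = rev(base), z3 = rev(base))
  rownames(v) <- paste0("c", 1:8)
  fm <- prune_correlated(make_fm(v))
  expect_identical(colnames(fm$values), c("x1", "y", "z1"))
  # orthogonal columns all survive
  vo <- diag(4); dimnames(vo) <- list(paste0("c", 1:4), paste0("f", 1:4))
  expect_equal(ncol(prune_correlated(make_fm(vo))$values), 4)
  # zero-variance columns are kept, never correlated
  vc <- cbind(const = rep(0.5, 8), x = base)
  rownames(vc) <- paste0("c", 1:8)
  expect_equal(ncol(prune_correlated(make_fm(vc))$values), 2)
})

test_that("filter cascade matches a brute-force oracle on planted matrices", {
  # 50 random 30 x 60 matrices with planted duplicate blocks
  for (seed in 1:50) {
    set.seed(seed)
    n <- 30; p <- 40
    v <- matrix(runif(n * p), n, p)
    # plant 10 near-duplicates of random existing columns and 10 rare columns
    for (j in 1:10) {
      src <- sample(p, 1)
      v <- cbind(v, v[, src] + rnorm(n, 0, 0.001))
    }
    v <- cbind(v, matrix(runif(n * 10, 0, 0.04), n, 10))
    colnames(v) <- sprintf("f%03d", seq_len(ncol(v)))
    rownames(v) <- sprintf("c%02d", seq_len(n))
    out <- prune_correlated(filter_rare(make_fm(v)), 0.9)
    kept <- colnames(out$values)
    # oracle 1: every kept column has max >= 0.05, every dropped-rare < 0.05
    expect_true(all(apply(v[, kept, drop = FALSE], 2, max) >= 0.05))
    # oracle 2: kept set is pairwise R^2 <= 0.9 (exhaustive scan)
    cm <- suppressWarnings(cor(v[, kept]))^2
    diag(cm) <- 0
    expect_true(max(cm, na.rm = TRUE) <= 0.9)
    # oracle 3: greedy maximality — every dropped non-rare column correlates
    # with some kept earlier column
    rare_ok <- colnames(v)[apply(v, 2, max) >= 0.05]
    dropped <- setdiff(rare_ok, kept)
    for (dcol in dropped) {
      earlier <- kept[kept < dcol]
      r2 <- suppressWarnings(cor(v[, dcol], v[, earlier, drop = FALSE]))^2
      expect_true(any(r2 > 0.9, na.rm = TRUE))
    }
  }
})

test_that("min-max normalization maps to [0,1] and is idempotent", {
  v <- cbind(a = c(0.1, 0.3, 0.5), b = c(0.2, 0.2, 0.2), c = c(0, 0.5, 1))
  rownames(v) <- paste0("c", 1:3)
  out <- minmax_normalize(make_fm(v))$values
  expect_equal(unname(out[, "a"]), c(0, 0.5, 1))
  expect_equal(unname(out[, "b"]), c(0, 0, 0))   # constant column
  expect_equal(unname(out[, "c"]), c(0, 0.5, 1)) # spanning column unchanged
  expect_equal(minmax_normalize(out), out)
})

test_that("feature matrices assemble from series and round-trip CSV", {
  feats <- c("D93-HB", "F138-APO", "K58-IP")
  sched <- function(loss) contact_schedule(feats, loss_frame = loss,
                                           n_frames = 20)
  series <- list(
    gen_if_series(sched(c(`D93-HB` = 5, `F138-APO` = 10, `K58-IP` = 15)),
                  seed = 1, compound_id = "c1", trajectory_id = "t1"),
    gen_if_series(sched(c(`D93-HB` = 4, `F138-APO` = 12, `K58-IP` = 16)),
                  seed = 2, compound_id = "c1", trajectory_id = "t2"),
    gen_if_series(sched(c(`D93-HB` = 15, `F138-APO` = 3, `K58-IP` = 8)),
                  seed = 3, compound_id = "c2", trajectory_id = "t1"))
  kin <- data.frame(compound_id = c("c1", "c2"), koff = c(1e-3, 1e-1),
                    outlier = c(FALSE, TRUE))
  fm <- build_feature_matrix(series, kin, mode = "A")
  expect_equal(rownames(fm$values), c("c1", "c2"))
  expect_equal(unname(fm$labels), c(3, 1))  # log10(1/koff)
  expect_true(all(fm$values >= 0 & fm$values <= 1))
  expect_identical(fm$annotations$outlier, c(FALSE, TRUE))
  rep <- attr(fm, "truncation_report")
  expect_equal(nrow(rep), 3)
  expect_true(all(rep$n_bound == 3))
  path <- file.path(tempdir(), "fm_roundtrip.csv")
  write_feature_matrix(fm, path)
  back <- read_feature_matrix(path)
  expect_equal(back$values, fm$values)
  expect_equal(back$labels, fm$labels)
  expect_equal(back$annotations$outlier, fm$annotations$outlier)
})

test_that("out-of-range compounds are clamped to the koff floor", {
  k <- clamp_out_of_range(c(0.02, 5), out_of_range = c(FALSE, TRUE))
  expect_equal(as.numeric(k), c(0.02, 1e-4))
  expect_identical(attr(k, "clamped"), c(FALSE, TRUE))
  k2 <- clamp_out_of_range(c(0.02, 5), out_of_range = c(FALSE, TRUE),
                           floor = 1e-5)
  expect_equal(as.numeric(k2)[2], 1e-5)
})
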