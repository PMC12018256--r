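# staggered round-based cross-validation, overlap exclusion, metrics

test_that("fold indices match hand-traced cases at l = 100", {
  expect_equal(fold_indices(100, 1, 0), 1:20)
  expect_equal(fold_indices(100, 2, 0), 21:40)
  expect_equal(fold_indices(100, 1, 4), 81:100)
  expect_equal(sort(unlist(lapply(0:4, fold_indices, l = 100, k = 1))), 1:100)
  # staggering: round position shifts the start, iteration shifts it again
  expect_equal(fold_indices(100, 3, 1), 61:80)
  expect_equal(fold_indices(100, 6, 0), 1:20)  # position cycles mod 5
})

test_that("folds partition every round exactly once across iterations", {
  set.seed(42)
  for (case in 1:30) {
    l <- sample(5:3000, 1)
    k <- sample(1:8, 1)
    sets <- lapply(0:4, fold_indices, l = l, k = k)
    expect_true(all(vapply(sets, function(s) all(diff(s) == 1), logical(1))))
    expect_equal(sort(unlist(sets)), 1:l)
    expect_equal(sum(vapply(sets, length, numeric(1))), l)
  }
})

make_cv_samples <- function(lens, labels = NULL) {
  do.call(rbind, lapply(seq_along(lens), function(r) {
    l <- lens[r]
    data.frame(t = seq_len(l), round_id = r,
               label = if (is.null(labels)) rep(FALSE, l) else labels[[r]],
               valid = TRUE,
               win_start = seq_len(l) - 45, win_end = seq_len(l) + 45)
  }))
}

test_that("assign_folds covers all rounds and respects validity filtering", {
  s <- make_cv_samples(c(100, 250, 87))
  s$valid[5] <- FALSE
  a <- assign_folds(s)
  expect_length(a, 5)
  expect_equal(nrow(a[[1]]$samples), sum(s$valid))
  for (j in 1:5) {
    expect_equal(sort(c(a[[j]]$val, a[[j]]$train)), seq_len(nrow(a[[1]]$samples)))
    expect_length(intersect(a[[j]]$val, a[[j]]$train), 0)
  }
  # each retained index validated exactly once over the five iterations
  all_val <- unlist(lapply(a, `[[`, "val"))
  expect_equal(sort(all_val), seq_len(nrow(a[[1]]$samples)))
  expect_error(assign_folds(make_cv_samples(c(100, 3))), "at least 5")
})

test_that("overlap exclusion discards exactly the window-intersecting training samples", {
  # one round, samples at t = 1..300, validation block t = 100..200
  s <- make_cv_samples(300)
  a <- structure(list(iteration = 0, val = 100:200,
                      train = setdiff(1:300, 100:200),
                      discarded = integer(0), rounds = list(), samples = s),
                 class = "fold_assignment")
  out <- exclude_overlap(a)
  expect_equal(sort(s$t[out$discarded]), c(11:99, 201:289))
  expect_true(all(s$t[out$train] <= 10 | s$t[out$train] >= 290))
  # no training window strictly overlaps any validation window
  v_lo <- min(s$win_start[out$val]); v_hi <- max(s$win_end[out$val])
  expect_true(all(s$win_end[out$train] <= v_lo | s$win_start[out$train] >= v_hi))
  # zero-width windows never overlap
  s0 <- s; s0$win_start <- s0$t; s0$win_end <- s0$t
  a0 <- a; a0$samples <- s0
  expect_length(exclude_overlap(a0)$discarded, 0)
})

test_that("adjacent training folds are not discarded against each other", {
  s <- make_cv_samples(500)
  a <- assign_folds(s)[[1]]  # validation 1..100, training 101..500
  out <- exclude_overlap(a)
  # only samples near the single validation block are discarded
  expect_true(all(s$t[out$discarded] < 100 + 90))
  expect_gt(length(out$train), 0)
})

test_that("metrics reproduce the hand-computed confusion example", {
  prob <- c(rep(0.9, 8), rep(0.1, 2), rep(0.2, 7), rep(0.8, 3))
  y <- c(rep(TRUE, 10), rep(FALSE, 10))
  m <- evaluate_predictions(prob, y, n_boot = 0)
  expect_equal(unname(m$confusion), c(8, 3, 7, 2))
  expect_equal(m$accuracy, 0.75)
  expect_equal(m$sensitivity, 0.8)
  expect_equal(m$specificity, 0.7)
  expect_equal(m$precision, 8 / 11)
  expect_equal(m$f1, 16 / 21)
  # perfect predictions
  mp <- evaluate_predictions(c(0.9, 0.9, 0.1), c(TRUE, TRUE, FALSE), n_boot = 0)
  expect_equal(mp$accuracy, 1)
  expect_equal(mp$auc, 1)
  expect_equal(mp$f1, 1)
})

test_that("AUC matches an independent implementation and is rank-invariant", {
  skip_if_not_installed("pROC")
  set.seed(7)
  prob <- runif(300)
  y <- runif(300) < plogis(3 * (prob - 0.5))
  m <- evaluate_predictions(prob, y, n_boot = 0)
  oracle <- as.numeric(pROC::auc(pROC::roc(as.numeric(y), prob, quiet = TRUE,
                                           levels = c(0, 1), direction = "<")))
  expect_equal(m$auc, oracle, tolerance = 1e-10)
  # strictly monotone transform of the scores leaves the ROC/AUC unchanged
  m2 <- evaluate_predictions(plogis(5 * prob - 2), y, n_boot = 0)
  expect_equal(m2$auc, m$auc, tolerance = 1e-12)
})

test_that("random scores give chance-level AUC and single-class sets warn", {
  set.seed(8)
  prob <- runif(4000)
  y <- sample(c(TRUE, FALSE), 4000, replace = TRUE)
  m <- evaluate_predictions(prob, y, n_boot = 0)
  expect_equal(m$auc, 0.5, tolerance = 0.05)
  expect_warning(ms <- evaluate_predictions(c(0.9, 0.8), c(TRUE, TRUE), n_boot = 0),
                 "single-class")
  expect_true(is.nan(ms$specificity))
  expect_equal(ms$sensitivity, 1)
  expect_true(is.na(ms$auc))
})

test_that("the bootstrap CI brackets the point AUC deterministically", {
  set.seed(9)
  prob <- runif(200)
  y <- runif(200) < plogis(4 * (prob - 0.5))
  m1 <- evaluate_predictions(prob, y, n_boot = 200, boot_seed = 3)
  m2 <- evaluate_predictions(prob, y, n_boot = 200, boot_seed = 3)
  expect_identical(m1$auc_ci, m2$auc_ci)
  expect_lte(m1$auc_ci[1], m1$auc)
  expect_gte(m1$auc_ci[2], m1$auc)
})

test_that("cross-validation runs five iterations with disjoint leakage-free splits", {
  feats <- simulate_feature_cohort(profiles = list(c(55, 20), c(45, 15), c(25, 8)),
                                   round_minutes = 8, seed = 17)
  cfg <- train_config(max_epochs = 30, patience = 10, seed = 1)
  cv <- run_cross_validation(feats, config = cfg, n_boot = 0)
  expect_length(cv$iterations, 5)
  expect_equal(nrow(cv$counts), 5)
  expect_equal(cv$counts$iteration, 1:5)
  for (it in cv$iterations) {
    a <- it$assignment
    expect_length(intersect(a$val, a$train), 0)
    s <- a$samples
    for (r in unique(s$round_id)) {
      vr <- a$val[s$round_id[a$val] == r]
      tr <- a$train[s$round_id[a$train] == r]
      if (!length(vr) || !length(tr)) next
      expect_true(all(s$win_end[tr] <= min(s$win_start[vr]) |
                      s$win_start[tr] >= max(s$win_end[vr])))
    }
  }
  # deterministic under identical configuration
  cv2 <- run_cross_validation(feats, config = cfg, n_boot = 0)
  expect_identical(cv$counts, cv2$counts)
})
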