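# Feature assembly, balanced SVM cross-validation, binomial test.

make_epochs_for_features <- function(n_ep = 20) {
  set.seed(17)
  channels <- c(montage_1020()$channel, "HEOG", "VEOG")
  arr <- array(rnorm(n_ep * 34 * 256), dim = c(n_ep, 34, 256),
               dimnames = list(NULL, channels, NULL))
  labels <- data.frame(trial_id = 1, serial_position = seq_len(n_ep),
                       is_target = rep(c(TRUE, FALSE), length.out = n_ep),
                       hit = NA, label = "nontarget",
                       event = seq_len(n_ep))
  labels$hit[labels$is_target] <- rep(c(TRUE, FALSE),
                                      length.out = sum(labels$is_target))
  labels$label <- ifelse(!labels$is_target, "nontarget",
                         ifelse(labels$hit, "hit", "miss"))
  structure(list(data = arr, times = (0:255) / 256, channels = channels,
                 fs = 256, labels = labels, rejected = integer(0),
                 n_skipped = 0L), class = "srp_epochs")
}

test_that("feature blocks have the documented dimensions", {
  ep <- make_epochs_for_features()
  eyef <- data.frame(event = 1:20, fixation_duration_ms = runif(20),
                     pupil_mm = runif(20) + 4, valid_fraction = 1)
  fm_srp <- build_feature_matrix(ep, NULL, feature_set_spec("SRP"))
  expect_equal(ncol(fm_srp$x), 32 * 192)
  fm_fd <- build_feature_matrix(ep, eyef, feature_set_spec("FIXDUR"))
  expect_equal(ncol(fm_fd$x), 1)
  fm_all <- build_feature_matrix(ep, eyef, feature_set_spec("ALL"))
  expect_equal(ncol(fm_all$x), 32 * 192 + 2)
  fm_eog <- build_feature_matrix(ep, eyef, feature_set_spec("SRP+EOG"))
  expect_equal(ncol(fm_eog$x), 34 * 192)
  # hit-vs-miss restricts to target epochs
  fm_hm <- build_feature_matrix(ep, NULL, feature_set_spec("SRP"),
                                "hit_vs_miss")
  expect_equal(nrow(fm_hm$x), sum(ep$labels$is_target))
  expect_setequal(levels(fm_hm$y), c("hit", "miss"))
  # rows with missing eye features dropped when needed
  eyef_na <- eyef; eyef_na$pupil_mm[3] <- NA
  fm_na <- build_feature_matrix(ep, eyef_na, feature_set_spec("PUPIL"))
  expect_equal(nrow(fm_na$x), 19)
  expect_equal(attr(fm_na, "n_dropped"), 1)
})

test_that("majority-class subsampling balances the training fold", {
  labels <- factor(c(rep("a", 10), rep("b", 40)))
  idx <- subsample_majority(labels, seed = 1)
  expect_equal(as.integer(table(labels[idx])), c(10L, 10L))
  # balanced input unchanged
  bal <- factor(rep(c("a", "b"), 10))
  expect_equal(subsample_majority(bal, seed = 1), 1:20)
  # different seeds: different subsets, identical class counts
  i1 <- subsample_majority(labels, seed = 2)
  i2 <- subsample_majority(labels, seed = 3)
  expect_false(identical(i1, i2))
  expect_equal(table(labels[i1]), table(labels[i2]))
  expect_error(subsample_majority(factor(rep("a", 5), levels = c("a", "b"))),
               "class")
})

test_that("SVM cross-validation separates, calibrates and does not leak", {
  # linearly separable classes with a large margin
  set.seed(18)
  x <- rbind(matrix(rnorm(25 * 5, 5), 25, 5),
             matrix(rnorm(25 * 5, -5), 25, 5))
  y <- factor(rep(c("target", "nontarget"), each = 25),
              levels = c("target", "nontarget"))
  res <- train_eval_svm_cv(x, y, seed = 1)
  expect_gte(res$accuracy, 0.95)
  expect_true(res$above_chance)
  expect_equal(res$n_test, 50)
  # pooled accuracy equals the weighted mean of fold accuracies
  expect_equal(res$accuracy,
               sum(res$fold_accuracy * res$fold_n, na.rm = TRUE) /
                 sum(res$fold_n))

  # pure-noise features: mean accuracy within 3 SE of 0.5 over repetitions
  accs <- vapply(1:60, function(s) {
    set.seed(100 + s)
    xn <- matrix(rnorm(40 * 6), 40, 6)
    yn <- factor(rep(c("a", "b"), each = 20))
    train_eval_svm_cv(xn, yn, seed = s)$accuracy
  }, 0)
  expect_lt(abs(mean(accs) - 0.5), 3 * sd(accs) / sqrt(length(accs)) + 0.02)

  # reproducibility
  r1 <- train_eval_svm_cv(x, y, seed = 7)
  r2 <- train_eval_svm_cv(x, y, seed = 7)
  expect_identical(r1$fold_accuracy, r2$fold_accuracy)
  expect_identical(r1$accuracy, r2$accuracy)

  # leakage probe: an extreme outlier placed in a test fold may change its
  # own prediction, but the fold's scaler and model are fitted on the
  # other folds, so at most that one prediction of the fold can flip. If
  # test-fold statistics leaked into the standardization, the outlier
  # would shift every test prediction of its fold.
  set.seed(19)
  x2 <- matrix(rnorm(50 * 4), 50, 4)
  y2 <- factor(rep(c("a", "b"), 25))
  base <- train_eval_svm_cv(x2, y2, seed = 3)
  k1 <- base$fold_id[1]
  x2c <- x2; x2c[1, ] <- 1e6
  pert <- train_eval_svm_cv(x2c, y2, seed = 3)
  expect_identical(pert$fold_id, base$fold_id)
  expect_lte(abs(pert$fold_correct[k1] - base$fold_correct[k1]), 1)
})

test_that("exact binomial tail matches enumeration", {
  b10 <- binomial_above_chance(10, 10)
  expect_equal(b10$p, 2^-10)
  expect_true(b10$flag)
  b5 <- binomial_above_chance(5, 10)
  expect_equal(b5$p, sum(choose(10, 5:10)) / 2^10)
  expect_false(b5$flag)
  b0 <- binomial_above_chance(0, 10)
  expect_equal(b0$p, 1)
  expect_false(b0$flag)
})

test_that("comparison grid gates hit/miss cells on the miss count", {
  ep <- make_epochs_for_features(60)
  eyef <- data.frame(event = 1:60, fixation_duration_ms = runif(60),
                     pupil_mm = runif(60) + 4, valid_fraction = 1)
  sessions <- list(high = list(epochs = ep, eye_features = eyef))
  grid <- comparison_grid(sessions, feature_ids = c("FIXDUR", "PUPIL"),
                          min_miss = 10, seed = 5)
  hm <- grid[grid$contrast == "hit_vs_miss", ]
  expect_true(all(hm$available))     # 15 misses here
  grid2 <- comparison_grid(sessions, feature_ids = "FIXDUR",
                           min_miss = 99, seed = 5)
  hm2 <- grid2[grid2$contrast == "hit_vs_miss", ]
  expect_false(any(hm2$available))
  expect_true(all(is.na(hm2$accuracy)))
})
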