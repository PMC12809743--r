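# direct construction of a labeled feature set, bypassing the EEG pipeline
make_featset <- function(n, p = 24, effect = 0, seed = 1, flags = NULL) {
  set.seed(seed)
  labels <- rep(c(TRUE, FALSE), length.out = n)
  X <- matrix(rnorm(n * p), n, p)
  X[labels, 1:4] <- X[labels, 1:4] + effect
  if (is.null(flags)) flags <- rep(FALSE, n)
  structure(list(features = X, flags = flags, labels = labels,
                 epoch_times = NULL,
                 scaler = list(mean = rep(0, p), sd = rep(1, p))),
            class = "epoch_feature_set")
}

test_that("training sets are balanced and capped at max_pcs", {
  fs <- make_featset(220, p = 24, effect = 1, seed = 2)
  fs$labels <- c(rep(TRUE, 120), rep(FALSE, 100))
  ts <- build_training_set(fs, max_pcs = 150, seed = 1)
  expect_equal(sum(ts$labels), 100)
  expect_equal(sum(!ts$labels), 100)
  expect_equal(ts$n_components, 24)       # p < 150: all available kept
  ts10 <- build_training_set(fs, max_pcs = 10, seed = 1)
  expect_equal(ts10$n_components, 10)
  # PC scores are standardized
  expect_equal(unname(colMeans(ts$scores)), rep(0, 24), tolerance = 0.2)
  # flagged-epoch and single-class errors
  fs2 <- make_featset(30, seed = 3)
  fs2$labels <- rep(TRUE, 30)
  expect_error(build_training_set(fs2), "class")
})

test_that("219-feature epochs keep up to 150 components", {
  fs <- make_featset(200, p = 219, effect = 0.5, seed = 4)
  ts <- build_training_set(fs, max_pcs = 150, seed = 1)
  expect_equal(ts$n_components, 150)
  fs2 <- make_featset(120, p = 219, effect = 0.5, seed = 5)
  ts2 <- build_training_set(fs2, max_pcs = 150, seed = 1)
  expect_equal(ts2$n_components, 120)     # fewer epochs: all available kept
})

test_that("AUC equals the pair-enumeration oracle", {
  # 4-point hand-built example: scores .9 .8 .4 .1, labels 1 0 1 0
  s <- c(0.9, 0.8, 0.4, 0.1)
  l <- c(TRUE, FALSE, TRUE, FALSE)
  expect_equal(roc_auc(s, l), 0.75)
  expect_equal(auc_by_pairs(s, l), 0.75)
  # random score sets agree with the oracle, ties included
  for (seed in 1:5) {
    set.seed(seed)
    sc <- sample(seq(0, 1, by = 0.1), 30, replace = TRUE)
    lb <- runif(30) > 0.5
    if (all(lb) || !any(lb)) next
    expect_equal(roc_auc(sc, lb), auc_by_pairs(sc, lb))
  }
})

test_that("classifier evaluation returns the documented indices", {
  m <- structure(list(gamma0 = 0, gamma = c(5, 0, 0), fitted = TRUE),
                 class = "eeg_classifier")
  sc <- cbind(c(2, 1.5, -1, -2), 0, 0)
  lab <- c(TRUE, TRUE, FALSE, FALSE)
  ev <- evaluate_classifier(m, sc, lab)
  expect_equal(ev$accuracy, 1)
  expect_equal(ev$auc, 1)
  expect_equal(unname(ev$confusion[1, 1]), 2)
  expect_equal(unname(ev$confusion[2, 2]), 2)
  # gamma = 0: constant probability logistic(gamma0)
  m0 <- structure(list(gamma0 = 0.3, gamma = rep(0, 3), fitted = TRUE),
                  class = "eeg_classifier")
  p <- decode_probability(m0, sc)
  expect_equal(p, rep(plogis(0.3), 4))
  expect_error(evaluate_classifier(m, sc[0, , drop = FALSE], logical(0)),
               "empty")
})

test_that("separable classes are decoded nearly perfectly", {
  fs <- make_featset(200, p = 24, effect = 3, seed = 6)
  ts <- build_training_set(fs, max_pcs = 20, seed = 1)
  m <- fit_eeg_classifier(ts$scores, ts$labels, cv_folds = 10, seed = 1,
                          nlambda = 40, pca = ts)
  expect_gte(m$validation$test$auc, 0.9)
  expect_gte(m$validation$train$accuracy, 0.9)
})

test_that("decoded probabilities are invariant to epoch order", {
  fs <- make_featset(100, p = 12, effect = 1, seed = 7)
  ts <- build_training_set(fs, max_pcs = 12, seed = 1)
  m <- fit_eeg_classifier(ts$scores, ts$labels, cv_folds = 5, seed = 1,
                          nlambda = 20, pca = ts)
  perm <- sample(nrow(ts$scores))
  p1 <- decode_probability(m, ts$scores)
  p2 <- decode_probability(m, ts$scores[perm, , drop = FALSE])
  expect_equal(p2, p1[perm])
})

test_that("the permutation test is exact-zero for perfect separation", {
  fs <- make_featset(60, p = 8, effect = 6, seed = 8)
  pt <- permutation_test(fs, max_pcs = 8, cv_folds = 5, n_perm = 30,
                         seed = 2, nlambda = 15)
  expect_equal(pt$observed_auc, 1)
  expect_equal(pt$p_value, 0)
  expect_length(pt$null_auc, 30)
  expect_error(permutation_test(fs, n_perm = 0), "n_perm")
})

test_that("back-projection satisfies the reconstruction identity", {
  fs <- make_featset(120, p = 219, effect = 1, seed = 9)
  ts <- build_training_set(fs, max_pcs = 40, seed = 1)
  m <- fit_eeg_classifier(ts$scores, ts$labels, cv_folds = 5, seed = 1,
                          nlambda = 20, pca = ts)
  wm <- backproject_weights(m)
  expect_equal(dim(wm$weights), c(73, 3))
  # identity: weights == basis %*% (gamma / pc sd)
  manual <- as.numeric(ts$pca_basis %*% (m$gamma / ts$pc_scaler$sd))
  expect_equal(as.numeric(wm$weights), manual, tolerance = 1e-10)
  expect_named(wm$band_means, c("theta", "alpha", "beta", "gamma"))
  # gamma = 0: all-zero map
  m0 <- m; m0$gamma <- rep(0, length(m0$gamma))
  wm0 <- backproject_weights(m0)
  expect_true(all(wm0$weights == 0))
  expect_true(all(wm0$band_means == 0))
})

test_that("back-projection with an identity basis isolates single bins", {
  m <- structure(list(gamma0 = 0, gamma = c(rep(0, 4), 2, rep(0, 214)),
                      pca_basis = diag(219),
                      pc_scaler = list(mean = rep(0, 219), sd = rep(1, 219)),
                      fitted = TRUE),
                 class = "eeg_classifier")
  wm <- backproject_weights(m)
  expect_equal(wm$weights[5, 1], 2)      # bin 5 of the left derivation
  expect_equal(sum(wm$weights != 0), 1)
  m$pca_basis <- NULL
  expect_error(backproject_weights(m), "basis")
})
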