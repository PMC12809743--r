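# PCA + logistic LASSO classifier of high- vs low-pleasure EEG states.
#
# Pipeline: drop flagged epochs -> PCA per participant (up to 150
# components) -> standardize PC scores -> balance classes by subsampling the
# larger -> 90/10 stratified split -> 20-fold cross-validated logistic LASSO
# (L1-penalized binomial deviance; the solver is glmnet, but prediction from
# a fitted model uses only the stored coefficients so snapshots reload
# bit-identically) -> confusion/ROC/AUC on train and test -> permutation
# test reusing the same 90/10 split -> back-projection of the coefficients
# into the 73-bin x 3-derivation feature space.

#' Build the balanced PC-score training set
#'
#' Flagged epochs are removed, PCA is fitted on the remaining epochs' (already
#' standardized) features, up to `max_pcs` components are retained, PC scores
#' are standardized, and the larger class is randomly subsampled to the size
#' of the smaller.
#'
#' @param featset an `epoch_feature_set` with logical `labels`.
#' @param max_pcs maximum principal components (default 150).
#' @param seed RNG seed for the subsampling.
#' @return list with `scores` (balanced standardized PC scores), `labels`,
#'   `pca_basis` (features x K loadings), `pca_center`, `pc_scaler`
#'   (`mean`, `sd` per component), `kept_rows` (indices into the non-flagged
#'   epochs), `n_components`.
#' @export
build_training_set <- function(featset, max_pcs = 150, seed = 1L) {
  stopifnot(inherits(featset, "epoch_feature_set"))
  if (is.null(featset$labels)) stop("featset has no labels", call. = FALSE)
  keep <- !featset$flags
  X <- featset$features[keep, , drop = FALSE]
  lab <- featset$labels[keep]
  tab <- table(factor(lab, levels = c(FALSE, TRUE)))
  if (any(tab == 0)) {
    stop("a class has no non-flagged epochs; cannot train", call. = FALSE)
  }
  pca <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  k <- min(max_pcs, ncol(pca$rotation))
  basis <- pca$rotation[, seq_len(k), drop = FALSE]
  scores <- pca$x[, seq_len(k), drop = FALSE]
  mu <- colMeans(scores)
  sd_ <- apply(scores, 2, stats::sd)
  sd_[!is.finite(sd_) | sd_ < 1e-12] <- 1e-12
  scores <- sweep(sweep(scores, 2, mu, "-"), 2, sd_, "/")
  set.seed(seed)
  n_min <- min(tab)
  rows <- c(sample(which(!lab), n_min), sample(which(lab), n_min))
  rows <- sort(rows)
  list(scores = scores[rows, , drop = FALSE], labels = lab[rows],
       pca_basis = basis, pca_center = pca$center,
       pc_scaler = list(mean = mu, sd = sd_),
       kept_rows = rows, n_components = k)
}

stratified_split <- function(labels, train_frac, seed) {
  set.seed(seed)
  test <- integer(0)
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    n_test <- max(1L, round(length(idx) * (1 - train_frac)))
    test <- c(test, sample(idx, n_test))
  }
  sort(test)
}

stratified_foldid <- function(labels, nfolds, seed) {
  set.seed(seed)
  id <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    id[idx] <- sample(rep_len(seq_len(nfolds), length(idx)))
  }
  id
}

# core fit at fixed split; returns coefficient vector + lambda
fit_logistic_lasso <- function(x_train, y_train, cv_folds, nlambda, seed) {
  nfolds <- min(cv_folds, length(y_train))
  foldid <- stratified_foldid(y_train, nfolds, seed)
  cv <- glmnet::cv.glmnet(x_train, y_train, family = "binomial",
                          foldid = foldid, nlambda = nlambda,
                          standardize = FALSE)
  co <- as.numeric(stats::coef(cv, s = "lambda.min"))
  list(gamma0 = co[1], gamma = co[-1], lambda = cv$lambda.min)
}

#' Decoded probability of the high-pleasure state
#' @param model a fitted `eeg_classifier` (or any list with `gamma0`,
#'   `gamma`).
#' @param scores standardized PC-score matrix (rows = epochs).
#' @return probabilities in (0, 1).
#' @export
decode_probability <- function(model, scores) {
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1)
  stats::plogis(model$gamma0 + as.numeric(scores %*% model$gamma))
}

#' Fit the EEG pleasure-state classifier
#'
#' Stratified 90/10 train/test split (the holdout never touches fitting or
#' lambda selection), then 20-fold cross-validated logistic LASSO on the
#' training portion.
#'
#' @param scores balanced standardized PC scores from [build_training_set()].
#' @param labels logical class labels (TRUE = high pleasure).
#' @param cv_folds CV folds for lambda selection (default 20).
#' @param split training fraction (default 0.9).
#' @param seed RNG seed (split + fold assignment).
#' @param nlambda lambda path length (default 100).
#' @param pca optional list carrying `pca_basis`, `pca_center`, `pc_scaler`
#'   from [build_training_set()], stored for back-projection and streaming.
#' @param feature_scaler optional stored [standardize_features()] scaler for
#'   streaming use.
#' @return object of class `"eeg_classifier"`.
#' @export
fit_eeg_classifier <- function(scores, labels, cv_folds = 20, split = 0.9,
                               seed = 1L, nlambda = 100L, pca = NULL,
                               feature_scaler = NULL) {
  scores <- as.matrix(scores)
  labels <- as.logical(labels)
  if (length(labels) < 20) {
    stop("need at least 20 balanced epochs to fit", call. = FALSE)
  }
  test_idx <- stratified_split(labels, split, seed)
  train_idx <- setdiff(seq_along(labels), test_idx)
  fit <- fit_logistic_lasso(scores[train_idx, , drop = FALSE],
                            labels[train_idx], cv_folds, nlambda, seed + 1L)
  model <- structure(
    list(gamma0 = fit$gamma0, gamma = fit$gamma, lambda = fit$lambda,
         pca_basis = pca$pca_basis, pca_center = pca$pca_center,
         pc_scaler = pca$pc_scaler, feature_scaler = feature_scaler,
         split_seed = seed, test_idx = test_idx, cv_folds = cv_folds,
         n_train = length(train_idx), fitted = TRUE),
    class = "eeg_classifier")
  model$validation <- list(
    train = evaluate_classifier(model, scores[train_idx, , drop = FALSE],
                                labels[train_idx]),
    test = evaluate_classifier(model, scores[test_idx, , drop = FALSE],
                               labels[test_idx]))
  model
}

#' @exportS3Method base::print
print.eeg_classifier <- function(x, ...) {
  cat(sprintf("<eeg_classifier> %d PCs, %d nonzero, lambda = %.4g\n",
              length(x$gamma), sum(x$gamma != 0), x$lambda))
  if (!is.null(x$validation)) {
    cat(sprintf("  train acc %.3f auc %.3f | test acc %.3f auc %.3f\n",
                x$validation$train$accuracy, x$validation$train$auc,
                x$validation$test$accuracy, x$validation$test$auc))
  }
  invisible(x)
}

#' Trapezoid-rule AUC from scores and labels
#' @param scores numeric classifier scores (higher = more positive).
#' @param labels logical truth.
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(scores, labels) {
  roc <- roc_points(scores, labels)
  sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)
}

#' ROC curve by threshold sweep
#' @inheritParams roc_auc
#' @return data frame with columns `threshold`, `fpr`, `tpr`, ordered by
#'   increasing false-positive rate.
#' @export
roc_points <- function(scores, labels) {
  labels <- as.logical(labels)
  np <- sum(labels); nn <- sum(!labels)
  if (np == 0 || nn == 0) stop("ROC needs both classes", call. = FALSE)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) sum(scores >= t & labels) / np, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & !labels) / nn, numeric(1))
  data.frame(threshold = thr, fpr = fpr, tpr = tpr)
}

#' Validation indices for a fitted classifier
#'
#' Confusion matrix at probability threshold 0.5, accuracy, ROC points, and
#' trapezoid AUC.
#'
#' @param model a fitted `eeg_classifier`.
#' @param scores standardized PC scores of the evaluation partition.
#' @param labels logical truth.
#' @return list with `confusion` (2 x 2: predicted x actual), `accuracy`,
#'   `roc`, `auc`, `probabilities`.
#' @export
evaluate_classifier <- function(model, scores, labels) {
  if (length(labels) == 0) stop("empty evaluation partition", call. = FALSE)
  p <- decode_probability(model, scores)
  pred <- p >= 0.5
  confusion <- table(predicted = factor(pred, c(TRUE, FALSE)),
                     actual = factor(labels, c(TRUE, FALSE)))
  list(confusion = confusion,
       accuracy = mean(pred == labels),
       roc = roc_points(p, labels),
       auc = roc_auc(p, labels),
       probabilities = p)
}

#' Permutation test of the classifier
#'
#' Shuffles the class labels of the non-flagged epochs `n_perm` times and
#' reruns the entire procedure (balancing, PC-score standardization, fit with
#' the SAME stored 90/10 split, test AUC). The p-value is the proportion of
#' permuted test AUCs strictly exceeding the observed test AUC.
#'
#' @param featset labeled `epoch_feature_set`.
#' @param max_pcs,cv_folds,split,seed,nlambda pipeline parameters (see
#'   [build_training_set()] and [fit_eeg_classifier()]).
#' @param n_perm number of label shuffles (>= 1; the full-scale default in
#'   the field setup is 1000, reduced values are allowed for testing).
#' @return list with `p_value`, `observed_auc`, `null_auc` (length `n_perm`)
#'   and the observed `model`.
#' @export
permutation_test <- function(featset, max_pcs = 150, cv_folds = 20,
                             split = 0.9, n_perm = 1000, seed = 1L,
                             nlambda = 100L) {
  if (n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  ts <- build_training_set(featset, max_pcs, seed)
  model <- fit_eeg_classifier(ts$scores, ts$labels, cv_folds, split, seed,
                              nlambda, pca = ts)
  observed <- model$validation$test$auc
  keep <- !featset$flags
  lab0 <- featset$labels[keep]
  fs_perm <- featset
  null_auc <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    set.seed(seed + 7919L * b)
    perm <- sample(lab0)
    lab_full <- featset$labels
    lab_full[keep] <- perm
    fs_perm$labels <- lab_full
    tsb <- build_training_set(fs_perm, max_pcs, seed + b)
    mb <- fit_eeg_classifier(tsb$scores, tsb$labels, cv_folds, split, seed,
                             nlambda, pca = NULL)
    null_auc[b] <- mb$validation$test$auc
  }
  # p_value follows the printed convention (strict ">"); with tied AUCs
  # (e.g. constant null models at AUC 0.5) that convention is
  # anti-conservative, so the add-one "greater or equal" variant is also
  # reported
  list(p_value = mean(null_auc > observed),
       p_value_addone = (1 + sum(null_auc >= observed)) / (1 + n_perm),
       observed_auc = observed, null_auc = null_auc, model = model)
}

#' Back-project classifier weights into frequency x derivation space
#'
#' The logistic LASSO coefficients over standardized PC scores are rescaled
#' by the PC standard deviations and multiplied by the PCA loadings, giving
#' one weight per original spectral feature; reshaped to bins x derivations,
#' with per-band means of the absolute weights (theta 4--7, alpha 8--13,
#' beta 14--30, gamma 31--40 Hz).
#'
#' @param model a fitted `eeg_classifier` carrying its `pca_basis` and
#'   `pc_scaler`.
#' @param feature_band,bin bin-centre geometry (defaults 4--40 Hz, 0.5).
#' @param abs_bands if `TRUE` (default) band means are over `|weight|`;
#'   `FALSE` gives signed means.
#' @return object of class `"weight_map"`: `weights` (bins x 3), `band_means`.
#' @export
backproject_weights <- function(model, feature_band = c(4, 40), bin = 0.5,
                                abs_bands = TRUE) {
  if (is.null(model$pca_basis)) {
    stop("model carries no PCA basis; refit with pca = build_training_set(...)",
         call. = FALSE)
  }
  basis <- as.matrix(model$pca_basis)
  w_feat <- as.numeric(basis %*% (model$gamma / model$pc_scaler$sd))
  centers <- seq(feature_band[1], feature_band[2], by = bin)
  n_bins <- length(centers)
  stopifnot(length(w_feat) == 3 * n_bins)
  wm <- matrix(w_feat, nrow = n_bins, ncol = 3,
               dimnames = list(format(centers, trim = TRUE),
                               c("left", "right", "diff")))
  bands <- BAND_DEFS
  bm <- vapply(bands, function(b) {
    sel <- centers >= b[1] & centers <= b[2]
    v <- wm[sel, ]
    if (abs_bands) mean(abs(v)) else mean(v)
  }, numeric(1))
  structure(list(weights = wm, band_means = bm, abs_bands = abs_bands),
            class = "weight_map")
}
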