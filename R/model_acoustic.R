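# Sparse linear regression predicting z-scored pleasure from acoustic
# features, solved by coordinate descent on the objective exactly as
# specified:
#
#   (1/N) * sum_i (y_i - beta0 - x_i' beta)^2 + lambda * ||beta||_1
#
# with an unpenalized intercept and no internal rescaling (features are
# assumed pre-standardized). lambda_max = max_j |(2/N) X_c' y_c| is the
# smallest lambda that zeroes every coefficient; the default grid is 100
# log-spaced values down to 1e-4 * lambda_max. The optimal lambda is chosen
# by K-fold cross-validated squared error with ties broken toward the larger
# (sparser) lambda. Note glmnet's gaussian objective is half this one, so
# lambda_glmnet = lambda / 2 for the same minimizer.

soft_threshold <- function(z, g) sign(z) * pmax(0, abs(z) - g)

# coordinate descent at one lambda; X centered, y centered, warm start beta.
# Active-set strategy with a maintained gradient cache
# g = (2/N) X'(y - X beta): cycle over the active set until converged, then
# check the Karush-Kuhn-Tucker conditions on all coordinates at once
# (vectorized) and absorb any violators.
cd_lasso_fit <- function(X, y, lambda, beta, xtx2n, xty2n, col_norm2n,
                         tol = 1e-9, max_iter = 100L) {
  p <- ncol(X)
  g <- xty2n - as.numeric(xtx2n %*% beta)   # (2/N) X'(y - X beta)
  r <- y - as.numeric(X %*% beta)           # residual, maintained per update
  active <- which(beta != 0 & col_norm2n > 0)
  obj <- mean(r^2) + lambda * sum(abs(beta))
  obj_scale <- mean(y^2) + 1e-12     # fixed scale so the stop rule does not
  repeat {                           # tighten as the objective approaches 0
    for (it in seq_len(max_iter)) {
      for (j in active) {
        z <- g[j] + col_norm2n[j] * beta[j]
        bj <- sign(z) * max(0, abs(z) - lambda) / col_norm2n[j]
        d <- bj - beta[j]
        if (d != 0) {
          beta[j] <- bj
          g <- g - xtx2n[, j] * d
          r <- r - X[, j] * d
        }
      }
      obj_new <- mean(r^2) + lambda * sum(abs(beta))
      if (obj - obj_new < tol * obj_scale) {
        obj <- obj_new
        break
      }
      obj <- obj_new
    }
    viol <- which(beta == 0 & col_norm2n > 0 & abs(g) > lambda * (1 + 1e-12))
    viol <- setdiff(viol, active)
    if (!length(viol)) break
    active <- union(active, viol)
  }
  beta
}

lasso_objective <- function(X, y, beta0, beta, lambda) {
  r <- y - beta0 - as.numeric(X %*% beta)
  mean(r^2) + lambda * sum(abs(beta))
}

# full path solve; returns p x nlambda coefficient matrix plus intercepts.
# The inner coordinate-descent kernel is compiled (src/cd_lasso.cpp); the R
# reference implementation cd_lasso_fit() above is retained for testing.
lasso_path <- function(X, y, lambda_grid, tol = 1e-8, max_iter = 100L) {
  X <- as.matrix(X)
  n <- nrow(X)
  xm <- colMeans(X); ym <- mean(y)
  Xc <- sweep(X, 2, xm, "-"); yc <- y - ym
  xtx2n <- crossprod(Xc) * (2 / n)
  xty2n <- as.numeric(crossprod(Xc, yc)) * (2 / n)
  col_norm2n <- diag(xtx2n)
  betas <- cd_lasso_path_cpp(Xc, yc, lambda_grid, xtx2n, xty2n, col_norm2n,
                             tol, as.integer(max_iter))
  beta0 <- ym - as.numeric(crossprod(betas, xm))
  list(beta = betas, beta0 = beta0, lambda = lambda_grid)
}

default_lambda_grid <- function(X, y, nlambda = 100L, min_ratio = 1e-4) {
  Xc <- sweep(as.matrix(X), 2, colMeans(X), "-")
  lmax <- max(abs(crossprod(Xc, y - mean(y)))) * 2 / nrow(Xc)
  if (lmax <= 0) lmax <- 1e-3
  exp(seq(log(lmax), log(lmax * min_ratio), length.out = nlambda))
}

#' Fit the acoustic pleasure model (sparse linear regression)
#'
#' L1-penalized least squares over a log-spaced lambda grid, with lambda
#' chosen by K-fold cross-validated mean squared error (seeded random
#' contiguous partitions; ties broken toward the larger lambda, i.e. the
#' sparser model). Folds are reduced to the number of rows with a warning
#' when necessary.
#'
#' @param X rows = songs, columns = standardized acoustic features.
#' @param y z-scored pleasure ratings.
#' @param cv_folds requested number of CV folds (default 5).
#' @param lambda_grid optional decreasing lambda values; default 100
#'   log-spaced values from lambda_max down to 1e-4 * lambda_max.
#' @param seed RNG seed for the fold shuffle.
#' @return object of class `"pleasure_regressor"`: `beta0`, `beta` (sparse,
#'   named), `lambda`, `cv_folds`, `cv_mse` (per lambda), `lambda_grid`,
#'   `fit_rows`, `fitted`.
#' @export
fit_pleasure_regressor <- function(X, y, cv_folds = 5, lambda_grid = NULL,
                                   seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 3) stop("need at least 3 rows to fit", call. = FALSE)
  if (cv_folds < 2) stop("cv_folds must be >= 2", call. = FALSE)
  if (pop_sd(y) == 0) stop("constant response: nothing to fit", call. = FALSE)
  if (cv_folds > n) {
    warning("cv_folds reduced from ", cv_folds, " to ", n, " (one per row)")
    cv_folds <- n
  }
  if (is.null(lambda_grid)) lambda_grid <- default_lambda_grid(X, y)
  lambda_grid <- sort(lambda_grid, decreasing = TRUE)
  set.seed(seed)
  fold_id <- sample(rep_len(seq_len(cv_folds), n))
  cv_err <- matrix(NA_real_, cv_folds, length(lambda_grid))
  for (f in seq_len(cv_folds)) {
    hold <- fold_id == f
    if (all(hold) || !any(hold)) next
    path <- lasso_path(X[!hold, , drop = FALSE], y[!hold], lambda_grid)
    pred <- sweep(X[hold, , drop = FALSE] %*% path$beta, 2, path$beta0, "+")
    cv_err[f, ] <- colMeans((pred - y[hold])^2)
  }
  mse <- colMeans(cv_err, na.rm = TRUE)
  best <- which(mse <= min(mse) + 1e-12)[1]  # grid is decreasing: first = largest
  path <- lasso_path(X, y, lambda_grid)
  beta <- path$beta[, best]
  names(beta) <- colnames(X)
  structure(list(beta0 = path$beta0[best], beta = beta,
                 lambda = lambda_grid[best], cv_folds = cv_folds,
                 cv_mse = mse, lambda_grid = lambda_grid,
                 fit_rows = n, seed = seed, fitted = TRUE),
            class = "pleasure_regressor")
}

#' Fit at a single fixed lambda (no cross-validation)
#' @inheritParams fit_pleasure_regressor
#' @param lambda the penalty weight (objective as printed in the module
#'   header; `lambda = 0` is ordinary least squares when well-posed).
#' @return a `pleasure_regressor`.
#' @export
fit_pleasure_regressor_fixed <- function(X, y, lambda) {
  X <- as.matrix(X)
  # warm-start down a short internal path for reliable convergence at small
  # lambda; only the final (requested) solution is kept
  lmax <- default_lambda_grid(X, y, nlambda = 2L)[1]
  grid <- if (lambda > 0 && lambda < lmax) {
    c(exp(seq(log(lmax), log(lambda), length.out = 30L))[-30L], lambda)
  } else lambda
  path <- lasso_path(X, y, lambda_grid = grid, tol = 1e-13,
                     max_iter = 5000L)
  k <- length(grid)
  beta <- path$beta[, k]
  names(beta) <- colnames(X)
  structure(list(beta0 = path$beta0[k], beta = beta, lambda = lambda,
                 cv_folds = 0L, cv_mse = NULL, lambda_grid = lambda,
                 fit_rows = nrow(X), seed = NA_integer_, fitted = TRUE),
            class = "pleasure_regressor")
}

#' Predict z-scored pleasure
#' @param model a fitted `pleasure_regressor`.
#' @param features matrix (rows = songs) or single feature vector with the
#'   model's dimension mask.
#' @return numeric predictions.
#' @export
predict_pleasure <- function(model, features) {
  stopifnot(inherits(model, "pleasure_regressor"))
  if (is.null(dim(features))) features <- matrix(features, nrow = 1)
  if (ncol(features) != length(model$beta)) {
    stop("feature dimension (", ncol(features), ") does not match the model (",
         length(model$beta), ")", call. = FALSE)
  }
  as.numeric(model$beta0 + features %*% model$beta)
}

#' @exportS3Method base::print
print.pleasure_regressor <- function(x, ...) {
  cat(sprintf("<pleasure_regressor> %d features, %d nonzero, lambda = %.4g (%d-fold CV, n = %d)\n",
              length(x$beta), sum(x$beta != 0), x$lambda, x$cv_folds, x$fit_rows))
  invisible(x)
}
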