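#' Smallest penalty that zeroes every lasso coefficient
#'
#' For the survey-weighted logistic lasso with unpenalized intercept,
#' the KKT conditions give the critical penalty
#' `max_j |sum_i w_i x_ij (y_i - ybar_w)|` with `ybar_w` the weighted
#' outcome mean; at or above it the fitted coefficient vector is
#' exactly zero.
#'
#' @param X design matrix (dense or sparse).
#' @param y binary outcome (0/1).
#' @param w positive weights; `NULL` for unit weights.
#' @return the critical penalty on the summed-loss scale.
#' @export
lambda_max <- function(X, y, w = NULL) {
  if (is.null(w)) w <- rep(1, length(y))
  ybar <- sum(w * y) / sum(w)
  max(abs(as.numeric(Matrix::crossprod(X, w * (y - ybar)))))
}

#' Default penalty grid
#'
#' Log-spaced values from `lambda_max` down to
#' `lambda_max * min_ratio`, in decreasing order, on the summed-loss
#' scale.
#'
#' @inheritParams lambda_max
#' @param nlambda number of grid values (default 50).
#' @param min_ratio ratio of the smallest to the largest value
#'   (default 1e-4).
#' @return decreasing numeric vector.
#' @export
default_lambda_grid <- function(X, y, w = NULL, nlambda = 50,
                                min_ratio = 1e-4) {
  lmax <- lambda_max(X, y, w)
  exp(seq(log(lmax), log(lmax * min_ratio), length.out = nlambda))
}

# summed-scale penalized objective; intercept unpenalized
penalized_objective <- function(X, y, w, intercept, theta, lambda, penalty) {
  eta <- intercept + as.numeric(X %*% theta)
  loss <- sum(w * (-y * eta + log1pexp(eta)))
  pen <- if (penalty == "l1") lambda * sum(abs(theta))
         else lambda * sum(theta^2)
  loss + pen
}

#' Survey-weighted penalized logistic regression
#'
#' Minimizes the summed weighted negative Bernoulli log-likelihood plus
#' `lambda * ||theta||_1` (lasso) or `lambda * ||theta||_2^2` (ridge);
#' the intercept is never penalized. Note that `lambda` is on the
#' *summed* (not mean) log-likelihood scale, so values are comparable
#' across data sets only after accounting for the total weight.
#' Penalized fits are computed with glmnet; `lambda = 0` falls back to
#' an unpenalized weighted IRLS fit.
#'
#' @inheritParams lambda_max
#' @param lambda nonnegative penalty (summed-loss scale).
#' @param penalty `"l1"` or `"l2"`.
#' @return a `penalized_fit`: named coefficient vector `theta`,
#'   `intercept`, `penalty`, `lambda`, `converged`, `objective_value`.
#' @export
fit_penalized_logistic <- function(X, y, w = NULL,
                                   lambda, penalty = c("l1", "l2")) {
  penalty <- match.arg(penalty)
  if (is.null(w)) w <- rep(1, length(y))
  stopifnot(nrow(X) == length(y), length(w) == length(y),
            all(w > 0), lambda >= 0)
  if (any(!is.finite(if (inherits(X, "sparseMatrix")) X@x else X)))
    stop("non-finite entries in X")
  fnames <- colnames(X) %||% paste0("x", seq_len(ncol(X)))

  if (lambda == 0) {
    Xd <- as.matrix(X)
    fit <- suppressWarnings(
      glm.fit(cbind(`(Intercept)` = 1, Xd), y, weights = w,
              family = binomial()))
    converged <- fit$converged &&
      !any(fit$fitted.values < 1e-10 | fit$fitted.values > 1 - 1e-10)
    theta <- fit$coefficients[-1]
    names(theta) <- fnames
    intercept <- fit$coefficients[1]
  } else if (penalty == "l1" && lambda >= lambda_max(X, y, w) * (1 - 1e-12)) {
    # KKT closed form: at or above the critical penalty the solution is
    # the null model with the weighted-logit intercept, exactly
    theta <- rep(0, ncol(X))
    names(theta) <- fnames
    intercept <- qlogis(sum(w * y) / sum(w))
    converged <- TRUE
  } else {
    wsum <- sum(w)
    lam_g <- if (penalty == "l1") lambda / wsum else 2 * lambda / wsum
    alpha <- if (penalty == "l1") 1 else 0
    pad <- ncol(X) == 1
    Xg <- if (pad) cbind(X, `..pad..` = 0) else X
    # short warm-start path ending at the target improves single-lambda
    # accuracy considerably
    lam_top <- max(lambda_max(X, y, w) / wsum * if (penalty == "l1") 1 else 20,
                   lam_g * 1.01)
    path <- unique(c(exp(seq(log(lam_top), log(lam_g), length.out = 6))))
    converged <- TRUE
    g <- withCallingHandlers(
      glmnet::glmnet(Xg, y, family = "binomial", weights = w,
                     alpha = alpha, lambda = path, standardize = FALSE,
                     thresh = 1e-12, maxit = 1e6),
      warning = function(wrn) {
        converged <<- FALSE
        invokeRestart("muffleWarning")
      })
    k <- length(g$lambda)
    theta <- as.numeric(g$beta[, k])
    if (pad) theta <- theta[1]
    names(theta) <- fnames
    intercept <- as.numeric(g$a0[k])
  }
  structure(list(theta = theta, intercept = intercept, penalty = penalty,
                 lambda = lambda, converged = converged,
                 objective_value = penalized_objective(
                   X, y, w, intercept, theta, lambda, penalty)),
            class = "penalized_fit")
}

#' @export
print.penalized_fit <- function(x, ...) {
  cat("<penalized_fit> ", toupper(x$penalty), " lambda=", signif(x$lambda, 4),
      "; ", sum(abs(x$theta) > 1e-10), "/", length(x$theta),
      " nonzero coefficients\n", sep = "")
  invisible(x)
}

#' Linear predictor of a penalized fit
#' @param object a `penalized_fit`.
#' @param newx design matrix with the same columns as the fit.
#' @param ... unused.
#' @return numeric linear predictor (log-odds scale).
#' @export
predict.penalized_fit <- function(object, newx, ...) {
  object$intercept + as.numeric(newx %*% object$theta)
}

#' Nonzero-support of a lasso fit
#'
#' @param fit a `penalized_fit` with `penalty = "l1"`.
#' @param tol absolute tolerance below which a coefficient counts as
#'   zero (default 1e-10).
#' @return character vector of feature names with `|theta| > tol`.
#' @export
lasso_support <- function(fit, tol = 1e-10) {
  stopifnot(inherits(fit, "penalized_fit"))
  if (fit$penalty != "l1")
    stop("lasso_support() is defined for L1 fits only")
  names(fit$theta)[abs(fit$theta) > tol]
}

#' Select the penalty by stratified k-fold cross-validation
#'
#' Splits the (training) rows into outcome-stratified folds, fits the
#' regularization path on each fold's training portion and scores each
#' grid value by the survey-weighted AUC on the held-out fold. The
#' selected penalty maximizes the mean fold AUC; exact ties go to the
#' stronger (larger) penalty.
#'
#' @inheritParams fit_penalized_logistic
#' @param grid decreasing penalty grid (summed-loss scale); default
#'   [default_lambda_grid()].
#' @param k number of folds (default 5).
#' @param seed integer seed for the fold assignment.
#' @return a `cv_result`: `lambda_grid`, `fold_auc` (grid x k matrix),
#'   `mean_auc`, `best_lambda`, `seed`, `penalty`.
#' @export
select_lambda_cv <- function(X, y, w = NULL, grid = NULL, k = 5,
                             seed = 1L, penalty = c("l1", "l2")) {
  penalty <- match.arg(penalty)
  if (is.null(w)) w <- rep(1, length(y))
  if (is.null(grid)) grid <- default_lambda_grid(X, y, w)
  grid <- sort(grid, decreasing = TRUE)
  stopifnot(length(grid) >= 1, all(grid > 0))
  if (min(table(y)) < k)
    stop("cannot stratify ", k, " folds: a class has fewer than ", k, " rows")
  folds <- with_seed(seed, {
    f <- integer(length(y))
    for (cls in unique(y)) {
      rows <- sample(which(y == cls))
      f[rows] <- rep_len(seq_len(k), length(rows))
    }
    f
  })
  wsum <- sum(w)
  lam_g <- if (penalty == "l1") grid / wsum else 2 * grid / wsum
  alpha <- if (penalty == "l1") 1 else 0
  pad <- ncol(X) == 1
  Xg <- if (pad) cbind(X, `..pad..` = 0) else X
  fold_auc <- matrix(NA_real_, length(grid), k)
  for (fold in seq_len(k)) {
    tr <- folds != fold
    g <- glmnet::glmnet(Xg[tr, , drop = FALSE], y[tr], weights = w[tr],
                        family = "binomial", alpha = alpha, lambda = lam_g,
                        standardize = FALSE)
    eta <- predict(g, Xg[!tr, , drop = FALSE])
    for (j in seq_len(ncol(eta)))
      fold_auc[j, fold] <- weighted_auc(eta[, j], y[!tr], w[!tr])
  }
  mean_auc <- rowMeans(fold_auc)
  best <- grid[which.max(mean_auc)]   # grid decreasing: ties -> larger lambda
  structure(list(lambda_grid = grid, fold_auc = fold_auc,
                 mean_auc = mean_auc, best_lambda = best,
                 seed = as.integer(seed), penalty = penalty),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("<cv_result> ", toupper(x$penalty), " ", length(x$lambda_grid),
      "-value grid; best lambda ", signif(x$best_lambda, 4),
      " (mean AUC ", signif(max(x$mean_auc), 4), ")\n", sep = "")
  invisible(x)
}
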