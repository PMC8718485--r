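#' Build a ranked coefficient curve
#'
#' Sorts absolute coefficient values (or nonnegative importances) in
#' decreasing order. Ties are broken lexicographically by feature name
#' for determinism. The higher a feature sits on the curve, the
#' stronger its (penalized) association with the outcome.
#'
#' @param values nonnegative finite values, one per feature.
#' @param names feature names aligned with `values`.
#' @param source label of the producing model (`"ridge"`,
#'   `"nn_importance"`, ...).
#' @return a `coef_curve` data.frame with columns `rank`, `feature`,
#'   `value`.
#' @export
coefficient_curve <- function(values, names, source = "ridge") {
  stopifnot(length(values) == length(names), all(is.finite(values)),
            all(values >= 0))
  o <- order(-values, names)
  structure(data.frame(rank = seq_along(o), feature = names[o],
                       value = as.numeric(values[o])),
            source = source, class = c("coef_curve", "data.frame"))
}

#' Ranked absolute-coefficient curve of a penalized fit
#'
#' Uses `|theta_j|` so that protective (negative) associations rank by
#' strength alongside risk factors; the intercept is excluded.
#'
#' @param fit a converged `penalized_fit`.
#' @return a `coef_curve`.
#' @export
rank_coefficients <- function(fit) {
  stopifnot(inherits(fit, "penalized_fit"))
  if (!isTRUE(fit$converged))
    warning("ranking coefficients of a non-converged fit")
  coefficient_curve(abs(fit$theta), names(fit$theta), source = fit$penalty)
}

#' Locate the knee of a ranked coefficient curve
#'
#' Fits a cubic smoothing spline f to the curve (values rescaled to
#' \[0, 1\] so the result is invariant to the overall coefficient
#' scale; smoothing chosen by generalized cross-validation, with the
#' effective degrees of freedom capped at 6: a ranked coefficient
#' curve has a single macroscopic bend, and an undersmoothed spline
#' would let rank-scale noise create spurious curvature maxima) and
#' evaluates the
#' curvature kappa(r) = |f''(r)| / (1 + f'(r)^2)^(3/2) at every rank.
#' The knee is the interior rank with maximal curvature; ties go to the
#' smallest rank. Flat or exactly linear curves have no knee and raise
#' an error.
#'
#' @param curve a `coef_curve` of length >= 5.
#' @param min_curvature curvature below which the curve is declared
#'   knee-free (default 1e-12, on the normalized scale).
#' @return a `knee_result`: `knee_rank`, per-rank `curvature`,
#'   `smoothing_df`.
#' @export
find_knee <- function(curve, min_curvature = 1e-12) {
  stopifnot(inherits(curve, "coef_curve"))
  v <- curve$value
  p <- length(v)
  if (p < 5) stop("need at least 5 ranked values to locate a knee")
  rng <- max(v) - min(v)
  if (rng < 1e-15) stop("no knee: flat coefficient curve")
  r <- seq_len(p)
  yn <- (v - min(v)) / rng
  cap <- min(6, p - 1)
  sp <- smooth.spline(r, yn)           # GCV bandwidth
  if (sp$df > cap) sp <- smooth.spline(r, yn, df = cap)
  f1 <- predict(sp, r, deriv = 1)$y
  f2 <- predict(sp, r, deriv = 2)$y
  kappa <- abs(f2) / (1 + f1^2)^1.5
  interior <- 2:(p - 1)
  if (max(kappa[interior]) < min_curvature)
    stop("no knee: curve is linear (curvature below tolerance)")
  knee <- interior[which.max(kappa[interior])]
  structure(list(knee_rank = knee, curvature = kappa,
                 smoothing_df = sp$df, smoothed = predict(sp, r)$y),
            class = "knee_result")
}

#' @export
print.knee_result <- function(x, ...) {
  cat("<knee_result> knee at rank ", x$knee_rank, " of ",
      length(x$curvature), " (spline df ", signif(x$smoothing_df, 4),
      ")\n", sep = "")
  invisible(x)
}

#' Features at or above the knee
#'
#' Returns the rank-prefix of the curve up to and including the knee
#' rank (the knee feature itself is selected; inclusivity at the
#' boundary is fixed by convention).
#'
#' @param curve a `coef_curve`.
#' @param knee the matching `knee_result`.
#' @return character vector of feature names in rank order.
#' @export
select_above_knee <- function(curve, knee) {
  stopifnot(inherits(curve, "coef_curve"), inherits(knee, "knee_result"))
  curve$feature[seq_len(knee$knee_rank)]
}

#' Write a coefficient curve and its curvature to CSV
#' @param curve a `coef_curve`.
#' @param knee optional `knee_result` supplying the curvature column.
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
write_curve <- function(curve, knee = NULL, path) {
  out <- as.data.frame(curve)
  if (!is.null(knee)) {
    out$curvature <- knee$curvature
    out$above_knee <- out$rank <= knee$knee_rank
  }
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}
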