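#' Stratified train/test split
#'
#' Partitions respondents into a training and a test set, stratified by
#' the binary outcome so that the rare class is represented on both
#' sides in (near) equal proportion. The split is deterministic given
#' the seed.
#'
#' @param y binary outcome vector (0/1).
#' @param train_fraction fraction of rows assigned to the training set
#'   (default 0.8).
#' @param stratified stratify by outcome? (default `TRUE`).
#' @param seed integer seed controlling the permutation.
#' @return list with integer index vectors `train` and `test`.
#' @export
make_split <- function(y, train_fraction = 0.8, stratified = TRUE, seed = 1L) {
  n <- length(y)
  if (n < 10) stop("need at least 10 rows to split")
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must be in (0, 1)")
  idx <- with_seed(seed, {
    if (stratified) {
      train <- integer(0)
      for (cls in sort(unique(y))) {
        rows <- which(y == cls)
        n_tr <- round(train_fraction * length(rows))
        train <- c(train, sample(rows, n_tr))
      }
      sort(train)
    } else {
      sort(sample(n, round(train_fraction * n)))
    }
  })
  test <- setdiff(seq_len(n), idx)
  for (side in list(idx, test)) {
    if (length(unique(y[side])) < 2)
      stop("a split side contains a single outcome class; ",
           "increase n or the rare-class count")
  }
  list(train = idx, test = test)
}

#' Survey-weighted AUC
#'
#' Area under the ROC curve as the weighted Mann-Whitney statistic:
#' the weighted probability that a randomly drawn positive scores above
#' a randomly drawn negative, counting ties as 1/2. With unit weights
#' this reduces exactly to the usual rank-based AUC.
#'
#' @param scores numeric risk scores (any monotone scale).
#' @param y binary outcome (0/1).
#' @param w positive observation weights; `NULL` for unit weights.
#' @return AUC in \[0, 1\].
#' @export
weighted_auc <- function(scores, y, w = NULL) {
  if (is.null(w)) w <- rep(1, length(y))
  stopifnot(length(scores) == length(y), length(w) == length(y))
  if (any(!is.finite(scores))) stop("non-finite scores")
  pos <- y == 1
  if (!any(pos) || all(pos)) stop("both outcome classes must be present")
  # group by unique score; accumulate neg weight below each block
  o <- order(scores)
  s <- scores[o]; yy <- y[o]; ww <- w[o]
  grp <- cumsum(c(TRUE, s[-1] != s[-length(s)]))
  wp <- tapply(ww * (yy == 1), grp, sum)
  wn <- tapply(ww * (yy == 0), grp, sum)
  below <- c(0, cumsum(wn)[-length(wn)])
  num <- sum(wp * (below + wn / 2))
  num / (sum(wp) * sum(wn))
}

#' Weighted confusion-matrix metrics
#'
#' Sensitivity, specificity and balanced error rate from binary
#' predictions, with each respondent contributing their survey weight.
#' BER = 1 - (sensitivity + specificity) / 2.
#'
#' @param yhat binary predictions (0/1).
#' @param y binary outcome (0/1).
#' @param w positive weights; `NULL` for unit weights.
#' @return list with `sensitivity`, `specificity`, `ber`.
#' @export
confusion_metrics <- function(yhat, y, w = NULL) {
  if (is.null(w)) w <- rep(1, length(y))
  stopifnot(length(yhat) == length(y), length(w) == length(y))
  tp <- sum(w[yhat == 1 & y == 1]); fn <- sum(w[yhat == 0 & y == 1])
  tn <- sum(w[yhat == 0 & y == 0]); fp <- sum(w[yhat == 1 & y == 0])
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  list(sensitivity = sens, specificity = spec,
       ber = 1 - (sens + spec) / 2)
}

#' Choose a classification threshold minimizing weighted BER
#'
#' Scans the observed unique scores; a respondent is classified positive
#' when their score strictly exceeds the threshold. Ties in BER are
#' broken toward the lower threshold. Intended to be applied to
#' *training* scores; the chosen threshold is then frozen for test-set
#' evaluation.
#'
#' @inheritParams weighted_auc
#' @return the selected threshold (a value of `scores`).
#' @export
choose_threshold <- function(scores, y, w = NULL) {
  if (is.null(w)) w <- rep(1, length(y))
  pos <- y == 1
  if (!any(pos) || all(pos)) stop("both outcome classes must be present")
  o <- order(scores)
  s <- scores[o]; yy <- y[o]; ww <- w[o]
  grp <- cumsum(c(TRUE, s[-1] != s[-length(s)]))
  uniq <- s[!duplicated(grp)]
  wp <- as.numeric(tapply(ww * (yy == 1), grp, sum))
  wn <- as.numeric(tapply(ww * (yy == 0), grp, sum))
  Wp <- sum(wp); Wn <- sum(wn)
  # threshold = uniq[k]: positives are scores > uniq[k]
  tp <- Wp - cumsum(wp)
  tn <- cumsum(wn)
  ber <- 1 - (tp / Wp + tn / Wn) / 2
  uniq[which.min(ber)]     # which.min takes the first (lowest) on ties
}

#' Evaluate scores against a binary outcome
#'
#' Convenience wrapper computing weighted AUC plus thresholded
#' sensitivity/specificity/BER, with unweighted versions alongside for
#' debugging.
#'
#' @inheritParams weighted_auc
#' @param threshold classification threshold (scores strictly above are
#'   called positive), typically chosen on training data via
#'   [choose_threshold()].
#' @return list of metrics.
#' @export
evaluate_scores <- function(scores, y, w = NULL, threshold) {
  yhat <- as.integer(scores > threshold)
  cm <- confusion_metrics(yhat, y, w)
  cm_u <- confusion_metrics(yhat, y, NULL)
  list(auc = weighted_auc(scores, y, w),
       auc_unweighted = weighted_auc(scores, y, NULL),
       sensitivity = cm$sensitivity, specificity = cm$specificity,
       ber = cm$ber, ber_unweighted = cm_u$ber,
       threshold = threshold)
}

#' Write a run report to disk
#'
#' Serializes an analysis report (from [run_iterative_analysis()] or
#' [nn_pipeline()]) as machine-readable JSON plus a Markdown summary
#' with per-round metrics and an included/excluded theme matrix.
#'
#' @param report an `ita_report` or `nn_report` object.
#' @param dir output directory (created if absent).
#' @return invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  json_path <- file.path(dir, "report.json")
  md_path <- file.path(dir, "report.md")
  jsonlite::write_json(unclass(report), json_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  writeLines(format_report_md(report), md_path)
  invisible(c(json = json_path, md = md_path))
}

#' Read a JSON run report back
#' @param path path to a `report.json` written by [write_report()].
#' @return the report as a list.
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                      simplifyMatrix = FALSE)
}

format_report_md <- function(report) {
  lines <- c("# Iterative thematic analysis report", "")
  if (!is.null(report$stop_reason))
    lines <- c(lines, paste0("Stop reason: `", report$stop_reason, "`"), "")
  rounds <- report$rounds
  if (length(rounds)) {
    lines <- c(lines,
      "| round | support | knee | selected vars | dominant theme | AUC | BER |",
      "|---|---|---|---|---|---|---|")
    for (r in rounds) {
      lines <- c(lines, sprintf(
        "| %d | %d | %s | %d | %s | %.3f | %.3f |",
        r$round, r$support_size %||% 0L,
        as.character(r$knee_rank %||% NA),
        length(r$selected_vars %||% character(0)),
        r$dominant_theme %||% "-",
        r$metrics$auc %||% NA_real_, r$metrics$ber %||% NA_real_))
    }
    lines <- c(lines, "", "## Themes excluded, in order", "")
    excl <- unlist(lapply(rounds, function(r) r$dominant_theme))
    if (length(excl)) lines <- c(lines, paste0(seq_along(excl), ". ", excl))
  }
  lines
}
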