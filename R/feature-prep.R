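#' Aggregate outcome items to an any-vs-none binary outcome
#'
#' The outcome is 1 if any of the three item indicators is 1, 0 if all
#' answered items are 0, and the respondent is dropped (with a count)
#' when all three items are missing.
#'
#' @param items n x 3 matrix or data.frame of 0/1/NA item indicators.
#' @return list with `outcome` (0/1, length = kept rows), `keep` (row
#'   indices kept) and `n_dropped`.
#' @export
aggregate_outcome <- function(items) {
  m <- as.matrix(items)
  stopifnot(ncol(m) == 3)
  any1 <- rowSums(m == 1, na.rm = TRUE) > 0
  n_miss <- rowSums(is.na(m))
  drop <- n_miss == 3 & !any1
  keep <- which(!drop)
  if (any(drop))
    message(sum(drop), " respondent(s) dropped: all outcome items missing")
  list(outcome = as.integer(any1[keep]), keep = keep,
       n_dropped = sum(drop))
}

#' One-hot encode a raw survey table
#'
#' Expands every categorical variable with >= 3 levels into one
#' indicator column per level (full one-hot, no reference level
#' dropped — penalization absorbs the induced collinearity), keeps
#' binary variables as a single 0/1 column and continuous variables as
#' numeric columns. Missing categorical/binary values contribute 0 to
#' every indicator; missing continuous values are mean-imputed, with a
#' companion `<var>__missing` indicator added when more than 1% of the
#' values are missing.
#'
#' @param table respondent-level data.frame; may contain `id`, `weight`,
#'   `outcome` and `msv_item_*` columns, which are not encoded.
#' @param dict a variable dictionary data.frame with columns `name`,
#'   `kind` (`categorical`/`binary`/`continuous`), `levels`
#'   (pipe-separated, categorical/binary only) and `duplicate_of`.
#' @param outcome binary outcome vector; defaults to `table$outcome`.
#' @param weights positive weights; defaults to `table$weight`, else 1.
#' @return an `encoded_matrix`: list with sparse `X`, `feature_names`,
#'   `y`, `w`, and a `provenance` data.frame (feature, variable, level,
#'   kind).
#' @export
one_hot_encode <- function(table, dict, outcome = NULL, weights = NULL) {
  outcome <- outcome %||% table$outcome
  weights <- weights %||% table$weight %||% rep(1, nrow(table))
  stopifnot(!is.null(outcome), length(outcome) == nrow(table),
            length(weights) == nrow(table), all(weights > 0))
  vars <- intersect(dict$name, colnames(table))
  missing_vars <- setdiff(colnames(table),
                          c(dict$name, "id", "weight", "outcome",
                            grep("^msv_item_", colnames(table), value = TRUE)))
  if (length(missing_vars))
    stop("table variables absent from dictionary: ",
         paste(missing_vars, collapse = ", "))

  n <- nrow(table)
  cols <- list(); prov <- list()
  for (v in vars) {
    row <- dict[dict$name == v, ]
    kind <- row$kind
    x <- table[[v]]
    if (kind == "categorical") {
      levs <- strsplit(row$levels, "|", fixed = TRUE)[[1]]
      if (length(levs) < 3)
        stop("categorical variable '", v, "' must declare >= 3 levels")
      xc <- as.character(x)
      bad <- setdiff(unique(xc[!is.na(xc)]), levs)
      if (length(bad))
        stop("unseen level '", bad[1], "' in variable '", v, "'")
      for (l in levs) {
        cols[[length(cols) + 1L]] <- as.numeric(!is.na(xc) & xc == l)
        prov[[length(prov) + 1L]] <- data.frame(
          feature = paste0(v, "=", l), variable = v, level = l,
          kind = "categorical")
      }
    } else if (kind == "binary") {
      levs <- strsplit(row$levels, "|", fixed = TRUE)[[1]]
      if (length(levs) != 2)
        stop("binary variable '", v, "' must declare exactly 2 levels")
      xc <- as.character(x)
      bad <- setdiff(unique(xc[!is.na(xc)]), levs)
      if (length(bad))
        stop("unseen level '", bad[1], "' in variable '", v, "'")
      cols[[length(cols) + 1L]] <- as.numeric(!is.na(xc) & xc == levs[2])
      prov[[length(prov) + 1L]] <- data.frame(
        feature = v, variable = v, level = levs[2], kind = "binary")
    } else if (kind == "continuous") {
      xn <- as.numeric(x)
      n_na <- sum(is.na(xn))
      if (n_na > 0) {
        mu <- mean(xn, na.rm = TRUE)
        if (n_na / n > 0.01) {
          cols[[length(cols) + 1L]] <- as.numeric(is.na(xn))
          prov[[length(prov) + 1L]] <- data.frame(
            feature = paste0(v, "__missing"), variable = v, level = NA,
            kind = "missing_indicator")
        }
        xn[is.na(xn)] <- mu
      }
      cols[[length(cols) + 1L]] <- xn
      prov[[length(prov) + 1L]] <- data.frame(
        feature = v, variable = v, level = NA, kind = "continuous")
    } else stop("unknown kind '", kind, "' for variable '", v, "'")
  }
  prov <- do.call(rbind, prov)
  X <- matrix(unlist(cols, use.names = FALSE), nrow = n)
  colnames(X) <- prov$feature
  X <- methods::as(Matrix::Matrix(X, sparse = TRUE), "CsparseMatrix")
  structure(list(X = X, feature_names = prov$feature,
                 y = as.integer(outcome), w = as.numeric(weights),
                 provenance = prov),
            class = "encoded_matrix")
}

#' @export
print.encoded_matrix <- function(x, ...) {
  cat("<encoded_matrix> ", nrow(x$X), " respondents x ", ncol(x$X),
      " features; weighted prevalence ",
      signif(sum(x$w * x$y) / sum(x$w), 3), "\n", sep = "")
  invisible(x)
}

#' Z-score continuous columns
#'
#' Standardizes every continuous column (and missingness indicators are
#' left as-is) to mean 0 and population SD 1, using unweighted moments:
#' the survey weights enter the likelihood, not the feature scaling.
#' Constant columns are dropped with a warning. Idempotent on
#' already-standardized input.
#'
#' @param enc an `encoded_matrix`.
#' @return the `encoded_matrix` with standardized continuous columns.
#' @export
normalize_continuous <- function(enc) {
  stopifnot(inherits(enc, "encoded_matrix"))
  cont <- which(enc$provenance$kind == "continuous")
  if (!length(cont)) return(enc)
  M <- as.matrix(enc$X[, cont, drop = FALSE])
  mu <- colMeans(M)
  sd_pop <- sqrt(colMeans(sweep(M, 2, mu)^2))
  const <- sd_pop < 1e-12
  keep <- cont[!const]
  if (any(const))
    warning("constant continuous column(s) dropped: ",
            paste(enc$feature_names[cont[const]], collapse = ", "))
  if (length(keep)) {
    scaled <- sweep(sweep(M[, !const, drop = FALSE], 2, mu[!const]),
                    2, sd_pop[!const], `/`)
    # rebuild by column concatenation: in-place sparse column
    # replacement is quadratic in practice
    others <- setdiff(seq_len(ncol(enc$X)), keep)
    X2 <- cbind(enc$X[, others, drop = FALSE],
                methods::as(Matrix::Matrix(scaled, sparse = TRUE),
                            "CsparseMatrix"))
    colnames(X2) <- c(colnames(enc$X)[others], colnames(enc$X)[keep])
    enc$X <- X2[, match(colnames(enc$X), colnames(X2)), drop = FALSE]
  }
  if (any(const)) enc <- drop_features(enc, cont[const])
  enc
}

drop_features <- function(enc, idx) {
  if (!length(idx)) return(enc)
  enc$X <- enc$X[, -idx, drop = FALSE]
  enc$provenance <- enc$provenance[-idx, , drop = FALSE]
  rownames(enc$provenance) <- NULL
  enc$feature_names <- enc$provenance$feature
  enc
}

#' Remove redundant representations
#'
#' Drops (a) every column derived from a dictionary variable whose
#' `duplicate_of` field is set (the source representation is kept), and
#' (b) exact duplicate columns — bitwise equal after encoding — keeping
#' the lexicographically first feature name of each group. Cycles in
#' `duplicate_of` raise an error.
#'
#' @param enc an `encoded_matrix`.
#' @param dict the variable dictionary used for encoding.
#' @return the pruned `encoded_matrix`.
#' @export
remove_redundant <- function(enc, dict) {
  stopifnot(inherits(enc, "encoded_matrix"))
  dup <- dict$duplicate_of
  names(dup) <- dict$name
  # cycle detection over duplicate_of chains
  for (v in dict$name[!is.na(dup)]) {
    seen <- character(0); cur <- v
    while (!is.na(dup[cur] %||% NA)) {
      if (cur %in% seen) stop("duplicate_of cycle involving '", v, "'")
      seen <- c(seen, cur)
      cur <- dup[[cur]]
      if (!cur %in% names(dup)) break
    }
  }
  derived_vars <- dict$name[!is.na(dup)]
  drop <- which(enc$provenance$variable %in% derived_vars)
  if (length(drop)) enc <- drop_features(enc, drop)

  # bitwise-identical columns: prefilter by (sum, nnz) signature
  X <- enc$X
  sig <- paste(Matrix::colSums(X), Matrix::colSums(X != 0))
  drop2 <- integer(0)
  for (g in unique(sig[duplicated(sig)])) {
    idx <- which(sig == g)
    idx <- idx[order(enc$feature_names[idx])]
    kept <- idx[1]; kept_cols <- list(as.numeric(X[, kept]))
    kept_idx <- kept
    for (j in idx[-1]) {
      xj <- as.numeric(X[, j])
      dup_of <- FALSE
      for (kc in kept_cols) if (identical(kc, xj)) { dup_of <- TRUE; break }
      if (dup_of) drop2 <- c(drop2, j)
      else { kept_cols <- c(kept_cols, list(xj)); kept_idx <- c(kept_idx, j) }
    }
  }
  if (length(drop2)) enc <- drop_features(enc, sort(drop2))
  enc
}

#' Full raw-table to design-matrix pipeline
#'
#' Aggregates the outcome from the `msv_item_*` columns when present
#' (dropping all-missing respondents), one-hot encodes, standardizes
#' continuous columns and removes redundant representations.
#'
#' @inheritParams one_hot_encode
#' @return an `encoded_matrix`.
#' @export
encode_survey <- function(table, dict) {
  items <- grep("^msv_item_", colnames(table), value = TRUE)
  if (length(items) == 3) {
    agg <- aggregate_outcome(table[items])
    table <- table[agg$keep, , drop = FALSE]
    outcome <- agg$outcome
  } else {
    outcome <- table$outcome
  }
  enc <- one_hot_encode(table, dict, outcome = outcome)
  enc <- normalize_continuous(enc)
  remove_redundant(enc, dict)
}

#' Write the feature-name manifest
#'
#' @param enc an `encoded_matrix`.
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
write_feature_manifest <- function(enc, path) {
  write.csv(enc$provenance, path, row.names = FALSE)
  invisible(path)
}
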