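# Small, fast synthetic configurations shared across tests.

small_themes <- function() {
  list(
    theme_spec("alpha", c("cont_01", "cont_02", "cont_03", "bin_01"),
               c(1.0, 0.9, 0.85, 0.9), within_theme_correlation = 0.3),
    theme_spec("beta", c("cont_04", "cont_05", "bin_02"),
               c(0.5, 0.5, 0.45), within_theme_correlation = 0.3)
  )
}

small_config <- function(seed = 1, n = 3000, ...) {
  synthetic_config(n_respondents = n, n_continuous = 12, n_binary = 8,
                   n_categorical = 15, levels_per_categorical = 4,
                   themes = small_themes(), n_duplicate_pairs = 2,
                   seed = seed, ...)
}

null_config <- function(seed = 1, n = 3000) {
  themes <- list(
    theme_spec("alpha", c("cont_01", "cont_02"), c(0, 0)),
    theme_spec("beta", c("cont_03", "cont_04"), c(0, 0)))
  synthetic_config(n_respondents = n, n_continuous = 10, n_binary = 6,
                   n_categorical = 10, levels_per_categorical = 4,
                   themes = themes, n_duplicate_pairs = 0, seed = seed)
}

# wrap a plain matrix as an encoded_matrix (continuous features)
wrap_enc <- function(X, y, w = NULL) {
  colnames(X) <- colnames(X) %||% sprintf("f%02d", seq_len(ncol(X)))
  if (is.null(w)) w <- rep(1, length(y))
  prov <- data.frame(feature = colnames(X), variable = colnames(X),
                     level = NA, kind = "continuous")
  structure(list(X = methods::as(Matrix::Matrix(X, sparse = TRUE),
                                 "CsparseMatrix"),
                 feature_names = colnames(X), y = as.integer(y),
                 w = as.numeric(w), provenance = prov),
            class = "encoded_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random small logistic problem for solver oracle tests
random_logistic_problem <- function(n = 500, p = 10, seed = 1,
                                    weighted = TRUE) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * p), n, p)
    beta <- rnorm(p, 0, 0.5) * rbinom(p, 1, 0.6)
    y <- rbinom(n, 1, plogis(-1 + drop(X %*% beta)))
    w <- if (weighted) exp(rnorm(n, 0, 0.4)) else rep(1, n)
    list(X = X, y = y, w = w / mean(w))
  })
}
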