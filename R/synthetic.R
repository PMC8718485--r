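#' Specify a planted latent theme
#'
#' A theme is a named group of generator variables that (a) are mutually
#' correlated through a Gaussian copula with equicorrelation
#' `within_theme_correlation` and (b) contribute the given log-odds
#' effects to the outcome's linear predictor. A variable may belong to
#' several themes (list it in each; its total effect is the sum of its
#' per-theme contributions, so use 0 for a purely topical membership).
#'
#' @param label theme label.
#' @param member_variables character vector (>= 2) of generator variable
#'   names (`cont_*` or `bin_*`).
#' @param effect_sizes signed log-odds contribution per member; same
#'   length as `member_variables`.
#' @param within_theme_correlation latent equicorrelation in \[0, 1).
#' @return a `theme_spec` object.
#' @export
theme_spec <- function(label, member_variables, effect_sizes,
                       within_theme_correlation = 0.3) {
  stopifnot(is.character(label), length(label) == 1,
            length(member_variables) >= 2,
            length(effect_sizes) == length(member_variables),
            within_theme_correlation >= 0, within_theme_correlation < 1)
  structure(list(label = label,
                 member_variables = member_variables,
                 effect_sizes = as.numeric(effect_sizes),
                 within_theme_correlation = within_theme_correlation),
            class = "theme_spec")
}

#' Default planted themes
#'
#' Three themes with well-separated mean absolute effect sizes
#' (approximately 0.78, 0.50 and 0.29 on the log-odds scale), echoing
#' how empirically coded survey themes span strong (violence exposure),
#' moderate (sexual behaviour) and weak (health access) associations
#' with a rare outcome. Each theme mixes continuous and binary items and
#' contains one protective (negative) effect; `cont_09` carries a dual
#' membership so multi-theme retention logic is exercised.
#'
#' @return list of [theme_spec()] objects.
#' @export
default_theme_specs <- function() {
  list(
    theme_spec("violence_exposure",
               c("cont_01", "cont_02", "cont_03", "cont_04", "cont_05",
                 "bin_01", "bin_02", "bin_03"),
               c(0.9, 0.85, 0.8, 0.75, 0.7, 0.8, -0.75, 0.7),
               within_theme_correlation = 0.35),
    theme_spec("sexual_behaviour",
               c("cont_06", "cont_07", "cont_08", "cont_09",
                 "bin_04", "bin_05"),
               c(0.55, 0.5, -0.5, 0.5, 0.45, 0.5),
               within_theme_correlation = 0.3),
    theme_spec("health_access",
               c("cont_10", "cont_11", "cont_12", "cont_09",
                 "bin_06", "bin_07"),
               c(0.3, 0.3, -0.28, 0.0, 0.3, 0.25),
               within_theme_correlation = 0.3)
  )
}

#' Configuration for the synthetic survey generator
#'
#' Defaults emulate the shape of a large demographic-survey domestic
#' violence module: tens of thousands of respondents, a mix of
#' continuous, binary and multi-level categorical variables that one-hot
#' expand to roughly 500 columns, heterogeneous sampling weights, planted
#' redundant representations, and a rare outcome (weighted prevalence
#' 5.7%) driven by a sparse set of themed variables.
#'
#' @param n_respondents number of rows.
#' @param n_continuous,n_binary,n_categorical counts of raw variables.
#' @param levels_per_categorical levels per categorical variable (>= 3).
#' @param themes list of [theme_spec()]; members must name `cont_*` /
#'   `bin_*` variables within range.
#' @param target_prevalence expected weighted outcome prevalence, in
#'   (0, 0.5); default 0.057.
#' @param n_duplicate_pairs how many continuous variables also get a
#'   binned categorical copy (a planted redundant representation).
#' @param weight_dispersion log-scale SD of the lognormal survey
#'   weights (renormalized to mean 1).
#' @param seed integer; fully determines the generated tables.
#' @return a `synthetic_config` object.
#' @export
synthetic_config <- function(n_respondents = 20000,
                             n_continuous = 40,
                             n_binary = 40,
                             n_categorical = 84,
                             levels_per_categorical = 5,
                             themes = default_theme_specs(),
                             target_prevalence = 0.057,
                             n_duplicate_pairs = 5,
                             weight_dispersion = 0.3,
                             seed = 1L) {
  stopifnot(n_respondents >= 10,
            target_prevalence > 0, target_prevalence < 0.5,
            levels_per_categorical >= 3,
            n_duplicate_pairs <= n_continuous,
            weight_dispersion > 0)
  cont <- sprintf("cont_%02d", seq_len(n_continuous))
  bin <- sprintf("bin_%02d", seq_len(n_binary))
  for (th in themes) {
    stopifnot(inherits(th, "theme_spec"))
    bad <- setdiff(th$member_variables, c(cont, bin))
    if (length(bad))
      stop("theme '", th$label, "' names unknown variables: ",
           paste(bad, collapse = ", "))
  }
  structure(list(n_respondents = as.integer(n_respondents),
                 n_continuous = as.integer(n_continuous),
                 n_binary = as.integer(n_binary),
                 n_categorical = as.integer(n_categorical),
                 levels_per_categorical = as.integer(levels_per_categorical),
                 themes = themes,
                 target_prevalence = target_prevalence,
                 n_duplicate_pairs = as.integer(n_duplicate_pairs),
                 weight_dispersion = weight_dispersion,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# latent equicorrelation matrix over the union of theme members;
# overlapping themes take the larger of the two correlations
build_theme_correlation <- function(themes, vars) {
  k <- length(vars)
  R <- diag(k)
  for (th in themes) {
    idx <- match(th$member_variables, vars)
    for (a in idx) for (b in idx) if (a != b)
      R[a, b] <- max(R[a, b], th$within_theme_correlation)
  }
  R
}

#' Draw a binary outcome at a calibrated prevalence
#'
#' Given a linear predictor built from the planted effects, finds (by
#' root-finding) the intercept c such that the *expected* weighted
#' prevalence `sum(w * plogis(c + eta)) / sum(w)` equals
#' `target_prevalence`, then draws the outcome Bernoulli(plogis(c + eta)).
#' Calibrating the expectation (not the realized draw) keeps the
#' intercept deterministic given the design.
#'
#' @param linear_predictor per-respondent planted log-odds contribution
#'   (excluding the intercept).
#' @param target_prevalence desired expected weighted prevalence.
#' @param weights positive survey weights; `NULL` for unit weights.
#' @return list with `outcome` (0/1 vector) and `intercept`.
#' @export
generate_outcome <- function(linear_predictor, target_prevalence,
                             weights = NULL) {
  eta <- as.numeric(linear_predictor)
  if (is.null(weights)) weights <- rep(1, length(eta))
  wsum <- sum(weights)
  f <- function(c) sum(weights * plogis(c + eta)) / wsum - target_prevalence
  lo <- -40; hi <- 40
  if (f(lo) > 0 || f(hi) < 0)
    stop(sprintf(
      "cannot calibrate intercept: achievable prevalence range [%.3g, %.3g]",
      f(lo) + target_prevalence, f(hi) + target_prevalence))
  intercept <- uniroot(f, c(lo, hi), tol = 1e-12)$root
  p <- plogis(intercept + eta)
  list(outcome = rbinom(length(eta), 1, p), intercept = intercept)
}

#' Generate a synthetic survey population with planted themes
#'
#' Draws a respondent-level table: correlated continuous/binary theme
#' members (Gaussian copula, binaries by thresholding the latent
#' Gaussian), independent noise variables, multi-level categoricals,
#' lognormal survey weights normalized to mean 1, a rare outcome drawn
#' from the planted linear predictor with a calibrated intercept, three
#' outcome item indicators whose any-vs-none aggregate reproduces the
#' outcome, and (optionally) binned categorical copies of continuous
#' variables as planted redundant representations.
#'
#' @param config a [synthetic_config()].
#' @return list with `table` (data.frame: id, weight, outcome, three
#'   `msv_item_*` columns, then variables), `dictionary` (a variable
#'   dictionary data.frame), and `ground_truth` (theme map, per-variable
#'   total effects, duplicate map, calibrated intercept).
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed, generate_population_impl(config))
}

generate_population_impl <- function(config) {
  n <- config$n_respondents
  cont <- sprintf("cont_%02d", seq_len(config$n_continuous))
  bin <- sprintf("bin_%02d", seq_len(config$n_binary))
  cats <- sprintf("cat_%02d", seq_len(config$n_categorical))

  themed <- unique(unlist(lapply(config$themes, `[[`, "member_variables")))
  R <- build_theme_correlation(config$themes, themed)
  U <- tryCatch(chol(R), error = function(e)
    stop("theme correlation structure is not positive definite ",
         "(themes: ", paste(vapply(config$themes, `[[`, "", "label"),
                            collapse = ", "), ")"))
  Z <- matrix(rnorm(n * length(themed)), n) %*% U
  colnames(Z) <- themed

  latent <- matrix(rnorm(n * (length(cont) + length(bin))), n)
  colnames(latent) <- c(cont, bin)
  latent[, themed] <- Z

  tab <- data.frame(id = seq_len(n))
  for (v in cont) tab[[v]] <- latent[, v]
  bin_prev <- runif(length(bin), 0.2, 0.6)
  for (i in seq_along(bin))
    tab[[bin[i]]] <- as.integer(latent[, bin[i]] > qnorm(1 - bin_prev[i]))
  k <- config$levels_per_categorical
  for (v in cats) {
    u <- runif(k, 0.5, 1.5); pr <- u / sum(u)
    g <- rnorm(n)
    cuts <- qnorm(cumsum(pr)[-k])
    tab[[v]] <- paste0("l", findInterval(g, cuts) + 1L)
  }

  # planted linear predictor; continuous enter as their (standard-normal)
  # values, binaries as raw 0/1 indicators
  true_effects <- numeric(0)
  theme_rows <- list()
  for (th in config$themes) {
    for (j in seq_along(th$member_variables)) {
      v <- th$member_variables[j]
      true_effects[v] <- (if (v %in% names(true_effects)) true_effects[v]
                          else 0) + th$effect_sizes[j]
      theme_rows[[length(theme_rows) + 1L]] <-
        data.frame(variable = v, theme = th$label)
    }
  }
  eta <- rep(0, n)
  for (v in names(true_effects)) eta <- eta + true_effects[v] * tab[[v]]

  w <- exp(rnorm(n, 0, config$weight_dispersion))
  w <- w / mean(w)

  out <- generate_outcome(eta, config$target_prevalence, w)
  y <- out$outcome

  # three item indicators whose any-vs-none aggregate equals the outcome;
  # only zero-valued items may go missing, and never all three at once
  items <- matrix(0L, n, 3)
  pos <- which(y == 1)
  forced <- sample(3, length(pos), replace = TRUE)
  items[cbind(pos, forced)] <- 1L
  extra <- matrix(rbinom(length(pos) * 3, 1, 0.25), ncol = 3)
  items[pos, ] <- pmax(items[pos, ], extra * 1L)
  miss <- matrix(runif(n * 3) < 0.02 & items == 0, n, 3)
  all_na <- rowSums(miss) == 3
  miss[all_na, 1] <- FALSE
  items[miss] <- NA_integer_

  dict <- data.frame(
    name = c(cont, bin, cats),
    kind = c(rep("continuous", length(cont)), rep("binary", length(bin)),
             rep("categorical", length(cats))),
    levels = c(rep("", length(cont)),
               rep("0|1", length(bin)),
               rep(paste0("l", seq_len(k), collapse = "|"), length(cats))),
    duplicate_of = NA_character_,
    stringsAsFactors = FALSE)

  tab_out <- data.frame(id = tab$id, weight = w, outcome = y,
                        msv_item_1 = items[, 1], msv_item_2 = items[, 2],
                        msv_item_3 = items[, 3])
  tab_out <- cbind(tab_out, tab[c(cont, bin, cats)])

  gt <- list(theme_map = unique(do.call(rbind, theme_rows)),
             true_effects = true_effects,
             duplicate_map = character(0),
             calibrated_intercept = out$intercept)
  rownames(gt$theme_map) <- NULL

  pop <- list(table = tab_out, dictionary = dict, ground_truth = gt)
  if (config$n_duplicate_pairs > 0)
    pop <- plant_duplicates(pop, config$n_duplicate_pairs)
  pop
}

#' Plant redundant categorical copies of continuous variables
#'
#' For each of the first `n_pairs` continuous variables, appends a
#' 5-level quantile-binned categorical copy (`<var>_grp`), records it in
#' the dictionary with `duplicate_of` set, and in the ground truth's
#' `duplicate_map`. Downstream redundancy removal must drop exactly the
#' derived representation.
#'
#' @param pop a population list from [generate_population()].
#' @param n_pairs number of continuous variables to duplicate.
#' @return the modified population list.
#' @export
plant_duplicates <- function(pop, n_pairs) {
  if (n_pairs == 0) return(pop)
  cont_vars <- pop$dictionary$name[pop$dictionary$kind == "continuous" &
                                     is.na(pop$dictionary$duplicate_of)]
  stopifnot(n_pairs <= length(cont_vars))
  for (v in head(cont_vars, n_pairs)) {
    dv <- paste0(v, "_grp")
    qs <- quantile(pop$table[[v]], probs = seq(0.2, 0.8, by = 0.2))
    pop$table[[dv]] <- paste0("l", findInterval(pop$table[[v]], qs) + 1L)
    pop$dictionary <- rbind(pop$dictionary, data.frame(
      name = dv, kind = "categorical",
      levels = paste0("l", 1:5, collapse = "|"),
      duplicate_of = v, stringsAsFactors = FALSE))
    pop$ground_truth$duplicate_map[dv] <- v
  }
  pop
}

#' Write a synthetic population to plain-text files
#'
#' Writes `survey.csv` (the respondent table), `dictionary.csv` and
#' `ground_truth.json` under `dir`.
#'
#' @param pop a population list from [generate_population()].
#' @param dir output directory (created if absent).
#' @return invisibly, the file paths.
#' @export
write_survey_data <- function(pop, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(survey = file.path(dir, "survey.csv"),
             dictionary = file.path(dir, "dictionary.csv"),
             ground_truth = file.path(dir, "ground_truth.json"))
  write.csv(pop$table, paths["survey"], row.names = FALSE)
  write.csv(pop$dictionary, paths["dictionary"], row.names = FALSE)
  gt <- pop$ground_truth
  gt$true_effects <- as.list(gt$true_effects)
  gt$duplicate_map <- as.list(gt$duplicate_map)
  jsonlite::write_json(gt, paths["ground_truth"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
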