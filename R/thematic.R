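#' Control parameters for the iterative thematic analysis
#'
#' @param seed master seed; every stochastic step (split, fold
#'   assignment) derives its own sub-seed from it, so runs are exactly
#'   reproducible and resumable.
#' @param train_fraction training share of the single up-front
#'   stratified split, reused across all rounds so AUC traces are
#'   comparable (default 0.8).
#' @param k_folds folds for penalty cross-validation (default 5).
#' @param nlambda,lambda_min_ratio penalty-grid shape per round; see
#'   [default_lambda_grid()].
#' @param auc_floor stop when the round's test AUC drops below this
#'   (default 0.75).
#' @param theme_min_frac a theme qualifies only when its selected
#'   members are at least this fraction of the selected variables
#'   (default 0.05), and
#' @param min_theme_members at least this many (default 2).
#' @param max_rounds hard guard on the number of rounds (default 25).
#' @param support_tol tolerance for [lasso_support()].
#' @return list of control parameters.
#' @export
ita_control <- function(seed = 1L, train_fraction = 0.8, k_folds = 5,
                        nlambda = 50, lambda_min_ratio = 1e-4,
                        auc_floor = 0.75, theme_min_frac = 0.05,
                        min_theme_members = 2, max_rounds = 25,
                        support_tol = 1e-10) {
  list(seed = as.integer(seed), train_fraction = train_fraction,
       k_folds = k_folds, nlambda = nlambda,
       lambda_min_ratio = lambda_min_ratio, auc_floor = auc_floor,
       theme_min_frac = theme_min_frac,
       min_theme_members = min_theme_members,
       max_rounds = as.integer(max_rounds), support_tol = support_tol)
}

theme_sets <- function(theme_map, variables = NULL) {
  if (is.null(variables)) variables <- unique(theme_map$variable)
  out <- lapply(variables, function(v)
    unique(theme_map$theme[theme_map$variable == v]))
  names(out) <- variables
  out
}

#' Qualify themes among the selected variables
#'
#' A theme qualifies when at least `min_members` of the selected
#' variables belong to it *and* its selected members number at least
#' `ceiling(min_frac * |selected|)`.
#'
#' @param selected_vars character vector of selected variable names.
#' @param theme_map data.frame with columns `variable`, `theme` (one
#'   row per membership).
#' @param min_frac minimum member share (default 0.05).
#' @param min_members minimum member count (default 2).
#' @return character vector of qualified theme labels (sorted), with a
#'   `counts` attribute of selected-member counts per theme.
#' @export
qualify_themes <- function(selected_vars, theme_map, min_frac = 0.05,
                           min_members = 2) {
  stopifnot(length(selected_vars) > 0)
  sub <- theme_map[theme_map$variable %in% selected_vars, , drop = FALSE]
  counts <- table(unique(sub[c("variable", "theme")])$theme)
  need <- max(min_members, ceiling(min_frac * length(selected_vars)))
  qualified <- sort(names(counts)[counts >= need])
  structure(qualified, counts = counts)
}

#' Dominant theme of a round
#'
#' Walks the ranked selection from the top; the first variable
#' belonging to any qualified theme determines the dominant theme. If
#' that variable sits in several qualified themes, ties break toward
#' the theme with more selected members, then lexicographically.
#'
#' @param ranked_vars selected variable names in coefficient-rank order.
#' @param theme_map membership data.frame (`variable`, `theme`).
#' @param qualified character vector of qualified theme labels.
#' @return the dominant theme label.
#' @export
find_dominant_theme <- function(ranked_vars, theme_map, qualified) {
  if (!length(qualified)) stop("no qualified theme this round")
  sets <- theme_sets(theme_map, ranked_vars)
  sub <- theme_map[theme_map$variable %in% ranked_vars, , drop = FALSE]
  counts <- table(unique(sub[c("variable", "theme")])$theme)
  for (v in ranked_vars) {
    cand <- intersect(sets[[v]], qualified)
    if (length(cand)) {
      cand <- cand[order(-as.numeric(counts[cand]), cand)]
      return(cand[1])
    }
  }
  stop("no selected variable belongs to a qualified theme")
}

#' Exclude the dominant theme
#'
#' Adds `dominant_theme` to the excluded set and removes from the
#' active variables every *coded* variable all of whose themes are now
#' excluded; a variable also belonging to a still-active theme is
#' retained, and uncoded variables are untouched.
#'
#' @param state list with `active` (character variable names) and
#'   `excluded_themes` (character, in exclusion order).
#' @param dominant_theme theme label to exclude.
#' @param theme_map membership data.frame.
#' @return the updated state list.
#' @export
apply_exclusion <- function(state, dominant_theme, theme_map) {
  state$excluded_themes <- c(state$excluded_themes, dominant_theme)
  sets <- theme_sets(theme_map)
  gone <- names(sets)[vapply(sets, function(s)
    length(s) > 0 && all(s %in% state$excluded_themes), logical(1))]
  state$active <- setdiff(state$active, gone)
  state
}

#' Drop newly surfaced variables of previously excluded themes
#'
#' Variables whose (nonempty) theme set is a subset of the already
#' excluded themes are removed before the next refit.
#'
#' @param new_vars candidate variable names.
#' @param excluded_themes character vector of excluded labels.
#' @param theme_map membership data.frame.
#' @return the retained variables (in input order).
#' @export
filter_previously_excluded <- function(new_vars, excluded_themes,
                                       theme_map) {
  if (!length(excluded_themes)) return(new_vars)
  sets <- theme_sets(theme_map, new_vars)
  keep <- vapply(new_vars, function(v) {
    s <- sets[[v]]
    length(s) == 0 || !all(s %in% excluded_themes)
  }, logical(1))
  new_vars[keep]
}

#' Stopping rules
#'
#' Stops when (a) the round's test AUC falls below the floor, (b) no
#' new theme has qualified for three consecutive rounds, (c) the latest
#' selection introduced no previously unseen variable, or the
#' `max_rounds` guard is hit.
#'
#' @param state list with `rounds_without_new_theme`, `n_new_vars`
#'   (new variables in the latest round) and `round`.
#' @param test_auc the round's test AUC.
#' @param auc_floor AUC threshold (default 0.75).
#' @param max_rounds round guard (default 25).
#' @return list with `stop` (logical) and `reason` (or `NULL`).
#' @export
check_stopping <- function(state, test_auc, auc_floor = 0.75,
                           max_rounds = 25) {
  if (is.finite(test_auc) && test_auc < auc_floor)
    return(list(stop = TRUE, reason = "auc_floor"))
  if (state$rounds_without_new_theme >= 3)
    return(list(stop = TRUE, reason = "no_new_themes_3"))
  if (state$n_new_vars == 0)
    return(list(stop = TRUE, reason = "no_new_variables"))
  if (state$round >= max_rounds)
    return(list(stop = TRUE, reason = "max_rounds"))
  list(stop = FALSE, reason = NULL)
}

#' Percent agreement between two coders
#'
#' Share of variables whose full theme set is identical under both
#' codings.
#'
#' @param map_a,map_b membership data.frames (`variable`, `theme`).
#' @param variables variables to compare; each must appear in both maps.
#' @return agreement percentage in \[0, 100\].
#' @export
coder_agreement <- function(map_a, map_b, variables) {
  for (m in list(a = map_a, b = map_b)) {
    un <- setdiff(variables, m$variable)
    if (length(un))
      stop("variables not covered by both coders: ",
           paste(un, collapse = ", "))
  }
  sa <- theme_sets(map_a, variables)
  sb <- theme_sets(map_b, variables)
  same <- vapply(variables, function(v)
    setequal(sa[[v]], sb[[v]]), logical(1))
  100 * mean(same)
}

#' Coding worksheet for uncoded variables
#'
#' Builds (and optionally writes) the worksheet handed to human coders
#' when selected variables lack a theme assignment: one row per
#' variable with its best rank and coefficient on the current curve.
#'
#' @param uncoded_vars variable names requiring coding.
#' @param curve the round's `coef_curve`.
#' @param provenance the encoded matrix's provenance (maps features to
#'   variables); `NULL` when curve features are variables already.
#' @param path optional CSV path to write.
#' @return the worksheet data.frame (`variable`, `rank`, `coefficient`,
#'   `theme` left blank for the coder).
#' @export
request_coding <- function(uncoded_vars, curve, provenance = NULL,
                           path = NULL) {
  var_of <- if (is.null(provenance)) curve$feature else
    provenance$variable[match(curve$feature, provenance$feature)]
  rows <- lapply(uncoded_vars, function(v) {
    i <- which(var_of == v)[1]
    data.frame(variable = v, rank = curve$rank[i],
               coefficient = curve$value[i], theme = "")
  })
  ws <- do.call(rbind, rows)
  if (!is.null(path)) write.csv(ws, path, row.names = FALSE)
  ws
}

#' Ground-truth theme provider
#'
#' Coding oracle for synthetic data: planted variables get their true
#' theme labels; any other variable (including planted redundant
#' copies, which inherit their source's themes) is coded into its own
#' singleton `misc::` label, which can never qualify as a theme.
#'
#' @param ground_truth the `ground_truth` element of
#'   [generate_population()].
#' @return a provider `function(variables)` returning a membership
#'   data.frame.
#' @export
ground_truth_provider <- function(ground_truth) {
  gt_map <- ground_truth$theme_map
  dup <- ground_truth$duplicate_map
  function(variables) {
    rows <- lapply(variables, function(v) {
      src <- if (v %in% names(dup)) dup[[v]] else v
      hit <- gt_map[gt_map$variable == src, , drop = FALSE]
      if (nrow(hit)) data.frame(variable = v, theme = hit$theme)
      else data.frame(variable = v, theme = paste0("misc::", v))
    })
    do.call(rbind, rows)
  }
}

ita_init_state <- function(enc, theme_map, control) {
  split <- make_split(enc$y, control$train_fraction, TRUE,
                      derive_seed(control$seed, 0))
  list(round = 0L,
       active = enc$feature_names,
       excluded_themes = character(0),
       map = theme_map %||%
         data.frame(variable = character(0), theme = character(0)),
       seen_vars = character(0),
       seen_themes = character(0),
       rounds_without_new_theme = 0L,
       history = list(),
       split = split,
       stop_reason = NULL)
}

# one full round; returns list(status, state, worksheet?)
ita_round <- function(enc, state, control, provider) {
  r <- state$round + 1L
  tr <- state$split$train; te <- state$split$test
  act <- match(state$active, enc$feature_names)
  Xtr <- enc$X[tr, act, drop = FALSE]
  ytr <- enc$y[tr]; wtr <- enc$w[tr]
  grid <- default_lambda_grid(Xtr, ytr, wtr, control$nlambda,
                              control$lambda_min_ratio)
  cv_l <- select_lambda_cv(Xtr, ytr, wtr, grid, control$k_folds,
                           derive_seed(control$seed, r, 1), "l1")
  lasso <- fit_penalized_logistic(Xtr, ytr, wtr, cv_l$best_lambda, "l1")
  support <- lasso_support(lasso, control$support_tol)

  rec <- list(round = r, n_active = length(state$active),
              lambda_lasso = cv_l$best_lambda,
              support_size = length(support))

  if (length(support) == 0) {
    # intercept-only model: constant scores, AUC exactly 1/2
    scores_te <- rep(0, length(te))
    thr <- -1
    m <- list(auc = 0.5, auc_unweighted = 0.5, sensitivity = 1,
              specificity = 0, ber = 0.5, ber_unweighted = 0.5,
              threshold = thr)
    rec$empty_support <- TRUE
    rec$metrics <- m
    state$round <- r
    state$history[[r]] <- rec
    chk <- check_stopping(
      list(rounds_without_new_theme = state$rounds_without_new_theme,
           n_new_vars = 1L, round = r),
      m$auc, control$auc_floor, control$max_rounds)
    state$stop_reason <- if (chk$stop) chk$reason else "empty_support"
    return(list(status = "stopped", state = state))
  }

  sidx <- match(support, colnames(Xtr))
  Xs_tr <- Xtr[, sidx, drop = FALSE]
  Xs_te <- enc$X[te, act, drop = FALSE][, sidx, drop = FALSE]
  grid_r <- default_lambda_grid(Xs_tr, ytr, wtr, control$nlambda,
                                control$lambda_min_ratio)
  cv_r <- select_lambda_cv(Xs_tr, ytr, wtr, grid_r, control$k_folds,
                           derive_seed(control$seed, r, 2), "l2")
  ridge <- fit_penalized_logistic(Xs_tr, ytr, wtr, cv_r$best_lambda, "l2")
  sc_tr <- predict(ridge, Xs_tr)
  sc_te <- predict(ridge, Xs_te)
  thr <- choose_threshold(sc_tr, ytr, wtr)
  m <- evaluate_scores(sc_te, enc$y[te], enc$w[te], thr)
  rec$lambda_ridge <- cv_r$best_lambda
  rec$metrics <- m

  curve <- rank_coefficients(ridge)
  knee <- tryCatch(find_knee(curve), error = function(e) e)
  if (inherits(knee, "error")) {
    rec$knee_error <- conditionMessage(knee)
    state$round <- r
    state$history[[r]] <- rec
    state$stop_reason <- if (m$auc < control$auc_floor) "auc_floor"
                         else "no_knee"
    return(list(status = "stopped", state = state))
  }
  rec$knee_rank <- knee$knee_rank
  sel_feat <- select_above_knee(curve, knee)
  sel_vars <- unique(enc$provenance$variable[
    match(sel_feat, enc$provenance$feature)])
  rec$selected_features <- sel_feat

  # theme coding for any not-yet-coded selected variable
  uncoded <- setdiff(sel_vars, state$map$variable)
  if (length(uncoded)) {
    if (is.null(provider)) {
      ws <- request_coding(uncoded, curve, enc$provenance)
      return(list(status = "awaiting_coding", state = state,
                  worksheet = ws))
    }
    coding <- provider(uncoded)
    still <- setdiff(uncoded, coding$variable)
    if (length(still))
      stop("provider left variables uncoded: ",
           paste(still, collapse = ", "))
    state$map <- unique(rbind(state$map, coding))
  }

  kept <- filter_previously_excluded(sel_vars, state$excluded_themes,
                                     state$map)
  dropped <- setdiff(sel_vars, kept)
  if (length(dropped)) {
    drop_feat <- enc$provenance$feature[enc$provenance$variable %in% dropped]
    state$active <- setdiff(state$active, drop_feat)
  }
  rec$selected_vars <- kept
  rec$dropped_previously_excluded <- dropped
  new_vars <- setdiff(kept, state$seen_vars)
  rec$new_vars <- new_vars
  state$seen_vars <- union(state$seen_vars, kept)

  qualified <- if (length(kept))
    as.character(qualify_themes(kept, state$map, control$theme_min_frac,
                                control$min_theme_members))
    else character(0)
  rec$qualified_themes <- qualified
  new_themes <- setdiff(qualified, state$seen_themes)
  state$seen_themes <- union(state$seen_themes, qualified)
  state$rounds_without_new_theme <-
    if (length(new_themes)) 0L else state$rounds_without_new_theme + 1L

  dominant <- NULL
  if (length(qualified)) {
    dominant <- find_dominant_theme(kept, state$map, qualified)
    st2 <- apply_exclusion(
      list(active = unique(enc$provenance$variable[
             match(state$active, enc$provenance$feature)]),
           excluded_themes = state$excluded_themes),
      dominant, state$map)
    state$excluded_themes <- st2$excluded_themes
    keep_feat <- enc$provenance$feature[
      enc$provenance$variable %in% st2$active]
    state$active <- intersect(state$active, keep_feat)
  }
  rec$dominant_theme <- dominant

  state$round <- r
  state$history[[r]] <- rec

  chk <- check_stopping(
    list(rounds_without_new_theme = state$rounds_without_new_theme,
         n_new_vars = length(new_vars), round = r),
    m$auc, control$auc_floor, control$max_rounds)
  if (chk$stop) {
    state$stop_reason <- chk$reason
    return(list(status = "stopped", state = state))
  }
  if (!length(qualified)) {
    state$stop_reason <- "no_qualified_theme"
    return(list(status = "stopped", state = state))
  }
  list(status = "continue", state = state)
}

#' Run the full iterative thematic analysis
#'
#' Per round, on a fixed 80/20 stratified split: (1) lasso with
#' cross-validated penalty on the active features; (2) ridge, again
#' cross-validated, on the lasso support; (3) survey-weighted test
#' AUC/BER; (4) knee-point selection on the ranked ridge coefficients;
#' (5) theme coding, qualification, dominant-theme exclusion (a
#' multi-theme variable leaves only when all its themes are excluded;
#' re-surfacing variables of excluded themes are filtered); (6)
#' stopping check (AUC floor, three theme-less rounds, no new
#' variables, round guard).
#'
#' When selected variables lack a coding and no `provider` is given,
#' the run halts resumably with a coding worksheet; complete it and
#' call [resume_analysis()].
#'
#' @param enc an `encoded_matrix`.
#' @param theme_map optional pre-existing membership data.frame
#'   (`variable`, `theme`).
#' @param provider optional coding oracle `function(variables)`
#'   returning a membership data.frame (see
#'   [ground_truth_provider()]).
#' @param control an [ita_control()] list.
#' @return an `ita_report` (status `"complete"`), or an `ita_run`
#'   awaiting coding (status `"awaiting_coding"` with `$worksheet`).
#' @export
run_iterative_analysis <- function(enc, theme_map = NULL, provider = NULL,
                                   control = ita_control()) {
  stopifnot(inherits(enc, "encoded_matrix"))
  state <- ita_init_state(enc, theme_map, control)
  ita_drive(enc, state, control, provider)
}

ita_drive <- function(enc, state, control, provider) {
  repeat {
    res <- ita_round(enc, state, control, provider)
    if (res$status == "awaiting_coding")
      return(structure(list(status = "awaiting_coding",
                            worksheet = res$worksheet, state = res$state,
                            enc = enc, control = control),
                       class = "ita_run"))
    state <- res$state
    if (res$status == "stopped") break
  }
  ita_assemble_report(state, control)
}

ita_assemble_report <- function(state, control) {
  structure(list(status = "complete",
                 n_rounds = state$round,
                 stop_reason = state$stop_reason,
                 excluded_themes = state$excluded_themes,
                 rounds = state$history,
                 theme_map = state$map,
                 split = list(n_train = length(state$split$train),
                              n_test = length(state$split$test)),
                 control = control),
            class = "ita_report")
}

#' Resume an interrupted run with a completed coding worksheet
#'
#' Re-enters the loop at the interrupted round; because every
#' stochastic step derives its seed from the master seed and round
#' number, the resumed run is identical to an uninterrupted run that
#' had the completed map from the start.
#'
#' @param run an `ita_run` with status `"awaiting_coding"`.
#' @param worksheet the completed worksheet (data.frame or CSV path)
#'   with a nonempty `theme` for every row.
#' @return an `ita_report` (or another awaiting `ita_run`).
#' @export
resume_analysis <- function(run, worksheet) {
  stopifnot(inherits(run, "ita_run"), run$status == "awaiting_coding")
  if (is.character(worksheet)) worksheet <- read.csv(worksheet)
  blank <- worksheet$variable[is.na(worksheet$theme) |
                                !nzchar(trimws(worksheet$theme))]
  if (length(blank))
    stop("worksheet rows left unassigned: ", paste(blank, collapse = ", "))
  state <- run$state
  state$map <- unique(rbind(state$map,
                            worksheet[c("variable", "theme")]))
  ita_drive(run$enc, state, run$control, provider = NULL)
}

#' @export
print.ita_report <- function(x, ...) {
  cat("<ita_report> ", x$n_rounds, " round(s); stop: ", x$stop_reason,
      "\n  excluded themes: ",
      if (length(x$excluded_themes))
        paste(x$excluded_themes, collapse = " > ") else "(none)",
      "\n", sep = "")
  for (r in x$rounds)
    cat(sprintf("  round %d: support %d, knee %s, AUC %.3f, BER %.3f\n",
                r$round, r$support_size %||% 0L,
                as.character(r$knee_rank %||% NA),
                r$metrics$auc, r$metrics$ber))
  invisible(x)
}

#' @export
print.ita_run <- function(x, ...) {
  cat("<ita_run> awaiting coding of", nrow(x$worksheet),
      "variable(s); complete $worksheet and call resume_analysis()\n")
  invisible(x)
}
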