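map_of <- function(...) {
  pairs <- list(...)
  do.call(rbind, lapply(names(pairs), function(v)
    data.frame(variable = v, theme = pairs[[v]])))
}

test_that("theme qualification enforces both the >=2 and the 5% rule", {
  # 40 selected, 2-member theme: ceil(0.05*40)=2 -> qualifies
  sel40 <- sprintf("v%02d", 1:40)
  map <- map_of(v01 = "t", v02 = "t")
  expect_equal(as.character(qualify_themes(sel40, map)), "t")
  # 100 selected, 4-member theme: ceil(5)=5 -> fails
  sel100 <- sprintf("v%03d", 1:100)
  map4 <- do.call(rbind, lapply(sprintf("v%03d", 1:4), function(v)
    data.frame(variable = v, theme = "t")))
  expect_length(qualify_themes(sel100, map4), 0)
  # 10 selected, 1-member theme: fails the >=2 rule regardless of 5%
  sel10 <- sprintf("v%02d", 1:10)
  expect_length(qualify_themes(sel10, map_of(v01 = "t")), 0)
  # boundary sweep: exhaustive over selection sizes 20..60 for a
  # 2-member theme (needs ceil(0.05 n) <= 2, i.e. n <= 40)
  for (n in c(20, 40, 41, 60)) {
    sel <- sprintf("v%02d", seq_len(n))
    q <- qualify_themes(sel, map)
    if (n <= 40) expect_equal(as.character(q), "t")
    else expect_length(q, 0)
  }
})

test_that("dominant theme follows the ranked walk-down and tie-breaks", {
  map <- rbind(map_of(top = "violence"),
               map_of(v1 = "violence", v2 = "violence"),
               map_of(d1 = "diet", d2 = "diet"))
  # top-ranked variable's qualified theme wins
  expect_equal(find_dominant_theme(c("top", "d1", "d2", "v1"), map,
                                   c("violence", "diet")), "violence")
  # unthemed top: walk down to the first coded variable
  expect_equal(find_dominant_theme(c("zz", "d1", "v1", "top"), map,
                                   c("violence", "diet")), "diet")
  # multi-theme top variable: larger qualified theme wins
  map2 <- rbind(map_of(x = c("big", "small")),
                do.call(rbind, lapply(sprintf("b%d", 1:5), function(v)
                  data.frame(variable = v, theme = "big"))),
                map_of(s1 = "small", s2 = "small"))
  sel <- c("x", sprintf("b%d", 1:5), "s1", "s2")
  expect_equal(find_dominant_theme(sel, map2, c("big", "small")), "big")
  # equal counts: lexicographic
  map3 <- rbind(map_of(x = c("bb", "aa")),
                map_of(p = "aa", q = "bb"))
  expect_equal(find_dominant_theme(c("x", "p", "q"), map3, c("aa", "bb")),
               "aa")
  expect_error(find_dominant_theme("x", map3, character(0)), "no qualified")
})

test_that("exclusion removes a variable only when all its themes are excluded", {
  map <- rbind(map_of(a = "violence"),
               map_of(b = c("violence", "health")),
               map_of(c = "health"))
  st <- list(active = c("a", "b", "c", "unthemed"),
             excluded_themes = character(0))
  st <- apply_exclusion(st, "violence", map)
  expect_setequal(st$active, c("b", "c", "unthemed"))  # b retained via health
  expect_equal(st$excluded_themes, "violence")
  st <- apply_exclusion(st, "health", map)
  expect_setequal(st$active, "unthemed")
  expect_equal(st$excluded_themes, c("violence", "health"))
})

test_that("re-surfacing variables of previously excluded themes are filtered", {
  map <- rbind(map_of(n1 = "substance"),
               map_of(n2 = c("substance", "diet")),
               map_of(n3 = "diet"))
  expect_equal(filter_previously_excluded(c("n1", "n2", "n3"),
                                          "substance", map),
               c("n2", "n3"))
  expect_equal(filter_previously_excluded(c("n1", "n2"),
                                          c("substance", "diet"), map),
               character(0))
  # no exclusions yet: identity (including uncoded variables)
  expect_equal(filter_previously_excluded(c("n1", "zz"), character(0), map),
               c("n1", "zz"))
})

test_that("stopping rules fire at the stated boundaries", {
  st <- function(rwnt = 0, nnew = 3, round = 1)
    list(rounds_without_new_theme = rwnt, n_new_vars = nnew, round = round)
  expect_equal(check_stopping(st(), 0.74)$reason, "auc_floor")
  expect_false(check_stopping(st(), 0.75)$stop)
  expect_equal(check_stopping(st(rwnt = 3), 0.78)$reason, "no_new_themes_3")
  expect_false(check_stopping(st(rwnt = 2), 0.78)$stop)
  expect_equal(check_stopping(st(nnew = 0), 0.80)$reason,
               "no_new_variables")
  expect_equal(check_stopping(st(round = 25), 0.9,
                              max_rounds = 25)$reason, "max_rounds")
  expect_false(check_stopping(st(), 0.80)$stop)
  # precedence: AUC floor reported first
  expect_equal(check_stopping(st(rwnt = 3, nnew = 0), 0.5)$reason,
               "auc_floor")
})

test_that("coder agreement is the share of identical theme sets", {
  a <- rbind(map_of(v1 = "x", v2 = "y"),
             do.call(rbind, lapply(sprintf("u%02d", 1:18), function(v)
               data.frame(variable = v, theme = "z"))))
  b <- a
  vars <- c("v1", "v2", sprintf("u%02d", 1:18))
  expect_equal(coder_agreement(a, b, vars), 100)
  b$theme[b$variable == "v1"] <- "w"
  expect_equal(coder_agreement(a, b, vars), 95)
  b$theme <- "other"
  expect_equal(coder_agreement(a, b, vars), 0)
  expect_error(coder_agreement(a, b, c(vars, "ghost")), "ghost")
})

test_that("full synthetic run recovers the strongest theme first and shrinks monotonically", {
  pop <- generate_population(small_config(seed = 21, n = 4000))
  enc <- encode_survey(pop$table, pop$dictionary)
  rep <- run_iterative_analysis(
    enc, provider = ground_truth_provider(pop$ground_truth),
    control = ita_control(seed = 21, nlambda = 20, lambda_min_ratio = 1e-2))
  expect_s3_class(rep, "ita_report")
  expect_equal(rep$rounds[[1]]$dominant_theme, "alpha")
  expect_gte(rep$rounds[[1]]$metrics$auc, 0.75)
  # active feature count never grows
  n_active <- vapply(rep$rounds, function(r) r$n_active, numeric(1))
  expect_true(all(diff(n_active) <= 0))
  # a later round never selects a variable whose every theme was
  # already excluded before that round began
  sets <- split(rep$theme_map$theme, rep$theme_map$variable)
  if (rep$n_rounds >= 2) {
    for (r in 2:rep$n_rounds) {
      excl_before <- unlist(lapply(rep$rounds[1:(r - 1)],
                                   function(x) x$dominant_theme))
      for (v in rep$rounds[[r]]$selected_vars)
        expect_false(all(sets[[v]] %in% excl_before))
    }
  }
  # report is reproducible bit-for-bit
  rep2 <- run_iterative_analysis(
    enc, provider = ground_truth_provider(pop$ground_truth),
    control = ita_control(seed = 21, nlambda = 20, lambda_min_ratio = 1e-2))
  expect_identical(rep, rep2)
})

test_that("a coding interruption resumes to the identical report", {
  pop <- generate_population(small_config(seed = 23, n = 3000))
  enc <- encode_survey(pop$table, pop$dictionary)
  ctrl <- ita_control(seed = 5, nlambda = 15, lambda_min_ratio = 1e-2)
  provider <- ground_truth_provider(pop$ground_truth)
  full <- run_iterative_analysis(enc, provider = provider, control = ctrl)
  # interactive path: no provider -> worksheet; fill it from the oracle
  run <- run_iterative_analysis(enc, control = ctrl)
  expect_s3_class(run, "ita_run")
  expect_equal(run$status, "awaiting_coding")
  expect_true(all(c("variable", "rank", "coefficient", "theme") %in%
                    colnames(run$worksheet)))
  resumed <- run
  while (inherits(resumed, "ita_run")) {
    ws <- resumed$worksheet
    coded <- provider(ws$variable)
    # collapse multi-membership into a worksheet row per membership
    ws <- merge(ws[c("variable", "rank", "coefficient")], coded,
                by = "variable")
    resumed <- resume_analysis(resumed, ws)
  }
  expect_identical(resumed$rounds, full$rounds)
  expect_identical(resumed$stop_reason, full$stop_reason)
  # unassigned worksheet rows are rejected by name
  run2 <- run_iterative_analysis(enc, control = ctrl)
  bad <- run2$worksheet
  bad$theme <- ""
  expect_error(resume_analysis(run2, bad), "unassigned")
})

test_that("worksheet requests cover exactly the uncoded variables", {
  curve <- coefficient_curve(c(0.9, 0.5, 0.3, 0.2, 0.1),
                             c("a", "b", "c", "d", "e"))
  ws <- request_coding(c("b", "d"), curve)
  expect_equal(ws$variable, c("b", "d"))
  expect_equal(ws$rank, c(2, 4))
  expect_equal(ws$coefficient, c(0.5, 0.2))
})
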