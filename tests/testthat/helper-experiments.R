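# Multi-seed recovery experiments at the study scale (n = 20 000,
# ~500 encoded features, three planted themes, prevalence 0.057).
# Computed lazily once per test run and shared across test files.

.experiment_cache <- new.env(parent = emptyenv())

experiment_control <- function(seed)
  ita_control(seed = seed, nlambda = 30, lambda_min_ratio = 1e-3)

experiment_nn_config <- function(seed)
  nn_config(epochs = 40, batch_size = 512, early_stop_patience = 10,
            seed = seed)

# variables planted with |log-odds| >= 0.5
strong_planted_vars <- function()
  c(sprintf("cont_%02d", 1:9), sprintf("bin_%02d", 1:5))

magnitude_order <- c("violence_exposure", "sexual_behaviour",
                     "health_access")

run_recovery_seed <- function(seed) {
  pop <- generate_population(synthetic_config(seed = seed))
  enc <- encode_survey(pop$table, pop$dictionary)
  planted <- names(pop$ground_truth$true_effects)
  ctrl <- experiment_control(seed)
  rep <- run_iterative_analysis(
    enc, provider = ground_truth_provider(pop$ground_truth),
    control = ctrl)
  r1 <- rep$rounds[[1]]
  strong <- strong_planted_vars()
  nnr <- nn_pipeline(enc, control = ctrl,
                     config = experiment_nn_config(seed))
  v <- enc$provenance$variable[match(nnr$importance$feature,
                                     enc$provenance$feature)]
  imp_planted <- nnr$importance$value[v %in% planted]
  imp_null <- nnr$importance$value[!v %in% planted]
  list(
    seed = seed,
    dominant1 = r1$dominant_theme,
    excluded = rep$excluded_themes,
    recall1 = length(intersect(r1$selected_vars, strong)) / length(strong),
    auc1 = r1$metrics$auc,
    ber1 = r1$metrics$ber,
    stop = rep$stop_reason,
    nn_p = stats::wilcox.test(imp_planted, imp_null,
                              alternative = "greater")$p.value,
    nn_median_gap = stats::median(imp_planted) - stats::median(imp_null),
    nn_prefix_ok = identical(
      nnr$selected_features,
      nnr$importance$feature[seq_len(nnr$knee_rank)]),
    nn_auc = nnr$metrics$auc,
    nn_ber = nnr$metrics$ber)
}

recovery_experiment <- function(n_seeds = 20) {
  key <- paste0("recovery", n_seeds)
  if (is.null(.experiment_cache[[key]]))
    .experiment_cache[[key]] <- lapply(seq_len(n_seeds), run_recovery_seed)
  .experiment_cache[[key]]
}

null_themes <- function()
  list(theme_spec("alpha", c("cont_01", "cont_02"), c(0, 0)),
       theme_spec("beta", c("cont_03", "cont_04"), c(0, 0)))

run_null_seed <- function(seed) {
  cfg <- synthetic_config(themes = null_themes(), n_duplicate_pairs = 0,
                          seed = seed)
  pop <- generate_population(cfg)
  enc <- encode_survey(pop$table, pop$dictionary)
  rep <- run_iterative_analysis(
    enc, provider = ground_truth_provider(pop$ground_truth),
    control = experiment_control(seed))
  list(seed = seed, stop = rep$stop_reason, n_rounds = rep$n_rounds,
       auc1 = rep$rounds[[1]]$metrics$auc)
}

null_experiment <- function(n_seeds = 20) {
  key <- paste0("null", n_seeds)
  if (is.null(.experiment_cache[[key]]))
    .experiment_cache[[key]] <- lapply(seq_len(n_seeds), run_null_seed)
  .experiment_cache[[key]]
}
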