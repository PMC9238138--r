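#' Study drivers: canned synthetic-cohort experiments
#'
#' These functions tie the generator, label construction, evaluation and
#' statistics together into the benchmark's standard study designs. Their
#' defaults are the study conditions (cohort size 2000, three cancer types,
#' planted effect size 2 over 20 features at prevalence 0.25, a reduced
#' 3 x 3 hyperparameter grid for the simulation studies); the methods
#' vignette discusses the choices.
#'
#' @name studies
NULL

reduced_grids <- function() {
  list(alpha = c(0.001, 0.1, 10), l1_ratio = c(0.05, 0.5, 1))
}

study_modalities <- function(p = 100) {
  list(modality_spec("expression", kind = "continuous", n_features = p),
       modality_spec("me_27k", kind = "bounded01", n_features = p))
}

#' Null-calibration study: many genes with no planted signal
#'
#' Simulates a cohort and `n_genes` null genes (mutation prevalence but no
#' -omics signature), runs the full benchmark for each against the
#' permuted-label baseline, and reports the fraction of genes called
#' significant at BH-corrected p < 0.05. Under a calibrated null this
#' fraction is small.
#'
#' @param n_genes number of null genes (default 50).
#' @param n cohort size (default 2000).
#' @param prevalence per-type mutation probability (default 0.25).
#' @param seed master seed.
#' @param grids hyperparameter grids (default: reduced 3 x 3).
#' @return list: `fraction_significant`, `calls`, `results`.
#' @export
study_null_calibration <- function(n_genes = 50, n = 2000, prevalence = 0.25,
                                   seed = 1, grids = reduced_grids()) {
  types <- c("LUAD", "BRCA", "COAD")
  genes <- lapply(seq_len(n_genes), function(i) {
    gene_spec(sprintf("NULL%03d", i), role = "oncogene",
              per_type_mutation_prob = stats::setNames(rep(prevalence, 3),
                                                       types))
  })
  bundle <- simulate_study(cohort_spec(n_samples = n,
                                       seed = child_seed(seed, "cohort")),
                           genes, study_modalities()[1],
                           seed = child_seed(seed, "bundle"))
  cfg <- default_config(grids = grids, seed = child_seed(seed, "runs"))
  results <- do.call(rbind, lapply(genes, function(g) {
    run_gene_experiment(g$gene, "expression", bundle, cfg)
  }))
  calls <- baseline_comparison(results, corrected_p = 0.001)
  list(fraction_significant = mean(calls$q_value < 0.05),
       calls = calls, results = results)
}

#' Power and modality-specificity study: planted single-modality signals
#'
#' Plants `n_per_modality` genes with an expression-only signature and the
#' same number with a methylation-only signature (effect size 2 over 20
#' features, prevalence 0.25), runs every gene against both modalities, and
#' reports (1) the fraction of genes well-predicted (BH-corrected p < 0.001
#' with positive mean delta AUPR) in their planted modality and (2) the
#' fraction whose planted-modality mean delta AUPR exceeds the unplanted
#' modality's.
#'
#' @param n_per_modality planted genes per modality (default 10).
#' @param n cohort size (default 2000).
#' @param effect_size planted standardized shift (default 2).
#' @param n_signal_features planted features per gene (default 20).
#' @param prevalence per-type mutation probability (default 0.25).
#' @param seed master seed.
#' @param grids hyperparameter grids (default: reduced 3 x 3).
#' @return list: `power_fraction`, `specificity_fraction`, `calls`,
#'   `planted_modality` (named vector), `results`.
#' @export
study_power_specificity <- function(n_per_modality = 10, n = 2000,
                                    effect_size = 2, n_signal_features = 20,
                                    prevalence = 0.25, seed = 1,
                                    grids = reduced_grids()) {
  types <- c("LUAD", "BRCA", "COAD")
  pt <- stats::setNames(rep(prevalence, 3), types)
  mk <- function(i, modality) {
    gene_spec(sprintf("%s%03d", toupper(substr(modality, 1, 2)), i),
              role = "oncogene", per_type_mutation_prob = pt,
              signal_modalities = modality, effect_size = effect_size,
              n_signal_features = n_signal_features)
  }
  genes <- c(lapply(seq_len(n_per_modality), mk, modality = "expression"),
             lapply(seq_len(n_per_modality), mk, modality = "me_27k"))
  planted <- stats::setNames(
    rep(c("expression", "me_27k"), each = n_per_modality),
    vapply(genes, `[[`, "", "gene"))
  bundle <- simulate_study(cohort_spec(n_samples = n,
                                       seed = child_seed(seed, "cohort")),
                           genes, study_modalities(),
                           seed = child_seed(seed, "bundle"))
  cfg <- default_config(grids = grids, seed = child_seed(seed, "runs"))
  results <- do.call(rbind, lapply(names(planted), function(g) {
    rbind(run_gene_experiment(g, "expression", bundle, cfg),
          run_gene_experiment(g, "me_27k", bundle, cfg))
  }))
  calls <- baseline_comparison(results, corrected_p = 0.001)
  hit <- vapply(names(planted), function(g) {
    row <- calls[calls$gene == g & calls$modality_set == planted[g], ]
    nrow(row) == 1 && row$well_predicted
  }, TRUE)
  specific <- vapply(names(planted), function(g) {
    own <- calls$mean_delta_aupr[calls$gene == g &
                                   calls$modality_set == planted[g]]
    other <- calls$mean_delta_aupr[calls$gene == g &
                                     calls$modality_set != planted[g]]
    length(own) == 1 && all(own > other)
  }, TRUE)
  list(power_fraction = mean(hit), specificity_fraction = mean(specific),
       calls = calls, planted_modality = planted, results = results)
}

#' Redundancy study: one latent signal driving two modalities
#'
#' For each seed, plants a single gene whose mutation signature appears in
#' both the expression-like and methylation-like modality, evaluates each
#' single-modality model and the concatenated multi-omics model, and tests
#' whether the multi-omics model significantly outperforms the best single
#' modality (paired fold-wise t-test). With redundant signal it rarely
#' should.
#'
#' @param n_seeds number of independent simulated studies (default 10).
#' @param n cohort size (default 2000).
#' @param effect_size,n_signal_features,prevalence planted-signal settings.
#' @param seed master seed.
#' @param grids hyperparameter grids (default: reduced 3 x 3).
#' @return list: `significant_gain` (logical per seed),
#'   `fraction_significant_gain`, `details` (per-seed data.frame).
#' @export
study_redundancy <- function(n_seeds = 10, n = 2000, effect_size = 2,
                             n_signal_features = 20, prevalence = 0.25,
                             seed = 1, grids = reduced_grids()) {
  types <- c("LUAD", "BRCA", "COAD")
  pt <- stats::setNames(rep(prevalence, 3), types)
  details <- list()
  for (s in seq_len(n_seeds)) {
    g <- gene_spec("DUAL", role = "oncogene", per_type_mutation_prob = pt,
                   signal_modalities = c("expression", "me_27k"),
                   effect_size = effect_size,
                   n_signal_features = n_signal_features)
    bundle <- simulate_study(
      cohort_spec(n_samples = n, seed = child_seed(seed, "cohort", s)),
      list(g), study_modalities(), seed = child_seed(seed, "bundle", s))
    cfg <- default_config(grids = grids, seed = child_seed(seed, "runs", s))
    res <- rbind(run_gene_experiment("DUAL", "expression", bundle, cfg),
                 run_gene_experiment("DUAL", "me_27k", bundle, cfg),
                 run_gene_experiment("DUAL", c("expression", "me_27k"),
                                     bundle, cfg))
    true <- res[res$condition == "true_labels", ]
    singles <- c("expression", "me_27k")
    mean_aupr <- tapply(true$aupr, true$modality_set, mean)
    best_single <- singles[which.max(mean_aupr[singles])]
    tt <- paired_delta_test(
      true[true$modality_set == "expression+me_27k", ],
      true[true$modality_set == best_single, ])
    details[[s]] <- data.frame(
      seed = s, best_single = best_single,
      best_single_aupr = unname(mean_aupr[best_single]),
      multi_aupr = unname(mean_aupr["expression+me_27k"]),
      delta = tt$mean_delta, p_value = tt$p_value,
      significant_gain = tt$p_value < 0.05 && tt$mean_delta > 0,
      stringsAsFactors = FALSE)
  }
  details <- do.call(rbind, details)
  list(significant_gain = details$significant_gain,
       fraction_significant_gain = mean(details$significant_gain),
       details = details)
}

#' Survival study: planted proportional-hazards signal in the latent factors
#'
#' Simulates survival with hazard driven by age, mutation burden and the
#' cohort latent factors the -omics matrix loads on, then compares the
#' cross-validated c-index of the elastic-net Cox model on `k`
#' principal components + covariates against the covariate-only baseline,
#' and checks that an unpenalized covariate-only fit recovers the planted
#' age and burden coefficient signs.
#'
#' @param n cohort size (default 2000).
#' @param k number of principal components (default 10).
#' @param coefficients planted hazard coefficients (age, burden, factors).
#' @param censoring_rate target censored fraction (default 0.4).
#' @param seed master seed.
#' @param grids Cox hyperparameter grids (default: a reduced grid).
#' @return list: `gain` (mean omics c-index minus mean baseline c-index),
#'   `baseline_cindex`, `omics_cindex`, `age_sign_correct`,
#'   `burden_sign_correct`, `records`.
#' @export
study_survival_gain <- function(n = 2000, k = 10,
                                coefficients = list(age = 0.03, burden = 0.5,
                                                    factors = c(0.8, -0.8,
                                                                0.5, 0, 0)),
                                censoring_rate = 0.4, seed = 1,
                                grids = list(alpha = c(1e-4, 0.01, 0.1, 1),
                                             l1_ratio = c(0, 0.5))) {
  types <- c("LUAD", "BRCA", "COAD")
  g <- gene_spec("G0", role = "oncogene",
                 per_type_mutation_prob = stats::setNames(rep(0.2, 3), types))
  bundle <- simulate_study(cohort_spec(n_samples = n,
                                       seed = child_seed(seed, "cohort")),
                           list(g), study_modalities()[1],
                           seed = child_seed(seed, "bundle"),
                           survival_coefficients = coefficients,
                           censoring_rate = censoring_rate)
  cfg <- default_config(survival_grids = grids,
                        seed = child_seed(seed, "runs"))
  records <- run_survival_experiment(bundle, "expression", k_values = k,
                                     config = cfg)
  base <- mean(records$cindex[records$model == "covariates_only"])
  omics <- mean(records$cindex[records$model == "expression"])

  # sign recovery from a near-unpenalized covariate-only fit
  surv <- select_endpoint(bundle, cfg$pfi_cancer_types)
  clin <- bundle$clinical
  excl <- detect_hypermutated(stats::setNames(clin$burden, clin$sample_id))
  inc <- setdiff(clin$sample_id, excl)
  cov <- build_covariates(clin, inc, include_age = TRUE)
  fit <- fit_elastic_net_cox(standardize(cov)$matrix,
                             surv[inc, "time"], surv[inc, "event"],
                             enet_hp(1e-4, 0))
  list(gain = omics - base, baseline_cindex = base, omics_cindex = omics,
       age_sign_correct = (unname(fit$weights["age"]) > 0) ==
         (coefficients$age > 0),
       burden_sign_correct = (unname(fit$weights["log10_burden"]) > 0) ==
         (coefficients$burden > 0),
       records = records)
}
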