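# Shared fixture builders. Everything is generated in code; sizes are kept
# small so the unit suite stays fast.

small_cohort_spec <- function(n = 400, seed = 101, ...) {
  cohort_spec(n_samples = n, seed = seed, ...)
}

planted_gene <- function(gene = "G1", modality = "expression",
                         prevalence = 0.25, effect = 2, n_signal = 20,
                         types = c("LUAD", "BRCA", "COAD"), role = "oncogene") {
  gene_spec(gene, role = role,
            per_type_mutation_prob = stats::setNames(rep(prevalence,
                                                         length(types)), types),
            signal_modalities = modality, effect_size = effect,
            n_signal_features = n_signal)
}

null_gene <- function(gene = "N1", prevalence = 0.25,
                      types = c("LUAD", "BRCA", "COAD")) {
  gene_spec(gene, role = "oncogene",
            per_type_mutation_prob = stats::setNames(rep(prevalence,
                                                         length(types)), types))
}

small_bundle <- function(n = 400, seed = 101, genes = NULL, p = 60,
                         with_methylation = FALSE, with_survival = FALSE,
                         survival_coefficients = list(age = 0.03, burden = 0.5,
                                                      factors = c(0.8, -0.8,
                                                                  0.5, 0, 0))) {
  if (is.null(genes)) {
    genes <- list(planted_gene(n_signal = min(20, p %/% 2)), null_gene())
  }
  modalities <- list(modality_spec("expression", n_features = p))
  if (with_methylation) {
    modalities <- c(modalities,
                    list(modality_spec("me_27k", kind = "bounded01",
                                       n_features = p)))
  }
  simulate_study(small_cohort_spec(n, seed), genes, modalities, seed = seed,
                 survival_coefficients = if (with_survival)
                   survival_coefficients else NULL)
}

fast_config <- function(...) {
  default_config(grids = list(alpha = c(0.001, 0.1, 1),
                              l1_ratio = c(0.1, 0.5, 1)), ...)
}

# Brute-force metric oracles, independent of the package implementation.

oracle_average_precision <- function(scores, labels) {
  n_pos <- sum(labels == 1)
  thresholds <- sort(unique(scores), decreasing = TRUE)
  ap <- 0
  prev_recall <- 0
  for (t in thresholds) {
    called <- scores >= t
    tp <- sum(labels[called] == 1)
    precision <- tp / sum(called)
    recall <- tp / n_pos
    ap <- ap + (recall - prev_recall) * precision
    prev_recall <- recall
  }
  ap
}

oracle_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

oracle_cindex <- function(scores, times, events) {
  conc <- 0; n_pairs <- 0
  n <- length(scores)
  for (i in seq_len(n)) {
    if (events[i] != 1) next
    for (j in seq_len(n)) {
      if (times[j] <= times[i]) next
      n_pairs <- n_pairs + 1
      if (scores[i] > scores[j]) conc <- conc + 1
      else if (scores[i] == scores[j]) conc <- conc + 0.5
    }
  }
  conc / n_pairs
}
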