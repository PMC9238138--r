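#!/usr/bin/env Rscript
# Simulate the synthetic multi-omics study cohort used by the downstream
# analysis steps and write it out as delimited tables.
#
# The cohort emulates the structure the benchmark assumes: three cancer
# types with distinct baseline profiles, a log-normal non-silent mutation
# burden with a hypermutated tail, two -omics readouts (a continuous
# expression-like matrix and a bounded methylation-like matrix with
# missingness), driver genes with planted modality-specific mutation
# signatures plus null control genes, CNV gains/losses tied to driver
# roles, and proportional-hazards survival with OS and PFI endpoints.

suppressMessages(library(omicbench))

seed <- 20260920L
out_dir <- "results/bundle"

types <- c(LUAD = 0.4, BRCA = 0.35, COAD = 0.25)
pt <- function(p) setNames(rep(p, 3), names(types))

genes <- list(
  # expression-signature drivers
  gene_spec("EXP1", role = "oncogene", per_type_mutation_prob = pt(0.25),
            cnv_gain_prob = 0.05, signal_modalities = "expression",
            effect_size = 2, n_signal_features = 20),
  gene_spec("EXP2", role = "tsg", per_type_mutation_prob = pt(0.2),
            cnv_loss_prob = 0.05, signal_modalities = "expression",
            effect_size = 1.5, n_signal_features = 20),
  # methylation-signature driver
  gene_spec("MET1", role = "tsg", per_type_mutation_prob = pt(0.25),
            cnv_loss_prob = 0.05, signal_modalities = "me_27k",
            effect_size = 2, n_signal_features = 20),
  # redundant dual-modality driver
  gene_spec("DUAL1", role = "both", per_type_mutation_prob = pt(0.25),
            cnv_gain_prob = 0.03, cnv_loss_prob = 0.03,
            signal_modalities = c("expression", "me_27k"),
            effect_size = 2, n_signal_features = 20),
  # null controls: mutated but with no -omics signature
  gene_spec("NULL1", role = "oncogene", per_type_mutation_prob = pt(0.25)),
  gene_spec("NULL2", role = "oncogene", per_type_mutation_prob = pt(0.25)),
  # too rare to pass the valid-cancer-type filter anywhere
  gene_spec("RARE1", role = "oncogene", per_type_mutation_prob = pt(0.01))
)

modalities <- list(
  modality_spec("expression", kind = "continuous", n_features = 100),
  # keep the per-probe expected missing count ~1 so the 1-or-2-missing
  # mean-imputation rule applies to most affected probes instead of the
  # >= 3-missing drop rule deleting them wholesale
  modality_spec("me_27k", kind = "bounded01", n_features = 100,
                missing_rate = 5e-4, n_high_missing_samples = 5)
)

bundle <- simulate_study(
  cohort_spec(n_samples = 2000, cancer_types = types, seed = seed),
  genes, modalities, seed = seed,
  survival_coefficients = list(age = 0.03, burden = 0.5,
                               factors = c(0.8, -0.8, 0.5, 0, 0)),
  censoring_rate = 0.4)

write_bundle(bundle, out_dir)

clin <- bundle$clinical
cat("Simulated cohort:", nrow(clin), "samples\n")
print(table(clin$cancer_type))
cat("hypermutated flag:", sum(clin$hypermutated), "samples\n")
cat("burden median:", median(clin$burden),
    " max:", max(clin$burden), "\n")
cat("OS event fraction:", round(mean(bundle$survival$OS$event), 3), "\n")
cat("wrote", out_dir, "\n")
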