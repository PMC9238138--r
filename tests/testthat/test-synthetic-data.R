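test_that("cohort generation is deterministic and respects degenerate proportions", {
  spec <- cohort_spec(n_samples = 100, cancer_types = c(LUAD = 1),
                      sample_types = c(primary = 1), seed = 5)
  cohort <- generate_cohort(spec)
  expect_equal(nrow(cohort$clinical), 100)
  expect_true(all(cohort$clinical$cancer_type == "LUAD"))
  cohort2 <- generate_cohort(spec)
  expect_identical(cohort, cohort2)
  # different seed differs
  cohort3 <- generate_cohort(cohort_spec(n_samples = 100,
                                         cancer_types = c(LUAD = 1),
                                         sample_types = c(primary = 1),
                                         seed = 6))
  expect_false(identical(cohort$clinical$burden, cohort3$clinical$burden))
})

test_that("cohort proportions concentrate at large n", {
  spec <- cohort_spec(n_samples = 10000,
                      cancer_types = c(A = 0.5, B = 0.3, C = 0.2), seed = 7)
  cohort <- generate_cohort(spec)
  emp <- table(cohort$clinical$cancer_type) / 10000
  expect_true(all(abs(emp[c("A", "B", "C")] - c(0.5, 0.3, 0.2)) < 0.02))
  expect_true(all(cohort$clinical$age >= 18 & cohort$clinical$age <= 100))
  expect_equal(sum(cohort$clinical$hypermutated), round(10000 * 0.02))
})

test_that("invalid cohort specs raise errors naming the offending field", {
  expect_error(cohort_spec(cancer_types = c(A = 0.6, B = 0.6)),
               "cancer_types")
  expect_error(cohort_spec(sample_types = c(0.5, 0.5)), "sample_types")
  expect_error(cohort_spec(hypermutated_fraction = 0.5),
               "hypermutated_fraction")
  expect_error(cohort_spec(n_samples = 0), "n_samples")
})

test_that("mutation data: null genes, prevalence concentration, seed contract", {
  spec <- cohort_spec(n_samples = 5000, cancer_types = c(LUAD = 1),
                      sample_types = c(primary = 1),
                      hypermutated_fraction = 0, seed = 11)
  cohort <- generate_cohort(spec)
  genes <- list(
    gene_spec("ZERO", per_type_mutation_prob = c(LUAD = 0)),
    gene_spec("G30", per_type_mutation_prob = c(LUAD = 0.3))
  )
  md <- generate_mutation_data(cohort, genes, seed = 1)
  expect_true(all(md$mutation[, "ZERO"] == 0))
  expect_true(all(md$cnv[, "ZERO"] == 0))
  expect_lt(abs(mean(md$mutation[, "G30"]) - 0.3), 0.02)
  md2 <- generate_mutation_data(cohort, genes, seed = 2)
  expect_false(identical(md$mutation[, "G30"], md2$mutation[, "G30"]))
})

test_that("mutation data rejects genes naming unknown cancer types", {
  cohort <- generate_cohort(small_cohort_spec(50))
  bad <- list(gene_spec("G", per_type_mutation_prob = c(NOPE = 0.5)))
  expect_error(generate_mutation_data(cohort, bad, seed = 1), "NOPE")
})

test_that("hypermutated samples have elevated genome-wide mutation rates", {
  spec <- cohort_spec(n_samples = 4000, cancer_types = c(LUAD = 1),
                      sample_types = c(primary = 1),
                      hypermutated_fraction = 0.1, seed = 13)
  cohort <- generate_cohort(spec)
  genes <- list(gene_spec("G", per_type_mutation_prob = c(LUAD = 0.05)))
  md <- generate_mutation_data(cohort, genes, seed = 3)
  hyper <- cohort$clinical$hypermutated
  expect_gt(mean(md$mutation[hyper, "G"]), 2 * mean(md$mutation[!hyper, "G"]))
})

test_that("omics: null genes leave group means equal, planted shifts recover", {
  spec <- cohort_spec(n_samples = 5000, cancer_types = c(LUAD = 1),
                      sample_types = c(primary = 1),
                      hypermutated_fraction = 0, seed = 17)
  cohort <- generate_cohort(spec)
  genes <- list(gene_spec("NULLG", per_type_mutation_prob = c(LUAD = 0.5)))
  md <- generate_mutation_data(cohort, genes, seed = 1)
  mod <- modality_spec("expression", n_features = 20)
  om <- generate_omics(cohort, md$mutation, mod, genes, seed = 1)
  mut <- md$mutation[, "NULLG"] == 1
  d <- abs(colMeans(om$matrix[mut, ]) - colMeans(om$matrix[!mut, ])) /
    apply(om$matrix, 2, sd)
  expect_true(all(d < 0.1)) # null: no feature shows a standardized shift

  planted <- list(gene_spec("SIG", per_type_mutation_prob = c(LUAD = 0.5),
                            signal_modalities = "expression",
                            effect_size = 2, n_signal_features = 50))
  md2 <- generate_mutation_data(cohort, planted, seed = 2)
  spec2k <- cohort_spec(n_samples = 2000, cancer_types = c(LUAD = 1),
                        sample_types = c(primary = 1),
                        hypermutated_fraction = 0, seed = 19)
  c2k <- generate_cohort(spec2k)
  md2 <- generate_mutation_data(c2k, planted, seed = 2)
  mod2 <- modality_spec("expression", n_features = 100, noise_sd = 1)
  om2 <- generate_omics(c2k, md2$mutation, mod2, planted, seed = 2)
  sig <- om2$signal_features$SIG
  mut2 <- md2$mutation[, "SIG"] == 1
  shift <- mean(colMeans(om2$matrix[mut2, sig]) -
                  colMeans(om2$matrix[!mut2, sig]))
  expect_lt(abs(shift - 2), 0.2) # recovered in noise-sd units (noise_sd = 1)
  off <- setdiff(om2$feature_ids, sig)
  off_shift <- mean(colMeans(om2$matrix[mut2, off]) -
                      colMeans(om2$matrix[!mut2, off]))
  expect_lt(abs(off_shift), 0.2)
})

test_that("bounded01 modalities stay in [0,1] and missingness is calibrated", {
  cohort <- generate_cohort(small_cohort_spec(1500, seed = 23))
  genes <- list(null_gene())
  md <- generate_mutation_data(cohort, genes, seed = 1)
  mod <- modality_spec("me_27k", kind = "bounded01", n_features = 100,
                       missing_rate = 0.02, n_high_missing_samples = 5)
  om <- generate_omics(cohort, md$mutation, mod, genes, seed = 1)
  vals <- om$matrix[!is.na(om$matrix)]
  expect_true(all(vals >= 0 & vals <= 1))
  # realized missing fraction within +/-20% relative of the target at >=1e5
  # entries; the 5 high-missing samples add 5 * (10x - 1x) * rate / n extra
  n_entries <- length(om$matrix)
  expect_gte(n_entries, 1e5)
  expected <- 0.02 + 5 * 9 * 0.02 / nrow(om$matrix)
  realized <- mean(is.na(om$matrix))
  expect_lt(abs(realized - expected) / expected, 0.2)
  hi_counts <- sort(rowSums(is.na(om$matrix)), decreasing = TRUE)
  # the 5 high-missing samples (~10x rate) dominate the typical sample
  expect_gt(mean(hi_counts[1:5]), 5 * median(rowSums(is.na(om$matrix))))
})

test_that("planted signals are recoverable and nulls calibrated", {
  # recoverability: effect 1.5, 20 features, prevalence 0.2, n = 1000
  rejections <- 0L; total <- 0L
  for (s in 1:5) {
    spec <- cohort_spec(n_samples = 1000, cancer_types = c(LUAD = 1),
                        sample_types = c(primary = 1),
                        hypermutated_fraction = 0, seed = 100 + s)
    cohort <- generate_cohort(spec)
    g <- list(gene_spec("SIG", per_type_mutation_prob = c(LUAD = 0.2),
                        signal_modalities = "expression", effect_size = 1.5,
                        n_signal_features = 20))
    md <- generate_mutation_data(cohort, g, seed = s)
    om <- generate_omics(cohort, md$mutation,
                         modality_spec("expression", n_features = 50), g,
                         seed = s)
    mut <- md$mutation[, "SIG"] == 1
    for (f in om$signal_features$SIG) {
      p <- t.test(om$matrix[mut, f], om$matrix[!mut, f])$p.value
      total <- total + 1L
      if (p < 1e-4) rejections <- rejections + 1L
    }
  }
  expect_gte(rejections / total, 0.95)

  # null calibration: per-feature group-contrast p-values uniform
  spec <- cohort_spec(n_samples = 500, cancer_types = c(LUAD = 1),
                      sample_types = c(primary = 1),
                      hypermutated_fraction = 0, seed = 31)
  cohort <- generate_cohort(spec)
  g <- list(null_gene("N", prevalence = 0.5, types = "LUAD"))
  md <- generate_mutation_data(cohort, g, seed = 9)
  # no latent factors here: the KS test needs independent per-feature
  # p-values, and shared factors would leave them uniform but dependent
  om <- generate_omics(cohort, md$mutation,
                       modality_spec("expression", n_features = 2000,
                                     n_latent_factors = 0), g,
                       seed = 9)
  mut <- md$mutation[, "N"] == 1
  pvals <- apply(om$matrix, 2, function(x) t.test(x[mut], x[!mut])$p.value)
  expect_gt(suppressWarnings(ks.test(pvals, "punif"))$p.value, 0.01)
})

test_that("survival: null model, planted factor effect, censoring control", {
  spec <- cohort_spec(n_samples = 2000, seed = 37)
  cohort <- generate_cohort(spec)
  null_coef <- list(age = 0, burden = 0, factors = rep(0, 5))
  sv <- generate_survival(cohort, cohort$latent, null_coef,
                          censoring_rate = 0, seed = 1)
  expect_true(all(sv$event == 1))
  expect_true(all(sv$time > 0))
  # covariate-independent: age as a risk score is uninformative
  ci <- concordance_index(cohort$clinical$age, sv$time, sv$event)
  expect_lt(abs(ci - 0.5), 0.05)

  strong <- list(age = 0, burden = 0, factors = c(2, 0, 0, 0, 0))
  sv2 <- generate_survival(cohort, cohort$latent, strong,
                           censoring_rate = 0.3, seed = 2)
  ci2 <- concordance_index(cohort$latent[, 1], sv2$time, sv2$event)
  expect_gt(ci2, 0.7)
  expect_lt(abs(mean(sv2$event) - 0.7), 0.05) # calibrated censoring

  expect_error(generate_survival(cohort, cohort$latent,
                                 list(age = Inf, burden = 0,
                                      factors = rep(0, 5)),
                                 0.2, seed = 3),
               "non-finite")
})

test_that("simulate_study produces a coherent, reproducible bundle", {
  b1 <- small_bundle(n = 200, seed = 41, with_methylation = TRUE,
                     with_survival = TRUE)
  b2 <- small_bundle(n = 200, seed = 41, with_methylation = TRUE,
                     with_survival = TRUE)
  expect_identical(b1$mutation, b2$mutation)
  expect_identical(b1$omics$expression$matrix, b2$omics$expression$matrix)
  expect_identical(b1$survival$OS, b2$survival$OS)
  expect_setequal(names(b1$omics), c("expression", "me_27k"))
  expect_equal(rownames(b1$mutation), b1$clinical$sample_id)
})
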