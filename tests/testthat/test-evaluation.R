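test_that("stratified splits balance strata and are deterministic", {
  clin <- data.frame(sample_id = paste0("S", 1:80),
                     cancer_type = rep(c("A", "B"), each = 40),
                     sample_type = "primary", stringsAsFactors = FALSE)
  sp <- make_cv_splits(clin, clin$sample_id, seed = 3)
  for (r in 1:2) {
    fold <- sp$assignments[[r]]
    expect_true(all(sort(unique(fold)) == 1:4))
    expect_true(all(table(fold) == 20))
    for (ct in c("A", "B")) {
      per_fold <- table(fold[clin$cancer_type[match(names(fold),
                                                    clin$sample_id)] == ct])
      expect_true(all(per_fold == 10)) # exact divisibility: 10 per type
    }
  }
  # test sets partition the samples within a replicate
  expect_setequal(names(sp$assignments[[1]]), clin$sample_id)
  sp2 <- make_cv_splits(clin, clin$sample_id, seed = 3)
  expect_identical(sp$assignments, sp2$assignments)
  sp3 <- make_cv_splits(clin, clin$sample_id, seed = 4)
  expect_false(identical(sp$assignments, sp3$assignments))
})

test_that("small strata merge instead of crashing and fold sizes stay balanced", {
  clin <- data.frame(sample_id = paste0("S", 1:42),
                     cancer_type = c(rep("A", 40), "B", "B"),
                     sample_type = c(rep("primary", 38), "recurrent",
                                     "recurrent", "primary", "primary"),
                     stringsAsFactors = FALSE)
  sp <- make_cv_splits(clin, clin$sample_id, seed = 5)
  counts <- table(sp$assignments[[1]])
  expect_true(max(counts) - min(counts) <= 2)
  expect_error(make_cv_splits(clin, clin$sample_id[1:3], seed = 1),
               "fewer samples")
})

test_that("stratified label permutation preserves per-cell positive counts exactly", {
  set.seed(6)
  n <- 120
  labels <- setNames(rbinom(n, 1, 0.3), paste0("S", 1:n))
  ct <- setNames(sample(c("A", "B", "C"), n, replace = TRUE), names(labels))
  train <- names(labels)[1:80]
  test <- names(labels)[81:n]
  for (s in 1:25) {
    perm <- permute_labels_stratified(labels, ct, train, test, seed = s)
    expect_setequal(names(perm), names(labels))
    for (part in list(train, test)) {
      for (type in unique(ct[part])) {
        cell <- part[ct[part] == type]
        expect_identical(sum(perm[cell]), sum(labels[cell]))
      }
    }
  }
  # all-zero cell unchanged
  lab0 <- setNames(rep(0, 10), paste0("Z", 1:10))
  ct0 <- setNames(rep("A", 10), names(lab0))
  expect_identical(permute_labels_stratified(lab0, ct0, names(lab0)[1:5],
                                             names(lab0)[6:10], 1), lab0)
})

test_that("a lone positive in a 2-sample cell lands uniformly across seeds", {
  labels <- setNames(c(1, 0), c("a", "b"))
  ct <- setNames(c("A", "A"), c("a", "b"))
  hits <- 0L
  for (s in 1:1000) {
    perm <- permute_labels_stratified(labels, ct, c("a", "b"), character(),
                                      seed = s)
    if (perm["a"] == 1) hits <- hits + 1L
  }
  expect_lt(abs(hits / 1000 - 0.5), 0.05)
})

test_that("nested grid search: degenerate grid, full grid size, tie-breaking", {
  b <- small_bundle(n = 300, seed = 73, p = 30)
  prep_cfg <- fast_config(seed = 7)
  clin <- b$clinical
  cov <- build_covariates(clin, clin$sample_id)
  fm <- assemble_feature_matrix(b$omics, cov, mode = "raw")
  y <- b$mutation[rownames(fm$matrix), "G1"]
  sp <- make_cv_splits(clin, rownames(fm$matrix), seed = 7)
  fold <- sp$assignments[[1]]
  train <- names(fold)[fold != 1]; test <- names(fold)[fold == 1]

  # grid of exactly one pair: degenerate search returns it
  one <- nested_grid_search(fm$matrix, y, train, test, sp$strata,
                            list(alpha = 0.1, l1_ratio = 0.5), seed = 1)
  expect_equal(one$alpha, 0.1)
  expect_equal(one$l1_ratio, 0.5)

  # default grids: 6 x 8 = 48 pairs scored per fold
  full <- nested_grid_search(fm$matrix, y, train, test, sp$strata,
                             default_config()$grids, seed = 1)
  expect_equal(dim(full$inner_scores), c(6, 8))
  expect_equal(length(default_config()$grids$alpha) *
                 length(default_config()$grids$l1_ratio), 48)
  expect_true(full$alpha %in% default_config()$grids$alpha)
  expect_true(full$metrics["aupr"] >= 0 && full$metrics["aupr"] <= 1)
})

test_that("gene experiments emit 8 paired records per condition", {
  b <- small_bundle(n = 400, seed = 79, p = 40)
  res <- run_gene_experiment("G1", "expression", b, fast_config(seed = 11))
  expect_equal(nrow(res), 16)
  expect_equal(sum(res$condition == "true_labels"), 8)
  expect_equal(sum(res$condition == "permuted_labels"), 8)
  keys_true <- with(res[res$condition == "true_labels", ],
                    paste(replicate, fold))
  keys_perm <- with(res[res$condition == "permuted_labels", ],
                    paste(replicate, fold))
  expect_setequal(keys_true, keys_perm)
  # permutation preserves test-set positive counts, so the paired fold has
  # the same number of test positives in both conditions
  merged <- merge(res[res$condition == "true_labels",
                      c("replicate", "fold", "n_test_positives")],
                  res[res$condition == "permuted_labels",
                      c("replicate", "fold", "n_test_positives")],
                  by = c("replicate", "fold"))
  expect_identical(merged$n_test_positives.x, merged$n_test_positives.y)
  # strong planted signal: small penalties win most outer folds
  true_res <- res[res$condition == "true_labels", ]
  expect_gte(sum(true_res$alpha <= 0.1), 6)
})

test_that("genes without valid cancer types are skipped with a reason", {
  rare <- gene_spec("RARE", per_type_mutation_prob = c(LUAD = 0.01,
                                                       BRCA = 0.01,
                                                       COAD = 0.01))
  b <- small_bundle(n = 300, seed = 83, genes = list(rare, null_gene()))
  out <- run_gene_experiment("RARE", "expression", b, fast_config())
  expect_equal(nrow(out), 0)
  expect_match(attr(out, "skip_reason"), "no valid cancer types")
})

test_that("paired delta test: identity, strong shift, cancellation, guards", {
  mk <- function(auprs) data.frame(replicate = rep(1:2, each = 4),
                                   fold = rep(1:4, 2), aupr = auprs)
  a <- mk(seq(0.5, 0.85, length.out = 8))
  same <- paired_delta_test(a, a)
  expect_equal(same$mean_delta, 0)
  expect_equal(same$p_value, 1)

  jitter <- c(1, -1, 1, -1, 1, -1, 1, -1) * 1e-6
  shifted <- mk(a$aupr + 0.1 + jitter)
  strong <- paired_delta_test(shifted, a)
  expect_equal(strong$mean_delta, 0.1, tolerance = 1e-5)
  expect_lt(strong$p_value, 1e-6)

  sym <- mk(a$aupr + c(0.1, 0.1, 0.1, 0.1, -0.1, -0.1, -0.1, -0.1))
  cancel <- paired_delta_test(sym, a)
  expect_equal(cancel$mean_delta, 0, tolerance = 1e-12)
  expect_equal(cancel$t_statistic, 0)
  expect_gt(cancel$p_value, 0.99)

  # constant nonzero deltas: epsilon floor, flagged degenerate
  const <- paired_delta_test(mk(a$aupr + 0.05), a)
  expect_true(const$degenerate)
  expect_lt(const$p_value, 1e-10)

  b_bad <- mk(a$aupr)[-1, ]
  expect_error(paired_delta_test(a, b_bad), "keys do not match")
})

test_that("BH correction: single test, hand example, monotonicity", {
  single <- fdr_correct(data.frame(p_value = 0.03))
  expect_equal(single$q_value, 0.03)
  hand <- fdr_correct(data.frame(p_value = c(0.01, 0.02, 0.03, 0.04)))
  expect_equal(hand$q_value, rep(0.04, 4))
  set.seed(16)
  p <- runif(50)
  q <- fdr_correct(data.frame(p_value = p))$q_value
  expect_true(all(q >= p))
  ord <- order(p)
  expect_true(all(diff(q[ord]) >= -1e-15))
  # families corrected independently
  fam <- rep(c("x", "y"), each = 2)
  two <- fdr_correct(data.frame(p_value = c(0.01, 0.04, 0.01, 0.04)), fam)
  expect_equal(two$q_value, c(0.02, 0.04, 0.02, 0.04))
})

test_that("summary grid: single-modality self-equivalence and the sign guard", {
  mk <- function(gene, modality, true_aupr, perm_aupr) {
    data.frame(gene = gene, modality_set = modality,
               replicate = rep(1:2, each = 4, times = 2),
               fold = rep(1:4, 4),
               condition = rep(c("true_labels", "permuted_labels"), each = 8),
               aupr = c(true_aupr, perm_aupr), auroc = 0.5, alpha = 0.1,
               l1_ratio = 0.5, n_test_positives = 10)
  }
  set.seed(17)
  base <- runif(8, 0.2, 0.25)
  solo <- mk("G", "expression", base + 0.3 + rnorm(8, 0, 0.01), base)
  g1 <- call_summary_grid(solo, corrected_p = 0.01)
  expect_true(g1$best)
  expect_true(g1$equivalent_to_best)
  expect_true(g1$well_predicted)

  # permuted beats true significantly: significant but never well-predicted
  worse <- mk("G", "expression", base, base + 0.3 + rnorm(8, 0, 0.01))
  g2 <- call_summary_grid(worse, corrected_p = 0.01)
  expect_lt(g2$mean_delta_aupr, 0)
  expect_true(g2$q_value < 0.01)
  expect_false(g2$well_predicted)

  # two modalities, one clearly better: the weaker is not equivalent
  two <- rbind(mk("G", "expression", base + 0.4 + rnorm(8, 0, 0.005), base),
               mk("G", "me_27k", base + 0.1 + rnorm(8, 0, 0.005), base))
  g3 <- call_summary_grid(two, corrected_p = 0.01)
  expect_identical(g3$modality_set[g3$best], "expression")
  expect_false(g3$equivalent_to_best[g3$modality_set == "me_27k"])
})

test_that("survival experiment: endpoint rule and covariate-only baseline", {
  spec <- cohort_spec(n_samples = 500,
                      cancer_types = c(BRCA = 0.5, LUAD = 0.5), seed = 89)
  genes <- list(null_gene(types = c("BRCA", "LUAD")))
  mods <- list(modality_spec("expression", n_features = 20))
  b <- simulate_study(spec, genes, mods, seed = 89,
                      survival_coefficients = list(age = 0.02, burden = 0.3,
                                                   factors = c(1, 0, 0, 0, 0)))
  surv <- select_endpoint(b)
  ct <- b$clinical$cancer_type[match(surv$sample_id, b$clinical$sample_id)]
  expect_true(all(surv$endpoint[ct == "BRCA"] == "PFI")) # PFI-listed type
  expect_true(all(surv$endpoint[ct == "LUAD"] == "OS"))
  expect_equal(surv$time[ct == "BRCA"],
               b$survival$PFI$time[match(surv$sample_id[ct == "BRCA"],
                                         b$survival$PFI$sample_id)])

  cfg <- default_config(survival_grids = list(alpha = c(0.01, 0.1),
                                              l1_ratio = 0.5), seed = 19)
  res <- suppressWarnings(run_survival_experiment(b, "expression",
                                                  k_values = c(3, 5), cfg))
  base <- res[res$model == "covariates_only", ]
  expect_equal(nrow(base), 8) # 8 c-index values, independent of k
  expect_true(all(is.na(base$k)))
  omics <- res[res$model == "expression", ]
  expect_setequal(unique(omics$k), c(3, 5))
  expect_equal(nrow(omics), 16)
  expect_true(all(res$cindex >= 0 & res$cindex <= 1))
})
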