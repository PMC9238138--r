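#' Default experiment configuration
#'
#' All defaults trace to the benchmark's standard settings: 2 replicates of
#' 4-fold cross-validation with 3 inner folds; classification grids
#' l1_ratio = {0, 0.05, 0.1, 0.3, 0.5, 0.7, 0.9, 1} and
#' alpha = {1e-4, 1e-3, 0.01, 0.1, 1, 10}; survival alpha grid
#' {0, 1e-5, 1e-4, 5e-4, 0.001, 0.005, 0.01, 0.05, 0.1, 0.5, 1, 10, 100,
#' 1000}; valid-cancer-type thresholds of 15 mutated samples and 5%
#' mutated; corrected significance threshold 0.001; PFI endpoint for the
#' nine cancer types with few observed deaths, OS otherwise.
#'
#' @param ... named overrides of any default.
#' @return list of class `run_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    grids = list(alpha = c(1e-4, 1e-3, 0.01, 0.1, 1, 10),
                 l1_ratio = c(0, 0.05, 0.1, 0.3, 0.5, 0.7, 0.9, 1)),
    survival_grids = list(
      alpha = c(0, 1e-5, 1e-4, 5e-4, 0.001, 0.005, 0.01, 0.05, 0.1,
                0.5, 1, 10, 100, 1000),
      l1_ratio = c(0, 0.05, 0.1, 0.3, 0.5, 0.7, 0.9, 1)),
    n_folds = 4, n_replicates = 2, n_inner = 3,
    min_mutated = 15, min_fraction = 0.05,
    corrected_p = 0.001, equivalence_alpha = 0.05,
    feature_mode = "raw", per_dataset_k = Inf,
    fit_scope = "paper_faithful", # or "leakage_safe"
    penalize_covariates = TRUE, include_shallow_cnv = FALSE,
    hypermutation_sd = 5,
    pfi_cancer_types = c("BRCA", "DLBC", "LGG", "PCPG", "PRAD", "READ",
                         "TGCT", "THCA", "THYM"),
    seed = 1
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    stop("default_config: unknown option(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(dots)] <- dots
  class(cfg) <- "run_config"
  cfg
}

# Prepare the per-gene experiment inputs: hypermutation exclusion, labels,
# modality sample intersection, valid-type filter, included samples.
prepare_gene_inputs <- function(gene, modality_set, bundle, config) {
  clin <- bundle$clinical
  burdens <- stats::setNames(clin$burden, clin$sample_id)
  excluded <- detect_hypermutated(burdens, n_sd = config$hypermutation_sd)
  role <- bundle$annotation$role[match(gene, bundle$annotation$gene)]
  if (is.na(role)) stop("prepare_gene_inputs: gene ", gene, " not annotated")
  ls <- build_mutation_labels(gene, role, bundle$mutation, bundle$cnv,
                              excluded,
                              include_shallow = config$include_shallow_cnv)
  common <- names(ls$labels)
  for (m in modality_set) {
    if (!m %in% names(bundle$omics)) {
      stop("prepare_gene_inputs: modality '", m, "' not in bundle")
    }
    common <- intersect(common, rownames(bundle$omics[[m]]$matrix))
  }
  if (length(common) == 0) {
    stop("prepare_gene_inputs: empty sample intersection for modalities ",
         paste(modality_set, collapse = "+"))
  }
  labels <- ls$labels[common]
  ct <- stats::setNames(clin$cancer_type, clin$sample_id)
  valid <- compute_valid_cancer_types(labels, ct, config$min_mutated,
                                      config$min_fraction)
  included <- common[ct[common] %in% valid]
  list(labels = labels, valid_types = valid, included = included,
       excluded = excluded, cancer_types = ct, label_set = ls)
}

# Build the feature matrix for one gene experiment on the included samples.
build_gene_features <- function(modality_set, bundle, included, config,
                                fit_samples = NULL, include_age = FALSE) {
  datasets <- lapply(bundle$omics[modality_set], function(d) {
    x <- d$matrix[included, , drop = FALSE]
    if (anyNA(x)) x <- impute_methylation(x)$matrix
    d$matrix <- x
    d
  })
  # imputation may drop samples from individual modalities; re-intersect
  included2 <- Reduce(intersect, lapply(datasets, function(d)
    rownames(d$matrix)))
  datasets <- lapply(datasets, function(d) {
    d$matrix <- d$matrix[included2, , drop = FALSE]
    d
  })
  cov <- build_covariates(bundle$clinical, included2, include_age = include_age)
  assemble_feature_matrix(datasets, cov, mode = config$feature_mode,
                          per_dataset_k = config$per_dataset_k,
                          fit_samples = fit_samples)
}

#' Run the mutation-prediction experiment for one gene and modality set
#'
#' Restricts samples to the modality intersection and the gene's valid
#' cancer types, builds features (with covariates appended), and runs the
#' full 2 x 4-fold evaluation with nested grid search twice on identical
#' splits: once with the true labels and once with labels permuted within
#' each (cancer type x train/test) cell. Hyperparameters are re-searched in
#' the permuted condition so the null model enjoys the same model-selection
#' flexibility. Emits exactly `n_replicates * n_folds` result records per
#' condition (folds with a degenerate test set are dropped with a warning).
#'
#' @param gene target gene symbol (must be in the bundle's annotation).
#' @param modality_set character vector of modality names.
#' @param bundle a `data_bundle` (see [simulate_study()] / [read_tables()]).
#' @param config a [default_config()].
#' @return data.frame of experiment records: gene, modality_set, replicate,
#'   fold, condition, aupr, auroc, alpha, l1_ratio, n_test_positives; or
#'   NULL (with attribute `skip_reason`) when the gene has no valid cancer
#'   type.
#' @export
run_gene_experiment <- function(gene, modality_set, bundle,
                                config = default_config()) {
  prep <- prepare_gene_inputs(gene, modality_set, bundle, config)
  if (length(prep$valid_types) == 0) {
    out <- data.frame()
    attr(out, "skip_reason") <- paste0("gene ", gene, ": no valid cancer types")
    return(out)
  }
  seed <- child_seed(config$seed, paste0("gene.", gene, ".",
                                         paste(modality_set, collapse = "+")))
  fm <- build_gene_features(modality_set, bundle, prep$included, config)
  included <- rownames(fm$matrix)
  labels <- prep$labels[included]
  splits <- make_cv_splits(bundle$clinical, included, seed,
                           config$n_folds, config$n_replicates)
  records <- list()
  for (r in seq_len(config$n_replicates)) {
    fold_of <- splits$assignments[[r]]
    for (f in seq_len(config$n_folds)) {
      test_set <- names(fold_of)[fold_of == f]
      train_set <- names(fold_of)[fold_of != f]
      x <- if (config$fit_scope == "leakage_safe") {
        build_gene_features(modality_set, bundle, included, config,
                            fit_samples = train_set)$matrix
      } else fm$matrix
      fold_seed <- child_seed(seed, "fold", r * 1000L + f)
      for (condition in c("true_labels", "permuted_labels")) {
        y <- if (condition == "true_labels") labels else {
          permute_labels_stratified(labels, prep$cancer_types[included],
                                    train_set, test_set, fold_seed)
        }
        res <- nested_grid_search(x, y, train_set, test_set, splits$strata,
                                  config$grids, family = "binomial",
                                  n_inner = config$n_inner,
                                  seed = child_seed(fold_seed, condition))
        if (is.null(res)) next
        records[[length(records) + 1]] <- data.frame(
          gene = gene, modality_set = paste(modality_set, collapse = "+"),
          replicate = r, fold = f, condition = condition,
          aupr = unname(res$metrics["aupr"]),
          auroc = unname(res$metrics["auroc"]),
          alpha = res$alpha, l1_ratio = res$l1_ratio,
          n_test_positives = unname(res$n_extra["n_test_positives"]),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, records)
}

#' Paired fold-wise comparison of two performance distributions
#'
#' Performance measurements from the same (replicate, fold) are paired; the
#' comparison is a two-sided paired t-test on the per-fold metric
#' differences (7 degrees of freedom in the standard 2 x 4 design). When
#' every delta is exactly zero the p-value is 1; when the deltas are
#' nonzero but have zero variance, an epsilon variance floor (1e-12) is
#' applied and the result flagged degenerate.
#'
#' @param a,b data.frames of experiment records with `replicate`, `fold`
#'   and the metric column; rows are matched on (replicate, fold) and must
#'   agree exactly.
#' @param metric metric column to compare (default `"aupr"`).
#' @return one-row data.frame: mean_delta, t_statistic, p_value, df,
#'   degenerate.
#' @export
paired_delta_test <- function(a, b, metric = "aupr") {
  key_a <- paste(a$replicate, a$fold)
  key_b <- paste(b$replicate, b$fold)
  if (anyDuplicated(key_a) || anyDuplicated(key_b) ||
      !setequal(key_a, key_b) || length(key_a) != length(key_b)) {
    stop("paired_delta_test: (replicate, fold) keys do not match")
  }
  b <- b[match(key_a, key_b), , drop = FALSE]
  deltas <- a[[metric]] - b[[metric]]
  n <- length(deltas)
  df <- n - 1
  m <- mean(deltas)
  s <- stats::sd(deltas)
  degenerate <- FALSE
  if (s == 0) {
    if (m == 0) {
      return(data.frame(mean_delta = 0, t_statistic = 0, p_value = 1,
                        df = df, degenerate = FALSE))
    }
    s <- sqrt(1e-12)
    degenerate <- TRUE
  }
  t_stat <- m / (s / sqrt(n))
  p <- 2 * stats::pt(-abs(t_stat), df)
  data.frame(mean_delta = m, t_statistic = t_stat, p_value = p, df = df,
             degenerate = degenerate)
}

#' Benjamini-Hochberg correction within families
#'
#' Applies the BH step-up procedure to `p_value` within each level of
#' `family` and adds nested significance flags at the corrected thresholds
#' 0.05, 0.01 and 0.001.
#'
#' @param calls data.frame with a `p_value` column.
#' @param family grouping vector (default: one family).
#' @return `calls` with `q_value`, `sig_0.05`, `sig_0.01`, `sig_0.001`.
#' @export
fdr_correct <- function(calls, family = rep(1, nrow(calls))) {
  stopifnot(all(calls$p_value >= 0 & calls$p_value <= 1))
  calls$q_value <- stats::ave(calls$p_value, family,
                              FUN = function(p) stats::p.adjust(p, "BH"))
  for (th in c(0.05, 0.01, 0.001)) {
    calls[[paste0("sig_", th)]] <- calls$q_value < th
  }
  calls
}

#' Compare each modality with the permuted baseline, per gene
#'
#' For every (gene, modality_set) present in `results`, pairs the true- and
#' permuted-label AUPR distributions fold-wise and runs
#' [paired_delta_test()], then BH-corrects within each modality-set family.
#'
#' @param results long experiment records from [run_gene_experiment()].
#' @param corrected_p corrected significance threshold for the
#'   well-predicted call (default 0.001).
#' @return data.frame of calls: gene, modality_set, mean_delta_aupr,
#'   t_statistic, p_value, q_value, significance flags, well_predicted.
#' @export
baseline_comparison <- function(results, corrected_p = 0.001) {
  keys <- unique(results[, c("gene", "modality_set")])
  calls <- do.call(rbind, lapply(seq_len(nrow(keys)), function(i) {
    sub <- results[results$gene == keys$gene[i] &
                     results$modality_set == keys$modality_set[i], ]
    tt <- paired_delta_test(sub[sub$condition == "true_labels", ],
                            sub[sub$condition == "permuted_labels", ])
    data.frame(gene = keys$gene[i], modality_set = keys$modality_set[i],
               mean_delta_aupr = tt$mean_delta, t_statistic = tt$t_statistic,
               p_value = tt$p_value, degenerate = tt$degenerate,
               stringsAsFactors = FALSE)
  }))
  calls <- fdr_correct(calls, family = calls$modality_set)
  calls$well_predicted <- calls$q_value < corrected_p &
    calls$mean_delta_aupr > 0
  calls
}

#' Per-gene x modality summary grid: well-predicted and equivalent-to-best
#'
#' A modality is well-predicted for a gene when it significantly
#' outperforms the permuted baseline at the corrected threshold with a
#' positive mean AUPR difference. The best modality per gene is the one
#' with the highest mean delta AUPR; every other modality is compared with
#' it by a pairwise paired t-test on the true-label AUPRs, BH-corrected
#' within the gene, and flagged equivalent when not significantly different
#' at `equivalence_alpha`.
#'
#' @param results long experiment records (both conditions) covering one or
#'   more genes and modality sets.
#' @param corrected_p corrected threshold for the baseline comparison.
#' @param equivalence_alpha corrected threshold for the equivalence call.
#' @return data.frame: gene, modality_set, mean_delta_aupr, q_value,
#'   well_predicted, best, equivalent_to_best.
#' @export
call_summary_grid <- function(results, corrected_p = 0.001,
                              equivalence_alpha = 0.05) {
  calls <- baseline_comparison(results, corrected_p)
  out <- list()
  for (g in unique(calls$gene)) {
    sub <- calls[calls$gene == g, , drop = FALSE]
    best <- sub$modality_set[which.max(sub$mean_delta_aupr)]
    best_true <- results[results$gene == g & results$modality_set == best &
                           results$condition == "true_labels", ]
    pw <- do.call(rbind, lapply(sub$modality_set, function(m) {
      if (m == best) {
        return(data.frame(modality_set = m, p_value = 1,
                          stringsAsFactors = FALSE))
      }
      m_true <- results[results$gene == g & results$modality_set == m &
                          results$condition == "true_labels", ]
      tt <- paired_delta_test(m_true, best_true)
      data.frame(modality_set = m, p_value = tt$p_value,
                 stringsAsFactors = FALSE)
    }))
    pw$q_equiv <- stats::p.adjust(pw$p_value, "BH")
    sub$best <- sub$modality_set == best
    sub$equivalent_to_best <- sub$best |
      pw$q_equiv[match(sub$modality_set, pw$modality_set)] >= equivalence_alpha
    out[[g]] <- sub
  }
  grid <- do.call(rbind, out)
  rownames(grid) <- NULL
  grid
}

#' Select the survival endpoint per sample
#'
#' Overall survival (OS) is used except for cancer types in
#' `pfi_cancer_types` (types with few observed deaths), which use the
#' progression-free interval (PFI).
#'
#' @param bundle a `data_bundle` with `survival$OS` and `survival$PFI`.
#' @param pfi_cancer_types cancer types mapped to PFI.
#' @return data.frame rownamed by sample: time, event, endpoint.
#' @export
select_endpoint <- function(bundle, pfi_cancer_types =
                              default_config()$pfi_cancer_types) {
  if (is.null(bundle$survival)) stop("select_endpoint: no survival data")
  os <- bundle$survival$OS
  pfi <- bundle$survival$PFI
  ct <- bundle$clinical$cancer_type[match(os$sample_id,
                                          bundle$clinical$sample_id)]
  use_pfi <- ct %in% pfi_cancer_types
  out <- os
  out$endpoint <- "OS"
  if (!is.null(pfi)) {
    idx <- match(os$sample_id[use_pfi], pfi$sample_id)
    out$time[use_pfi] <- pfi$time[idx]
    out$event[use_pfi] <- pfi$event[idx]
    out$endpoint[use_pfi] <- "PFI"
  }
  rownames(out) <- out$sample_id
  out
}

#' Run the survival-prediction experiment
#'
#' For each modality and each number of principal components k, fits
#' elastic-net Cox models on the top min(p, k) PCA scores plus covariates
#' (age, log10 mutation burden, one-hot cancer type) under the same
#' 2 x 4-fold evaluation with a 3-fold inner grid search scored by mean
#' inner c-index; also fits a covariate-only baseline. Hypermutated
#' samples are excluded for consistency with the mutation experiments.
#'
#' @param bundle a `data_bundle` with survival annotations.
#' @param modalities modality names to evaluate (default: all in bundle).
#' @param k_values numbers of principal components
#'   (default `c(10, 100, 500, 1000, 5000)`).
#' @param config a [default_config()].
#' @return data.frame: model (modality or "covariates_only"), k, replicate,
#'   fold, cindex, alpha, l1_ratio, n_test_events.
#' @export
run_survival_experiment <- function(bundle, modalities = names(bundle$omics),
                                    k_values = c(10, 100, 500, 1000, 5000),
                                    config = default_config()) {
  surv <- select_endpoint(bundle, config$pfi_cancer_types)
  clin <- bundle$clinical
  burdens <- stats::setNames(clin$burden, clin$sample_id)
  excluded <- detect_hypermutated(burdens, n_sd = config$hypermutation_sd)
  included <- setdiff(clin$sample_id, excluded)
  mats <- list()
  for (m in modalities) {
    xm <- bundle$omics[[m]]$matrix
    xm <- xm[intersect(included, rownames(xm)), , drop = FALSE]
    if (anyNA(xm)) xm <- impute_methylation(xm)$matrix
    mats[[m]] <- xm
  }
  included <- Reduce(intersect, c(list(included), lapply(mats, rownames)))
  mats <- lapply(mats, function(x) x[included, , drop = FALSE])
  seed <- child_seed(config$seed, "survival")
  splits <- make_cv_splits(clin, included, seed, config$n_folds,
                           config$n_replicates)
  cov <- build_covariates(clin, included, include_age = TRUE)
  cov_std <- standardize(cov)$matrix
  y <- surv[included, c("time", "event")]

  run_model <- function(x, label, k) {
    recs <- list()
    for (r in seq_len(config$n_replicates)) {
      fold_of <- splits$assignments[[r]]
      for (f in seq_len(config$n_folds)) {
        test_set <- names(fold_of)[fold_of == f]
        train_set <- names(fold_of)[fold_of != f]
        res <- tryCatch(
          nested_grid_search(x, y, train_set, test_set, splits$strata,
                             config$survival_grids, family = "cox",
                             n_inner = config$n_inner,
                             seed = child_seed(seed, label, r * 1000L + f)),
          error = function(e) {
            warning("survival fold (", label, ", r", r, ", f", f,
                    ") failed: ", conditionMessage(e))
            NULL
          })
        if (is.null(res)) next
        recs[[length(recs) + 1]] <- data.frame(
          model = label, k = k, replicate = r, fold = f,
          cindex = unname(res$metrics["cindex"]),
          alpha = res$alpha, l1_ratio = res$l1_ratio,
          n_test_events = unname(res$n_extra["n_test_events"]),
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, recs)
  }

  records <- list(run_model(cov_std, "covariates_only", NA_real_))
  for (m in modalities) {
    xm_std <- standardize(mats[[m]])$matrix
    for (k in k_values) {
      scores <- pca_compress(xm_std, min(k, ncol(xm_std)))$scores
      x <- cbind(scores, cov_std)
      records[[length(records) + 1]] <- run_model(x, m, k)
    }
  }
  do.call(rbind, records)
}
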