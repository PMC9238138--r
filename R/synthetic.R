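#' Specify a synthetic tumor cohort
#'
#' The generator emulates the structure of a pan-cancer cohort: a mixture of
#' cancer types with stated proportions, sample types (primary/recurrent
#' etc.), a long-tailed non-silent mutation burden with a hypermutated
#' outlier subpopulation, patient ages, and a shared low-rank latent-factor
#' structure that downstream modalities (and optionally survival) load on.
#'
#' @param n_samples number of samples.
#' @param cancer_types named numeric vector of cancer-type proportions
#'   (must sum to 1).
#' @param sample_types named numeric vector of sample-type proportions.
#' @param burden_log10_mean,burden_log10_sd mean and sd of log10 non-silent
#'   mutation count.
#' @param hypermutated_fraction fraction of samples whose burden is inflated
#'   (must be in [0, 0.2]).
#' @param hypermutated_multiplier burden multiplier for hypermutated samples
#'   (> 1); also elevates their genome-wide per-gene mutation rate.
#' @param age_mean,age_sd age distribution (years); ages are clipped to
#'   [18, 100].
#' @param n_latent_factors number of cohort-level latent factors shared by
#'   all modalities.
#' @param seed integer master seed for the cohort.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_samples = 2000,
                        cancer_types = c(LUAD = 0.4, BRCA = 0.35, COAD = 0.25),
                        sample_types = c(primary = 0.9, recurrent = 0.1),
                        burden_log10_mean = 2, burden_log10_sd = 0.5,
                        hypermutated_fraction = 0.02,
                        hypermutated_multiplier = 10,
                        age_mean = 60, age_sd = 12,
                        n_latent_factors = 5,
                        seed = 42) {
  spec <- list(
    n_samples = as.integer(n_samples), cancer_types = cancer_types,
    sample_types = sample_types, burden_log10_mean = burden_log10_mean,
    burden_log10_sd = burden_log10_sd,
    hypermutated_fraction = hypermutated_fraction,
    hypermutated_multiplier = hypermutated_multiplier,
    age_mean = age_mean, age_sd = age_sd,
    n_latent_factors = as.integer(n_latent_factors), seed = as.integer(seed)
  )
  class(spec) <- "cohort_spec"
  validate_cohort_spec(spec)
  spec
}

validate_cohort_spec <- function(spec) {
  check_props <- function(p, field) {
    if (is.null(names(p)) || any(!nzchar(names(p)))) {
      stop("cohort_spec: '", field, "' must be a named vector", call. = FALSE)
    }
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
      stop("cohort_spec: proportions in '", field,
           "' must be nonnegative and sum to 1", call. = FALSE)
    }
  }
  check_props(spec$cancer_types, "cancer_types")
  check_props(spec$sample_types, "sample_types")
  if (spec$n_samples < 1) {
    stop("cohort_spec: 'n_samples' must be >= 1", call. = FALSE)
  }
  if (spec$hypermutated_fraction < 0 || spec$hypermutated_fraction > 0.2) {
    stop("cohort_spec: 'hypermutated_fraction' must be in [0, 0.2]",
         call. = FALSE)
  }
  if (spec$hypermutated_multiplier <= 1) {
    stop("cohort_spec: 'hypermutated_multiplier' must be > 1", call. = FALSE)
  }
  invisible(spec)
}

#' Specify a target or control gene for simulation
#'
#' A gene is defined by its driver role (which controls the copy-number
#' labeling rule downstream), per-cancer-type mutation prevalence, gain/loss
#' probabilities for thresholded copy-number calls, and a planted -omics
#' signature: in each modality listed in `signal_modalities`, a fixed random
#' subset of `n_signal_features` features is shifted by `effect_size` (in
#' units of the modality's noise sd) in mutated samples. `effect_size = 0`
#' defines a null gene.
#'
#' @param gene gene symbol.
#' @param role one of `"oncogene"`, `"tsg"`, `"both"`, `"fusion_only"`.
#' @param per_type_mutation_prob named numeric vector, cancer type ->
#'   mutation probability.
#' @param cnv_gain_prob,cnv_loss_prob probabilities of a +2 gain / -2 deep
#'   loss call per sample.
#' @param signal_modalities character vector of modality names carrying the
#'   planted signature.
#' @param effect_size standardized mean shift (noise-sd units), >= 0.
#' @param n_signal_features number of features shifted per modality.
#' @return an object of class `gene_spec`.
#' @export
gene_spec <- function(gene, role = "oncogene",
                      per_type_mutation_prob = numeric(),
                      cnv_gain_prob = 0, cnv_loss_prob = 0,
                      signal_modalities = character(),
                      effect_size = 0, n_signal_features = 0) {
  role <- match.arg(role, c("oncogene", "tsg", "both", "fusion_only"))
  probs <- c(per_type_mutation_prob, cnv_gain_prob, cnv_loss_prob)
  if (length(probs) && (any(probs < 0) || any(probs > 1))) {
    stop("gene_spec: probabilities must be in [0, 1] for gene ", gene,
         call. = FALSE)
  }
  if (effect_size < 0) stop("gene_spec: 'effect_size' must be >= 0")
  structure(list(gene = gene, role = role,
                 per_type_mutation_prob = per_type_mutation_prob,
                 cnv_gain_prob = cnv_gain_prob, cnv_loss_prob = cnv_loss_prob,
                 signal_modalities = signal_modalities,
                 effect_size = effect_size,
                 n_signal_features = as.integer(n_signal_features)),
            class = "gene_spec")
}

#' Specify a synthetic -omics modality
#'
#' @param name modality identifier (e.g. `"expression"`, `"me_27k"`).
#' @param kind `"continuous"` (expression/protein-like), `"bounded01"`
#'   (methylation-beta-like; values squashed to [0,1] by a logistic map), or
#'   `"nonnegative"` (signature-exposure-like; values are softplus-mapped).
#' @param n_features number of features.
#' @param n_latent_factors how many of the cohort latent factors this
#'   modality loads on.
#' @param type_effect_sd sd of per-cancer-type per-feature baseline offsets.
#' @param latent_loading_sd sd of latent-factor loadings.
#' @param noise_sd feature-level iid noise sd; also the unit of planted
#'   effect sizes.
#' @param missing_rate probability that an entry is missing.
#' @param n_high_missing_samples number of samples with ~10x the missing
#'   rate.
#' @return an object of class `modality_spec`.
#' @export
modality_spec <- function(name, kind = "continuous", n_features = 100,
                          n_latent_factors = 5, type_effect_sd = 0.5,
                          latent_loading_sd = 0.3, noise_sd = 1,
                          missing_rate = 0, n_high_missing_samples = 0) {
  kind <- match.arg(kind, c("continuous", "bounded01", "nonnegative"))
  if (n_features < 1) stop("modality_spec: 'n_features' must be >= 1")
  if (missing_rate < 0 || missing_rate > 1) {
    stop("modality_spec: 'missing_rate' must be in [0, 1]")
  }
  structure(list(name = name, kind = kind, n_features = as.integer(n_features),
                 n_latent_factors = as.integer(n_latent_factors),
                 type_effect_sd = type_effect_sd,
                 latent_loading_sd = latent_loading_sd, noise_sd = noise_sd,
                 missing_rate = missing_rate,
                 n_high_missing_samples = as.integer(n_high_missing_samples)),
            class = "modality_spec")
}

#' Generate a synthetic cohort
#'
#' Draws per-sample cancer type, sample type, non-silent mutation burden
#' (log-normal, with a randomly chosen hypermutated subset multiplied by
#' `hypermutated_multiplier`), age (normal, clipped to [18, 100]), and the
#' cohort-level latent factor scores shared by all modalities. Fully
#' reproducible from `spec$seed`.
#'
#' @param spec a [cohort_spec()].
#' @return a list of class `cohort` with elements `clinical` (data.frame:
#'   sample_id, cancer_type, sample_type, burden, age, hypermutated),
#'   `latent` (n x k matrix of factor scores) and `spec`.
#' @export
generate_cohort <- function(spec) {
  validate_cohort_spec(spec)
  n <- spec$n_samples
  rng <- local_rng(child_seed(spec$seed, "cohort"))
  on.exit(rng(), add = TRUE)

  sample_id <- sprintf("S%05d", seq_len(n))
  cancer_type <- sample(names(spec$cancer_types), n, replace = TRUE,
                        prob = spec$cancer_types)
  sample_type <- sample(names(spec$sample_types), n, replace = TRUE,
                        prob = spec$sample_types)
  burden <- 10^rnorm(n, spec$burden_log10_mean, spec$burden_log10_sd)
  n_hyper <- round(n * spec$hypermutated_fraction)
  hyper <- rep(FALSE, n)
  if (n_hyper > 0) {
    hyper[sample.int(n, n_hyper)] <- TRUE
    burden[hyper] <- burden[hyper] * spec$hypermutated_multiplier
  }
  burden <- pmax(0L, as.integer(round(burden)))
  age <- pmin(100, pmax(18, rnorm(n, spec$age_mean, spec$age_sd)))
  latent <- matrix(rnorm(n * spec$n_latent_factors), nrow = n,
                   dimnames = list(sample_id,
                                   paste0("F", seq_len(spec$n_latent_factors))))
  clinical <- data.frame(sample_id = sample_id, cancer_type = cancer_type,
                         sample_type = sample_type, burden = burden,
                         age = age, hypermutated = hyper,
                         stringsAsFactors = FALSE)
  structure(list(clinical = clinical, latent = latent, spec = spec),
            class = "cohort")
}

# Save/restore the global RNG state so generators behave as pure functions
# of (spec, seed) without disturbing the caller's stream.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
}

#' Generate binary mutation and thresholded copy-number matrices
#'
#' Point mutations are Bernoulli per gene with per-cancer-type prevalence
#' from each [gene_spec()]. Hypermutated samples get an elevated genome-wide
#' rate: their per-gene probability p becomes 1 - (1 - p)^m with m the
#' cohort's hypermutated multiplier, emulating the covariance between burden
#' and labels that the hypermutation filter exists to remove. Copy-number
#' calls are GISTIC-style integers in -2..2; +2 gains and -2 deep losses
#' occur with the gene's gain/loss probabilities, shallow +/-1 calls with a
#' fixed small background rate, independently of point mutations.
#'
#' @param cohort a [generate_cohort()] result.
#' @param genes list of [gene_spec()] objects with unique symbols.
#' @param seed integer seed.
#' @param shallow_prob background probability of a +1 and of a -1 call.
#' @return list with `mutation` and `cnv`, both sample x gene matrices
#'   (mutation binary; cnv integer in -2..2).
#' @export
generate_mutation_data <- function(cohort, genes, seed, shallow_prob = 0.05) {
  stopifnot(inherits(cohort, "cohort"))
  syms <- vapply(genes, `[[`, "", "gene")
  if (anyDuplicated(syms)) stop("generate_mutation_data: duplicate gene symbols")
  clin <- cohort$clinical
  n <- nrow(clin)
  if (n == 0) stop("generate_mutation_data: empty cohort")
  known_types <- names(cohort$spec$cancer_types)
  rng <- local_rng(child_seed(seed, "mutation"))
  on.exit(rng(), add = TRUE)

  mult <- cohort$spec$hypermutated_multiplier
  mutation <- matrix(0L, n, length(genes),
                     dimnames = list(clin$sample_id, syms))
  cnv <- matrix(0L, n, length(genes), dimnames = list(clin$sample_id, syms))
  for (j in seq_along(genes)) {
    g <- genes[[j]]
    extra <- setdiff(names(g$per_type_mutation_prob), known_types)
    if (length(extra)) {
      stop("generate_mutation_data: gene ", g$gene,
           " lists cancer type(s) absent from cohort: ",
           paste(extra, collapse = ", "))
    }
    p <- rep(0, n)
    for (ct in names(g$per_type_mutation_prob)) {
      p[clin$cancer_type == ct] <- g$per_type_mutation_prob[[ct]]
    }
    p[clin$hypermutated] <- 1 - (1 - p[clin$hypermutated])^mult
    mutation[, j] <- as.integer(runif(n) < p)
    pr <- c(g$cnv_loss_prob, shallow_prob, 0, shallow_prob, g$cnv_gain_prob)
    if (g$cnv_loss_prob == 0 && g$cnv_gain_prob == 0) {
      pr <- c(0, 0, 1, 0, 0) # null gene: keep the CNV column all-zero
    } else {
      pr[3] <- 1 - sum(pr[-3])
      if (pr[3] < 0) stop("generate_mutation_data: CNV probabilities for ",
                          g$gene, " exceed 1")
    }
    cnv[, j] <- sample(c(-2L, -1L, 0L, 1L, 2L), n, replace = TRUE, prob = pr)
  }
  list(mutation = mutation, cnv = cnv)
}

#' Generate one synthetic -omics modality
#'
#' The matrix is a Gaussian latent-factor model: per-cancer-type baseline
#' offsets (per feature, sd `type_effect_sd`) plus low-rank structure from
#' the cohort latent factors through modality-specific loadings, plus iid
#' feature noise. For each gene whose `signal_modalities` includes this
#' modality, a fixed random subset of `n_signal_features` features receives
#' an additive shift of `effect_size * noise_sd` in mutated samples.
#' `bounded01` modalities pass the latent values through a logistic map;
#' `nonnegative` through softplus. Missing entries are then inserted at
#' `missing_rate`, with `n_high_missing_samples` samples at 10x that rate.
#'
#' @param cohort a [generate_cohort()] result.
#' @param mutations binary sample x gene matrix from
#'   [generate_mutation_data()].
#' @param modality a [modality_spec()].
#' @param genes list of [gene_spec()] objects.
#' @param seed integer seed.
#' @return list of class `omics_dataset`: `name`, `kind`, `matrix` (sample x
#'   feature, may contain NA), `feature_ids`, `preprocessing_state`
#'   (character vector, empty), and `signal_features` (named list, gene ->
#'   planted feature ids) for manifest cross-checks.
#' @export
generate_omics <- function(cohort, mutations, modality, genes, seed) {
  stopifnot(inherits(cohort, "cohort"), inherits(modality, "modality_spec"))
  clin <- cohort$clinical
  n <- nrow(clin)
  p <- modality$n_features
  k <- min(modality$n_latent_factors, ncol(cohort$latent))
  rng <- local_rng(child_seed(seed, paste0("omics.", modality$name)))
  on.exit(rng(), add = TRUE)

  feature_ids <- sprintf("%s_f%05d", modality$name, seq_len(p))
  type_offsets <- matrix(rnorm(length(cohort$spec$cancer_types) * p,
                               sd = modality$type_effect_sd),
                         nrow = length(cohort$spec$cancer_types),
                         dimnames = list(names(cohort$spec$cancer_types), NULL))
  loadings <- matrix(rnorm(p * k, sd = modality$latent_loading_sd), nrow = p)
  x <- type_offsets[clin$cancer_type, , drop = FALSE] +
    cohort$latent[, seq_len(k), drop = FALSE] %*% t(loadings) +
    matrix(rnorm(n * p, sd = modality$noise_sd), n, p)

  signal_features <- list()
  for (g in genes) {
    if (!(modality$name %in% g$signal_modalities) || g$effect_size == 0) next
    if (g$n_signal_features > p) {
      stop("generate_omics: gene ", g$gene, " requests ", g$n_signal_features,
           " signal features but modality ", modality$name, " has ", p)
    }
    idx_rng <- local_rng(child_seed(seed, paste0("signal.", modality$name,
                                                 ".", g$gene)))
    idx <- sort(sample.int(p, g$n_signal_features))
    idx_rng()
    mut <- mutations[clin$sample_id, g$gene] == 1
    x[mut, idx] <- x[mut, idx] + g$effect_size * modality$noise_sd
    signal_features[[g$gene]] <- feature_ids[idx]
  }

  x <- switch(modality$kind,
              continuous = x,
              bounded01 = stats::plogis(x),
              nonnegative = log1p(exp(x)))

  if (modality$missing_rate > 0 || modality$n_high_missing_samples > 0) {
    rate <- rep(modality$missing_rate, n)
    if (modality$n_high_missing_samples > 0) {
      hi <- sample.int(n, min(modality$n_high_missing_samples, n))
      rate[hi] <- pmin(0.9, 10 * modality$missing_rate)
    }
    miss <- matrix(runif(n * p), n, p) < rate
    x[miss] <- NA_real_
  }
  dimnames(x) <- list(clin$sample_id, feature_ids)
  structure(list(name = modality$name, kind = modality$kind, matrix = x,
                 feature_ids = feature_ids, preprocessing_state = character(),
                 signal_features = signal_features),
            class = "omics_dataset")
}

#' Generate survival annotations under a proportional-hazards model
#'
#' Event times are exponential with hazard proportional to
#' exp(beta_age * age + beta_burden * log10(burden + 1) + gamma . factors);
#' the linear predictor is centered before exponentiation (absorbed into the
#' baseline hazard). Censoring is independent exponential, with its rate
#' calibrated numerically so that the expected observed-event fraction is
#' 1 - `censoring_rate`.
#'
#' @param cohort a [generate_cohort()] result.
#' @param latent_factors n x k matrix of factor scores (usually
#'   `cohort$latent`).
#' @param coefficients list with `age`, `burden` (scalars) and `factors`
#'   (length-k vector).
#' @param censoring_rate target fraction censored, in [0, 1).
#' @param seed integer seed.
#' @param endpoint endpoint label attached to every sample (e.g. "OS").
#' @param baseline_hazard exponential baseline rate (per day).
#' @return data.frame: sample_id, time, event, endpoint.
#' @export
generate_survival <- function(cohort, latent_factors, coefficients,
                              censoring_rate, seed, endpoint = "OS",
                              baseline_hazard = log(2) / 730) {
  clin <- cohort$clinical
  k <- ncol(latent_factors)
  if (length(coefficients$factors) != k) {
    stop("generate_survival: 'coefficients$factors' must have length ", k)
  }
  lp <- coefficients$age * clin$age +
    coefficients$burden * log10(clin$burden + 1) +
    as.numeric(latent_factors %*% coefficients$factors)
  if (any(!is.finite(lp))) stop("generate_survival: non-finite linear predictor")
  lp <- lp - mean(lp)
  rng <- local_rng(child_seed(seed, paste0("survival.", endpoint)))
  on.exit(rng(), add = TRUE)

  rates <- baseline_hazard * exp(lp)
  te <- rexp(length(rates), rates)
  if (censoring_rate <= 0) {
    time <- te
    event <- rep(1L, length(te))
  } else {
    # E[event fraction] = mean(lambda_i / (lambda_i + r)); solve for r
    f <- function(r) mean(rates / (rates + r)) - (1 - censoring_rate)
    r <- stats::uniroot(f, lower = 1e-12, upper = 1e6,
                        tol = 1e-12)$root
    tc <- rexp(length(rates), r)
    time <- pmin(te, tc)
    event <- as.integer(te <= tc)
  }
  data.frame(sample_id = clin$sample_id, time = time, event = event,
             endpoint = endpoint, stringsAsFactors = FALSE)
}

#' Simulate a complete multi-omics study bundle
#'
#' Convenience wrapper tying the generators together into the bundle shape
#' the rest of the pipeline consumes: clinical table, mutation and CNV
#' matrices, one `omics_dataset` per modality, gene annotations derived from
#' the gene specs, and (optionally) OS and PFI survival annotations.
#'
#' @param cohort_spec a [cohort_spec()].
#' @param genes list of [gene_spec()].
#' @param modalities list of [modality_spec()].
#' @param seed master seed; component seeds are derived from it.
#' @param survival_coefficients if non-NULL, a list (`age`, `burden`,
#'   `factors`) used to generate OS and PFI endpoints (PFI uses a higher
#'   event rate, emulating the endpoint used where deaths are few).
#' @param censoring_rate target censoring fraction for OS.
#' @return a list of class `data_bundle`.
#' @export
simulate_study <- function(cohort_spec, genes, modalities, seed = 1,
                           survival_coefficients = NULL,
                           censoring_rate = 0.5) {
  cohort <- generate_cohort(cohort_spec)
  mut <- generate_mutation_data(cohort, genes, child_seed(seed, "mut"))
  omics <- lapply(modalities, function(m) {
    generate_omics(cohort, mut$mutation, m, genes, child_seed(seed, "omics"))
  })
  names(omics) <- vapply(modalities, `[[`, "", "name")
  annotation <- data.frame(
    gene = vapply(genes, `[[`, "", "gene"),
    role = vapply(genes, `[[`, "", "role"),
    stringsAsFactors = FALSE
  )
  survival <- NULL
  if (!is.null(survival_coefficients)) {
    os <- generate_survival(cohort, cohort$latent, survival_coefficients,
                            censoring_rate, child_seed(seed, "os"),
                            endpoint = "OS")
    pfi <- generate_survival(cohort, cohort$latent, survival_coefficients,
                             max(0, censoring_rate - 0.2),
                             child_seed(seed, "pfi"), endpoint = "PFI",
                             baseline_hazard = log(2) / 365)
    survival <- list(OS = os, PFI = pfi)
  }
  structure(list(cohort = cohort, clinical = cohort$clinical,
                 mutation = mut$mutation, cnv = mut$cnv, omics = omics,
                 annotation = annotation, survival = survival,
                 seed = as.integer(seed)),
            class = "data_bundle")
}
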