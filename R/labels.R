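#' Detect hypermutated samples by the 5-standard-deviation rule
#'
#' A sample is hypermutated when its non-silent somatic mutation count is
#' five or more standard deviations above the cohort mean. The mean and SD
#' are computed over all samples before any exclusion; "five or more" is
#' read inclusively (count >= mean + 5 SD). When the SD is exactly zero all
#' counts equal the mean and nothing qualifies as an outlier, so the
#' exclusion set is empty.
#'
#' @param burdens named numeric vector, sample -> non-silent mutation count.
#' @param n_sd number of standard deviations (default 5).
#' @param sd_estimator `"sample"` (n - 1 denominator, the default) or
#'   `"population"`.
#' @return character vector of excluded sample ids.
#' @export
detect_hypermutated <- function(burdens, n_sd = 5,
                                sd_estimator = c("sample", "population")) {
  sd_estimator <- match.arg(sd_estimator)
  if (length(burdens) == 0) stop("detect_hypermutated: empty input")
  if (length(burdens) < 2) stop("detect_hypermutated: need >= 2 samples")
  if (any(burdens < 0)) stop("detect_hypermutated: counts must be nonnegative")
  m <- mean(burdens)
  s <- stats::sd(burdens)
  if (sd_estimator == "population") {
    s <- s * sqrt((length(burdens) - 1) / length(burdens))
  }
  if (!is.finite(s) || s == 0) return(character())
  names(burdens)[burdens >= m + n_sd * s]
}

#' Merge cancer-gene sources into a single annotated gene set
#'
#' Takes per-source role annotations (vocabulary `oncogene`, `tsg`,
#' `fusion`), unions the genes across sources, resolves conflicting
#' oncogene/TSG annotations to role `both`, and drops genes whose only
#' annotation anywhere is `fusion`. A gene with a fusion annotation plus an
#' oncogene or TSG annotation keeps the substantive role.
#'
#' @param sources data.frame with columns `source`, `gene`, `role`.
#' @return data.frame with columns `gene`, `role`
#'   (oncogene/tsg/both/fusion-dropped genes absent), `sources`
#'   (comma-separated), sorted by gene symbol.
#' @export
merge_gene_sets <- function(sources) {
  stopifnot(all(c("source", "gene", "role") %in% names(sources)))
  bad <- !(sources$role %in% c("oncogene", "tsg", "fusion"))
  if (any(bad)) {
    i <- which(bad)[1]
    stop("merge_gene_sets: unknown role '", sources$role[i],
         "' for gene ", sources$gene[i], " in source ", sources$source[i])
  }
  out <- lapply(split(sources, sources$gene), function(d) {
    roles <- unique(d$role)
    substantive <- setdiff(roles, "fusion")
    if (length(substantive) == 0) return(NULL) # fusion-only: dropped
    role <- if (all(c("oncogene", "tsg") %in% substantive)) "both"
            else substantive
    data.frame(gene = d$gene[1], role = role,
               sources = paste(sort(unique(d$source)), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(out)) {
    return(data.frame(gene = character(), role = character(),
                      sources = character(), stringsAsFactors = FALSE))
  }
  out <- out[order(out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build binary mutation labels for a target gene
#'
#' A sample is positive when it carries a non-silent somatic variant in the
#' target gene, or a qualifying copy-number event: gains for oncogenes,
#' losses for tumor suppressors, either for dual-annotated (`both`) genes.
#' By default only deep events qualify (+2 / -2 thresholded calls);
#' `include_shallow = TRUE` widens this to +/-1. Hypermutated samples are
#' removed before labeling; every remaining sample without a qualifying
#' event is labeled 0.
#'
#' @param gene target gene symbol.
#' @param role the gene's driver role (`oncogene`, `tsg`, `both`).
#' @param mutations binary sample x gene matrix.
#' @param cnv integer sample x gene matrix of thresholded calls in -2..2.
#' @param excluded character vector of samples to drop (hypermutated).
#' @param include_shallow also count +/-1 calls as gains/losses.
#' @return list of class `label_set`: `gene`, `labels` (named 0/1 vector on
#'   included samples), `provenance` (positives from variants / from CNV
#'   only).
#' @export
build_mutation_labels <- function(gene, role, mutations, cnv, excluded =
                                    character(), include_shallow = FALSE) {
  if (!(gene %in% colnames(mutations)) || !(gene %in% colnames(cnv))) {
    stop("build_mutation_labels: gene ", gene, " absent from input matrices")
  }
  samples <- setdiff(rownames(mutations), excluded)
  mut <- mutations[samples, gene] == 1
  calls <- cnv[samples, gene]
  gain_cut <- if (include_shallow) 1L else 2L
  loss_cut <- if (include_shallow) -1L else -2L
  gain <- calls >= gain_cut
  loss <- calls <= loss_cut
  cnv_pos <- (gain & role %in% c("oncogene", "both")) |
             (loss & role %in% c("tsg", "both"))
  labels <- as.integer(mut | cnv_pos)
  names(labels) <- samples
  structure(list(gene = gene, role = role, labels = labels,
                 provenance = c(variant = sum(mut),
                                cnv_only = sum(cnv_pos & !mut))),
            class = "label_set")
}

#' Determine the valid cancer types for a target gene
#'
#' A cancer type is valid for a gene when it has at least `min_mutated`
#' positively labeled samples and at least `min_fraction` of its samples
#' positive (both bounds inclusive). Genes with no valid cancer type are
#' flagged for exclusion from target lists.
#'
#' @param labels named 0/1 vector (sample -> label).
#' @param cancer_types named character vector (sample -> cancer type),
#'   covering at least the labeled samples.
#' @param min_mutated minimum positive count (default 15).
#' @param min_fraction minimum positive fraction (default 0.05).
#' @return character vector of valid cancer types (possibly empty).
#' @export
compute_valid_cancer_types <- function(labels, cancer_types,
                                       min_mutated = 15,
                                       min_fraction = 0.05) {
  ct <- cancer_types[names(labels)]
  pos <- tapply(labels, ct, sum)
  tot <- tapply(labels, ct, length)
  ok <- pos >= min_mutated & pos / tot >= min_fraction
  sort(names(pos)[ok])
}

#' Select control gene sets: random or most-mutated
#'
#' `most_mutated` returns the `n_genes` genes with the highest total
#' non-silent mutation counts, ties broken by gene-symbol order. `random`
#' draws uniformly without replacement from `pool` (callers pre-filter the
#' pool to genes with at least one valid cancer type), reproducibly by seed.
#'
#' @param mutations binary sample x gene matrix.
#' @param n_genes number of genes to return.
#' @param mode `"random"` or `"most_mutated"`.
#' @param pool candidate genes for random mode (default: all columns).
#' @param seed integer seed (random mode).
#' @return character vector of gene symbols.
#' @export
build_control_gene_sets <- function(mutations, n_genes,
                                    mode = c("random", "most_mutated"),
                                    pool = colnames(mutations), seed = 1) {
  mode <- match.arg(mode)
  if (mode == "most_mutated") {
    counts <- colSums(mutations)
    if (length(counts) < n_genes) {
      stop("build_control_gene_sets: pool of ", length(counts),
           " genes is smaller than n_genes = ", n_genes)
    }
    ord <- order(-counts, colnames(mutations))
    return(colnames(mutations)[ord][seq_len(n_genes)])
  }
  if (length(pool) < n_genes) {
    stop("build_control_gene_sets: pool of ", length(pool),
         " genes is smaller than n_genes = ", n_genes)
  }
  if (length(pool) == n_genes) return(pool)
  rng <- local_rng(child_seed(seed, "control_genes"))
  on.exit(rng(), add = TRUE)
  sample(pool, n_genes)
}
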