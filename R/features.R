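#' Column-wise z-score standardization
#'
#' Each column is transformed to (x - mean) / sd with statistics computed on
#' `fit_samples` only and applied to all rows. In the default whole-dataset
#' mode (`fit_samples = NULL`) the statistics come from every sample, which
#' mirrors fitting the scaler before splitting; pass training-fold rows for
#' a leakage-safe variant. Zero-variance columns map to all zeros.
#'
#' @param matrix numeric matrix (samples x features).
#' @param fit_samples row names or indices to fit on (default: all rows).
#' @param sd_estimator `"sample"` (n - 1, default) or `"population"`.
#' @param scaler optionally, a previously fitted scaler to re-apply.
#' @return list: `matrix` (standardized), `scaler` (list of `center`, `scale`).
#' @export
standardize <- function(matrix, fit_samples = NULL,
                        sd_estimator = c("sample", "population"),
                        scaler = NULL) {
  sd_estimator <- match.arg(sd_estimator)
  if (is.null(scaler)) {
    fit <- if (is.null(fit_samples)) matrix else matrix[fit_samples, , drop = FALSE]
    if (nrow(fit) == 0) stop("standardize: 'fit_samples' is empty")
    center <- colMeans(fit)
    scale <- apply(fit, 2, stats::sd)
    if (sd_estimator == "population") {
      scale <- scale * sqrt((nrow(fit) - 1) / nrow(fit))
    }
    scaler <- list(center = center, scale = scale)
  }
  s <- scaler$scale
  s[!is.finite(s) | s == 0] <- Inf # zero-variance columns -> all zeros
  out <- sweep(sweep(matrix, 2, scaler$center), 2, s, "/")
  list(matrix = out, scaler = scaler)
}

#' Select the top-k features by mean absolute deviation
#'
#' Ranks columns by mean absolute deviation about the column mean,
#' mean(|x - mean(x)|), computed on unstandardized values (standardizing
#' first would equalize spread and make the ranking meaningless). Ties are
#' broken by column order; `k >= ncol` returns all columns.
#'
#' @param matrix numeric matrix (samples x features); NAs ignored per column.
#' @param k number of columns to keep (>= 1).
#' @return integer vector of selected column indices, in original column
#'   order.
#' @export
select_top_mad <- function(matrix, k) {
  if (k < 1) stop("select_top_mad: 'k' must be >= 1")
  if (k >= ncol(matrix)) return(seq_len(ncol(matrix)))
  mad_mean <- apply(matrix, 2, function(x) {
    x <- x[!is.na(x)]
    mean(abs(x - mean(x)))
  })
  sort(order(-mad_mean)[seq_len(k)])
}

#' Clean missing values from a methylation-like matrix
#'
#' Three steps: (1) drop the `n_drop` samples with the most missing values
#' (ties broken by sample order; skipped entirely when no value is missing,
#' unless `drop_when_clean = TRUE`); (2) mean-impute columns with exactly
#' 1 or 2 values missing after step 1; (3) drop columns with 3 or more
#' values still missing. The result contains no missing values.
#'
#' @param matrix numeric matrix (samples x features) possibly with NAs.
#' @param n_drop number of highest-missing samples to remove (default 10).
#' @param drop_when_clean drop `n_drop` samples even when nothing is missing.
#' @return list: `matrix` (complete), `dropped_samples`, `dropped_features`.
#' @export
impute_methylation <- function(matrix, n_drop = 10, drop_when_clean = FALSE) {
  miss_per_sample <- rowSums(is.na(matrix))
  dropped_samples <- character()
  if ((max(miss_per_sample) > 0 || drop_when_clean) && n_drop > 0) {
    n_drop <- min(n_drop, nrow(matrix))
    ord <- order(-miss_per_sample) # stable: ties keep sample order
    drop_idx <- sort(ord[seq_len(n_drop)])
    dropped_samples <- rownames(matrix)[drop_idx]
    matrix <- matrix[-drop_idx, , drop = FALSE]
  }
  miss_per_col <- colSums(is.na(matrix))
  impute_cols <- which(miss_per_col >= 1 & miss_per_col <= 2)
  for (j in impute_cols) {
    x <- matrix[, j]
    matrix[is.na(x), j] <- mean(x, na.rm = TRUE)
  }
  drop_cols <- which(miss_per_col >= 3)
  dropped_features <- colnames(matrix)[drop_cols]
  if (length(drop_cols)) matrix <- matrix[, -drop_cols, drop = FALSE]
  stopifnot(!anyNA(matrix))
  list(matrix = matrix, dropped_samples = dropped_samples,
       dropped_features = dropped_features)
}

#' Principal-component compression
#'
#' Fits a PCA basis on `fit_samples` (whole matrix by default) and projects
#' all samples onto the top min(p, k, n_fit - 1) components, ordered by
#' decreasing explained variance. The matrix is expected to be standardized
#' already; columns are re-centered on the fit-sample means so the scores
#' are exact projections. Component signs are fixed by making each
#' component's largest-magnitude loading positive.
#'
#' @param matrix numeric matrix (samples x features), standardized.
#' @param k requested number of components (>= 1).
#' @param fit_samples rows to fit the basis on (default: all).
#' @param basis optionally, a previously fitted basis to re-apply.
#' @return list: `scores` (samples x n_components), `basis` (list with
#'   `rotation`, `center`, `sdev`).
#' @export
pca_compress <- function(matrix, k, fit_samples = NULL, basis = NULL) {
  if (is.null(basis)) {
    if (k < 1) stop("pca_compress: 'k' must be >= 1")
    fit <- if (is.null(fit_samples)) matrix else matrix[fit_samples, , drop = FALSE]
    ncomp <- min(ncol(fit), k, nrow(fit) - 1)
    pc <- stats::prcomp(fit, center = TRUE, scale. = FALSE, rank. = ncomp)
    rotation <- pc$rotation[, seq_len(ncomp), drop = FALSE]
    flip <- apply(rotation, 2, function(v) sign(v[which.max(abs(v))]))
    flip[flip == 0] <- 1
    rotation <- sweep(rotation, 2, flip, "*")
    basis <- list(rotation = rotation, center = pc$center,
                  sdev = pc$sdev[seq_len(ncomp)])
  }
  scores <- sweep(matrix, 2, basis$center) %*% basis$rotation
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  list(scores = scores, basis = basis)
}

#' Build the covariate block: one-hot cancer type + log10 burden
#'
#' One column per cancer type present among `included_samples` plus a
#' log10(burden + 1) column (the +1 offset admits zero mutation counts).
#' For survival models an age column can be added.
#'
#' @param clinical data.frame with `sample_id`, `cancer_type`, `burden`
#'   (and `age` if `include_age`).
#' @param included_samples sample ids to build rows for.
#' @param include_age also include an age column.
#' @return numeric matrix (samples x covariates) with named columns.
#' @export
build_covariates <- function(clinical, included_samples, include_age = FALSE) {
  rownames(clinical) <- clinical$sample_id
  clin <- clinical[included_samples, , drop = FALSE]
  types <- sort(unique(clin$cancer_type))
  onehot <- sapply(types, function(ct) as.numeric(clin$cancer_type == ct))
  onehot <- base::matrix(onehot, nrow = nrow(clin),
                         dimnames = list(included_samples,
                                         paste0("type_", types)))
  out <- cbind(onehot, log10_burden = log10(clin$burden + 1))
  if (include_age) out <- cbind(out, age = clin$age)
  out
}

#' Assemble a (multi-)omics feature matrix with covariates
#'
#' Concatenates the given datasets column-wise in the given order, each
#' preprocessed per `mode`: `"raw"` selects the top `per_dataset_k` features
#' by mean absolute deviation and standardizes them; `"pca"` standardizes
#' and keeps the top `per_dataset_k` principal-component scores. The
#' covariate block is always appended last and column provenance is
#' recorded for coefficient reporting.
#'
#' @param datasets named list of `omics_dataset` objects (complete, no NAs)
#'   sharing the sample axis.
#' @param covariates covariate matrix from [build_covariates()] on the same
#'   samples.
#' @param mode `"raw"` or `"pca"`.
#' @param per_dataset_k named vector or single number: features/components
#'   per dataset (default: all).
#' @param fit_samples rows used to fit scalers/bases (default: all).
#' @return list of class `feature_matrix`: `predictors` (samples x p),
#'   `covariates`, `matrix` (cbind of both), `provenance` (column ->
#'   modality or "covariate").
#' @export
assemble_feature_matrix <- function(datasets, covariates,
                                    mode = c("raw", "pca"),
                                    per_dataset_k = Inf,
                                    fit_samples = NULL) {
  mode <- match.arg(mode)
  sample_sets <- lapply(datasets, function(d) rownames(d$matrix))
  ref <- sample_sets[[1]]
  for (i in seq_along(sample_sets)[-1]) {
    if (!setequal(ref, sample_sets[[i]])) {
      diff <- union(setdiff(ref, sample_sets[[i]]),
                    setdiff(sample_sets[[i]], ref))
      stop("assemble_feature_matrix: sample-axis mismatch between '",
           names(datasets)[1], "' and '", names(datasets)[i],
           "'; differing samples: ", paste(utils::head(diff, 5), collapse = ", "))
    }
  }
  if (!setequal(ref, rownames(covariates))) {
    stop("assemble_feature_matrix: covariate sample axis mismatch")
  }
  get_k <- function(nm) {
    if (length(per_dataset_k) == 1 && is.null(names(per_dataset_k))) {
      per_dataset_k
    } else {
      if (!nm %in% names(per_dataset_k)) Inf else per_dataset_k[[nm]]
    }
  }
  blocks <- list()
  provenance <- character()
  for (nm in names(datasets)) {
    x <- datasets[[nm]]$matrix[ref, , drop = FALSE]
    if (anyNA(x)) stop("assemble_feature_matrix: dataset '", nm,
                       "' contains missing values; impute first")
    if (ncol(x) == 0) stop("assemble_feature_matrix: dataset '", nm,
                           "' has no features left after preprocessing")
    k <- get_k(nm)
    if (mode == "raw") {
      keep <- select_top_mad(x, min(k, ncol(x)))
      x <- standardize(x[, keep, drop = FALSE], fit_samples)$matrix
    } else {
      x <- standardize(x, fit_samples)$matrix
      x <- pca_compress(x, min(k, ncol(x)), fit_samples)$scores
      colnames(x) <- paste0(nm, "_", colnames(x))
    }
    blocks[[nm]] <- x
    provenance <- c(provenance, rep(nm, ncol(x)))
  }
  predictors <- do.call(cbind, blocks)[ref, , drop = FALSE]
  covariates <- covariates[ref, , drop = FALSE]
  provenance <- c(provenance, rep("covariate", ncol(covariates)))
  full <- cbind(predictors, covariates)
  names(provenance) <- colnames(full)
  structure(list(predictors = predictors, covariates = covariates,
                 matrix = full, provenance = provenance),
            class = "feature_matrix")
}
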