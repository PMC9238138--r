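write_tsv_matrix <- function(x, path, id_col = "sample_id") {
  dt <- data.table::as.data.table(x, keep.rownames = id_col)
  data.table::fwrite(dt, path, sep = "\t")
}

read_tsv_matrix <- function(path, id_col = "sample_id") {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  if (names(dt)[1] != id_col) {
    stop("read_tsv_matrix: malformed header in ", path,
         " (first column must be '", id_col, "', found '", names(dt)[1], "')")
  }
  ids <- as.character(dt[[1]])
  if (anyDuplicated(ids)) {
    stop("read_tsv_matrix: duplicate ids in ", path, ": ",
         paste(utils::head(unique(ids[duplicated(ids)]), 3), collapse = ", "))
  }
  m <- as.matrix(dt[, -1])
  if (!is.numeric(m)) {
    bad <- which(!vapply(dt[, -1], is.numeric, TRUE))[1]
    stop("read_tsv_matrix: non-numeric cells in ", path,
         ", column '", names(dt)[-1][bad], "'")
  }
  rownames(m) <- ids
  m
}

#' Write a data bundle to delimited tables
#'
#' Writes the formats the pipeline reads back: one samples x features TSV
#' per modality (header row of feature ids, first column of sample ids), a
#' binary mutation TSV (samples x genes), a CNV TSV (genes x samples,
#' integers -2..2), a clinical TSV, a gene-annotation TSV, survival TSVs
#' when present, and a JSON sidecar recording the cohort spec and seed.
#'
#' @param bundle a `data_bundle`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  data.table::fwrite(bundle$clinical, file.path(dir, "clinical.tsv"),
                     sep = "\t")
  write_tsv_matrix(bundle$mutation, file.path(dir, "mutation.tsv"))
  write_tsv_matrix(t(bundle$cnv), file.path(dir, "cnv.tsv"), id_col = "gene")
  data.table::fwrite(bundle$annotation, file.path(dir, "annotation.tsv"),
                     sep = "\t")
  for (nm in names(bundle$omics)) {
    write_tsv_matrix(bundle$omics[[nm]]$matrix,
                     file.path(dir, paste0("omics_", nm, ".tsv")))
  }
  if (!is.null(bundle$survival)) {
    for (ep in names(bundle$survival)) {
      data.table::fwrite(bundle$survival[[ep]],
                         file.path(dir, paste0("survival_", tolower(ep), ".tsv")),
                         sep = "\t")
    }
  }
  sidecar <- list(seed = bundle$seed,
                  cohort_spec = unclass(bundle$cohort$spec),
                  modalities = lapply(bundle$omics, function(d) {
                    list(name = d$name, kind = d$kind,
                         n_features = length(d$feature_ids))
                  }))
  jsonlite::write_json(sidecar, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a study bundle from delimited tables
#'
#' Loads the tables written by [write_bundle()] (or equivalently formatted
#' external tables), validates ids, and intersects the sample axes across
#' the mutation data and the selected modalities, reporting per-cancer-type
#' dropped-sample counts as an attribute.
#'
#' @param dir directory of tables.
#' @param modalities modality names to load (default: every `omics_*.tsv`).
#' @return a `data_bundle`; attribute `dropped_by_type` tabulates samples
#'   outside the intersection.
#' @export
read_tables <- function(dir, modalities = NULL) {
  clinical <- as.data.frame(data.table::fread(file.path(dir, "clinical.tsv")))
  if (anyDuplicated(clinical$sample_id)) {
    stop("read_tables: duplicate sample ids in clinical table")
  }
  mutation <- read_tsv_matrix(file.path(dir, "mutation.tsv"))
  cnv <- t(read_tsv_matrix(file.path(dir, "cnv.tsv"), id_col = "gene"))
  annotation <- as.data.frame(data.table::fread(file.path(dir, "annotation.tsv")))
  files <- list.files(dir, pattern = "^omics_.*\\.tsv$")
  found <- sub("^omics_(.*)\\.tsv$", "\\1", files)
  if (is.null(modalities)) modalities <- found
  missing <- setdiff(modalities, found)
  if (length(missing)) {
    stop("read_tables: no table for modalit", if (length(missing) > 1) "ies" else "y",
         " ", paste(missing, collapse = ", "))
  }
  omics <- lapply(modalities, function(nm) {
    m <- read_tsv_matrix(file.path(dir, paste0("omics_", nm, ".tsv")))
    kind <- if (all(m >= 0 & m <= 1, na.rm = TRUE)) "bounded01" else "continuous"
    structure(list(name = nm, kind = kind, matrix = m,
                   feature_ids = colnames(m),
                   preprocessing_state = character()),
              class = "omics_dataset")
  })
  names(omics) <- modalities
  common <- Reduce(intersect, c(list(clinical$sample_id, rownames(mutation)),
                                lapply(omics, function(d) rownames(d$matrix))))
  if (length(common) == 0) {
    stop("read_tables: empty intersection across mutation data and ",
         paste(modalities, collapse = ", "))
  }
  dropped <- setdiff(clinical$sample_id, common)
  dropped_by_type <- table(clinical$cancer_type[match(dropped,
                                                      clinical$sample_id)])
  survival <- NULL
  for (ep in c("os", "pfi")) {
    f <- file.path(dir, paste0("survival_", ep, ".tsv"))
    if (file.exists(f)) {
      survival[[toupper(ep)]] <- as.data.frame(data.table::fread(f))
    }
  }
  bundle <- structure(list(clinical = clinical, mutation = mutation,
                           cnv = cnv, omics = omics, annotation = annotation,
                           survival = survival, seed = NA_integer_),
                      class = "data_bundle")
  attr(bundle, "intersection") <- common
  attr(bundle, "dropped_by_type") <- dropped_by_type
  bundle
}

#' Write experiment results, calls and summary grid
#'
#' Writes the long-format results TSV, the comparison-calls TSV and the
#' per-gene x modality grid TSV, plus a JSON run manifest containing the
#' resolved configuration and its content hash. Numeric fields round-trip
#' bit-exactly (17 significant digits).
#'
#' @param results,calls,grid data.frames (calls/grid may be NULL).
#' @param out_dir output directory.
#' @param config the resolved `run_config` to record.
#' @return named vector of written paths, invisibly.
#' @export
write_results <- function(results, calls = NULL, grid = NULL, out_dir,
                          config = default_config()) {
  if (is.null(results) || nrow(results) == 0) {
    stop("write_results: empty results")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(results = file.path(out_dir, "results.tsv"))
  fwrite17 <- function(d, p) {
    num <- vapply(d, is.numeric, TRUE)
    d[num] <- lapply(d[num], function(x) sprintf("%.17g", x))
    data.table::fwrite(d, p, sep = "\t")
  }
  fwrite17(results, paths["results"])
  if (!is.null(calls)) {
    paths["calls"] <- file.path(out_dir, "calls.tsv")
    fwrite17(calls, paths["calls"])
  } else {
    paths["calls"] <- file.path(out_dir, "calls.tsv")
    data.table::fwrite(data.frame(gene = character(),
                                  modality_set = character(),
                                  mean_delta_aupr = numeric(),
                                  p_value = numeric(), q_value = numeric()),
                       paths["calls"], sep = "\t")
  }
  if (!is.null(grid)) {
    paths["grid"] <- file.path(out_dir, "grid.tsv")
    fwrite17(grid, paths["grid"])
  }
  cfg_path <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(unclass(config), cfg_path)
  manifest <- list(config_file = basename(cfg_path),
                   config_hash = unname(tools::md5sum(cfg_path)),
                   n_results = nrow(results),
                   written = basename(unname(paths)))
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Re-read a results TSV written by [write_results()]
#' @param path file path.
#' @return data.frame with numeric columns restored.
#' @export
read_results <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t"))
}

#' Summarize a benchmark run
#'
#' Produces the volcano table (per gene x modality: mean delta AUPR and
#' -log10 p), a per-modality distribution summary of the mean delta AUPR
#' with a percentile-bootstrap 95% confidence interval of the median
#' (2000 resamples, seeded), and per-modality counts of well-predicted
#' genes.
#'
#' @param calls FDR-corrected calls from [baseline_comparison()] or
#'   [call_summary_grid()].
#' @param n_boot bootstrap resamples (default 2000).
#' @param seed integer seed for the bootstrap.
#' @return list: `volcano`, `modality_summary`, `well_predicted_counts`.
#' @export
summarize_run <- function(calls, n_boot = 2000, seed = 1) {
  volcano <- data.frame(gene = calls$gene, modality_set = calls$modality_set,
                        mean_delta_aupr = calls$mean_delta_aupr,
                        neg_log10_p = -log10(pmax(calls$p_value, 1e-300)),
                        stringsAsFactors = FALSE)
  rng <- local_rng(child_seed(seed, "bootstrap"))
  on.exit(rng(), add = TRUE)
  modality_summary <- do.call(rbind, lapply(split(calls, calls$modality_set),
                                            function(d) {
    x <- d$mean_delta_aupr
    boot <- replicate(n_boot, stats::median(sample(x, replace = TRUE)))
    data.frame(modality_set = d$modality_set[1], n_genes = length(x),
               median_delta_aupr = stats::median(x),
               ci_lower = unname(stats::quantile(boot, 0.025)),
               ci_upper = unname(stats::quantile(boot, 0.975)),
               stringsAsFactors = FALSE)
  }))
  rownames(modality_summary) <- NULL
  counts <- stats::aggregate(well_predicted ~ modality_set, data = calls, FUN = sum)
  names(counts)[2] <- "n_well_predicted"
  list(volcano = volcano, modality_summary = modality_summary,
       well_predicted_counts = counts)
}

#' Load a run configuration from YAML
#'
#' Unknown keys are rejected; values override [default_config()] defaults.
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(default_config, vals)
}
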