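Package: omicbench
Title: Benchmarking -Omics Readouts as Predictors of Cancer Mutation Status and Survival
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A benchmark pipeline for quantifying how well different -omics
    readouts (expression-like, methylation-like arrays, protein-array-like,
    miRNA-like, mutational-signature exposures) predict cancer driver-gene
    mutation status and patient survival. Implements binary mutation-label
    construction from non-silent variants and thresholded copy-number calls
    with driver-role rules, a hypermutated-sample filter, cancer-type
    validity filters, stratified cross-validation with a cancer-type
    stratified permuted-label null, elastic-net logistic and Cox models with
    nested grid search, average-precision / AUROC / censored-concordance
    metrics, paired fold-wise t-tests with Benjamini-Hochberg correction,
    multi-omics feature concatenation, and a synthetic multi-omics cohort
    generator with planted, controllable mutation signatures so the whole
    pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    glmnet,
    survival,
    data.table,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
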