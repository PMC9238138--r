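---
title: "Benchmarking -omics readouts as predictors of mutation status: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking -omics readouts as predictors of mutation status: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

When a cancer driver gene is mutated, the perturbation can leave a
signature in many layers of cellular readout: transcript abundance, DNA
methylation, protein levels, microRNA expression, even the genome-wide
pattern of somatic mutations. Which layer carries the signal — and whether
several layers carry *the same* signal — matters for anyone choosing a
functional readout for a study. `omicbench` frames this as a supervised
benchmark: for each target gene, train a classifier to predict the gene's
binary mutation status from each -omics readout, score it against a
carefully matched permuted-label null, and compare readouts with paired
fold-wise statistics. A companion task predicts censored patient survival
from the same readouts. Because the interesting properties of the pipeline
(calibration of the null, power against planted signal, modality
specificity, behaviour under redundant signal) cannot be established on
real data where ground truth is unknown, the package ships a synthetic
cohort generator whose planted structure makes every one of those
properties testable.

## Label construction

A sample is a positive for a target gene when it has a non-silent somatic
variant in the gene, or a qualifying thresholded copy-number call: gains
for oncogenes, deep losses for tumor suppressors, either for genes
annotated with both roles. Three boundary choices are deliberate:

* **CNV thresholds.** Only deep events (+2 / −2 in the −2..2 call scale)
  qualify by default; a configuration switch widens this to shallow ±1
  calls. Deep calls are the conservative reading of thresholded
  copy-number data.
* **Dual-role genes.** For `role = "both"` the positive set is the union
  of the gain and loss rules. Role conflicts between annotation sources
  resolve to `both`.
* **Hypermutated samples** are removed before labeling: a sample is
  hypermutated when its non-silent mutation count is at least
  mean + 5 SD, with mean and SD computed over all samples before any
  exclusion and SD the sample (n−1) estimator. "At least" is read
  inclusively. A consequence worth knowing: a single outlier among n
  samples can be at most (n−1)/√n SDs from the mean, so the filter only
  bites in reasonably large cohorts, which is the setting it is meant for.

Per gene, only "valid" cancer types enter the experiment: those with at
least 15 positive samples *and* at least 5% positive (both inclusive).
Genes with no valid type are dropped from target lists.

## Features

Each modality is reduced to a samples × features block and concatenated
with a covariate block (one-hot cancer type and log10 of the non-silent
mutation count, with a +1 offset so zero counts are admissible; survival
models add age):

* **Raw mode** keeps the top-k features by mean absolute deviation about
  the mean — the literal mean-|x − mean| statistic, not the median-based
  robust MAD — computed on unstandardized values, then z-scores them.
  Selecting after standardization would be meaningless, since z-scoring
  equalizes spread.
* **PCA mode** z-scores, then keeps the top min(p, k, n−1) principal
  component scores. Component signs are pinned by making each component's
  largest-magnitude loading positive, so results are reproducible across
  BLAS implementations.
* **Methylation-style missingness** is cleaned by dropping the 10 samples
  with the most missing values (skipped when nothing is missing),
  mean-imputing probes with 1 or 2 missing values, and dropping probes
  with 3 or more. Note the interplay with missingness structure: this rule
  presumes missingness is concentrated in few probes and samples. Under
  uniform random missingness at rate r, a probe expects n·r missing
  entries, so at n = 2000 even r = 0.5% would delete essentially every
  probe. The synthetic cohorts therefore default to r values that keep the
  expected per-probe missing count near 1, which is also the regime the
  rule was designed for.
* **Fit scope.** By default scalers and PCA bases are fitted on all
  included samples before splitting (`fit_scope = "paper_faithful"`, the
  whole-dataset convention of the benchmark this package implements). A
  `leakage_safe` mode refits them inside each training fold; the test
  suite uses it to confirm the transform machinery respects fold
  boundaries.

## The classifier and its objective

The model is elastic-net logistic regression. With `alpha` the overall
penalty strength and `l1_ratio` the L1 fraction, the fitted weights
minimize

    mean NLL(w, b) + alpha * ( l1_ratio * ||w||_1
                             + (1 - l1_ratio)/2 * ||w||_2^2 )

with the intercept unpenalized. Two parameterization notes. First, the
objective is stated on the mean-log-likelihood scale; the sum-scale form
differs only by rescaling `alpha` by n. Second, the L2 term is the
*squared* norm — the standard elastic net. (Some write-ups of this penalty
omit the square typographically; the squared form is what the cited
implementations optimize and what makes the penalty strongly convex.)
Naming follows the mutation-prediction literature: `alpha` is the
strength and `l1_ratio` (often written λ there) the mixing weight — the
inverse of the glmnet convention, where strength is `lambda` and mixing is
`alpha`.

Fitting is delegated to glmnet's coordinate descent, with the mapping
`glmnet lambda = alpha`, `glmnet alpha = l1_ratio`, internal
standardization disabled (features arrive standardized; covariates are
penalized like predictors unless configured otherwise), and a short
warm-start path ending at the requested strength. Any optimizer satisfying
the oracle checks in the test suite would do; the suite verifies the
returned optimum against an unpenalized maximum-likelihood fit (alpha = 0)
and against a dense brute-force grid search of the penalized objective on
tiny instances. The survival model is the analogous elastic-net Cox
regression: mean-scaled negative log partial likelihood (Breslow tie
handling) plus the same penalty, fitted by glmnet's coxnet. For degenerate
instances too small for coxnet to initialize (a handful of samples or
events), the same objective is minimized directly by a generic optimizer
so the model surface keeps its contract down to n = 2.

## Evaluation design

Each gene × modality experiment runs **two replicates of stratified 4-fold
cross-validation** — eight train/test splits, stratified on the joint
(cancer type, sample type) stratum, with strata smaller than the fold
count merged into their cancer type's largest stratum. Hyperparameters are
chosen per outer fold by **3-fold inner cross-validation** over the grid
`l1_ratio ∈ {0, 0.05, 0.1, 0.3, 0.5, 0.7, 0.9, 1}` ×
`alpha ∈ {1e-4, 1e-3, 0.01, 0.1, 1, 10}` (48 pairs), scored by mean inner
AUPR; ties break toward smaller `alpha`, then larger `l1_ratio` (prefer
the less-penalized, sparser model only as a last resort). Inner folds with
a single class are skipped with a warning; outer folds whose test set is
single-class are dropped.

The **permuted-label null** is the heart of the benchmark. For every
split, labels are permuted separately in the training and the test set,
and independently within each cancer type, so per-(type × side) positive
counts are preserved exactly and a classifier that merely learns
cancer-type base rates gains nothing. The permuted condition re-runs the
full hyperparameter search: the null model must enjoy the same
model-selection flexibility as the real one, otherwise the comparison
would be biased in the real model's favor.

Metrics are **average precision** (AUPR; one precision–recall point per
distinct score, so tied scores are grouped — with constant scores the AUPR
is exactly the prevalence) and **AUROC** (Mann–Whitney with ties counted
half). Survival uses **Harrell's censored concordance**: admissible pairs
require the earlier sample to have an observed event and a strictly
earlier time; tied risk scores count half. All three are verified against
exhaustive enumeration in the tests.

Comparisons are **paired fold-wise t-tests** (7 df in the 2×4 design) on
per-fold AUPR differences, two-sided. When all deltas are exactly zero,
p = 1; nonzero deltas with zero variance get a 1e-12 variance floor and a
"degenerate" flag rather than a silent NaN. Multiple testing uses
Benjamini–Hochberg, corrected **within each modality family** for the
baseline comparisons and **within each gene** for the cross-modality
equivalence tests (correction families are a genuinely open choice; the
within-gene family makes the equivalence call a per-gene statement, which
is how the summary grid is read). A gene is **well-predicted** in a
modality when it beats the permuted baseline at corrected p < 0.001 *and*
the mean delta is positive — the sign guard matters because a gene
significantly *worse* than its null is a false-positive sentinel, not a
discovery. The **equivalent-to-best** flag marks modalities not
significantly different (corrected p ≥ 0.05) from the best-performing
modality for that gene.

Survival experiments use overall survival as the endpoint except in nine
cancer types with few observed deaths (BRCA, DLBC, LGG, PCPG, PRAD, READ,
TGCT, THCA, THYM), which use progression-free intervals; the map is
configurable. The Cox grid defaults to the wider strength grid
`{0, 1e-5, 1e-4, 5e-4, 0.001, 0.005, 0.01, 0.05, 0.1, 0.5, 1, 10, 100,
1000}`, scored by inner c-index, with a covariate-only baseline fitted
under the identical protocol.

## The synthetic cohort generator

The generator is a Gaussian latent-factor model chosen so that the
detectability of planted signal by a linear classifier is analytically
controllable:

* Cohort: cancer types and sample types drawn from stated proportions;
  log-normal non-silent mutation burden with a hypermutated subpopulation
  whose burden is multiplied (default ×10) *and* whose per-gene mutation
  probability p is inflated to 1 − (1 − p)^m — hypermutated samples are
  mutated in everything, which is exactly the covariance between burden
  and labels the 5-SD filter exists to remove; ages normal, clipped to
  [18, 100]; k latent factor scores per sample (default 5) shared by all
  modalities.
* Modalities: per-(cancer type, feature) baseline offsets (sd 0.5), the
  shared factors through modality-specific loadings (sd 0.3), and iid
  noise (sd 1). A gene's signature adds `effect_size` × noise-sd to a
  fixed random subset of features in mutated samples. Methylation-like
  matrices pass the latent values through a logistic map to [0, 1];
  signature-exposure-like matrices through softplus. Because the latent
  factors are shared, "the same signal drives two modalities" is the
  natural state of a dual-planted gene, which is what the redundancy
  study exploits.
* CNV calls are drawn independently of point mutations (gains with the
  gene's gain probability, deep losses with its loss probability, shallow
  ±1 background at 5%), keeping the oncogene/TSG label-rule cases
  separable in tests.
* Survival: exponential event times with hazard proportional to
  exp(β_age·age + β_burden·log10(burden+1) + γ·factors), linear predictor
  centered into the baseline hazard, and independent exponential censoring
  whose rate is solved numerically so the expected event fraction matches
  the target.
* Seeds: a single master seed expands into per-component child seeds by a
  fixed multiplicative-hash derivation (`child_seed`), so any component
  can be regenerated independently and all generators are pure functions
  of (spec, seed).

What the generator does *not* emulate: real marginal distributions of any
TCGA platform, probe-level annotation or genomic coordinates, tumor
purity, subclonality, or nonlinear mutation signatures. Passing the
benchmark's tests therefore demonstrates that the *pipeline* is calibrated
and powerful under a linear additive world — it says nothing about how
much signal any real readout carries.

## Study conditions and problem sizes

The canned studies (`study_null_calibration`, `study_power_specificity`,
`study_redundancy`, `study_survival_gain`) fix the conditions the
package's guarantees are stated under: cohorts of n = 2000 with three
cancer types (0.4/0.35/0.25), mutation prevalence 0.25 per type, planted
effect size 2 (in noise-sd units) over 20 of 100 features, 2%
hypermutated samples at ×10 burden, and survival coefficients
β_age = 0.03 per year, β_burden = 0.5 per log10 count,
γ = (0.8, −0.8, 0.5, 0, 0) with 40% censoring. Effect size 2 with 20
features is a "strong driver" in the sense of pan-cancer signatures that
multiple modalities detect; there is no canonical published value for
this scale, so it is a calibration choice of this package, fixed once.
The simulation studies use a reduced 3 × 3 hyperparameter grid
(`alpha ∈ {0.001, 0.1, 10}`, `l1_ratio ∈ {0.05, 0.5, 1}`) — a pipeline
configuration, not a change to the method: the full 48-pair grid is the
default for single experiments, and the reduced grid spans the same
ranges while keeping a 100-gene simulation study to minutes on one core.

## Known limitations

* The paired fold-wise t-test treats the eight folds as independent
  paired measurements; folds share training data, so the test is known to
  be somewhat liberal in general. The permuted-label pairing removes the
  dominant shared-split variance component, and the null-calibration
  study verifies the realized false-positive rate stays low under the
  package's study conditions, but the 7-df t-test is a convention, not an
  exact test.
* `paper_faithful` fit scope standardizes and fits PCA on all samples
  before splitting; absolute AUPRs are therefore mildly optimistic. The
  permuted baseline inherits the same optimism, which is why comparisons
  are always stated as deltas.
* Average precision on small test folds is noisy when positives are few;
  the valid-cancer-type filter (≥15 and ≥5% positives) exists precisely
  to keep folds out of that regime.
* The generator's additive Gaussian signal favors linear classifiers by
  construction; it cannot reveal advantages of nonlinear models.
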