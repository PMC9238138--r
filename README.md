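# omicbench

Benchmarking -omics readouts as predictors of cancer driver-gene mutation
status and patient survival.

## The problem

Mutations in cancer driver genes leave signatures in downstream cellular
readouts — transcript abundance, DNA methylation, protein levels, microRNA
expression, somatic-mutation patterns. Which readout carries the signal for
a given gene, and whether several readouts carry redundant copies of the
same signal, matters for anyone choosing an assay as a functional readout.
`omicbench` turns the question into a supervised benchmark: for each target
gene, predict the gene's binary mutation status from each readout with
elastic-net logistic regression, score it against a matched permuted-label
null, and compare readouts with paired fold-wise statistics. A companion
task predicts censored survival with elastic-net Cox models. A synthetic
multi-omics cohort generator with planted, controllable signatures makes
every property of the pipeline (null calibration, power, modality
specificity, behaviour under redundant signal) testable end to end without
any external data.

## The model

Labels: a sample is positive for a target gene if it has a non-silent
somatic variant in the gene, or a qualifying copy-number call (gain for
oncogenes, deep loss for tumor suppressors, either for dual-role genes).
Hypermutated samples (non-silent count ≥ mean + 5 SD) are excluded, and
per gene only "valid" cancer types (≥ 15 and ≥ 5% mutated samples) enter.

Classifier: elastic-net logistic regression with weights minimizing

    mean NLL(w, b) + α ( λ ||w||₁ + (1−λ)/2 ||w||₂² )

(α = overall strength, λ = L1 fraction; intercept unpenalized), with
one-hot cancer type and log10 mutation burden as covariates. Evaluation is
two replicates of 4-fold cross-validation stratified by cancer type and
sample type — 8 paired train/test splits — with hyperparameters chosen per
fold by 3-fold inner CV over a 6 × 8 grid, scored by average precision
(AUPR). The null condition permutes labels separately in train and test and
independently within each cancer type, preserving class balance exactly,
and re-runs the full hyperparameter search. Genes are called
*well-predicted* when a paired fold-wise t-test against the null passes a
BH-corrected p < 0.001 with positive mean AUPR difference; cross-modality
*equivalent-to-best* calls come from pairwise paired t-tests corrected
within gene. Survival models are penalized Cox (Breslow ties) on top-k
principal components plus covariates, scored by Harrell's censored
concordance against a covariate-only baseline.

See `vignettes/omicbench-methods.Rmd` for the full account, including the
synthetic generator's latent-factor model and every numerical convention.

## Worked example

The `analysis/` scripts run a complete study on a simulated cohort of 2000
samples across three cancer types, with drivers planted in an
expression-like readout, a methylation-like readout, both, or neither:

```sh
Rscript analysis/01_simulate.R       # write the cohort bundle
Rscript analysis/02_build_labels.R   # labels, filters, exclusions
Rscript analysis/03_run_mutation.R   # single-modality benchmark
Rscript analysis/04_multiomics.R     # concatenated multi-omics comparison
Rscript analysis/05_survival.R       # Cox models vs covariate baseline
Rscript analysis/06_summarize.R      # roll-up tables
```

Step 03 prints, per gene × modality, the mean AUPR difference against the
permuted baseline and the resulting calls — the planted genes separate
cleanly from the null controls:

```
  gene modality_set mean_delta_aupr  q_value well_predicted  best
  MET1       me_27k        0.628113 1.62e-10           TRUE  TRUE
 DUAL1   expression        0.607487 4.98e-12           TRUE FALSE
 DUAL1       me_27k        0.607533 1.50e-12           TRUE  TRUE
 NULL1   expression        0.028526 1.21e-01          FALSE  TRUE
 NULL2       me_27k        0.022120 6.24e-02          FALSE FALSE
```

`DUAL1` (planted in both readouts) is well-predicted by both and flagged
equivalent-to-best in both; the null controls are never called. Step 04
shows the redundancy result — concatenating the two readouts for `DUAL1`
buys nothing over the best single readout:

```
Multi-omics vs best single (me_27k): delta AUPR = 0.0004, p = 0.943
-> no significant gain from early integration (redundant signal)
```

and step 05 the survival gain of -omics features over the covariate-only
baseline:

```
  covariates only: 0.605
  expression   k = 10   0.763  (gain +0.158)
  me_27k       k = 10   0.760  (gain +0.155)
```

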