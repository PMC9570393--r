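# dilimark

Ensemble-weighted biomarker discovery for case/control transcriptomics,
modelled on drug-induced liver injury (DILI) microarray cohorts.

DILI lacks a specific diagnostic marker. Given a log2 gene × sample
expression matrix with case/control and batch labels, `dilimark` screens
differentially expressed genes (DEGs) on a training split, asks six
unrelated classifiers how much each DEG matters, and keeps the genes on
which the whole ensemble agrees. The consensus statistic is the **overall
weight**

```
W_g = Σ_m |w_{g,m}| / max_g' |w_{g',m}| ,   m ∈ {lasso, SVM, RF, NN, GBM, DT}
```

— each model's importances are max-absolute normalized to [0, 1] and summed,
so 0 ≤ W_g ≤ 6; genes with W_g > 3 are selected and then evaluated by
per-gene ROC/AUC on both splits, case/control location tests, and Spearman
correlation against immune-cell fraction profiles. DEGs are called with an
empirical-Bayes moderated t (|logFC| > 0.8, BH-FDR < 0.05, p < 0.05), after
quantile normalization and location/scale batch adjustment. Hypergeometric
over-representation and GSEA running-sum statistics are available for
user-supplied GMT gene sets. A synthetic cohort generator with planted
effects (103 cases / 29 controls, six batches by default) makes every stage
testable offline.

## Worked example

```r
library(dilimark)

res <- run_pipeline(pipeline_config(seed = 234))
res
#> Biomarker-discovery pipeline result
#>   2000 genes x 132 samples; 105 train / 27 test
#>   DEGs passing filter: 20
#>   selected genes (overall weight > 3): GENE1761, GENE0079, GENE0874

head(res$weight_table, 4)
#>       gene      lasso svm_linear random_forest neural_net       gbm decision_tree    total
#> 1 GENE1761 1.00000000  0.9560534     1.0000000  1.0000000 1.0000000             1 5.956053
#> 2 GENE0079 0.68754226  1.0000000     0.9769593  0.8616347 0.5345374             0 4.060674
#> 3 GENE0874 0.08422922  0.7878994     0.8926563  0.8455913 0.9114658             0 3.521842
#> 4 GENE0043 0.35496803  0.4414997     0.7195347  0.7893168 0.1895001             0 2.494819

res$auc_table
#>       gene cohort       auc
#> 1 GENE1761  train 0.9968187
#> 2 GENE0079  train 0.9957582
#> 3 GENE0874  train 0.9984093
#> 4 GENE1761   test 1.0000000
#> 5 GENE0079   test 0.9682540
#> 6 GENE0874   test 1.0000000
```

The default configuration plants 20 upregulated genes (logFC 1–2, noise sd
0.5) in a 2000-gene, 132-sample six-batch cohort. All 20 are recovered by
the DEG filter with no false positives; the dominant planted marker
(GENE1761, true logFC 2.0) tops the weight table at W = 5.96 of a possible
6, and every selected gene separates cases from controls with AUC > 0.96 on
the held-out test split.

The package also ships a published 21-gene, six-model reference weight
table for a DILI cohort (`reference_weight_table()`); running
`normalize_importances()` + `select_genes()` on it reproduces the printed
totals (DDIT3 5.134241, GADD45A 3.586528, RBM24 3.520456, SLC3A2 3.401055)
and selects exactly those four genes at the default threshold.

A thin CLI over the same functions lives in `inst/scripts/dilimark.R`
(subcommands `simulate`, `preprocess`, `degs`, `train`, `weights`,
`evaluate`, `enrich`, `run-all`).

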