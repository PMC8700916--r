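# omicsMKL

Binary tumor-stage classification from multi-omics data by combining
minimum-redundancy-maximum-relevance (mRMR) feature selection with a
multiple-kernel-learning (MKL) support vector machine that gives every
omics block its own kernels.

## The problem and the method

Staging cohorts carry several sample-by-feature matrices per patient —
copy number calls, DNA methylation, gene expression, miRNA, protein
abundance — with far more features than samples and wildly different
scales per block. omicsMKL addresses both problems:

1. **Filter.** Continuous features are ternary-coded around their mean
   (−1 / 0 / +1 outside and inside the band μ ± ασ, α = 0.5), and ranked
   by the incremental mRMR criterion

   max over unselected x_j of  I(x_j; c) − (1/|S|) Σ_{x′∈S} I(x_j; x′),

   where I is plug-in mutual information in bits, c the class, and S the
   already-selected set — maximal class relevance, minimal redundancy,
   capped at 500 features.

2. **Wrapper.** The retained-feature count N is chosen from
   {20, 30, …, 500} by inner cross-validated AUC of the downstream
   classifier, re-running mRMR inside every training split.

3. **MKL classifier.** Each block gets a Gaussian kernel (median-heuristic
   bandwidth) and a degree-2 polynomial kernel on its selected, z-scored
   features, all spherically normalized to unit diagonal. The classifier
   learns a convex combination K = Σ d_m K_m (d on the simplex) jointly
   with the SVM in the simpleMKL fashion: alternate SVM solves (a C++ SMO
   solver) with reduced-gradient steps on d until the relative duality
   gap closes. The simplex constraint drives uninformative kernels to
   zero weight.

Evaluation is by stratified nested cross-validation with Mann–Whitney
AUC; single-block and leave-one-block-out suites run under paired fold
assignments. A synthetic five-block generator with known ground truth
(planted informative features, correlated redundant copies) makes every
stage testable end to end.

## Worked example

```r
library(omicsMKL)

sim <- generate_multiomics(paper_mini_config(seed = 7))
ds  <- sim$dataset
ds
#> <multiomics_dataset> 200 samples (46 late / 154 early), 5 blocks
#>   CNV               500 features (integer-coded)
#>   Methylation       400 features (unit-interval)
#>   GeneExpression    400 features (continuous)
#>   miRNA              80 features (continuous)
#>   Protein            50 features (continuous)

ranking <- rank_features(ds, cap = 50)
head(as.data.frame(ranking)[, c("rank", "block", "feature_id",
                                "relevance", "score")], 5)
#>   rank       block        feature_id relevance     score
#> 1    1         CNV         CNV_f0476 0.2240809 0.2240809
#> 2    2         CNV         CNV_f0457 0.1973381 0.1313042
#> 3    3 Methylation Methylation_f0229 0.1565135 0.1080092
#> 4    4 Methylation Methylation_f0053 0.1844912 0.1163319
#> 5    5       miRNA       miRNA_f0015 0.1424581 0.1046725
```

`relevance` is each feature's mutual information with the stage label in
bits; `score` is the achieved mRMR criterion (relevance minus mean MI
with the features ranked above it). Training the classifier on the top
40 features shows which blocks the kernel mix actually uses:

```r
model <- mkl_fit(ds, head(ranking, 40))
round(model$kernel_weights[model$kernel_weights > 0.01], 3)
#>            CNV.polynomial    Methylation.polynomial GeneExpression.polynomial
#>                     0.260                     0.232                     0.267
#>          miRNA.polynomial        Protein.polynomial
#>                     0.201                     0.040
```

Every block carries signal in this fixture, and the learned weights
spread across all five blocks (the remaining five kernels are at zero).
Nested cross-validation estimates out-of-sample discrimination:

```r
cfg <- cv_config(outer_folds = 5, inner_folds = 3,
                 n_grid = seq(20, 60, 10), seed = 7)
nested_cv_evaluate(ds, cfg)
#> <mkl_eval_report> all-blocks: aggregate AUC 0.9993 (pooled 0.9996) over 5 folds
#> chosen N per fold: 60, 20, 30, 40, 30

ffs <- final_feature_set(ds, cfg)
composition_summary(ffs$features, block_names = names(ds$blocks))
#>            block count percentage
#> 1            CNV    14         28
#> 2    Methylation    12         24
#> 3 GeneExpression    17         34
#> 4          miRNA     5         10
#> 5        Protein     2          4
```

The aggregate AUC is the mean of the five held-out fold AUCs (the planted
signal — 30 informative features at one SD of class shift — is strongly
detectable at n = 200). The final table is the per-block composition of
the single feature set selected by non-nested CV (N* = 50 here).

A thin CLI wraps the same functions:

```sh
inst/exec/omics-mkl simulate --out data/ --seed 7
inst/exec/omics-mkl rank --manifest data/manifest.yaml --out ranked.tsv --cap 100
inst/exec/omics-mkl evaluate --manifest data/manifest.yaml --out folds.tsv \
    --outer-folds 5 --inner-folds 3 --n-grid 20:60:10
```

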