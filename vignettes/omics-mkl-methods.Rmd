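---
title: "Multi-omics stage classification with mRMR and multiple kernel learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-omics stage classification with mRMR and multiple kernel learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(omicsMKL)
```

## The problem

Tumor staging from molecular data is naturally a multi-omics problem: copy
number variation (genome), DNA methylation (epigenome), gene and miRNA
expression (transcriptome) and protein abundance (proteome) each carry
partial, overlapping information about disease progression. omicsMKL
implements a binary stage classifier (early = T1–T2 coded $-1$, late =
T3–T4 coded $+1$) for sample-by-feature matrices organized in *blocks*, one
per omics data type. Two difficulties shape the design: the feature space
is far larger than the sample count, and the blocks are heterogeneous in
scale, dimension and value type, so neither a single concatenated model nor
a single kernel treats them well.

The pipeline has two stages: a filter–wrapper feature selection built on
minimum-redundancy-maximum-relevance (mRMR) ranking, and a multiple kernel
learning (MKL) support vector machine that assigns separate kernels to each
block.

## Feature selection

### Ternary discretization

Mutual information on continuous features would require density estimation;
instead each continuous feature is coded into three levels relative to its
own distribution. With mean $\mu$ and sample (n−1) standard deviation
$\sigma$, a value $x$ is coded

$$-1 \;\text{if}\; x < \mu - \alpha\sigma, \qquad
  0 \;\text{if}\; \mu - \alpha\sigma \le x \le \mu + \alpha\sigma, \qquad
  +1 \;\text{if}\; x > \mu + \alpha\sigma,$$

with $\alpha = 0.5$ by default. The band is closed, so boundary values and
constant features ($\sigma = 0$) code to 0. At $\alpha = 0.5$ a Gaussian
feature codes to 0 with probability $P(|Z| \le 0.5) \approx 0.383$. The
coding is invariant under positive affine transforms of the feature.
Integer-coded blocks such as CNV gain/loss calls in $\{-2,\dots,2\}$ are
already categorical and pass through unchanged; re-coding five-level calls
by $\mu \pm \alpha\sigma$ would destroy their meaning (this is switchable
by declaring the block continuous). Inside cross-validation, $\mu$ and
$\sigma$ are estimated on training samples only and reused to code
held-out samples, so no validation information reaches the selection
stage.

### mRMR ranking

Relevance of feature $x_j$ is the plug-in mutual information $I(x_j; c)$
with the class $c$, estimated from the contingency table in bits
(log base 2; the base rescales all values uniformly and cannot change the
ranking). Empty cells contribute zero and no pseudo-counts are added,
matching standard mRMR practice. Ranking is incremental: the first feature
maximizes relevance; the $m$-th feature maximizes

$$I(x_j; c) \;-\; \frac{1}{m-1} \sum_{x' \in S_{m-1}} I(x_j; x'),$$

i.e. relevance penalized by the mean mutual information with the already
selected set $S_{m-1}$, stopping at a cap of 500 features. Pairwise MI is
only ever computed against selected features (an incremental cache), which
is what makes the ranking affordable at tens of thousands of candidates —
the full pairwise MI matrix never exists. Ties in the criterion are broken
by higher relevance, then by column order; both rules exist purely for
determinism.

### Wrapper search for N

The filter produces an ordered list, not a model size. The wrapper stage
scans $N \in \{20, 30, 40, \dots, 500\}$ (grid step 10 after the first
value, configurable): for each inner cross-validation split the training
part is discretized and ranked from scratch, the first $N$ features are
kept, the MKL classifier is trained, and the validation part is scored.
The $N$ with the largest mean inner AUC wins; ties go to the smallest $N$
(parsimony). If the grid exceeds the number of available features it is
truncated with a warning.

## The MKL classifier

Each block contributes a Gaussian kernel
$K(x, x') = \exp(-\lVert x - x' \rVert^2 / 2\sigma_b^2)$ and a polynomial
kernel $K(x, x') = (x \cdot x' / q + 1)^2$ on its selected, z-scored
features ($q$ = the block's selected feature count), giving up to
$M = 2 \times \#\text{blocks}$ kernels. The combined kernel is the convex
combination

$$K(x, x') = \sum_{m=1}^{M} d_m K_m(x, x'), \qquad d_m \ge 0,\;
  \sum_m d_m = 1,$$

and the decision function is the usual kernel expansion
$f(x) = \sum_i a_i^* K(x, x_i) + b^*$, with class $\mathrm{sign}(f(x))$
and a score of exactly zero mapped to $+1$. Weights and SVM are trained
jointly in the simpleMKL fashion: alternate (i) solving the C-SVM dual on
the current combined kernel and (ii) a reduced-gradient step on $d$ within
the simplex, using $\partial J / \partial d_m = -\tfrac12 \sum_{ij}
\alpha_i \alpha_j y_i y_j K_m(x_i, x_j)$, with a backtracking line search
in which every trial step re-solves the (warm-started) SVM and only
objective-decreasing steps are accepted. Convergence is declared when the
relative duality gap

$$\frac{\max_m S_m - \sum_m d_m S_m}{2\,|J|}, \qquad
  S_m = \boldsymbol\alpha^\top Y K_m Y \boldsymbol\alpha$$

drops below `tol`. The simplex constraint is the L1-type mixed norm that
gives simpleMKL its sparsity: kernels of uninformative blocks tend to
receive zero weight.

The inner solver is a sequential minimal optimization (SMO) routine with
maximal-violating-pair working-set selection, written in C++; the bias is
recovered from the KKT conditions on free support vectors. The test suite
checks it against an independent interior-point QP solution of the same
dual.

### Parameters that matter

| parameter | default | meaning / why |
|---|---|---|
| `alpha` | 0.5 | discretization band half-width, in SDs of the feature |
| `cap` | 500 | maximum mRMR list length |
| `n_grid` | 20, 30, …, 500 | wrapper grid for the retained-feature count |
| `C` | 1 | SVM soft-margin cost |
| bandwidth | median heuristic | Gaussian $\sigma_b$ = median nonzero pairwise training distance of the block; parameter-free and robust to block dimension |
| degree / offset | 2 / 1 | polynomial kernel shape |
| `tol` | $10^{-3}$ | relative duality gap at which simpleMKL stops |
| `mkl_max_iter` | 200 | outer iteration budget |

Kernel hyperparameters are deliberately parameter-free defaults: blocks
differ by orders of magnitude in feature count, and both the per-$q$
scaling of the polynomial inner product and the spherical normalization
$K(x,x')/\sqrt{K(x,x)K(x',x')}$ (unit diagonal) exist to stop the largest
block's kernels from dominating the combination. All are configurable.

### Numerical choices

* SMO terminates at KKT violation $10^{-8}$; warm starts across MKL
  iterations keep re-solves cheap.
* Kernel weights extinguished by a line-search step are snapped to zero
  below $10^{-10}$ and the vector renormalized; otherwise a float residue
  of order $10^{-16}$ would cap the next feasible step at that size and
  stall the solver at the boundary.
* mRMR and wrapper ties are broken deterministically (relevance then
  column order; smallest $N$).
* Degenerate inputs: constant features have zero relevance and unit scale
  in z-scoring; a block with no selected features contributes no kernels
  (classed warning) and the weight mass redistributes; identical samples
  give raw Gaussian similarity exactly 1.

## Evaluation design

Generalization is estimated by nested cross-validation: stratified outer
folds (10 by default; stratification matters at the 77/23 class imbalance
the generator mirrors) hold data out; the wrapper runs only on
outer-training data; the pipeline is refit per outer fold with the chosen
$N$. AUC is the Mann–Whitney statistic (ties count one half), computed by
midranks — exactly equivalent to exhaustive pair counting. The aggregate
AUC is the mean of per-fold AUCs (robust to fold-specific score scales);
the pooled AUC over all held-out scores is also reported. The experiment
suite runs all-blocks, each single block, and each leave-one-block-out
subset under identical fold assignments, so comparisons are paired.

For an interpretable final feature list, a non-nested k-fold CV over the
grid (mRMR repeated per split) picks $N^*$, and mRMR runs once on the
whole dataset; the first $N^*$ entries are the final set, summarized per
block with half-up rounding to two decimals.

## The synthetic generator

Real multi-omics cohorts with staging labels are access-restricted, so the
package ships a generator with known ground truth. It emulates the shape
of a five-block staging cohort at desk scale: the default fixture
(`paper_mini_config()`) has 200 samples at 23% late-stage prevalence and
blocks CNV 500 (integer-coded), methylation 400 (unit-interval), gene
expression 400, miRNA 80 and protein 50 features, with a small set of
informative features per block (8/8/8/4/2), redundant correlated copies
(4/4/4/2/0, target correlation 0.9) to exercise the mRMR redundancy
penalty, and pure-noise remainder.

The base model is class-conditional Gaussians with equal variance:
informative features are mean-shifted between classes by
`effect_size` × SD (default 1, a moderate single-feature effect:
per-feature AUC ≈ 0.76); redundant features are parent + Gaussian noise
scaled to the target correlation in expectation. Value-kind transforms are
applied after signal injection: rounding/clipping to $\{-2..2\}$
(CNV-like), the normal CDF squashing into $[0, 1]$ (methylation-beta-like),
or identity. Positives are assigned at a fixed count
(`round(prevalence × n)`) so class sizes are stable across seeds, and
column positions of planted features are randomized.

What the generator does **not** emulate: TCGA-like marginal distributions
(read-count overdispersion, methylation bimodality), inter-block
correlation of the noise, batch effects, missingness, or label noise. A
passing suite therefore demonstrates correctness of the algorithms and the
expected *qualitative* behavior (integration ≥ best single block, signal
blocks dominating kernel weights, redundancy suppression, chance-level AUC
under permuted labels) — not clinical-scale performance numbers, which
additionally depend on unpublished kernel hyperparameters and full-scale
data.

## Problem sizes used by the shipped checks

Tests and the acceptance script run the generator's defaults with a
reduced search: outer folds 5 (10 for the final-feature-set CV), inner
folds 3, grid 20–100 by 10. These sizes keep full nested runs in the tens
of seconds while leaving every pipeline stage (ranking depth, wrapper
search, kernel mixing) genuinely exercised; the grid upper end of 100
comfortably exceeds the 30 planted informative features.

## Known limitations

* Binary outcomes only; multi-class staging is out of scope.
* mRMR consumes the ternary codes; the MKL stage consumes the continuous
  values (discretization exists only because plug-in MI needs categorical
  data). Different discretizations of the CNV block are not explored.
* No class weighting by default; a cost-scaling flag would be the first
  addition for heavily imbalanced cohorts.
* AUC differences between nested-CV runs have no unbiased variance
  estimate, so the suite's comparisons are qualitative, not significance
  tests.
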