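Package: omicsMKL
Title: Multi-Omics Stage Classification with mRMR Feature Selection and
    Multiple Kernel Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Binary classification of multi-omics sample-by-feature data
    (copy number, DNA methylation, gene expression, miRNA, protein) by
    combining minimum-redundancy-maximum-relevance (mRMR) feature ranking
    with a filter-wrapper search for the number of retained features and a
    multiple-kernel-learning support vector machine that assigns a Gaussian
    and a polynomial kernel to each omics block. Includes readers and
    writers for per-block matrices, a synthetic multi-omics generator with
    known ground truth, nested cross-validation with ROC/AUC evaluation,
    single-block and leave-one-block-out experiment suites, and final
    feature-set selection with composition summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    kernlab,
    pROC,
    optparse,
    jsonlite,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
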