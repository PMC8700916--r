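#' ROC curve and AUC
#'
#' The AUC is the Mann-Whitney statistic: the probability that a random
#' positive sample outscores a random negative one, with ties counting
#' one half. Computed via midranks, which is exactly equivalent to
#' exhaustive pair counting. ROC points are swept over the distinct score
#' thresholds.
#'
#' @param scores Real-valued decision scores (larger = more positive).
#' @param labels Vector in `{+1, -1}`; both classes must be present.
#' @return List with `auc` and `roc`, a data.frame of `threshold`, `fpr`,
#'   `tpr` points (including the (0,0) and (1,1) endpoints).
#' @export
roc_auc <- function(scores, labels) {
  y <- as.integer(labels)
  if (!all(y %in% c(-1L, 1L))) stop("labels must be +1/-1")
  npos <- sum(y == 1L)
  nneg <- sum(y == -1L)
  if (npos == 0 || nneg == 0) stop("both classes must be present")
  r <- rank(scores)
  auc <- (sum(r[y == 1L]) - npos * (npos + 1) / 2) / (npos * nneg)

  o <- order(scores, decreasing = TRUE)
  ys <- y[o]
  ss <- scores[o]
  keep <- !duplicated(ss, fromLast = TRUE)  # last index of each tie group
  tpr <- cumsum(ys == 1L)[keep] / npos
  fpr <- cumsum(ys == -1L)[keep] / nneg
  roc <- data.frame(threshold = c(Inf, ss[keep]),
                    fpr = c(0, fpr), tpr = c(0, tpr))
  list(auc = auc, roc = roc)
}

#' Stratified k-fold assignment
#'
#' Assigns each sample to one of `k` folds; with `stratified = TRUE`
#' each class is spread across folds so per-fold class proportions are
#' within one sample of the global proportions. Uses the current RNG
#' state (wrap in a seed for reproducibility).
#'
#' @param labels Class labels.
#' @param k Number of folds (>= 2).
#' @param stratified Stratify by class (default `TRUE`).
#' @return Integer fold id per sample.
#' @export
make_folds <- function(labels, k, stratified = TRUE) {
  n <- length(labels)
  stopifnot(k >= 2, k <= n)
  fold <- integer(n)
  if (stratified) {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  } else {
    fold <- sample(rep_len(seq_len(k), n))
  }
  fold
}

#' Cross-validation and model configuration
#'
#' Bundles the nested cross-validation layout, the wrapper grid for the
#' retained-feature count N, and the model hyperparameters carried
#' through the pipeline.
#'
#' @param outer_folds Outer CV folds (default 10).
#' @param inner_folds Inner (wrapper) CV folds (default 10).
#' @param n_grid Candidate numbers of retained features (default
#'   `seq(20, 500, by = 10)`).
#' @param stratified Stratify folds by class (default `TRUE`).
#' @param seed Integer seed driving all fold assignments.
#' @param alpha Discretization band half-width for mRMR.
#' @param cap mRMR ranking cap (default 500).
#' @param C SVM cost.
#' @param families Kernel families per block.
#' @param degree,offset,bandwidth Kernel parameters, see [kernel_spec()].
#' @param mkl_tol,mkl_max_iter simpleMKL convergence controls.
#' @return An object of class `cv_config`.
#' @export
cv_config <- function(outer_folds = 10, inner_folds = 10,
                      n_grid = seq(20, 500, by = 10), stratified = TRUE,
                      seed = 1, alpha = 0.5, cap = 500, C = 1,
                      families = c("gaussian", "polynomial"), degree = 2,
                      offset = 1, bandwidth = "median", mkl_tol = 1e-3,
                      mkl_max_iter = 200) {
  stopifnot(outer_folds >= 2, inner_folds >= 2, length(n_grid) >= 1,
            all(diff(n_grid) > 0), n_grid[1] >= 1)
  structure(list(outer_folds = outer_folds, inner_folds = inner_folds,
                 n_grid = as.integer(n_grid), stratified = stratified,
                 seed = as.integer(seed), alpha = alpha, cap = cap, C = C,
                 families = families, degree = degree, offset = offset,
                 bandwidth = bandwidth, mkl_tol = mkl_tol,
                 mkl_max_iter = mkl_max_iter),
            class = "cv_config")
}

# deterministic sub-seed for inner folds so experiment-suite runs share
# fold assignments across sub-experiments
sub_seed <- function(seed, i) {
  as.integer((as.numeric(seed) + 104729 * i) %% 2147483629L)
}

# fit on training samples with the top-n ranked features, suppressing the
# routine empty-block warnings that small n inevitably produces
fit_top_n <- function(train_ds, ranking, n, cfg) {
  feats <- head(ranking, n)
  withCallingHandlers(
    mkl_fit(train_ds, feats, C = cfg$C, families = cfg$families,
            degree = cfg$degree, offset = cfg$offset,
            bandwidth = cfg$bandwidth, tol = cfg$mkl_tol,
            max_iter = cfg$mkl_max_iter),
    omicsmkl_empty_block = function(w) invokeRestart("muffleWarning"),
    warning = function(w) {
      if (grepl("simpleMKL stopped", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
}

effective_grid <- function(cfg, total_features) {
  grid <- cfg$n_grid[cfg$n_grid <= total_features]
  if (length(grid) < length(cfg$n_grid)) {
    warning("N grid truncated to the ", total_features,
            " available features", call. = FALSE)
    if (length(grid) == 0) grid <- total_features
  }
  grid
}

#' Wrapper search for the number of retained features
#'
#' For each candidate N in the grid, runs an inner cross-validation in
#' which every training split is discretized and mRMR-ranked from
#' scratch, the first N features are kept, the multiple-kernel SVM is
#' trained, and the held-in validation part is scored. The best N is the
#' grid value with the largest mean inner AUC (ties resolved toward the
#' smallest N).
#'
#' @param train_ds Training `multiomics_dataset`.
#' @param cfg A [cv_config()].
#' @param seed Seed for the inner fold assignment (defaults to
#'   `cfg$seed`).
#' @return List with `best_n` and `curve`, a data.frame of `n` and mean
#'   inner `auc`.
#' @export
wrapper_select_n <- function(train_ds, cfg, seed = cfg$seed) {
  grid <- effective_grid(cfg, n_features(train_ds))
  folds <- with_local_seed(seed, {
    make_folds(train_ds$labels, cfg$inner_folds, cfg$stratified)
  })
  aucs <- matrix(NA_real_, length(grid), cfg$inner_folds)
  for (j in seq_len(cfg$inner_folds)) {
    tr <- subset_dataset(train_ds, samples = which(folds != j))
    va <- subset_dataset(train_ds, samples = which(folds == j))
    if (length(unique(va$labels)) < 2 || length(unique(tr$labels)) < 2) next
    ranking <- rank_features(tr, alpha = cfg$alpha,
                             cap = min(cfg$cap, max(grid)))
    for (gi in seq_along(grid)) {
      model <- fit_top_n(tr, ranking, grid[gi], cfg)
      sc <- predict(model, va)
      aucs[gi, j] <- roc_auc(sc, va$labels)$auc
    }
  }
  mean_auc <- rowMeans(aucs, na.rm = TRUE)
  best <- grid[which.max(mean_auc)]  # which.max takes the first (smallest N)
  list(best_n = best,
       curve = data.frame(n = grid, auc = mean_auc),
       fold_aucs = aucs)
}

#' Nested cross-validation evaluation
#'
#' The outer loop estimates generalization: for each outer fold, the
#' wrapper search (inner loop, run only on outer-training data) picks the
#' retained-feature count N, the pipeline (discretization, mRMR ranking,
#' kernel construction, MKL training) is refit on the full outer-training
#' set with that N, and the held-out fold is scored. Feature selection
#' and all preprocessing statistics are computed on training samples
#' only.
#'
#' @param ds A `multiomics_dataset`.
#' @param cfg A [cv_config()].
#' @param blocks Optional character vector restricting the run to a block
#'   subset.
#' @param folds Optional precomputed outer fold assignment (used by
#'   [run_experiment_suite()] to pair runs).
#' @param label Experiment label stored in the report.
#' @return An object of class `mkl_eval_report` with per-fold results
#'   (`folds`: fold, chosen N, AUC), `aggregate_auc` (mean of fold AUCs),
#'   `pooled_auc` (AUC of all held-out scores pooled), `roc` (pooled ROC
#'   points) and the held-out `scores`.
#' @export
nested_cv_evaluate <- function(ds, cfg, blocks = NULL, folds = NULL,
                               label = NULL) {
  stopifnot(inherits(ds, "multiomics_dataset"), inherits(cfg, "cv_config"))
  if (!is.null(blocks)) ds <- subset_dataset(ds, blocks = blocks)
  if (is.null(label)) {
    label <- if (is.null(blocks)) "all-blocks" else {
      paste0("blocks:", paste(blocks, collapse = "+"))
    }
  }
  if (is.null(folds)) {
    folds <- with_local_seed(cfg$seed, {
      make_folds(ds$labels, cfg$outer_folds, cfg$stratified)
    })
  }
  k <- max(folds)
  fold_rows <- vector("list", k)
  score_rows <- vector("list", k)
  curves <- vector("list", k)
  for (i in seq_len(k)) {
    tr <- subset_dataset(ds, samples = which(folds != i))
    te <- subset_dataset(ds, samples = which(folds == i))
    if (length(unique(tr$labels)) < 2) {
      stop("outer fold ", i, " leaves a single-class training set; ",
           "use stratified folds")
    }
    sel <- wrapper_select_n(tr, cfg, seed = sub_seed(cfg$seed, i))
    ranking <- rank_features(tr, alpha = cfg$alpha,
                             cap = min(cfg$cap, sel$best_n))
    model <- fit_top_n(tr, ranking, sel$best_n, cfg)
    sc <- predict(model, te)
    auc_i <- if (length(unique(te$labels)) < 2) NA_real_ else {
      roc_auc(sc, te$labels)$auc
    }
    fold_rows[[i]] <- data.frame(fold = i, n_chosen = sel$best_n,
                                 auc = auc_i, n_test = length(sc))
    score_rows[[i]] <- data.frame(sample_id = te$sample_ids, fold = i,
                                  score = as.numeric(sc), label = te$labels,
                                  stringsAsFactors = FALSE)
    curves[[i]] <- sel$curve
  }
  fold_df <- do.call(rbind, fold_rows)
  score_df <- do.call(rbind, score_rows)
  pooled <- roc_auc(score_df$score, score_df$label)
  structure(list(label = label, folds = fold_df,
                 aggregate_auc = mean(fold_df$auc, na.rm = TRUE),
                 pooled_auc = pooled$auc, roc = pooled$roc,
                 scores = score_df, wrapper_curves = curves,
                 seed = cfg$seed),
            class = "mkl_eval_report")
}

#' @export
print.mkl_eval_report <- function(x, ...) {
  cat(sprintf(
    "<mkl_eval_report> %s: aggregate AUC %.4f (pooled %.4f) over %d folds\n",
    x$label, x$aggregate_auc, x$pooled_auc, nrow(x$folds)))
  cat("chosen N per fold:", paste(x$folds$n_chosen, collapse = ", "), "\n")
  invisible(x)
}

#' Single-block and leave-one-block-out experiment suite
#'
#' Evaluates (a) all blocks jointly, (b) each block alone (that block's
#' kernels only) and (c) each leave-one-block-out subset, with identical
#' outer fold assignments across every run so the comparisons are paired.
#'
#' @param ds A `multiomics_dataset` with at least 2 blocks.
#' @param cfg A [cv_config()].
#' @param experiments Subset of `c("all", "single", "drop")`.
#' @return Named list of `mkl_eval_report`s: `"all-blocks"`,
#'   `"single:<block>"`, `"drop:<block>"`.
#' @export
run_experiment_suite <- function(ds, cfg,
                                 experiments = c("all", "single", "drop")) {
  stopifnot(length(ds$blocks) >= 2)
  experiments <- match.arg(experiments, several.ok = TRUE)
  folds <- with_local_seed(cfg$seed, {
    make_folds(ds$labels, cfg$outer_folds, cfg$stratified)
  })
  out <- list()
  if ("all" %in% experiments) {
    out[["all-blocks"]] <- nested_cv_evaluate(ds, cfg, folds = folds,
                                              label = "all-blocks")
  }
  bn <- names(ds$blocks)
  if ("single" %in% experiments) {
    for (b in bn) {
      out[[paste0("single:", b)]] <-
        nested_cv_evaluate(ds, cfg, blocks = b, folds = folds,
                           label = paste0("single:", b))
    }
  }
  if ("drop" %in% experiments) {
    for (b in bn) {
      out[[paste0("drop:", b)]] <-
        nested_cv_evaluate(ds, cfg, blocks = setdiff(bn, b), folds = folds,
                           label = paste0("drop:", b))
    }
  }
  out
}

#' Final feature-set selection on the whole dataset
#'
#' A single interpretable feature list: a non-nested k-fold
#' cross-validation over the N grid (mRMR repeated within each training
#' split) picks the N with the largest mean cross-validated AUC, then
#' mRMR is run once on the whole dataset and the first N features are
#' returned.
#'
#' @param ds A `multiomics_dataset`.
#' @param cfg A [cv_config()]; `outer_folds` sets the (non-nested) fold
#'   count.
#' @return List with `features` (a `ranked_features` data.frame of length
#'   `n`), `n` (the chosen N) and `curve` (mean CV AUC per grid value).
#' @export
final_feature_set <- function(ds, cfg) {
  stopifnot(inherits(ds, "multiomics_dataset"), inherits(cfg, "cv_config"))
  tmp_cfg <- cfg
  tmp_cfg$inner_folds <- cfg$outer_folds
  sel <- wrapper_select_n(ds, tmp_cfg, seed = cfg$seed)
  ranking <- rank_features(ds, alpha = cfg$alpha, cap = sel$best_n)
  list(features = head(ranking, sel$best_n), n = sel$best_n,
       curve = sel$curve)
}

#' Per-block composition of a selected feature set
#'
#' Counts the selected features per block and reports percentages of the
#' total, rounded half-up to 2 decimals. Accepts either a
#' `ranked_features` data.frame (or any data.frame with a `block` column)
#' or a named vector of per-block counts. An optional annotated subset
#' (e.g. features with known disease associations) is summarized the same
#' way against the same total.
#'
#' @param selected Selected features or named per-block counts.
#' @param block_names Optional block ordering/universe; blocks without
#'   selected features are reported with count 0.
#' @param annotated Optional count (or subset data.frame) of annotated
#'   features among the selected ones.
#' @return A data.frame of `block`, `count`, `percentage`, with
#'   attributes `total` and (when requested) `annotated_percentage`.
#' @export
composition_summary <- function(selected, block_names = NULL,
                                annotated = NULL) {
  if (is.data.frame(selected)) {
    counts <- table(selected$block)
  } else {
    counts <- selected
    if (is.null(names(counts))) stop("counts must be named by block")
  }
  if (is.null(block_names)) block_names <- names(counts)
  cnt <- stats::setNames(rep(0L, length(block_names)), block_names)
  cnt[names(counts)] <- as.integer(counts)
  total <- sum(cnt)
  if (total == 0) stop("no selected features to summarize")
  out <- data.frame(block = block_names, count = as.integer(cnt),
                    percentage = round_half_up(100 * cnt / total, 2),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "total") <- total
  if (!is.null(annotated)) {
    n_ann <- if (is.data.frame(annotated)) nrow(annotated) else annotated
    attr(out, "annotated_percentage") <- round_half_up(100 * n_ann / total, 2)
  }
  out
}
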