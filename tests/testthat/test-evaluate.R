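test_that("AUC matches exhaustive pair counting and handles ties", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, -1, -1))$auc, 1.0)
  expect_equal(roc_auc(c(0.5, 0.5), c(1, -1))$auc, 0.5)
  expect_equal(roc_auc(c(0.9, 0.4, 0.6, 0.1), c(1, -1, 1, -1))$auc, 1.0)
  expect_equal(roc_auc(c(0.9, 0.4, 0.6, 0.1), c(-1, 1, -1, 1))$auc, 0.0)
  expect_error(roc_auc(c(1, 2), c(1, 1)), "both classes")
  withr::with_seed(3, {
    for (i in 1:15) {
      n <- sample(5:50, 1)
      y <- c(1, -1, sample(c(-1, 1), n - 2, replace = TRUE))
      s <- sample(seq(0, 1, 0.1), n, replace = TRUE)  # many ties
      expect_equal(roc_auc(s, y)$auc, auc_pairs(s, y), tolerance = 1e-12)
    }
  })
})

test_that("AUC and ROC points agree with an independent ROC package", {
  skip_if_not_installed("pROC")
  withr::with_seed(5, {
    y <- sample(c(-1, 1), 60, replace = TRUE)
    s <- rnorm(60) + 0.8 * y
    got <- roc_auc(s, y)
    ref <- pROC::roc(response = y, predictor = s, levels = c(-1, 1),
                     direction = "<", quiet = TRUE)
    expect_equal(got$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
    # ROC endpoints and monotonicity
    expect_equal(got$roc$fpr[1], 0)
    expect_equal(got$roc$tpr[nrow(got$roc)], 1)
    expect_true(all(diff(got$roc$fpr) >= 0) && all(diff(got$roc$tpr) >= 0))
  })
})

test_that("stratified folds are disjoint, covering, and class-balanced", {
  withr::with_seed(7, {
    y <- rep(c(1, -1), c(23, 77))
    f <- make_folds(y, 10)
    expect_setequal(unique(f), 1:10)
    expect_equal(length(f), 100)
    for (k in 1:10) {
      npos <- sum(y[f == k] == 1)
      expect_true(npos %in% c(floor(23 / 10), ceiling(23 / 10)))
    }
  })
})

test_that("wrapper search: singleton grid, determinism and truncation", {
  sim <- generate_multiomics(synthetic_config(
    n_samples = 60, prevalence_positive = 0.4, seed = 71,
    blocks = list(list(name = "A", value_kind = "continuous",
                       n_features = 30, n_informative = 5,
                       effect_size = 2),
                  list(name = "B", value_kind = "continuous",
                       n_features = 20))))
  ds <- sim$dataset
  cfg1 <- cv_config(inner_folds = 2, n_grid = 20, seed = 71)
  sel1 <- wrapper_select_n(ds, cfg1)
  expect_equal(sel1$best_n, 20L)

  cfg2 <- cv_config(inner_folds = 2, n_grid = c(10, 20), seed = 71)
  sel2a <- wrapper_select_n(ds, cfg2)
  sel2b <- wrapper_select_n(ds, cfg2)
  expect_identical(sel2a, sel2b)
  expect_true(sel2a$best_n %in% cfg2$n_grid)
  expect_true(all(sel2a$curve$auc >= 0 & sel2a$curve$auc <= 1))

  cfg3 <- cv_config(inner_folds = 2, n_grid = c(10, 200), seed = 71)
  expect_warning(sel3 <- wrapper_select_n(ds, cfg3), "truncated")
  expect_equal(sel3$curve$n, 10L)
})

test_that("nested CV is deterministic and reports valid per-fold results", {
  sim <- generate_multiomics(synthetic_config(
    n_samples = 70, prevalence_positive = 0.4, seed = 73,
    blocks = list(list(name = "A", value_kind = "continuous",
                       n_features = 25, n_informative = 6,
                       effect_size = 2.5),
                  list(name = "B", value_kind = "continuous",
                       n_features = 15))))
  cfg <- cv_config(outer_folds = 3, inner_folds = 2, n_grid = c(5, 10),
                   seed = 73)
  r1 <- nested_cv_evaluate(sim$dataset, cfg)
  r2 <- nested_cv_evaluate(sim$dataset, cfg)
  expect_identical(r1, r2)
  expect_true(all(r1$folds$auc >= 0 & r1$folds$auc <= 1))
  expect_true(all(r1$folds$n_chosen %in% cfg$n_grid))
  expect_equal(nrow(r1$scores), 70)
  expect_equal(r1$aggregate_auc, mean(r1$folds$auc))
  expect_equal(r1$pooled_auc,
               roc_auc(r1$scores$score, r1$scores$label)$auc)
  # strong planted signal at small n: the rule must beat chance clearly
  expect_gt(r1$aggregate_auc, 0.7)
})

test_that("feature selection state never depends on held-out samples", {
  sim <- generate_multiomics(synthetic_config(
    n_samples = 50, prevalence_positive = 0.4, seed = 79,
    blocks = list(list(name = "A", value_kind = "continuous",
                       n_features = 20, n_informative = 4,
                       effect_size = 2))))
  ds <- sim$dataset
  tr_idx <- 1:40
  ds_canary <- ds
  # plant an absurd value in a validation-only sample
  ds_canary$blocks$A$values[45, ] <- 1e6
  cfg <- cv_config(inner_folds = 2, n_grid = c(5, 10), seed = 79)

  tr1 <- subset_dataset(ds, samples = tr_idx)
  tr2 <- subset_dataset(ds_canary, samples = tr_idx)
  expect_identical(wrapper_select_n(tr1, cfg), wrapper_select_n(tr2, cfg))
  expect_identical(rank_features(tr1, cap = 10), rank_features(tr2, cap = 10))
  m1 <- mkl_fit(tr1, rank_features(tr1, cap = 10))
  m2 <- mkl_fit(tr2, rank_features(tr2, cap = 10))
  expect_identical(m1$core$d, m2$core$d)
  expect_identical(m1$prep, m2$prep)
})

test_that("experiment suite enumerates runs with paired fold assignments", {
  sim <- generate_multiomics(synthetic_config(
    n_samples = 50, prevalence_positive = 0.4, seed = 83,
    blocks = list(list(name = "A", value_kind = "continuous",
                       n_features = 15, n_informative = 4,
                       effect_size = 2),
                  list(name = "B", value_kind = "continuous",
                       n_features = 10))))
  cfg <- cv_config(outer_folds = 2, inner_folds = 2, n_grid = 5, seed = 83)
  suite <- run_experiment_suite(sim$dataset, cfg)
  expect_named(suite, c("all-blocks", "single:A", "single:B",
                        "drop:A", "drop:B"))
  # 1 + n_blocks + n_blocks reports for a 2-block dataset
  expect_length(suite, 5)
  # identical fold assignment across sub-experiments
  fold_map <- lapply(suite, function(r) {
    r$scores[order(r$scores$sample_id), c("sample_id", "fold")]
  })
  for (i in 2:length(fold_map)) {
    expect_identical(fold_map[[i]], fold_map[[1]])
  }
})

test_that("final feature set honors a singleton grid and is deterministic", {
  sim <- generate_multiomics(synthetic_config(
    n_samples = 60, prevalence_positive = 0.4, seed = 89,
    blocks = list(list(name = "A", value_kind = "continuous",
                       n_features = 30, n_informative = 5,
                       effect_size = 2))))
  cfg <- cv_config(outer_folds = 2, n_grid = 12, seed = 89)
  f1 <- final_feature_set(sim$dataset, cfg)
  expect_equal(f1$n, 12L)
  expect_equal(nrow(f1$features), 12)
  expect_identical(f1, final_feature_set(sim$dataset, cfg))
})

test_that("composition percentages partition the selection and round half-up", {
  comp <- composition_summary(c(CNV = 10, Methyl = 21, GE = 34,
                                miRNA = 3, Protein = 2))
  expect_equal(attr(comp, "total"), 70)
  expect_equal(comp$percentage, c(14.29, 30.00, 48.57, 4.29, 2.86))
  expect_lt(abs(sum(comp$percentage) - 100), 0.02)

  single <- composition_summary(c(GE = 13))
  expect_equal(single$percentage, 100.00)

  ann <- composition_summary(c(A = 50, B = 20), annotated = 18)
  expect_equal(attr(ann, "annotated_percentage"), 25.71)

  # random partitions: rounded percentages stay near 100
  withr::with_seed(97, {
    for (i in 1:10) {
      k <- sample(2:6, 1)
      cnt <- setNames(sample(1:40, k), paste0("b", 1:k))
      cs <- composition_summary(cnt)
      expect_lt(abs(sum(cs$percentage) - 100), 0.02 + 0.005 * k)
      expect_equal(sum(cs$count), attr(cs, "total"))
    }
  })

  # a data.frame selection with explicit block universe
  df <- data.frame(block = c("A", "A", "B"), feature_id = c("x", "y", "z"))
  cs <- composition_summary(df, block_names = c("A", "B", "C"))
  expect_equal(cs$count, c(2L, 1L, 0L))
  expect_equal(cs$percentage, c(66.67, 33.33, 0))
})
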