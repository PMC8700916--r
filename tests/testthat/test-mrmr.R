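test_that("mutual information matches hand-computed plug-in values", {
  expect_equal(mutual_information(c(0, 0, 1, 1), c(0, 0, 1, 1)), 1.0,
               tolerance = 1e-12)
  expect_equal(mutual_information(c(0, 0, 1, 1), c(0, 1, 0, 1)), 0.0,
               tolerance = 1e-12)
  # 1/2 log2(4/3) + 1/4 log2(2/3) + 1/4 log2(2)
  expect_equal(mutual_information(c(0, 0, 0, 1), c(0, 0, 1, 1)),
               0.5 * log2(4 / 3) + 0.25 * log2(2 / 3) + 0.25,
               tolerance = 1e-10)
  expect_error(mutual_information(c(0, 1), c(0, 1, 0)), "equal length")
})

test_that("mutual information is symmetric, bounded and label-invariant", {
  withr::with_seed(17, {
    for (i in 1:20) {
      x <- sample(-1:1, 30, replace = TRUE)
      y <- sample(c(-1L, 1L), 30, replace = TRUE)
      mi <- mutual_information(x, y)
      expect_gte(mi, 0)
      expect_lte(mi, min(entropy_oracle(x), entropy_oracle(y)) + 1e-12)
      expect_equal(mutual_information(y, x), mi, tolerance = 1e-12)
      # relabeling categories preserves MI
      expect_equal(mutual_information(5L - x, y), mi, tolerance = 1e-12)
      expect_equal(mutual_information(x, letters[y + 2]), mi,
                   tolerance = 1e-12)
      # and it agrees with the naive contingency-table oracle
      expect_equal(mi, mi_oracle(x, y), tolerance = 1e-12)
    }
  })
})

test_that("relevance scores are per-column MI with the class", {
  withr::with_seed(23, {
    y <- rep(c(1L, -1L), each = 10)
    X <- cbind(y, 7L, sample(-1:1, 20, replace = TRUE))
    colnames(X) <- c("copy", "const", "rand")
    rel <- max_relevance_scores(X, y)
    expect_equal(rel[1], entropy_oracle(y), tolerance = 1e-12)
    expect_equal(rel[2], 0)
    expect_equal(rel[3], mi_oracle(X[, 3], y), tolerance = 1e-12)
  })
})

test_that("a redundant exact copy is demoted below a weak independent signal", {
  withr::with_seed(29, {
    n <- 40
    y <- rep(c(1L, -1L), each = n / 2)
    A <- y
    A[c(1, 2, 21, 22)] <- -A[c(1, 2, 21, 22)]  # strong but imperfect
    B <- A                                      # exact copy of A
    C <- y
    C[sample(n, 14)] <- sample(c(-1L, 1L), 14, replace = TRUE)  # weak
    X <- cbind(A = A, C = C, B = B)
    r <- mrmr_rank(X, y)
    expect_identical(r$feature_id, c("A", "C", "B"))
    expect_identical(colnames(X)[mrmr_brute(X, y)], c("A", "C", "B"))
    # the copy's criterion is its relevance minus the full entropy of A
    expect_equal(r$score[1], r$relevance[1], tolerance = 1e-12)
  })
})

test_that("ranking equals brute-force criterion maximization step by step", {
  withr::with_seed(37, {
    for (i in 1:8) {
      n <- 40
      p <- sample(6:12, 1)
      y <- sample(c(-1L, 1L), n, replace = TRUE)
      X <- matrix(sample(-1:1, n * p, replace = TRUE), n, p)
      # plant a few informative and one duplicated column
      X[, 1] <- ifelse(runif(n) < 0.8, y, X[, 1])
      X[, 2] <- X[, 1]
      r <- mrmr_rank(X, y)
      expect_identical(r$column, mrmr_brute(X, y))
      expect_equal(r$relevance[1], max(max_relevance_scores(X, y)),
                   tolerance = 1e-12)
    }
  })
})

test_that("zero redundancy reduces the ranking to descending relevance", {
  withr::with_seed(43, {
    n <- 60
    y <- rep(c(1L, -1L), each = n / 2)
    # mutually independent deterministic functions of disjoint sample parts
    X <- sapply(1:5, function(j) {
      v <- y
      v[sample(n, 6 * j)] <- sample(c(-1L, 1L), 6 * j, replace = TRUE)
      v
    })
    rel <- max_relevance_scores(X, y)
    r <- mrmr_rank(X, y)
    red <- vapply(2:5, function(m) {
      mean(vapply(seq_len(m - 1), function(s) {
        mi_oracle(X[, r$column[m]], X[, r$column[s]])
      }, numeric(1)))
    }, numeric(1))
    # in this construction redundancy is small relative to relevance gaps,
    # so the order follows relevance
    if (all(red < min(abs(diff(sort(rel, decreasing = TRUE)))))) {
      expect_identical(r$column, order(rel, decreasing = TRUE))
    }
    expect_identical(r$column[1], which.max(rel))
  })
})

test_that("redundant synthetic copies are never picked right after parents", {
  sim <- generate_multiomics(synthetic_config(
    n_samples = 150, prevalence_positive = 0.4, seed = 51,
    blocks = list(list(name = "X", value_kind = "continuous",
                       n_features = 40, n_informative = 6, effect_size = 1.5,
                       n_redundant = 6, redundancy_correlation = 0.98))))
  r <- rank_features(sim$dataset, cap = 20)
  gt <- sim$ground_truth
  parent_of <- setNames(gt$parent, gt$feature_id)
  for (m in 2:nrow(r)) {
    p <- parent_of[r$feature_id[m]]
    if (!is.na(p)) expect_false(identical(p, r$feature_id[m - 1]))
  }
})

test_that("ranking respects the cap and rejects single-class labels", {
  withr::with_seed(61, {
    X <- matrix(sample(-1:1, 200, replace = TRUE), 20, 10)
    y <- sample(c(-1L, 1L), 20, replace = TRUE)
    expect_equal(nrow(mrmr_rank(X, y, cap = 4)), 4)
    expect_equal(nrow(mrmr_rank(X, y, cap = 500)), 10)
    expect_error(mrmr_rank(X, rep(1L, 20)), "single class")
  })
})
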