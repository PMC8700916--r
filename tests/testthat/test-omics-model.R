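test_that("write/load round trip reproduces values and ordering exactly", {
  sim <- generate_multiomics(synthetic_config(
    n_samples = 12, prevalence_positive = 0.4, seed = 7,
    blocks = list(
      list(name = "CNV", value_kind = "integer-coded", n_features = 6),
      list(name = "Meth", value_kind = "unit-interval", n_features = 5),
      list(name = "Expr", value_kind = "continuous", n_features = 4,
           n_informative = 2)
    )))
  ds <- sim$dataset
  dir <- withr::local_tempdir()
  manifest <- write_dataset(ds, dir)
  ds2 <- read_manifest(manifest)
  expect_identical(ds2$sample_ids, ds$sample_ids)
  expect_identical(ds2$labels, ds$labels)
  expect_identical(names(ds2$blocks), names(ds$blocks))
  for (bn in names(ds$blocks)) {
    expect_identical(ds2$blocks[[bn]]$values, ds$blocks[[bn]]$values)
    expect_identical(ds2$blocks[[bn]]$value_kind, ds$blocks[[bn]]$value_kind)
  }
})

test_that("loader keeps the intersection of labeled and per-block samples", {
  dir <- withr::local_tempdir()
  writeLines(c("sample_id\tstage", "s1\tearly", "s2\tlate", "s3\tearly"),
             file.path(dir, "labels.tsv"))
  writeLines(c("sample_id\tf1\tf2", "s1\t1\t2", "s2\t3\t4", "s3\t5\t6"),
             file.path(dir, "a.tsv"))
  writeLines(c("sample_id\tg1", "s1\t0.1", "s2\t0.2"),
             file.path(dir, "b.tsv"))
  expect_message(
    ds <- load_dataset(
      list(A = list(path = file.path(dir, "a.tsv")),
           B = list(path = file.path(dir, "b.tsv"))),
      file.path(dir, "labels.tsv")),
    "dropped 1")
  expect_identical(ds$sample_ids, c("s1", "s2"))
  expect_identical(ds$labels, c(-1L, 1L))
  expect_length(ds$blocks, 2)

  # full agreement: no message, three samples retained in label order
  writeLines(c("sample_id\tg1", "s2\t0.2", "s1\t0.1", "s3\t0.3"),
             file.path(dir, "b3.tsv"))
  ds3 <- load_dataset(
    list(A = list(path = file.path(dir, "a.tsv")),
         B = list(path = file.path(dir, "b3.tsv"))),
    file.path(dir, "labels.tsv"))
  expect_identical(ds3$sample_ids, c("s1", "s2", "s3"))
  expect_identical(ds3$blocks$B$values[, 1], c(s1 = 0.1, s2 = 0.2, s3 = 0.3))
})

test_that("loader rejects malformed inputs with informative errors", {
  dir <- withr::local_tempdir()
  writeLines(c("sample_id\tstage", "s1\tearly", "s2\tmid"),
             file.path(dir, "labels_bad.tsv"))
  writeLines(c("sample_id\tstage", "s1\tearly", "s1\tlate"),
             file.path(dir, "labels_dup.tsv"))
  writeLines(c("sample_id\tstage", "s1\tearly", "s2\tlate"),
             file.path(dir, "labels.tsv"))
  writeLines(c("sample_id\tf1", "s1\t1", "s2\tNOT_A_NUMBER"),
             file.path(dir, "bad.tsv"))
  writeLines(c("sample_id\tf1", "s1\t1", "s2\t2"), file.path(dir, "a.tsv"))
  writeLines(c("sample_id\tf1", "x1\t1", "x2\t2"),
             file.path(dir, "disjoint.tsv"))
  blocks_a <- list(A = list(path = file.path(dir, "a.tsv")))

  expect_error(load_dataset(blocks_a, file.path(dir, "labels_bad.tsv")),
               "mid")
  expect_error(load_dataset(blocks_a, file.path(dir, "labels_dup.tsv")),
               "duplicated sample ids")
  expect_error(
    load_dataset(list(A = list(path = file.path(dir, "bad.tsv"))),
                 file.path(dir, "labels.tsv")),
    "non-numeric")
  expect_error(
    load_dataset(list(A = list(path = file.path(dir, "disjoint.tsv"))),
                 file.path(dir, "labels.tsv")),
    "shares no samples")
})

test_that("T1-T4 stage labels map onto the early/late binary coding", {
  expect_identical(omicsMKL:::encode_labels(c("T1", "T2", "T3", "T4")),
                   c(-1L, -1L, 1L, 1L))
  expect_identical(omicsMKL:::encode_labels(c("late", "early")), c(1L, -1L))
})

test_that("validate_dataset reports violations naming the offender", {
  ds <- manual_dataset(list(A = matrix(rnorm(12), 4)),
                       labels = c(1, -1, 1, -1))
  expect_identical(validate_dataset(ds), character(0))

  bad <- ds
  bad$blocks$A$feature_ids[2] <- bad$blocks$A$feature_ids[1]
  v <- validate_dataset(bad)
  expect_length(v, 1)
  expect_match(v, "duplicated feature ids")
  expect_match(v, "A_f1")

  mono <- ds
  mono$labels <- rep(1L, 4)
  expect_match(validate_dataset(mono), "single class")
})

test_that("dataset constructors enforce alignment and uniqueness", {
  m <- matrix(rnorm(8), 4)
  expect_error(multiomics_dataset(c("s1", "s1", "s2", "s3"),
                                  c(1, -1, 1, -1),
                                  list(feature_block("A", m))),
               "duplicated sample ids")
  expect_error(multiomics_dataset(c("s1", "s2", "s3"), c(1, -1, 1),
                                  list(feature_block("A", m))),
               "3 samples")
  m_na <- m
  m_na[2, 1] <- NA
  expect_error(feature_block("A", m_na), "missing values")
})

test_that("subset_dataset restricts samples and blocks consistently", {
  sim <- generate_multiomics(synthetic_config(
    n_samples = 10, prevalence_positive = 0.4, seed = 1,
    blocks = list(list(name = "A", value_kind = "continuous", n_features = 3),
                  list(name = "B", value_kind = "continuous", n_features = 2))))
  ds <- sim$dataset
  sub <- subset_dataset(ds, samples = 3:7, blocks = "B")
  expect_identical(sub$sample_ids, ds$sample_ids[3:7])
  expect_identical(names(sub$blocks), "B")
  expect_identical(sub$blocks$B$values, ds$blocks$B$values[3:7, ])
  expect_error(subset_dataset(ds, blocks = "C"), "unknown block")
})
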