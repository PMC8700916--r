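#' Construct a single omics feature block
#'
#' A feature block is one molecular data type's sample-by-feature matrix,
#' e.g. gene-level copy number calls, CpG methylation beta values or gene
#' expression. Rows are samples, columns are features.
#'
#' @param name Block identifier, e.g. `"CNV"` or `"Methylation"`.
#' @param values Numeric matrix, rows = samples, columns = features.
#' @param feature_ids Character vector of unique feature identifiers; taken
#'   from `colnames(values)` when omitted.
#' @param value_kind One of `"integer-coded"` (e.g. CNV gain/loss calls in
#'   -2..2), `"unit-interval"` (e.g. methylation beta values) or
#'   `"continuous"`.
#' @return An object of class `feature_block`.
#' @export
feature_block <- function(name, values,
                          feature_ids = colnames(values),
                          value_kind = c("continuous", "integer-coded",
                                         "unit-interval")) {
  value_kind <- match.arg(value_kind)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(feature_ids)) {
    feature_ids <- paste0(name, "_f", seq_len(ncol(values)))
  }
  if (length(feature_ids) != ncol(values)) {
    stop("feature_ids length must equal column count in block '", name, "'")
  }
  if (anyDuplicated(feature_ids)) {
    stop("duplicated feature_ids in block '", name, "': ",
         paste(unique(feature_ids[duplicated(feature_ids)]), collapse = ", "))
  }
  if (anyNA(values)) {
    stop("block '", name, "' contains missing values; ",
         "load with impute = TRUE or clean the data first")
  }
  colnames(values) <- feature_ids
  structure(list(name = name, values = values, feature_ids = feature_ids,
                 value_kind = value_kind),
            class = "feature_block")
}

#' @export
print.feature_block <- function(x, ...) {
  cat(sprintf("<feature_block> %s: %d samples x %d features (%s)\n",
              x$name, nrow(x$values), ncol(x$values), x$value_kind))
  invisible(x)
}

#' Assemble a multi-omics dataset
#'
#' Binds aligned feature blocks with binary class labels. The convention
#' throughout the package is `+1` = late tumor stage (T3-T4) and `-1` =
#' early stage (T1-T2); any binary outcome can be coded the same way.
#'
#' @param sample_ids Character vector of unique sample identifiers.
#' @param labels Per-sample labels in `{+1, -1}` (or a factor/character
#'   vector with values `early`/`late`).
#' @param blocks List of [feature_block()] objects, each with
#'   `length(sample_ids)` rows in the same order.
#' @return An object of class `multiomics_dataset`.
#' @export
multiomics_dataset <- function(sample_ids, labels, blocks) {
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids)) {
    stop("duplicated sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  labels <- encode_labels(labels)
  if (length(labels) != length(sample_ids)) {
    stop("labels and sample_ids must have equal length")
  }
  if (length(blocks) < 1) stop("need at least one feature block")
  nm <- vapply(blocks, function(b) b$name, character(1))
  names(blocks) <- nm
  if (anyDuplicated(nm)) stop("duplicated block names")
  blocks <- lapply(blocks, function(b) {
    if (nrow(b$values) != length(sample_ids)) {
      stop("block '", b$name, "' has ", nrow(b$values),
           " rows but dataset has ", length(sample_ids), " samples")
    }
    rownames(b$values) <- sample_ids
    b
  })
  structure(list(sample_ids = sample_ids, labels = labels, blocks = blocks),
            class = "multiomics_dataset")
}

# map stage descriptions to the +/-1 coding (late stage = +1)
encode_labels <- function(labels) {
  if (is.numeric(labels)) {
    if (!all(labels %in% c(-1, 1))) {
      stop("numeric labels must be +1 (late) or -1 (early)")
    }
    return(as.integer(labels))
  }
  lab <- tolower(as.character(labels))
  map <- c(early = -1L, late = 1L, t1 = -1L, t2 = -1L, t3 = 1L, t4 = 1L)
  if (!all(lab %in% names(map))) {
    bad <- unique(lab[!lab %in% names(map)])
    stop("unrecognized stage label(s): ", paste(bad, collapse = ", "),
         " (expected early/late or T1..T4)")
  }
  unname(map[lab])
}

#' @export
print.multiomics_dataset <- function(x, ...) {
  cat(sprintf(
    "<multiomics_dataset> %d samples (%d late / %d early), %d blocks\n",
    length(x$sample_ids), sum(x$labels == 1), sum(x$labels == -1),
    length(x$blocks)))
  for (b in x$blocks) {
    cat(sprintf("  %-14s %6d features (%s)\n", b$name, ncol(b$values),
                b$value_kind))
  }
  invisible(x)
}

#' Number of samples and total feature count
#' @param ds A `multiomics_dataset`.
#' @return Integer.
#' @export
n_samples <- function(ds) length(ds$sample_ids)

#' @rdname n_samples
#' @export
n_features <- function(ds) {
  sum(vapply(ds$blocks, function(b) ncol(b$values), integer(1)))
}

#' Subset a multi-omics dataset by samples and/or blocks
#'
#' @param ds A `multiomics_dataset`.
#' @param samples Integer or character index of samples to keep.
#' @param blocks Character vector of block names to keep.
#' @return A `multiomics_dataset`.
#' @export
subset_dataset <- function(ds, samples = NULL, blocks = NULL) {
  keep_b <- ds$blocks
  if (!is.null(blocks)) {
    missing_b <- setdiff(blocks, names(ds$blocks))
    if (length(missing_b)) {
      stop("unknown block(s): ", paste(missing_b, collapse = ", "))
    }
    keep_b <- ds$blocks[blocks]
  }
  idx <- seq_along(ds$sample_ids)
  if (!is.null(samples)) {
    idx <- if (is.character(samples)) {
      match(samples, ds$sample_ids)
    } else {
      samples
    }
    if (anyNA(idx)) stop("unknown sample id(s) in subset")
  }
  keep_b <- lapply(keep_b, function(b) {
    feature_block(b$name, b$values[idx, , drop = FALSE], b$feature_ids,
                  b$value_kind)
  })
  multiomics_dataset(ds$sample_ids[idx], ds$labels[idx], keep_b)
}

#' Validate multi-omics dataset invariants
#'
#' Checks the structural invariants (unique sample and feature ids, aligned
#' row counts, both classes present, globally unique block/feature pairs,
#' no missing values) and reports violations rather than stopping.
#'
#' @param ds A `multiomics_dataset`.
#' @return Character vector of violation descriptions; empty when valid.
#' @export
validate_dataset <- function(ds) {
  out <- character(0)
  n <- length(ds$sample_ids)
  if (anyDuplicated(ds$sample_ids)) {
    out <- c(out, paste0("duplicated sample ids: ",
                         paste(unique(ds$sample_ids[duplicated(ds$sample_ids)]),
                               collapse = ", ")))
  }
  if (!all(ds$labels %in% c(-1L, 1L))) {
    out <- c(out, "labels outside {+1, -1}")
  }
  if (length(unique(ds$labels)) < 2) {
    out <- c(out, "single class: both label values must be present")
  }
  for (b in ds$blocks) {
    if (nrow(b$values) != n) {
      out <- c(out, paste0("block '", b$name, "' has ", nrow(b$values),
                           " rows, expected ", n))
    }
    if (anyDuplicated(b$feature_ids)) {
      dup <- unique(b$feature_ids[duplicated(b$feature_ids)])
      out <- c(out, paste0("block '", b$name, "' duplicated feature ids: ",
                           paste(dup, collapse = ", ")))
    }
    if (anyNA(b$values)) {
      out <- c(out, paste0("block '", b$name, "' contains missing values"))
    }
  }
  out
}

#' Read a multi-omics dataset from per-block TSV/CSV matrices
#'
#' Each matrix file has a header row of feature ids and a first column of
#' sample ids. The label file is a two-column TSV (`sample_id`, `stage`)
#' with stage in `early`/`late` or `T1..T4` (T1-T2 map to early, T3-T4 to
#' late). Samples are ordered as in the label file; samples missing from
#' any block are dropped with a message (the completeness filter used when
#' assembling multi-omics cohorts). Blocks sharing no samples with the
#' label file are an error.
#'
#' @param blocks Named list describing the blocks, each element a list with
#'   `path`, optional `value_kind` (default `"continuous"`) and optional
#'   `transpose` flag for files stored features-by-samples.
#' @param label_path Path to the label TSV.
#' @param impute Impute missing cells with the per-feature median instead
#'   of failing (logged). Default `FALSE`.
#' @return A `multiomics_dataset`.
#' @seealso [read_manifest()], [write_dataset()]
#' @export
load_dataset <- function(blocks, label_path, impute = FALSE) {
  lab <- data.table::fread(label_path, header = TRUE, sep = "\t",
                           colClasses = "character", data.table = FALSE)
  if (ncol(lab) < 2) stop("label file needs columns sample_id and stage")
  sample_ids <- lab[[1]]
  if (anyDuplicated(sample_ids)) {
    stop("duplicated sample ids in label file: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  labels <- encode_labels(lab[[2]])

  mats <- list()
  for (nm in names(blocks)) {
    spec <- blocks[[nm]]
    m <- read_matrix_file(spec$path, transpose = isTRUE(spec$transpose))
    if (anyNA(m)) {
      if (impute) {
        nmiss <- sum(is.na(m))
        for (j in seq_len(ncol(m))) {
          jna <- is.na(m[, j])
          if (any(jna)) m[jna, j] <- stats::median(m[, j], na.rm = TRUE)
        }
        message("block '", nm, "': imputed ", nmiss,
                " missing cells with per-feature medians")
      } else {
        stop("block '", nm, "' contains missing values; ",
             "set impute = TRUE to impute per-feature medians")
      }
    }
    if (length(intersect(rownames(m), sample_ids)) == 0) {
      stop("block '", nm, "' shares no samples with the label file")
    }
    mats[[nm]] <- m
  }

  keep <- sample_ids
  for (nm in names(mats)) keep <- keep[keep %in% rownames(mats[[nm]])]
  dropped <- length(sample_ids) - length(keep)
  if (dropped > 0) {
    message("dropped ", dropped,
            " sample(s) missing from at least one block")
  }
  if (length(keep) == 0) stop("no sample present in every block")

  fb <- lapply(names(mats), function(nm) {
    spec <- blocks[[nm]]
    feature_block(nm, mats[[nm]][keep, , drop = FALSE],
                  value_kind = spec$value_kind %||% "continuous")
  })
  multiomics_dataset(keep, labels[match(keep, sample_ids)], fb)
}

read_matrix_file <- function(path, transpose = FALSE) {
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  ids <- as.character(dt[[1]])
  m <- as.matrix(dt[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!vapply(dt[, -1, drop = FALSE], is.numeric, logical(1)))
    stop("non-numeric values in ", path, ", column(s): ",
         paste(colnames(dt)[bad + 1], collapse = ", "))
  }
  rownames(m) <- ids
  if (transpose) m <- t(m)
  if (anyDuplicated(rownames(m))) {
    stop("duplicated sample ids in ", path)
  }
  m
}

#' Load a dataset described by a manifest file
#'
#' The manifest is a YAML file with a `labels` entry (path to the label
#' TSV) and a `blocks` list, each with `name`, `path`, `value_kind` and an
#' optional `transpose` flag. Relative paths are resolved against the
#' manifest's directory.
#'
#' @param path Path to the manifest YAML.
#' @param impute Passed to [load_dataset()].
#' @return A `multiomics_dataset`.
#' @export
read_manifest <- function(path, impute = FALSE) {
  man <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (file.exists(p)) p else file.path(base, p)
  }
  blocks <- list()
  for (b in man$blocks) {
    blocks[[b$name]] <- list(path = resolve(b$path),
                             value_kind = b$value_kind %||% "continuous",
                             transpose = isTRUE(b$transpose))
  }
  load_dataset(blocks, resolve(man$labels), impute = impute)
}

#' Write a multi-omics dataset to TSV matrices plus a manifest
#'
#' Produces one `<block>.tsv` per block, a `labels.tsv` and a
#' `manifest.yaml`, in the formats [load_dataset()] reads, so that a
#' write/load round trip reproduces the dataset exactly.
#'
#' @param ds A `multiomics_dataset`.
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  for (b in ds$blocks) {
    # %.17g guarantees doubles survive the text round trip bit-exactly
    chr <- matrix(sprintf("%.17g", b$values), nrow(b$values),
                  dimnames = dimnames(b$values))
    df <- data.frame(sample_id = ds$sample_ids, chr, check.names = FALSE)
    f <- file.path(dir, paste0(b$name, ".tsv"))
    data.table::fwrite(df, f, sep = "\t", quote = FALSE)
    paths[[b$name]] <- basename(f)
  }
  lab <- data.frame(sample_id = ds$sample_ids,
                    stage = ifelse(ds$labels == 1, "late", "early"))
  data.table::fwrite(lab, file.path(dir, "labels.tsv"), sep = "\t")
  man <- list(
    labels = "labels.tsv",
    blocks = lapply(ds$blocks, function(b) {
      list(name = b$name, path = paths[[b$name]], value_kind = b$value_kind)
    })
  )
  names(man$blocks) <- NULL
  manifest <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(man, manifest)
  invisible(manifest)
}
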