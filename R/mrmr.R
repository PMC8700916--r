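#' Mutual information between two categorical vectors
#'
#' Plug-in (maximum-likelihood) estimate in bits:
#' `sum p(a,b) * log2(p(a,b) / (p(a) p(b)))` over observed cells, with
#' empty cells contributing zero and no pseudo-counts. Inputs may be
#' integer codes, factors, characters or logicals; the estimate is
#' invariant under relabeling of categories and symmetric in its
#' arguments.
#'
#' @param x,y Equal-length categorical vectors.
#' @return Nonnegative mutual information in bits.
#' @export
mutual_information <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  mi_discrete_cpp(as_codes(x), as_codes(y))
}

as_codes <- function(x) {
  if (is.integer(x)) return(x)
  if (is.double(x)) {
    xi <- as.integer(round(x))
    if (max(abs(x - xi)) > 1e-8) {
      stop("numeric categorical codes must be whole numbers")
    }
    return(xi)
  }
  as.integer(factor(x))
}

#' Per-feature relevance: mutual information with the class
#'
#' @param codes Integer matrix of categorical codes (samples x features),
#'   e.g. from [discretize_dataset()].
#' @param labels Per-sample class labels in `{+1, -1}` (any categorical
#'   coding works).
#' @return Numeric vector of per-column mutual information in bits.
#' @export
max_relevance_scores <- function(codes, labels) {
  codes <- as_code_matrix(codes)
  relevance_cpp(codes, as_codes(labels))
}

as_code_matrix <- function(codes) {
  if (is.list(codes) && !is.null(codes$codes)) codes <- codes$codes
  codes <- as.matrix(codes)
  if (is.double(codes)) storage.mode(codes) <- "integer"
  codes
}

#' mRMR feature ranking
#'
#' Incremental minimum-redundancy-maximum-relevance ordering: the first
#' feature maximizes mutual information with the class; feature `m`
#' maximizes `I(x_j; c) - mean over selected x' of I(x_j; x')` among
#' unselected features, stopping at `cap` features. Ties are broken by
#' higher relevance, then by column order. Pairwise mutual information is
#' accumulated incrementally against selected features only, so ranking
#' scales to tens of thousands of candidate features.
#'
#' @param codes Integer code matrix or the result of
#'   [discretize_dataset()] (whose feature map is then carried into the
#'   ranking).
#' @param labels Class labels; both classes must be present.
#' @param cap Maximum ranking length (default 500).
#' @return A `ranked_features` data.frame with columns `rank`, `block`,
#'   `feature_id`, `column` (position in the joined matrix), `relevance`
#'   (bits) and `score` (the achieved selection criterion, bits).
#' @export
mrmr_rank <- function(codes, labels, cap = 500) {
  features <- NULL
  if (is.list(codes) && !is.null(codes$features)) features <- codes$features
  m <- as_code_matrix(codes)
  y <- as_codes(labels)
  if (length(unique(y)) < 2) {
    stop("labels contain a single class; mRMR needs both classes")
  }
  stopifnot(cap >= 1)
  res <- mrmr_rank_cpp(m, y, as.integer(cap))
  k <- length(res$order)
  out <- data.frame(rank = seq_len(k),
                    block = NA_character_,
                    feature_id = colnames(m)[res$order] %||% NA_character_,
                    column = res$order,
                    relevance = res$relevance[res$order],
                    score = res$score,
                    stringsAsFactors = FALSE)
  if (!is.null(features)) {
    out$block <- features$block[res$order]
    out$feature_id <- features$feature_id[res$order]
  }
  class(out) <- c("ranked_features", "data.frame")
  out
}

#' Discretize a dataset and rank all features by mRMR
#'
#' Convenience wrapper chaining [discretize_dataset()] and [mrmr_rank()]
#' on (typically training) samples.
#'
#' @param ds A `multiomics_dataset`.
#' @param alpha Discretization band half-width.
#' @param cap Maximum ranking length.
#' @return A `ranked_features` data.frame.
#' @export
rank_features <- function(ds, alpha = 0.5, cap = 500) {
  dd <- discretize_dataset(ds, alpha)
  mrmr_rank(dd, ds$labels, cap = cap)
}

#' @export
print.ranked_features <- function(x, ...) {
  cat(sprintf("<ranked_features> %d features (top relevance %.4f bits)\n",
              nrow(x), if (nrow(x)) x$relevance[1] else NA_real_))
  print.data.frame(head(x, 10))
  if (nrow(x) > 10) cat("  ...", nrow(x) - 10, "more\n")
  invisible(x)
}
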