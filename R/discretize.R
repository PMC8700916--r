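#' Ternary discretization of a continuous feature
#'
#' Codes each value relative to a band of half-width `alpha` standard
#' deviations around the mean: `-1` below `mu - alpha*sigma`, `0` inside
#' the closed band `[mu - alpha*sigma, mu + alpha*sigma]`, `+1` above.
#' `mu` and `sigma` default to the mean and sample (n-1) standard
#' deviation of `x`, but can be supplied so that statistics fitted on
#' training samples code held-out samples without information leakage.
#' A constant feature (`sigma = 0`) codes to all zeros.
#'
#' @param x Numeric vector, length >= 2 unless `center`/`scale` are given.
#' @param alpha Positive band half-width in standard deviations
#'   (default 0.5).
#' @param center,scale Optional externally fitted mean and standard
#'   deviation.
#' @return Integer vector of codes in `{-1, 0, 1}`.
#' @export
discretize_feature <- function(x, alpha = 0.5, center = NULL, scale = NULL) {
  stopifnot(alpha > 0)
  if (is.null(center) || is.null(scale)) {
    if (length(x) < 2) stop("need at least 2 values to fit mu and sigma")
    center <- mean(x)
    scale <- sd(x)
  }
  if (!is.finite(scale) || scale == 0) {
    return(rep(0L, length(x)))
  }
  lo <- center - alpha * scale
  hi <- center + alpha * scale
  out <- integer(length(x))
  out[x < lo] <- -1L
  out[x > hi] <- 1L
  out
}

#' Fit discretization statistics on a feature block
#'
#' Computes per-feature mean and sample standard deviation (the coding
#' statistics), typically on training samples only, so that
#' [apply_discretizer()] can code any sample set with training-derived
#' thresholds. Integer-coded blocks (e.g. CNV calls) are marked as
#' pass-through: their values are already categorical and are not
#' re-coded.
#'
#' @param block A [feature_block()].
#' @param alpha Band half-width in standard deviations.
#' @return An object of class `discretizer_fit`.
#' @export
fit_discretizer <- function(block, alpha = 0.5) {
  stopifnot(inherits(block, "feature_block"), alpha > 0)
  pass <- block$value_kind == "integer-coded"
  structure(list(block_name = block$name, alpha = alpha,
                 pass_through = pass,
                 center = if (pass) NULL else colMeans(block$values),
                 scale = if (pass) NULL else apply(block$values, 2, sd),
                 feature_ids = block$feature_ids),
            class = "discretizer_fit")
}

#' @rdname fit_discretizer
#' @param fit A `discretizer_fit`.
#' @param values Numeric matrix with the fitted block's features as
#'   columns.
#' @return Integer matrix of categorical codes.
#' @export
apply_discretizer <- function(fit, values) {
  stopifnot(inherits(fit, "discretizer_fit"))
  values <- as.matrix(values)
  if (ncol(values) != length(fit$feature_ids)) {
    stop("column count does not match the fitted block")
  }
  if (fit$pass_through) {
    codes <- round(values)
    storage.mode(codes) <- "integer"
  } else {
    codes <- matrix(0L, nrow(values), ncol(values))
    for (j in seq_len(ncol(values))) {
      codes[, j] <- discretize_feature(values[, j], fit$alpha,
                                       center = fit$center[j],
                                       scale = fit$scale[j])
    }
  }
  colnames(codes) <- fit$feature_ids
  codes
}

#' Discretize a whole feature block
#'
#' Column-wise ternary coding of a block with statistics estimated from
#' the block itself; integer-coded blocks pass through unchanged as
#' categorical codes.
#'
#' @inheritParams fit_discretizer
#' @return Integer matrix of categorical codes.
#' @export
discretize_block <- function(block, alpha = 0.5) {
  apply_discretizer(fit_discretizer(block, alpha), block$values)
}

#' Discretize every block of a dataset into one joined categorical matrix
#'
#' The joined matrix is the input to mutual-information estimation and
#' mRMR ranking; the accompanying feature map locates each column in its
#' originating block.
#'
#' @param ds A `multiomics_dataset`.
#' @param alpha Band half-width in standard deviations.
#' @return A list with `codes` (integer matrix, samples x all features)
#'   and `features` (data.frame with columns `block`, `feature_id`,
#'   `column` giving the source column index within the block).
#' @export
discretize_dataset <- function(ds, alpha = 0.5) {
  stopifnot(inherits(ds, "multiomics_dataset"))
  mats <- lapply(ds$blocks, discretize_block, alpha = alpha)
  refs <- lapply(ds$blocks, function(b) {
    data.frame(block = b$name, feature_id = b$feature_ids,
               column = seq_along(b$feature_ids),
               stringsAsFactors = FALSE)
  })
  list(codes = do.call(cbind, mats),
       features = do.call(rbind, c(refs, make.row.names = FALSE)))
}
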