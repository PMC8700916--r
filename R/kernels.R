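#' Kernel specification for one omics block
#'
#' Each omics block gets one Gaussian and one polynomial kernel by
#' default. The Gaussian bandwidth defaults to the median heuristic
#' (median of the nonzero pairwise training distances); the polynomial
#' kernel is `(x . x' / q + offset)^degree` with `q` the block's selected
#' feature count, so inner products stay commensurable across blocks of
#' very different dimension. All kernels are spherically normalized to
#' unit diagonal.
#'
#' @param block_name Name of the omics block the kernel is computed on.
#' @param family `"gaussian"` or `"polynomial"`.
#' @param bandwidth Gaussian bandwidth: `"median"` for the median
#'   heuristic or a fixed positive number.
#' @param degree Polynomial degree (default 2).
#' @param offset Polynomial offset (default 1).
#' @return An object of class `kernel_spec`.
#' @export
kernel_spec <- function(block_name, family = c("gaussian", "polynomial"),
                        bandwidth = "median", degree = 2, offset = 1) {
  family <- match.arg(family)
  if (is.numeric(bandwidth) && bandwidth <= 0) stop("bandwidth must be > 0")
  if (degree < 1) stop("degree must be >= 1")
  structure(list(block_name = block_name, family = family,
                 bandwidth = bandwidth, degree = degree, offset = offset),
            class = "kernel_spec")
}

#' Build a normalized kernel matrix on training samples
#'
#' Computes the raw Gaussian `exp(-||x - x'||^2 / (2 s^2))` or polynomial
#' `(x . x' / q + offset)^degree` Gram matrix on the supplied (already
#' preprocessed) block submatrix, then applies spherical normalization
#' `K(x,x') / sqrt(K(x,x) K(x',x'))` so every kernel has unit diagonal.
#' The resolved bandwidth and the raw training self-similarities are kept
#' on the object so that test samples can later be normalized against the
#' training geometry.
#'
#' @param x Numeric training matrix (samples x selected features of one
#'   block), at least 2 samples and 1 feature.
#' @param spec A [kernel_spec()].
#' @return An object of class `kernel_matrix` with fields `values`
#'   (normalized symmetric Gram matrix), `spec` (with bandwidth resolved)
#'   and `diag_raw`.
#' @export
build_kernel <- function(x, spec) {
  stopifnot(inherits(spec, "kernel_spec"))
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("need at least 2 samples")
  if (ncol(x) < 1) stop("need at least 1 feature")
  if (spec$family == "gaussian") {
    d2 <- sq_dist(x, x)
    if (identical(spec$bandwidth, "median")) {
      d <- sqrt(d2[upper.tri(d2)])
      d <- d[d > 0]
      spec$bandwidth <- if (length(d)) median(d) else 1
    }
    raw <- exp(-d2 / (2 * spec$bandwidth^2))
  } else {
    raw <- (tcrossprod(x) / ncol(x) + spec$offset)^spec$degree
  }
  diag_raw <- diag(raw)
  if (any(diag_raw <= 0)) stop("non-positive kernel self-similarity")
  inv <- 1 / sqrt(diag_raw)
  values <- raw * tcrossprod(inv)
  diag(values) <- 1
  structure(list(values = values, spec = spec, diag_raw = diag_raw),
            class = "kernel_matrix")
}

# squared euclidean distances between rows of a and rows of b
sq_dist <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}

# normalized cross-kernel between new samples (rows of xnew) and the
# training samples the kernel was built on
cross_kernel <- function(km, xtrain, xnew) {
  spec <- km$spec
  if (spec$family == "gaussian") {
    raw <- exp(-sq_dist(xnew, xtrain) / (2 * spec$bandwidth^2))
    dnew <- rep(1, nrow(xnew))
  } else {
    raw <- (tcrossprod(xnew, xtrain) / ncol(xtrain) + spec$offset)^spec$degree
    dnew <- (rowSums(xnew^2) / ncol(xtrain) + spec$offset)^spec$degree
  }
  raw / sqrt(outer(dnew, km$diag_raw))
}

#' Convex combination of kernel matrices
#'
#' Elementwise weighted sum `sum(d_m * K_m)` with the weights on the
#' probability simplex (`d_m >= 0`, `sum d_m = 1`).
#'
#' @param kernels List of `kernel_matrix` objects (or plain matrices) of
#'   equal dimension.
#' @param d Weight vector on the simplex.
#' @return A `kernel_matrix` with family `"combined"`.
#' @export
combine_kernels <- function(kernels, d) {
  mats <- lapply(kernels, function(k) {
    if (inherits(k, "kernel_matrix")) k$values else as.matrix(k)
  })
  if (length(mats) != length(d)) stop("one weight per kernel required")
  dims <- vapply(mats, dim, integer(2))
  if (any(dims != dims[, 1])) stop("kernel matrices must share dimensions")
  if (any(d < 0)) stop("kernel weights must be nonnegative")
  if (abs(sum(d) - 1) > 1e-8) stop("kernel weights must sum to 1")
  out <- matrix(0, dims[1, 1], dims[2, 1])
  for (m in seq_along(mats)) {
    if (d[m] != 0) out <- out + d[m] * mats[[m]]
  }
  structure(list(values = out,
                 spec = list(block_name = "combined", family = "combined"),
                 diag_raw = diag(out)),
            class = "kernel_matrix")
}

#' @export
print.kernel_matrix <- function(x, ...) {
  cat(sprintf("<kernel_matrix> %s/%s: %d x %d\n", x$spec$block_name,
              x$spec$family, nrow(x$values), ncol(x$values)))
  invisible(x)
}
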