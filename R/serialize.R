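#' Save / load a fitted model as a self-describing JSON archive
#'
#' The archive stores everything prediction needs: the selected features,
#' per-block standardization statistics, the (standardized) training
#' submatrices that anchor the kernel expansion, the resolved kernel
#' specifications with their raw training self-similarities, the learned
#' kernel weights, signed dual coefficients and bias, plus a `schema`
#' entry naming the format and version. Plain text, so archives are
#' diff-able and portable.
#'
#' @param model An `omics_mkl_model` from [mkl_fit()].
#' @param path Output file path (conventionally `.json`).
#' @return `path`, invisibly.
#' @export
save_mkl_model <- function(model, path) {
  stopifnot(inherits(model, "omics_mkl_model"))
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop("model serialization requires the jsonlite package")
  }
  obj <- list(
    schema = list(format = "omicsMKL-model", version = 1L),
    C = model$C,
    sample_ids = model$sample_ids,
    labels = model$labels,
    features = model$features,
    kernel_names = names(model$kernels),
    kernel_weights = unname(model$kernel_weights),
    coef = model$core$coef,
    b = model$core$b,
    convergence = model$core$convergence[c("iterations", "gap",
                                           "converged")],
    blocks = lapply(names(model$prep), function(bn) {
      list(name = bn,
           feature_ids = model$prep[[bn]]$feature_ids,
           center = unname(model$prep[[bn]]$center),
           scale = unname(model$prep[[bn]]$scale),
           xtrain = unname(model$xtrain[[bn]]))
    }),
    kernels = lapply(unname(model$kernels), function(k) {
      list(block_name = k$spec$block_name, family = k$spec$family,
           bandwidth = k$spec$bandwidth, degree = k$spec$degree,
           offset = k$spec$offset, diag_raw = unname(k$diag_raw))
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_mkl_model
#' @return For `load_mkl_model`, an `omics_mkl_model` whose predictions
#'   reproduce the saved model's.
#' @export
load_mkl_model <- function(path) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop("model serialization requires the jsonlite package")
  }
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(obj$schema$format, "omicsMKL-model")) {
    stop(path, " is not an omicsMKL model archive")
  }
  num <- function(x) as.numeric(unlist(x))
  chr <- function(x) as.character(unlist(x))
  prep <- list()
  xtrain <- list()
  for (b in obj$blocks) {
    ids <- chr(b$feature_ids)
    prep[[b$name]] <- list(feature_ids = ids,
                           center = stats::setNames(num(b$center), ids),
                           scale = stats::setNames(num(b$scale), ids))
    x <- do.call(rbind, lapply(b$xtrain, num))
    colnames(x) <- ids
    xtrain[[b$name]] <- x
  }
  kernels <- lapply(obj$kernels, function(k) {
    bw <- if (is.character(k$bandwidth)) k$bandwidth else num(k$bandwidth)
    structure(list(values = NULL,
                   spec = structure(list(block_name = k$block_name,
                                         family = k$family,
                                         bandwidth = bw,
                                         degree = num(k$degree),
                                         offset = num(k$offset)),
                                    class = "kernel_spec"),
                   diag_raw = num(k$diag_raw)),
              class = "kernel_matrix")
  })
  names(kernels) <- chr(obj$kernel_names)
  features <- data.frame(
    block = vapply(obj$features, function(f) f$block, character(1)),
    feature_id = vapply(obj$features, function(f) f$feature_id,
                        character(1)),
    stringsAsFactors = FALSE)
  w <- stats::setNames(num(obj$kernel_weights), names(kernels))
  core <- list(d = unname(w), coef = num(obj$coef), b = num(obj$b),
               convergence = list(iterations = num(obj$convergence$iterations),
                                  gap = num(obj$convergence$gap),
                                  converged = isTRUE(unlist(
                                    obj$convergence$converged))))
  structure(list(core = core, kernels = kernels, prep = prep,
                 xtrain = xtrain, features = features, C = num(obj$C),
                 sample_ids = chr(obj$sample_ids),
                 labels = as.integer(unlist(obj$labels)),
                 kernel_weights = w),
            class = "omics_mkl_model")
}
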