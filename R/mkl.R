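#' Train a multiple-kernel SVM by alternating SVM solves and reduced
#' gradient steps on the kernel weights
#'
#' Learns a convex combination `K(d) = sum(d_m K_m)` jointly with the SVM:
#' at each iteration the SVM dual is solved on the current combined kernel
#' (warm-started), the gradient of the objective with respect to the
#' weights, `dJ/dd_m = -0.5 * a' Y K_m Y a`, is projected onto the simplex
#' as a reduced-gradient descent direction, and a backtracking line search
#' (each trial re-solving the SVM) accepts only objective-decreasing
#' steps. Termination is by relative duality gap: with
#' `S_m = a' Y K_m Y a`, the gap is
#' `0.5 * (max_m S_m - sum_m d_m S_m) / |J|`.
#'
#' @param kernels List of `kernel_matrix` objects (or matrices) over the
#'   same training samples.
#' @param labels Vector in `{+1, -1}`.
#' @param C Soft-margin cost.
#' @param tol Relative duality-gap threshold (default 1e-3).
#' @param max_iter Maximum outer iterations (default 200).
#' @param svm_eps KKT tolerance of the inner SVM solver.
#' @return An object of class `mkl_fit` with fields `d` (kernel weights on
#'   the simplex), `alpha`, `coef` (signed duals), `b`, `objective`,
#'   `decision` (training decision values) and `convergence` (iterations,
#'   final relative gap, `converged` flag, objective trace `J_trace` and
#'   per-iteration weight trace `d_trace`).
#' @export
train_simplemkl <- function(kernels, labels, C = 1, tol = 1e-3,
                            max_iter = 200, svm_eps = 1e-8) {
  M <- length(kernels)
  if (M < 1) stop("need at least one kernel")
  mats <- lapply(kernels, function(k) {
    if (inherits(k, "kernel_matrix")) k$values else as.matrix(k)
  })
  y <- as.integer(labels)

  d <- rep(1 / M, M)
  solve_at <- function(d, warm) {
    Kd <- Reduce(`+`, Map(`*`, d, mats))
    solve_svm_fixed_weights(Kd, y, C = C, eps = svm_eps, alpha0 = warm)
  }

  fit <- solve_at(d, NULL)
  J <- fit$objective
  J_trace <- J
  d_trace <- list(d)
  gap <- Inf
  iters <- 0L

  for (it in seq_len(max_iter)) {
    iters <- it
    ay <- fit$coef
    S <- vapply(mats, function(K) drop(crossprod(ay, K %*% ay)), numeric(1))
    gap <- 0.5 * (max(S) - sum(d * S)) / max(abs(J), .Machine$double.eps)
    if (gap <= tol) break

    grad <- -0.5 * S
    mu <- which.max(d)
    red <- grad - grad[mu]
    D <- numeric(M)
    active <- d > 0 | red < 0
    D[active] <- -red[active]
    D[mu] <- 0
    D[mu] <- -sum(D)
    if (max(abs(D)) < 1e-12) break

    neg <- which(D < 0)
    gmax <- min(-d[neg] / D[neg])
    if (!is.finite(gmax) || gmax <= 0) break

    # backtracking line search; each trial solves the SVM (warm-started)
    gamma <- gmax
    improved <- FALSE
    for (ls in 1:12) {
      d_try <- d + gamma * D
      # snap components extinguished by the step (up to float error) to 0,
      # otherwise a ~1e-16 residue caps the next step length at ~1e-16
      d_try[d_try < 1e-10] <- 0
      d_try <- d_try / sum(d_try)
      fit_try <- solve_at(d_try, fit$alpha)
      if (fit_try$objective < J - 1e-12 * max(1, abs(J))) {
        d <- d_try
        fit <- fit_try
        J <- fit$objective
        improved <- TRUE
        break
      }
      gamma <- gamma / 2
    }
    J_trace <- c(J_trace, J)
    d_trace <- c(d_trace, list(d))
    if (!improved) break
  }

  converged <- gap <= tol
  if (!converged) {
    warning(sprintf(
      "simpleMKL stopped after %d iterations with relative gap %.3e > %g",
      iters, gap, tol))
  }
  structure(list(d = d, alpha = fit$alpha, coef = fit$coef, b = fit$b,
                 objective = J, decision = fit$decision,
                 convergence = list(iterations = iters, gap = gap,
                                    converged = converged,
                                    J_trace = J_trace, d_trace = d_trace)),
            class = "mkl_fit")
}

#' Fit the full multi-omics MKL classifier on a dataset
#'
#' End-to-end training on (typically training-fold) samples: the selected
#' features are taken per block, z-scored with training statistics, a
#' Gaussian and/or polynomial kernel is built per block, and the
#' multiple-kernel SVM is trained. Blocks with no selected feature
#' contribute no kernels; their weight mass redistributes over the
#' remaining kernels (a warning of class `omicsmkl_empty_block` is
#' signalled).
#'
#' @param ds Training `multiomics_dataset`.
#' @param features Data.frame with columns `block` and `feature_id` (e.g.
#'   the head of a [mrmr_rank()] result) naming the features to use.
#' @param C Soft-margin cost (default 1).
#' @param families Kernel families built per block (default both Gaussian
#'   and polynomial).
#' @param degree,offset Polynomial kernel parameters.
#' @param bandwidth Gaussian bandwidth rule or fixed value.
#' @param tol,max_iter simpleMKL convergence controls.
#' @return An object of class `omics_mkl_model`.
#' @export
mkl_fit <- function(ds, features, C = 1,
                    families = c("gaussian", "polynomial"),
                    degree = 2, offset = 1, bandwidth = "median",
                    tol = 1e-3, max_iter = 200) {
  stopifnot(inherits(ds, "multiomics_dataset"))
  features <- as.data.frame(features)[, c("block", "feature_id")]
  if (nrow(features) < 1) stop("no features selected")

  prep <- list()
  kernels <- list()
  xtrain <- list()
  for (bn in names(ds$blocks)) {
    ids <- features$feature_id[features$block == bn]
    if (length(ids) == 0) {
      warning(warningCondition(
        paste0("block '", bn,
               "' has no selected features; its kernels are omitted"),
        class = "omicsmkl_empty_block"))
      next
    }
    b <- ds$blocks[[bn]]
    miss <- setdiff(ids, b$feature_ids)
    if (length(miss)) {
      stop("feature(s) not in block '", bn, "': ",
           paste(miss, collapse = ", "))
    }
    x <- b$values[, ids, drop = FALSE]
    ctr <- colMeans(x)
    scl <- apply(x, 2, sd)
    scl[scl == 0 | !is.finite(scl)] <- 1
    xs <- scale(x, center = ctr, scale = scl)
    attr(xs, "scaled:center") <- NULL
    attr(xs, "scaled:scale") <- NULL
    prep[[bn]] <- list(feature_ids = ids, center = ctr, scale = scl)
    xtrain[[bn]] <- xs
    for (fam in families) {
      km <- build_kernel(xs, kernel_spec(bn, fam, bandwidth = bandwidth,
                                         degree = degree, offset = offset))
      kernels[[paste(bn, fam, sep = ".")]] <- km
    }
  }
  if (length(kernels) == 0) stop("no block has any selected feature")

  core <- train_simplemkl(kernels, ds$labels, C = C, tol = tol,
                          max_iter = max_iter)
  structure(list(core = core, kernels = kernels, prep = prep,
                 xtrain = xtrain, features = features, C = C,
                 sample_ids = ds$sample_ids, labels = ds$labels,
                 kernel_weights = stats::setNames(core$d, names(kernels))),
            class = "omics_mkl_model")
}

#' @export
print.omics_mkl_model <- function(x, ...) {
  cat(sprintf(
    "<omics_mkl_model> %d training samples, %d features, %d kernels\n",
    length(x$sample_ids), nrow(x$features), length(x$kernels)))
  w <- round(x$kernel_weights, 4)
  cat("kernel weights:\n")
  print(w)
  cat(sprintf("converged: %s (relative gap %.2e, %d iterations)\n",
              x$core$convergence$converged, x$core$convergence$gap,
              x$core$convergence$iterations))
  invisible(x)
}

# per-block standardized feature submatrix for new samples
model_block_matrix <- function(model, bn, newdata) {
  pr <- model$prep[[bn]]
  if (inherits(newdata, "multiomics_dataset")) {
    if (!bn %in% names(newdata$blocks)) {
      stop("new data lacks block '", bn, "'")
    }
    b <- newdata$blocks[[bn]]
    miss <- setdiff(pr$feature_ids, b$feature_ids)
    if (length(miss)) {
      stop("new data block '", bn, "' is missing feature(s): ",
           paste(miss, collapse = ", "))
    }
    x <- b$values[, pr$feature_ids, drop = FALSE]
  } else {
    x <- as.matrix(newdata[[bn]])
    miss <- setdiff(pr$feature_ids, colnames(x))
    if (length(miss)) {
      stop("new data block '", bn, "' is missing feature(s): ",
           paste(miss, collapse = ", "))
    }
    x <- x[, pr$feature_ids, drop = FALSE]
  }
  scale(x, center = pr$center, scale = pr$scale)
}

#' Decision values and class predictions for new samples
#'
#' The decision function is `f(x) = sum_i a*_i K(x, x_i) + b*` with
#' `K = sum_m d_m K_m`; cross-kernels use the training-derived bandwidths
#' and training self-similarities for spherical normalization, and new
#' features are standardized with the training statistics. The predicted
#' class is the sign of the decision value, with a score of exactly zero
#' mapped to `+1`.
#'
#' @param object An `omics_mkl_model`.
#' @param newdata A `multiomics_dataset` or a named list of per-block
#'   matrices carrying (at least) the model's selected features.
#' @param type `"decision"` for real-valued scores, `"class"` for labels
#'   in `{+1, -1}`.
#' @param ... Unused.
#' @return Numeric scores or integer labels, named by sample when
#'   available.
#' @export
predict.omics_mkl_model <- function(object, newdata,
                                    type = c("decision", "class"), ...) {
  type <- match.arg(type)
  xnew <- list()
  for (bn in names(object$prep)) {
    xnew[[bn]] <- model_block_matrix(object, bn, newdata)
  }
  n_new <- nrow(xnew[[1]])
  score <- rep(object$core$b, n_new)
  d <- object$core$d
  coef <- object$core$coef
  for (m in seq_along(object$kernels)) {
    if (d[m] == 0) next
    km <- object$kernels[[m]]
    bn <- km$spec$block_name
    Kc <- cross_kernel(km, object$xtrain[[bn]], xnew[[bn]])
    score <- score + d[m] * as.numeric(Kc %*% coef)
  }
  if (inherits(newdata, "multiomics_dataset")) {
    names(score) <- newdata$sample_ids
  }
  if (type == "class") ifelse(score >= 0, 1L, -1L) else score
}
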