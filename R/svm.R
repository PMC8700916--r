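#' Solve the soft-margin SVM dual on a fixed (combined) kernel
#'
#' Sequential minimal optimization on the C-SVC dual
#' `max sum(alpha) - 0.5 sum_ij alpha_i alpha_j y_i y_j K_ij` subject to
#' `0 <= alpha_i <= C` and `sum alpha_i y_i = 0`, with maximal-violating-
#' pair working-set selection. The bias is recovered from the KKT
#' conditions on free (non-bound) support vectors.
#'
#' @param K A `kernel_matrix` or plain symmetric Gram matrix.
#' @param labels Vector in `{+1, -1}`; both classes must be present.
#' @param C Soft-margin cost (default 1).
#' @param eps KKT violation tolerance for termination (default 1e-8).
#' @param max_iter Working-set iteration budget; default `100 * n`,
#'   at least 10000.
#' @param alpha0 Optional warm-start multipliers (must be feasible).
#' @return List with `alpha` (multipliers), `coef` (signed duals
#'   `alpha_i * y_i`), `b` (bias), `objective` (dual objective at the
#'   solution), `decision` (training decision values), `iterations`,
#'   `kkt_gap` and `converged`.
#' @export
solve_svm_fixed_weights <- function(K, labels, C = 1, eps = 1e-8,
                                    max_iter = NULL, alpha0 = NULL) {
  Kv <- if (inherits(K, "kernel_matrix")) K$values else as.matrix(K)
  y <- as.integer(labels)
  if (!all(y %in% c(-1L, 1L))) stop("labels must be +1/-1")
  if (length(unique(y)) < 2) stop("both classes must be present")
  if (C <= 0) stop("C must be positive")
  n <- nrow(Kv)
  if (is.null(max_iter)) max_iter <- max(10000L, 100L * n)
  if (is.null(alpha0)) alpha0 <- numeric(0)
  fit <- smo_solve_cpp(Kv, y, C, eps, as.integer(max_iter),
                       as.numeric(alpha0))
  if (!fit$converged && fit$kkt_gap > sqrt(eps)) {
    stop(sprintf(
      "SVM solver did not converge in %d iterations (KKT gap %.3e)",
      fit$iterations, fit$kkt_gap))
  }
  coef <- fit$alpha * y
  fit$coef <- coef
  fit$decision <- as.numeric(Kv %*% coef) + fit$b
  fit
}
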