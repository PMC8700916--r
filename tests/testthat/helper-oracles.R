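# Independent brute-force oracles used to validate the implementation.
# These deliberately use naive table/loop arithmetic, never the package's
# own code paths.

# plug-in mutual information in bits via a contingency table
mi_oracle <- function(x, y) {
  tab <- table(x, y)
  n <- sum(tab)
  mi <- 0
  for (a in seq_len(nrow(tab))) {
    for (b in seq_len(ncol(tab))) {
      c_ab <- tab[a, b]
      if (c_ab == 0) next
      pab <- c_ab / n
      mi <- mi + pab * log2(pab / ((sum(tab[a, ]) / n) * (sum(tab[, b]) / n)))
    }
  }
  mi
}

entropy_oracle <- function(x) {
  p <- table(x) / length(x)
  -sum(p * log2(p))
}

# step-by-step mRMR: re-evaluates the selection criterion over every
# remaining candidate at every step (relevance minus mean pairwise MI
# with the selected set), ties by higher relevance then column order
mrmr_brute <- function(X, y, cap = ncol(X)) {
  p <- ncol(X)
  rel <- vapply(seq_len(p), function(j) mi_oracle(X[, j], y), numeric(1))
  selected <- integer(0)
  for (m in seq_len(min(cap, p))) {
    cand <- setdiff(seq_len(p), selected)
    crit <- vapply(cand, function(j) {
      if (length(selected) == 0) return(rel[j])
      red <- mean(vapply(selected, function(s) mi_oracle(X[, j], X[, s]),
                         numeric(1)))
      rel[j] - red
    }, numeric(1))
    best <- cand[crit == max(crit)]
    if (length(best) > 1) best <- best[rel[best] == max(rel[best])]
    selected <- c(selected, best[1])
  }
  selected
}

# AUC by exhaustive positive/negative pair counting, ties worth one half
auc_pairs <- function(scores, labels) {
  sp <- scores[labels == 1]
  sn <- scores[labels == -1]
  tot <- 0
  for (a in sp) for (b in sn) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}

# SVM dual solved by kernlab's interior-point QP, as an implementation-
# independent reference: max sum(a) - 0.5 a' (yy' * K) a,
# 0 <= a <= C, sum(a y) = 0
svm_qp_oracle <- function(K, y, C) {
  H <- K * tcrossprod(y)
  n <- length(y)
  sol <- kernlab::ipop(c = rep(-1, n), H = H, A = matrix(as.numeric(y), 1),
                       b = 0, l = rep(0, n), u = rep(C, n), r = 0,
                       sigf = 10, maxiter = 100)
  alpha <- kernlab::primal(sol)
  coef <- alpha * y
  u <- as.numeric(K %*% coef)
  free <- alpha > 1e-7 * C & alpha < C * (1 - 1e-7)
  b <- if (any(free)) mean(y[free] - u[free]) else 0
  list(alpha = alpha, b = b,
       objective = sum(alpha) - 0.5 * drop(crossprod(alpha, H %*% alpha)),
       decision = u + b)
}

# small two-block dataset where only the first block carries class signal
signal_noise_dataset <- function(seed, n = 80, p_sig = 10, p_noise = 40,
                                 effect = 2) {
  cfg <- synthetic_config(
    n_samples = n, prevalence_positive = 0.4, seed = seed,
    blocks = list(
      list(name = "Signal", value_kind = "continuous", n_features = p_sig,
           n_informative = p_sig, effect_size = effect),
      list(name = "Noise", value_kind = "continuous", n_features = p_noise)
    ))
  generate_multiomics(cfg)$dataset
}

with_seed_shuffle <- function(x, seed) {
  withr::with_seed(seed, sample(x))
}

# tiny hand-buildable dataset from explicit matrices
manual_dataset <- function(blocks, labels,
                           sample_ids = sprintf("s%d", seq_along(labels))) {
  fbs <- lapply(names(blocks), function(nm) {
    m <- blocks[[nm]]
    if (is.null(colnames(m))) {
      colnames(m) <- sprintf("%s_f%d", nm, seq_len(ncol(m)))
    }
    feature_block(nm, m, value_kind = "continuous")
  })
  multiomics_dataset(sample_ids, labels, fbs)
}
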