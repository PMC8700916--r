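#' Configure a synthetic multi-omics dataset
#'
#' Describes a dataset of class-conditional Gaussian feature blocks with a
#' known set of class-informative features, optional correlated
#' ("redundant") copies of informative features, and per-block value-kind
#' transforms: an integer-coded block is rounded and clipped to
#' `{-2..2}` (CNV-like gain/loss calls), a unit-interval block is squashed
#' into `[0,1]` through the normal CDF (methylation-beta-like), and
#' continuous blocks are left unbounded (expression/miRNA/protein-like).
#'
#' @param n_samples Number of samples.
#' @param prevalence_positive Fraction of late-stage (+1) samples in (0,1);
#'   the positive count is fixed at `round(prevalence * n)` so class sizes
#'   are stable across seeds.
#' @param blocks List of per-block settings, each a list with `name`,
#'   `value_kind`, `n_features`, and optionally `n_informative` (default
#'   0), `effect_size` (standardized between-class mean shift per
#'   informative feature, default 1), `n_redundant` (near-duplicate copies
#'   of informative features, default 0) and `redundancy_correlation`
#'   (target parent/copy correlation in (0,1), default 0.9).
#' @param noise_sd Latent feature standard deviation (default 1).
#' @param seed Integer seed; the same config and seed always generate a
#'   byte-identical dataset.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_samples, prevalence_positive, blocks,
                             noise_sd = 1, seed = 1) {
  stopifnot(n_samples >= 4, prevalence_positive > 0, prevalence_positive < 1,
            noise_sd > 0, length(blocks) >= 1)
  n_pos <- round(prevalence_positive * n_samples)
  if (n_pos < 2 || n_samples - n_pos < 2) {
    stop("infeasible config: need at least 2 samples per class ",
         "(prevalence ", prevalence_positive, " at n = ", n_samples, ")")
  }
  defaults <- list(n_informative = 0L, effect_size = 1, n_redundant = 0L,
                   redundancy_correlation = 0.9)
  blocks <- lapply(blocks, function(b) {
    b <- modifyList(defaults, b)
    stopifnot(!is.null(b$name), !is.null(b$value_kind), b$n_features >= 1)
    if (b$n_informative + b$n_redundant > b$n_features) {
      stop("block '", b$name,
           "': n_informative + n_redundant exceeds n_features")
    }
    if (b$n_redundant > 0 && b$n_informative == 0) {
      stop("block '", b$name, "': redundant copies need informative parents")
    }
    stopifnot(b$redundancy_correlation > 0, b$redundancy_correlation < 1)
    b
  })
  structure(list(n_samples = n_samples,
                 prevalence_positive = prevalence_positive,
                 blocks = blocks, noise_sd = noise_sd, seed = seed),
            class = "synthetic_config")
}

#' The default desk-scale five-block study configuration
#'
#' Five blocks shaped like a reduced multi-omics tumor-staging cohort: an
#' integer-coded CNV-like block, a unit-interval methylation-like block and
#' three continuous blocks (gene expression, miRNA, protein), 200 samples
#' at 23% late-stage prevalence, with a modest number of informative
#' features per block plus correlated redundant copies.
#'
#' @param seed Integer seed.
#' @param effect_size Standardized class shift of informative features.
#' @return A `synthetic_config`.
#' @export
paper_mini_config <- function(seed = 1, effect_size = 1) {
  synthetic_config(
    n_samples = 200, prevalence_positive = 0.23, seed = seed,
    blocks = list(
      list(name = "CNV", value_kind = "integer-coded", n_features = 500,
           n_informative = 8, effect_size = effect_size, n_redundant = 4),
      list(name = "Methylation", value_kind = "unit-interval",
           n_features = 400, n_informative = 8, effect_size = effect_size,
           n_redundant = 4),
      list(name = "GeneExpression", value_kind = "continuous",
           n_features = 400, n_informative = 8, effect_size = effect_size,
           n_redundant = 4),
      list(name = "miRNA", value_kind = "continuous", n_features = 80,
           n_informative = 4, effect_size = effect_size, n_redundant = 2),
      list(name = "Protein", value_kind = "continuous", n_features = 50,
           n_informative = 2, effect_size = effect_size, n_redundant = 0)
    )
  )
}

#' Generate a synthetic multi-omics dataset with known ground truth
#'
#' Labels are assigned at the configured prevalence; each informative
#' feature's latent values are shifted between classes by
#' `effect_size * noise_sd`; each redundant feature is its parent plus
#' Gaussian noise scaled so the parent/copy correlation is the configured
#' target in expectation; remaining features are pure noise. Value-kind
#' transforms are applied after signal injection (see
#' [synthetic_config()]). Informative/redundant columns are placed at
#' random positions within each block.
#'
#' @param cfg A `synthetic_config`.
#' @return A list with `dataset` (a `multiomics_dataset`) and
#'   `ground_truth`, a data.frame with columns `block`, `feature_id`,
#'   `role` (`informative`/`redundant`/`noise`) and `parent` (the parent
#'   feature id for redundant copies, `NA` otherwise).
#' @export
generate_multiomics <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  with_local_seed(cfg$seed, {
    n <- cfg$n_samples
    n_pos <- round(cfg$prevalence_positive * n)
    y <- rep(-1L, n)
    y[sample.int(n, n_pos)] <- 1L
    sample_ids <- sprintf("S%04d", seq_len(n))

    truth <- list()
    blocks <- list()
    for (b in cfg$blocks) {
      p <- b$n_features
      lat <- matrix(rnorm(n * p, sd = cfg$noise_sd), n, p)
      ids <- sprintf("%s_f%04d", b$name, seq_len(p))
      role <- rep("noise", p)
      parent <- rep(NA_character_, p)

      pos <- sample.int(p, b$n_informative + b$n_redundant)
      inf_idx <- pos[seq_len(b$n_informative)]
      red_idx <- if (b$n_redundant > 0) {
        pos[b$n_informative + seq_len(b$n_redundant)]
      } else {
        integer(0)
      }

      shift <- b$effect_size * cfg$noise_sd
      for (j in inf_idx) {
        lat[, j] <- lat[, j] + ifelse(y == 1L, shift / 2, -shift / 2)
      }
      role[inf_idx] <- "informative"

      if (length(red_idx)) {
        rho <- b$redundancy_correlation
        par_of <- rep_len(inf_idx, length(red_idx))
        for (k in seq_along(red_idx)) {
          pj <- par_of[k]
          v <- lat[, pj]
          lat[, red_idx[k]] <- rho * v +
            sqrt(1 - rho^2) * sd(v) * rnorm(n)
        }
        role[red_idx] <- "redundant"
        parent[red_idx] <- ids[par_of]
      }

      vals <- switch(b$value_kind,
        "integer-coded" = pmin(pmax(round(lat), -2), 2),
        "unit-interval" = pnorm(lat / cfg$noise_sd),
        "continuous" = lat,
        stop("unknown value_kind '", b$value_kind, "'")
      )
      colnames(vals) <- ids
      blocks[[b$name]] <- feature_block(b$name, vals, ids, b$value_kind)
      truth[[b$name]] <- data.frame(block = b$name, feature_id = ids,
                                    role = role, parent = parent,
                                    stringsAsFactors = FALSE)
    }
    list(dataset = multiomics_dataset(sample_ids, y, blocks),
         ground_truth = do.call(rbind, c(truth, make.row.names = FALSE)))
  })
}

#' Write a generated dataset and its ground truth to disk
#'
#' Emits the TSV matrices, labels and manifest via [write_dataset()], plus
#' `ground_truth.tsv` (block, feature_id, role, parent).
#'
#' @param sim Result of [generate_multiomics()].
#' @param dir Output directory.
#' @return The directory, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  write_dataset(sim$dataset, dir)
  data.table::fwrite(sim$ground_truth, file.path(dir, "ground_truth.tsv"),
                     sep = "\t")
  invisible(dir)
}
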