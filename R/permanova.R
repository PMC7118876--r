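#' Bray-Curtis distance matrix between samples
#'
#' `d(i, j) = 1 - 2 * sum_g min(x_gi, x_gj) / sum_g (x_gi + x_gj)`,
#' computed with [vegan::vegdist()] on the sample-by-gene orientation.
#'
#' @param table a [gene_table()] with >= 2 samples (normalized input
#'   recommended, so distances live on the compositional scale).
#' @return a symmetric numeric matrix with zero diagonal, samples as
#'   dimnames.
#' @export
bray_curtis_matrix <- function(table) {
  if (ncol(table) < 2L) stop("need at least 2 samples")
  as.matrix(vegan::vegdist(t(unclass(table)), method = "bray"))
}

ss_within <- function(d2, members) {
  total <- 0
  for (idx in members) {
    if (length(idx) > 1L) {
      total <- total + sum(d2[idx, idx]) / 2 / length(idx)
    }
  }
  total
}

#' One-factor PERMANOVA R-squared
#'
#' Distance-based effect size of a two-group factor: the sums of squares
#' are partitioned as `SS_total = sum_{i<j} d_ij^2 / n` and
#' `SS_within = sum_groups sum_{i<j in group} d_ij^2 / n_group`, with
#' `R^2 = (SS_total - SS_within) / SS_total` and pseudo-F
#' `(SS_between/(a-1)) / (SS_within/(n-a))` for `a = 2` groups. The P
#' value comes from random relabelings of samples (Monte Carlo
#' permutation test; the observed labeling counts toward the numerator
#' and denominator).
#'
#' @param distances symmetric distance matrix with sample dimnames (e.g.
#'   [bray_curtis_matrix()]).
#' @param metadata a [study_metadata()] covering the samples.
#' @param n_permutations number of random relabelings (default 999).
#' @param seed RNG seed.
#' @return object of class `effect_size_result`: list with `r_squared`,
#'   `pseudo_f`, `p_value`, `n_permutations`, `seed`, `n_samples`.
#' @export
permanova_r2 <- function(distances, metadata, n_permutations = 999L, seed = 1L) {
  distances <- as.matrix(distances)
  samples <- colnames(distances)
  idx <- group_indices(metadata, samples)
  if (length(idx$g1) < 2L || length(idx$g2) < 2L) {
    stop("each group needs at least 2 samples")
  }
  n <- length(samples)
  d2 <- distances^2
  sst <- sum(d2[upper.tri(d2)]) / n
  stat <- function(g1_idx) {
    g2_idx <- setdiff(seq_len(n), g1_idx)
    ssw <- ss_within(d2, list(g1_idx, g2_idx))
    ssb <- sst - ssw
    r2 <- if (sst > 0) ssb / sst else 0
    f <- if (ssw > 0) (ssb / 1) / (ssw / (n - 2)) else Inf
    c(r2 = r2, f = f)
  }
  obs <- stat(idx$g1)
  set.seed(seed)
  n1 <- length(idx$g1)
  exceed <- 0L
  for (k in seq_len(n_permutations)) {
    f_k <- stat(sample.int(n, n1))[["f"]]
    if (f_k >= obs[["f"]]) exceed <- exceed + 1L
  }
  structure(list(r_squared = obs[["r2"]], pseudo_f = obs[["f"]],
                 p_value = (exceed + 1L) / (n_permutations + 1L),
                 n_permutations = n_permutations, seed = seed,
                 n_samples = n),
            class = "effect_size_result")
}

#' @export
print.effect_size_result <- function(x, ...) {
  cat(sprintf("PERMANOVA: R2 = %.4f, pseudo-F = %.3f, P = %.4g (%d permutations, n = %d)\n",
              x$r_squared, x$pseudo_f, x$p_value, x$n_permutations, x$n_samples))
  invisible(x)
}

#' Write an effect-size result to TSV
#'
#' @param result a [permanova_r2()] result.
#' @param path output TSV path.
#' @export
write_effect_size_tsv <- function(result, path) {
  df <- data.frame(r_squared = result$r_squared, pseudo_f = result$pseudo_f,
                   p_value = result$p_value,
                   n_permutations = result$n_permutations)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
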