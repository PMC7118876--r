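# Independent oracles used against the package implementations.

# Exact two-sided Wilcoxon rank-sum P by enumeration of all
# choose(n1+n2, n1) assignments of the pooled ranks to group1.
exact_wilcox_oracle <- function(group1, group2) {
  n1 <- length(group1)
  pooled <- c(group1, group2)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n1)])
  splits <- utils::combn(length(pooled), n1)
  w_all <- apply(splits, 2L, function(idx) sum(r[idx]))
  p_low <- mean(w_all <= w_obs)
  p_high <- mean(w_all >= w_obs)
  min(1, 2 * min(p_low, p_high))
}

# Spearman rho via the classical rank-difference formula (tie-free only).
spearman_rank_formula <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# Exhaustive two-group PERMANOVA P: pseudo-F over all distinct
# assignments of n1 samples to group1.
exhaustive_permanova_p <- function(distances, n1) {
  n <- nrow(distances)
  d2 <- distances^2
  sst <- sum(d2[upper.tri(d2)]) / n
  f_of <- function(g1_idx) {
    g2_idx <- setdiff(seq_len(n), g1_idx)
    ssw <- sum(d2[g1_idx, g1_idx]) / 2 / length(g1_idx) +
      sum(d2[g2_idx, g2_idx]) / 2 / length(g2_idx)
    ((sst - ssw) / 1) / (ssw / (n - 2))
  }
  splits <- utils::combn(n, n1)
  f_all <- apply(splits, 2L, f_of)
  f_obs <- f_of(seq_len(n1))
  mean(f_all >= f_obs - 1e-12)
}

# tiny deterministic paired tables for hand checks
tiny_table <- function(values, genes, samples) {
  m <- matrix(values, nrow = length(genes), byrow = TRUE,
              dimnames = list(genes, samples))
  gene_table(m)
}

tiny_metadata <- function(samples, split = length(samples) / 2) {
  study_metadata(stats::setNames(rep(c("g1", "g2"),
                                     c(split, length(samples) - split)),
                                 samples),
                 group_labels = c("g1", "g2"))
}
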