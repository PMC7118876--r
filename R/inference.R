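#' Signed log10 transform of a Wilcoxon P value
#'
#' `p_t = log10(P) * sign(mean_group1 - mean_group2)`: the magnitude
#' carries the strength of evidence against the per-gene null of equal
#' group distributions, and the sign of the group-mean difference carries
#' the direction of change. With this convention a strongly significant
#' gene that is higher in group1 receives a large negative value
#' (log10 of a small P is negative); any consistent sign flip applied to
#' both methods leaves the concordance rho unchanged. `sign(0) = 0`, so
#' exactly equal means give `p_t = 0`.
#'
#' @param p_value two-sided Wilcoxon P in (0, 1].
#' @param mean_group1,mean_group2 per-group sample means of the gene.
#' @return the signed transformed value (dimensionless).
#' @export
signed_log10_p <- function(p_value, mean_group1, mean_group2) {
  if (any(p_value <= 0) || any(p_value > 1)) stop("p_value must be in (0, 1]")
  log10(p_value) * sign(mean_group1 - mean_group2)
}

#' Per-gene inference vector
#'
#' For each requested gene, splits its abundances by the metadata's two
#' groups (in declared order), runs the two-sided Wilcoxon rank-sum test
#' and applies the signed log10 transform using group sample means. Raw P
#' values are used as statistics, not thresholds: no multiple-testing
#' correction is applied.
#'
#' @param table a [gene_table()].
#' @param metadata a [study_metadata()] covering the table's samples.
#' @param genes gene IDs to test; defaults to all genes in the table.
#' @return object of class `inference_vector`: data.frame with columns
#'   `gene_id`, `p_value`, `mean_group1`, `mean_group2`, `p_t`;
#'   attributes record the group labels and the two-sided convention.
#' @export
inference_vector <- function(table, metadata, genes = rownames(table)) {
  missing_genes <- setdiff(genes, rownames(table))
  if (length(missing_genes)) {
    stop("genes not in table: ", paste(utils::head(missing_genes, 3L), collapse = ", "))
  }
  idx <- group_indices(metadata, colnames(table))
  if (length(idx$g1) < 2L || length(idx$g2) < 2L) {
    stop("each group needs at least 2 samples")
  }
  m <- unclass(table)[genes, , drop = FALSE]
  p <- wilcoxon_matrix_p(m, idx$g1, idx$g2)
  m1 <- rowMeans(m[, idx$g1, drop = FALSE])
  m2 <- rowMeans(m[, idx$g2, drop = FALSE])
  out <- data.frame(gene_id = genes, p_value = p,
                    mean_group1 = m1, mean_group2 = m2,
                    p_t = signed_log10_p(p, m1, m2),
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(out, class = c("inference_vector", "data.frame"),
            group_labels = metadata$group_labels, alternative = "two.sided")
}

concordance_row <- function(rho, p_value, n_genes, scope, source) {
  data.frame(scope = scope, source = source, rho = rho, p_value = p_value,
             n_genes = n_genes,
             display = !is.na(rho) && rho > 0 && !is.na(p_value) && p_value < 0.05,
             stringsAsFactors = FALSE)
}

#' Inference concordance between two methods
#'
#' Tie-aware Spearman correlation of the signed log10 transformed P
#' values of two inference vectors over their shared genes: the accuracy
#' estimate of the evaluation. Unlike raw composition correlation, it is
#' destroyed by gene-wise permutation of the underlying table.
#'
#' @param v_pred,v_obs [inference_vector()]s (predicted and observed).
#' @return a one-row `concordance_result` data.frame with `scope`,
#'   `source`, `rho`, `p_value`, `n_genes`, `display`.
#' @export
inference_correlation <- function(v_pred, v_obs) {
  shared <- intersect(v_pred$gene_id, v_obs$gene_id)
  if (length(shared) < 3L) stop("need at least 3 shared genes")
  x <- v_pred$p_t[match(shared, v_pred$gene_id)]
  y <- v_obs$p_t[match(shared, v_obs$gene_id)]
  res <- spearman(x, y)
  structure(concordance_row(res$rho, res$p_value, length(shared), "all", "real"),
            class = c("concordance_result", "data.frame"))
}

#' Permutation null of the inference concordance
#'
#' For each permutation, the observed table is gene-wise permuted across
#' samples ([permute_genes_across_samples()]), its inference vector is
#' recomputed, and the concordance rho against the unchanged predicted
#' inference vector is recorded. The resulting null distribution centers
#' on zero, demonstrating that the inference metric — unlike raw
#' composition correlation — is sensitive to sample-linked structure.
#'
#' @param pair an [align_pair()] result.
#' @param metadata a [study_metadata()].
#' @param n_permutations number of permutations (default 100).
#' @param seed RNG seed.
#' @return a `concordance_result` data.frame, one row per permutation
#'   with `source = "permutation_k"`.
#' @export
inference_permutation_null <- function(pair, metadata, n_permutations = 100L,
                                       seed = 1L) {
  if (n_permutations < 1L) stop("n_permutations must be >= 1")
  v_pred <- inference_vector(pair$predicted, metadata, pair$shared_genes)
  obs_shared <- gene_table(unclass(pair$observed)[pair$shared_genes, , drop = FALSE])
  set.seed(seed)
  rows <- vector("list", n_permutations)
  for (k in seq_len(n_permutations)) {
    perm <- permute_genes_across_samples(obs_shared)
    v_perm <- inference_vector(perm, metadata)
    res <- spearman(v_pred$p_t, v_perm$p_t)
    rows[[k]] <- concordance_row(res$rho, res$p_value, res$n, "all",
                                 sprintf("permutation_%d", k))
  }
  structure(do.call(rbind, rows), class = c("concordance_result", "data.frame"))
}

#' Subsample the design and recompute the inference concordance
#'
#' Draws `per_group` samples per group without replacement, recomputes
#' both inference vectors on the subsample, and records the concordance
#' rho — the control for unequal sample sizes across datasets (5 per
#' group matches the smallest design).
#'
#' @param pair an [align_pair()] result.
#' @param metadata a [study_metadata()].
#' @param per_group samples to draw per group (default 5).
#' @param n_repeats number of independent draws.
#' @param seed RNG seed.
#' @return a `concordance_result` data.frame, one row per repeat with
#'   `source = "subsample_k"`.
#' @export
subsample_and_recompute <- function(pair, metadata, per_group = 5L,
                                    n_repeats = 25L, seed = 1L) {
  idx <- group_indices(metadata, pair$shared_samples)
  if (length(idx$g1) < per_group || length(idx$g2) < per_group) {
    stop("a group has fewer than per_group samples")
  }
  set.seed(seed)
  rows <- vector("list", n_repeats)
  for (k in seq_len(n_repeats)) {
    take <- c(idx$g1[sample.int(length(idx$g1), per_group)],
              idx$g2[sample.int(length(idx$g2), per_group)])
    samples_k <- pair$shared_samples[sort(take)]
    pred_k <- gene_table(unclass(pair$predicted)[, samples_k, drop = FALSE])
    obs_k <- gene_table(unclass(pair$observed)[, samples_k, drop = FALSE])
    v_pred <- inference_vector(pred_k, metadata, pair$shared_genes)
    v_obs <- inference_vector(obs_k, metadata, pair$shared_genes)
    res <- spearman(v_pred$p_t, v_obs$p_t)
    rows[[k]] <- concordance_row(res$rho, res$p_value, res$n, "all",
                                 sprintf("subsample_%d", k))
  }
  structure(do.call(rbind, rows), class = c("concordance_result", "data.frame"))
}

#' Category-stratified inference concordance
#'
#' One concordance result per level-2 functional category with at least
#' `min_genes` shared genes; a multi-mapped gene contributes to every
#' category it maps to. All qualifying results are computed and returned;
#' the `display` flag marks positive, significant (P < 0.05) correlations
#' — the convention for which results are plotted — without dropping the
#' rest. Categories below `min_genes` are skipped with a message.
#'
#' @param v_pred,v_obs [inference_vector()]s.
#' @param hierarchy a [functional_hierarchy()].
#' @param min_genes minimum shared genes per category (>= 3, default 10).
#' @return a `concordance_result` data.frame, one row per category
#'   (`scope` = category name, `source = "real"`).
#' @export
category_inference_correlations <- function(v_pred, v_obs, hierarchy,
                                            min_genes = 10L) {
  if (min_genes < 3L) stop("min_genes must be >= 3")
  shared <- intersect(v_pred$gene_id, v_obs$gene_id)
  x_all <- v_pred$p_t[match(shared, v_pred$gene_id)]
  y_all <- v_obs$p_t[match(shared, v_obs$gene_id)]
  cats <- category_genes(hierarchy, level = 2L)
  rows <- list()
  for (cat_name in sort(names(cats))) {
    in_cat <- shared %in% cats[[cat_name]]
    n_cat <- sum(in_cat)
    if (n_cat < min_genes) {
      message(sprintf("skipping category '%s': %d shared genes < min_genes=%d",
                      cat_name, n_cat, min_genes))
      next
    }
    res <- suppressWarnings(spearman(x_all[in_cat], y_all[in_cat]))
    rows[[cat_name]] <- concordance_row(res$rho, res$p_value, n_cat,
                                        cat_name, "real")
  }
  if (!length(rows)) {
    empty <- data.frame(scope = character(0), source = character(0),
                        rho = numeric(0), p_value = numeric(0),
                        n_genes = integer(0), display = logical(0),
                        stringsAsFactors = FALSE)
    return(structure(empty, class = c("concordance_result", "data.frame")))
  }
  structure(do.call(rbind, c(rows, list(make.row.names = FALSE))),
            class = c("concordance_result", "data.frame"))
}

#' Write per-gene inference results to TSV
#'
#' One row per shared gene: both methods' P values and transformed
#' values, plus level-1/level-2 annotation (first category pair when
#' multi-mapped, `NA` when unannotated).
#'
#' @param v_pred,v_obs [inference_vector()]s.
#' @param hierarchy a [functional_hierarchy()] or `NULL`.
#' @param path output TSV path.
#' @export
write_inference_tsv <- function(v_pred, v_obs, hierarchy, path) {
  shared <- intersect(v_pred$gene_id, v_obs$gene_id)
  ip <- match(shared, v_pred$gene_id)
  io <- match(shared, v_obs$gene_id)
  df <- data.frame(gene_id = shared,
                   p_pred = v_pred$p_value[ip], p_obs = v_obs$p_value[io],
                   p_t_pred = v_pred$p_t[ip], p_t_obs = v_obs$p_t[io],
                   level1 = NA_character_, level2 = NA_character_,
                   stringsAsFactors = FALSE)
  if (!is.null(hierarchy)) {
    hit <- match(shared, hierarchy$entries$gene_id)
    df$level1 <- hierarchy$entries$level1[hit]
    df$level2 <- hierarchy$entries$level2[hit]
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write concordance results to TSV
#'
#' @param results one or more `concordance_result` data.frames (rbind-ed).
#' @param path output TSV path.
#' @export
write_concordance_tsv <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
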