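#' Configuration for the paired-study generator
#'
#' Defines the statistical structure of a synthetic paired
#' predicted/observed study: per-gene lognormal baselines with a heavy
#' right tail (a few genes dominate composition, as in real KO tables),
#' multiplicative between-sample variation, a two-group design with a
#' subset of truly differential genes, partial mirroring of the
#' differential signal in the predicted table, and prediction-missed /
#' spuriously predicted genes.
#'
#' @param n_genes number of genes in the observed table.
#' @param n_samples_per_group samples per group (two groups).
#' @param n_differential number of truly differential genes; default 20%
#'   of `n_genes`.
#' @param effect_fold multiplicative group effect (> 0) applied to
#'   differential genes in group1 (up- or down-regulated per gene).
#' @param between_sample_cv coefficient of variation of a gene's abundance
#'   across samples (before any group effect); 0 means every sample shares
#'   the gene's baseline exactly.
#' @param concordance fraction in \[0, 1\] of differential genes whose group
#'   effect is mirrored in the predicted table (each differential gene is
#'   mirrored independently with this probability).
#' @param category_concordance optional named numeric vector of per-level-2
#'   category overrides of `concordance`.
#' @param miss_fraction fraction of observed genes absent from the
#'   predicted table.
#' @param spurious_fraction fraction of the predicted table's genes that
#'   are absent from the observed table.
#' @param noise_sd sdlog of the multiplicative lognormal noise linking
#'   predicted to observed values.
#' @param n_categories number of level-2 categories in the synthetic
#'   hierarchy (split across two level-1 groups).
#' @param seed RNG seed; fully determines the output (R's default
#'   Mersenne-Twister stream, draws in documented order).
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_genes = 2000L,
                             n_samples_per_group = 20L,
                             n_differential = NULL,
                             effect_fold = 3,
                             between_sample_cv = 0.5,
                             concordance = 0.9,
                             category_concordance = NULL,
                             miss_fraction = 0.2,
                             spurious_fraction = 0.1,
                             noise_sd = 0.3,
                             n_categories = 8L,
                             seed = 1L) {
  if (is.null(n_differential)) n_differential <- round(0.2 * n_genes)
  cfg <- list(n_genes = as.integer(n_genes),
              n_samples_per_group = as.integer(n_samples_per_group),
              n_differential = as.integer(n_differential),
              effect_fold = effect_fold,
              between_sample_cv = between_sample_cv,
              concordance = concordance,
              category_concordance = category_concordance,
              miss_fraction = miss_fraction,
              spurious_fraction = spurious_fraction,
              noise_sd = noise_sd,
              n_categories = as.integer(n_categories),
              seed = as.integer(seed))
  if (cfg$n_genes < 1L) stop("n_genes must be >= 1")
  if (cfg$n_samples_per_group < 2L) stop("n_samples_per_group must be >= 2")
  if (cfg$n_differential < 0L || cfg$n_differential > cfg$n_genes) {
    stop("n_differential must be in [0, n_genes]")
  }
  if (cfg$effect_fold <= 0) stop("effect_fold must be > 0")
  fr <- c(concordance = cfg$concordance, miss_fraction = cfg$miss_fraction,
          spurious_fraction = cfg$spurious_fraction)
  bad <- names(fr)[fr < 0 | fr > 1]
  if (length(bad)) stop("fractions must be in [0, 1]: ", paste(bad, collapse = ", "))
  if (!is.null(cfg$category_concordance)) {
    if (is.null(names(cfg$category_concordance)) ||
        any(cfg$category_concordance < 0 | cfg$category_concordance > 1)) {
      stop("category_concordance must be a named vector of fractions in [0, 1]")
    }
  }
  if (cfg$between_sample_cv < 0) stop("between_sample_cv must be >= 0")
  if (cfg$noise_sd < 0) stop("noise_sd must be >= 0")
  if (cfg$n_categories < 1L) stop("n_categories must be >= 1")
  structure(cfg, class = "synthetic_config")
}

# lognormal sdlog giving a target coefficient of variation
cv_to_sdlog <- function(cv) sqrt(log(1 + cv^2))

synthetic_level1 <- c("Metabolism", "Genetic Information Processing")

#' Generate a paired predicted/observed study
#'
#' Builds the observed table from per-gene lognormal baselines
#' (`meanlog = 0`, `sdlog = 1.5`, a heavy right tail) with multiplicative
#' per-sample variation matching `between_sample_cv`; differential genes
#' get their abundance multiplied by `effect_fold` (up) or
#' `1/effect_fold` (down, chosen per gene) in group1. The predicted table
#' starts from the same realization with the group effect kept only for
#' the mirrored (concordant) differential genes, then receives
#' multiplicative lognormal noise of sdlog `noise_sd`, loses a
#' `miss_fraction` of genes and gains spurious non-differential genes.
#' Both tables are normalized. Each gene carries exactly one level-2
#' category; `category_concordance` overrides the global mirroring
#' probability per category.
#'
#' @param config a [synthetic_config()].
#' @return a list with elements `observed`, `predicted` ([gene_table()]s),
#'   `metadata` ([study_metadata()]), `hierarchy`
#'   ([functional_hierarchy()]) and `truth` (per-gene data.frame with
#'   `gene_id`, `differential`, `direction` (+1 higher in group1, -1
#'   lower, 0 none), `mirrored`, `level1`, `level2`).
#' @export
generate_paired_study <- function(config) {
  if (!inherits(config, "synthetic_config")) config <- do.call(synthetic_config, config)
  set.seed(config$seed)
  ng <- config$n_genes
  npg <- config$n_samples_per_group
  ns <- 2L * npg
  genes <- sprintf("K%05d", seq_len(ng))
  samples <- sprintf("sample_%03d", seq_len(ns))
  groups <- rep(c("group1", "group2"), each = npg)

  # hierarchy: one level-2 category per gene, categories split over two
  # level-1 groups
  lvl2 <- sprintf("Category_%02d", seq_len(config$n_categories))
  lvl1 <- synthetic_level1[(seq_len(config$n_categories) - 1L) %%
                             length(synthetic_level1) + 1L]
  gene_cat <- sample(seq_len(config$n_categories), ng, replace = TRUE)

  # draw order: categories, baselines, sample noise, effect directions,
  # mirroring, misses, spurious block
  baseline <- stats::rlnorm(ng, meanlog = 0, sdlog = 1.5)
  sdlog_s <- cv_to_sdlog(config$between_sample_cv)
  base <- baseline * matrix(stats::rlnorm(ng * ns, 0, sdlog_s), ng, ns)
  dimnames(base) <- list(genes, samples)

  diff_idx <- if (config$n_differential > 0L) {
    sort(sample.int(ng, config$n_differential))
  } else integer(0)
  direction <- integer(ng)
  direction[diff_idx] <- sample(c(1L, -1L), length(diff_idx), replace = TRUE)

  effect <- matrix(1, ng, ns)
  g1 <- which(groups == "group1")
  effect[diff_idx, g1] <- config$effect_fold^direction[diff_idx]
  observed_raw <- base * effect

  conc <- rep(config$concordance, ng)
  if (!is.null(config$category_concordance)) {
    for (cat_name in names(config$category_concordance)) {
      k <- match(cat_name, lvl2)
      if (is.na(k)) stop("category_concordance names unknown category: ", cat_name)
      conc[gene_cat == k] <- config$category_concordance[[cat_name]]
    }
  }
  mirrored <- logical(ng)
  mirrored[diff_idx] <- stats::runif(length(diff_idx)) < conc[diff_idx]

  pred_effect <- matrix(1, ng, ns)
  mir_idx <- which(mirrored)
  pred_effect[mir_idx, g1] <- config$effect_fold^direction[mir_idx]
  predicted_raw <- base * pred_effect
  if (config$noise_sd > 0) {
    predicted_raw <- predicted_raw * matrix(stats::rlnorm(ng * ns, 0, config$noise_sd), ng, ns)
  }

  n_miss <- round(config$miss_fraction * ng)
  miss_idx <- if (n_miss > 0L) sort(sample.int(ng, n_miss)) else integer(0)
  keep_idx <- setdiff(seq_len(ng), miss_idx)
  predicted_raw <- predicted_raw[keep_idx, , drop = FALSE]

  sf <- config$spurious_fraction
  n_spur <- if (sf > 0) round(sf * length(keep_idx) / (1 - sf)) else 0L
  if (n_spur > 0L) {
    spur_genes <- sprintf("K%05d", ng + seq_len(n_spur))
    spur_base <- stats::rlnorm(n_spur, 0, 1.5) *
      matrix(stats::rlnorm(n_spur * ns, 0, sdlog_s), n_spur, ns)
    dimnames(spur_base) <- list(spur_genes, samples)
    predicted_raw <- rbind(predicted_raw, spur_base)
  }

  truth <- data.frame(gene_id = genes,
                      differential = seq_len(ng) %in% diff_idx,
                      direction = direction,
                      mirrored = mirrored,
                      level1 = lvl1[gene_cat],
                      level2 = lvl2[gene_cat],
                      stringsAsFactors = FALSE)

  hier_df <- truth[, c("gene_id", "level1", "level2")]
  if (n_spur > 0L) {
    spur_cat <- sample(seq_len(config$n_categories), n_spur, replace = TRUE)
    hier_df <- rbind(hier_df,
                     data.frame(gene_id = sprintf("K%05d", ng + seq_len(n_spur)),
                                level1 = lvl1[spur_cat], level2 = lvl2[spur_cat],
                                stringsAsFactors = FALSE))
  }

  list(observed = normalize_gene_table(gene_table(observed_raw)),
       predicted = normalize_gene_table(gene_table(predicted_raw)),
       metadata = study_metadata(stats::setNames(groups, samples),
                                 group_labels = c("group1", "group2")),
       hierarchy = functional_hierarchy(hier_df),
       truth = truth,
       config = config)
}

#' Write a synthetic study to a fixture directory
#'
#' Writes `observed.tsv`, `predicted.tsv`, `metadata.tsv`, `hierarchy.tsv`
#' and `truth.tsv` in the formats the readers consume, so that re-reading
#' reproduces the generated objects.
#'
#' @param study result of [generate_paired_study()].
#' @param dir existing writable directory.
#' @return `dir`, invisibly.
#' @export
write_study_fixtures <- function(study, dir) {
  if (!dir.exists(dir)) stop("directory does not exist: ", dir)
  write_gene_table(study$observed, file.path(dir, "observed.tsv"))
  write_gene_table(study$predicted, file.path(dir, "predicted.tsv"))
  write_study_metadata(study$metadata, file.path(dir, "metadata.tsv"))
  write_functional_hierarchy(study$hierarchy, file.path(dir, "hierarchy.tsv"))
  utils::write.table(study$truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a synthetic study back from a fixture directory
#'
#' @param dir directory written by [write_study_fixtures()].
#' @return a list with `observed`, `predicted`, `metadata`, `hierarchy`,
#'   `truth`.
#' @export
read_study_fixtures <- function(dir) {
  list(observed = read_gene_table(file.path(dir, "observed.tsv")),
       predicted = read_gene_table(file.path(dir, "predicted.tsv")),
       metadata = read_study_metadata(file.path(dir, "metadata.tsv"),
                                      group_labels = c("group1", "group2")),
       hierarchy = read_functional_hierarchy(file.path(dir, "hierarchy.tsv")),
       truth = utils::read.delim(file.path(dir, "truth.tsv"),
                                 stringsAsFactors = FALSE))
}
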