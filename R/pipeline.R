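#' Build a pipeline run configuration
#'
#' Exactly one of `inputs` (paths to the four TSVs) or `synthetic` (a
#' [synthetic_config()] or argument list for one) must be given. A seed
#' is mandatory because the permutation controls, the permutation null
#' and subsampling are stochastic.
#'
#' @param inputs named list with `observed`, `predicted`, `metadata`,
#'   `hierarchy` TSV paths (hierarchy optional), or `NULL`.
#' @param synthetic a [synthetic_config()] (or list of its arguments), or
#'   `NULL`.
#' @param group_labels declared group ordering for file inputs.
#' @param n_permutations permutations for both the composition control
#'   and the inference null.
#' @param subsample_per_group,subsample_repeats subsampling design; set
#'   `subsample_per_group = NULL` to skip the stage.
#' @param min_prevalence detection threshold for gene sets.
#' @param min_genes minimum shared genes per category result.
#' @param seed RNG seed for every stochastic stage.
#' @param output_dir directory for stage TSVs and the JSON summary.
#' @return a `run_config` list.
#' @export
run_config <- function(inputs = NULL, synthetic = NULL, group_labels = NULL,
                       n_permutations = 100L, subsample_per_group = 5L,
                       subsample_repeats = 25L, min_prevalence = 1L,
                       min_genes = 10L, seed = 1L, output_dir = NULL) {
  if (is.null(inputs) == is.null(synthetic)) {
    stop("exactly one of `inputs` or `synthetic` must be given")
  }
  if (is.null(seed)) stop("seed is mandatory")
  if (!is.null(synthetic) && !inherits(synthetic, "synthetic_config")) {
    synthetic <- do.call(synthetic_config, synthetic)
  }
  structure(list(inputs = inputs, synthetic = synthetic,
                 group_labels = group_labels,
                 n_permutations = as.integer(n_permutations),
                 subsample_per_group = subsample_per_group,
                 subsample_repeats = as.integer(subsample_repeats),
                 min_prevalence = as.integer(min_prevalence),
                 min_genes = as.integer(min_genes),
                 seed = as.integer(seed), output_dir = output_dir),
            class = "run_config")
}

load_run_inputs <- function(config) {
  if (!is.null(config$synthetic)) {
    study <- generate_paired_study(config$synthetic)
    return(study[c("observed", "predicted", "metadata", "hierarchy")])
  }
  paths <- config$inputs
  req <- c("observed", "predicted", "metadata")
  if (!all(req %in% names(paths))) {
    stop("inputs must name observed, predicted and metadata TSVs")
  }
  list(observed = normalize_gene_table(read_gene_table(paths$observed)),
       predicted = normalize_gene_table(read_gene_table(paths$predicted)),
       metadata = read_study_metadata(paths$metadata, config$group_labels),
       hierarchy = if (!is.null(paths$hierarchy)) {
         read_functional_hierarchy(paths$hierarchy)
       })
}

#' Run the full evaluation pipeline
#'
#' Sequences every stage of the evaluation on one predicted/observed
#' pair: alignment, per-sample composition correlations with the
#' gene-wise permutation control, inference vectors and their
#' concordance, the inference permutation null, subsampled concordance,
#' category-stratified concordance, the gene-overlap report, and
#' PERMANOVA effect sizes of the group factor on both tables. When
#' `config$output_dir` is set, each stage's TSV plus a versioned JSON
#' summary of the headline numbers are written there; on failure,
#' partial outputs are removed.
#'
#' @param config a [run_config()].
#' @return a `pipeline_result` list with all stage objects and `summary`
#'   (the JSON-ready list).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) stop("config must be a run_config")
  out_dir <- config$output_dir
  written <- character(0)
  emit <- function(name, writer) {
    if (is.null(out_dir)) return(invisible(NULL))
    path <- file.path(out_dir, name)
    writer(path)
    written <<- c(written, path)
    invisible(path)
  }
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(force(expr), error = function(e) {
      unlink(written)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    message(sprintf("stage %-22s %6.2fs", name,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    res
  }
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }

  dat <- stage("load", load_run_inputs(config))
  pair <- stage("align", align_pair(dat$predicted, dat$observed,
                                    config$min_prevalence))
  comp <- stage("composition", composition_with_permutation_control(
    pair, config$n_permutations, seed = config$seed))
  emit("composition.tsv", function(p) write_composition_tsv(comp, p))

  v_pred <- stage("inference_pred",
                  inference_vector(pair$predicted, dat$metadata, pair$shared_genes))
  v_obs <- stage("inference_obs",
                 inference_vector(pair$observed, dat$metadata, pair$shared_genes))
  conc <- stage("inference_correlation", inference_correlation(v_pred, v_obs))
  null_dist <- stage("inference_null", inference_permutation_null(
    pair, dat$metadata, config$n_permutations, seed = config$seed + 1L))
  sub <- if (!is.null(config$subsample_per_group)) {
    stage("subsample", subsample_and_recompute(
      pair, dat$metadata, config$subsample_per_group,
      config$subsample_repeats, seed = config$seed + 2L))
  }
  cats <- if (!is.null(dat$hierarchy)) {
    stage("categories", suppressMessages(category_inference_correlations(
      v_pred, v_obs, dat$hierarchy, config$min_genes)))
  }
  all_conc <- rbind(conc, null_dist, sub, cats)
  emit("concordance.tsv", function(p) write_concordance_tsv(all_conc, p))
  emit("inference_genes.tsv",
       function(p) write_inference_tsv(v_pred, v_obs, dat$hierarchy, p))

  overlap <- stage("overlap", overlap_report(dat$predicted, dat$observed,
                                             dat$hierarchy,
                                             config$min_prevalence))
  emit("overlap.tsv", function(p) write_overlap_tsv(overlap, p))

  effect_obs <- stage("permanova_obs", permanova_r2(
    bray_curtis_matrix(dat$observed), dat$metadata, seed = config$seed + 3L))
  effect_pred <- stage("permanova_pred", permanova_r2(
    bray_curtis_matrix(dat$predicted), dat$metadata, seed = config$seed + 3L))
  emit("effect_size_observed.tsv", function(p) write_effect_size_tsv(effect_obs, p))
  emit("effect_size_predicted.tsv", function(p) write_effect_size_tsv(effect_pred, p))

  summary <- list(
    schema_version = "1.0",
    seed = config$seed,
    n_shared_genes = length(pair$shared_genes),
    n_shared_samples = length(pair$shared_samples),
    composition = list(mean_real_rho = mean(comp$per_sample$rho),
                       mean_permuted_rho = mean(comp$permuted$rho)),
    inference = list(rho = conc$rho, p_value = conc$p_value,
                     null_mean_rho = mean(null_dist$rho),
                     null_q95_rho = unname(stats::quantile(null_dist$rho, 0.95)),
                     subsample_mean_rho = if (!is.null(sub)) mean(sub$rho)),
    overlap = as.list(overlap$overall[, -1L]),
    effect_size = list(observed_r2 = effect_obs$r_squared,
                       predicted_r2 = effect_pred$r_squared)
  )
  emit("summary.json", function(p) {
    jsonlite::write_json(summary, p, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
  })

  structure(list(pair = pair, composition = comp, v_pred = v_pred,
                 v_obs = v_obs, concordance = all_conc, overlap = overlap,
                 effect_size = list(observed = effect_obs, predicted = effect_pred),
                 summary = summary, config = config),
            class = "pipeline_result")
}

#' Compare two inference-vector TSVs
#'
#' Reads two per-gene TSVs with `gene_id` and `p_t` columns (e.g. from
#' independent runs) and returns their concordance.
#'
#' @param path_pred,path_obs TSV paths.
#' @return a one-row `concordance_result` data.frame.
#' @export
compare_inference_files <- function(path_pred, path_obs) {
  read_v <- function(p) {
    df <- utils::read.delim(p, stringsAsFactors = FALSE)
    if (!all(c("gene_id", "p_t") %in% names(df))) {
      stop("inference TSV needs gene_id and p_t columns: ", p)
    }
    df
  }
  a <- read_v(path_pred)
  b <- read_v(path_obs)
  shared <- intersect(a$gene_id, b$gene_id)
  if (length(shared) < 3L) stop("need at least 3 shared genes")
  res <- spearman(a$p_t[match(shared, a$gene_id)],
                  b$p_t[match(shared, b$gene_id)])
  structure(concordance_row(res$rho, res$p_value, length(shared), "all", "real"),
            class = c("concordance_result", "data.frame"))
}

#' Read a pipeline configuration from a YAML file
#'
#' One flat document whose keys mirror [run_config()] arguments; `inputs`
#' and `synthetic` are nested blocks.
#'
#' @param path YAML file path.
#' @param overrides named list of values taking precedence over the file.
#' @return a [run_config()].
#' @export
read_run_config <- function(path, overrides = list()) {
  doc <- yaml::read_yaml(path)
  for (k in names(overrides)) doc[[k]] <- overrides[[k]]
  keep <- intersect(names(doc), names(formals(run_config)))
  do.call(run_config, doc[keep])
}
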