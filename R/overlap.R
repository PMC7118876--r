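overlap_counts <- function(pred_set, obs_set) {
  n_shared <- length(intersect(pred_set, obs_set))
  n_pred_only <- length(setdiff(pred_set, obs_set))
  n_obs_only <- length(setdiff(obs_set, pred_set))
  n_obs <- n_shared + n_obs_only
  n_pred <- n_shared + n_pred_only
  data.frame(n_shared = n_shared, n_pred_only = n_pred_only,
             n_obs_only = n_obs_only,
             frac_obs_missed = if (n_obs > 0) n_obs_only / n_obs else NA_real_,
             frac_pred_undetected = if (n_pred > 0) n_pred_only / n_pred else NA_real_)
}

#' Gene-overlap report between predicted and observed tables
#'
#' Set arithmetic over each table's detected gene set: how many genes the
#' prediction missed and how many it predicted that were never observed,
#' overall and per level-2 functional category. The two fractions use
#' distinct denominators: `frac_obs_missed` is the share of observed
#' detected genes absent from the prediction, `frac_pred_undetected` the
#' share of predicted genes not detected by sequencing. Category rows are
#' computed over each category's gene universe, so multi-mapped genes
#' appear in every category they map to.
#'
#' @param predicted,observed [gene_table()]s.
#' @param hierarchy a [functional_hierarchy()] or `NULL` for no category
#'   breakdown.
#' @param min_prevalence detection threshold (see [detected_genes()]).
#' @return object of class `overlap_report`: list with `overall` (one-row
#'   data.frame) and `per_category` (one row per level-2 category).
#' @export
overlap_report <- function(predicted, observed, hierarchy = NULL,
                           min_prevalence = 1L) {
  pred_set <- detected_genes(predicted, min_prevalence)
  obs_set <- detected_genes(observed, min_prevalence)
  overall <- cbind(data.frame(scope = "all", stringsAsFactors = FALSE),
                   overlap_counts(pred_set, obs_set))
  per_category <- NULL
  if (!is.null(hierarchy)) {
    cats <- category_genes(hierarchy, level = 2L)
    rows <- lapply(sort(names(cats)), function(cat_name) {
      universe <- cats[[cat_name]]
      cbind(data.frame(scope = cat_name, stringsAsFactors = FALSE),
            overlap_counts(intersect(pred_set, universe),
                           intersect(obs_set, universe)))
    })
    per_category <- do.call(rbind, rows)
  }
  structure(list(overall = overall, per_category = per_category),
            class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  with(x$overall, cat(sprintf(
    "overlap_report: %d shared; %d observed-only (%.1f%% of observed missed); %d predicted-only (%.1f%% of predicted undetected)\n",
    n_shared, n_obs_only, 100 * frac_obs_missed,
    n_pred_only, 100 * frac_pred_undetected)))
  invisible(x)
}

#' Write an overlap report to TSV
#'
#' One row overall plus one per category.
#'
#' @param report an [overlap_report()] result.
#' @param path output TSV path.
#' @export
write_overlap_tsv <- function(report, path) {
  utils::write.table(rbind(report$overall, report$per_category), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
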