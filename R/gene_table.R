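#' Construct a gene abundance table
#'
#' A `gene_table` is a non-negative numeric matrix of gene (row) by sample
#' (column) relative abundances, the central exchange object of the package.
#' Both tables produced by 16S-based prediction tools (PICRUSt, PICRUSt2,
#' Tax4Fun) and shotgun-metagenome functional profiles (e.g. HUMAnN2 KO
#' regroupings) fit this shape, with KEGG ortholog (KO) identifiers as gene
#' keys.
#'
#' @param values numeric matrix, genes x samples, with unique non-empty
#'   rownames (gene IDs) and colnames (sample IDs). All entries must be
#'   finite and non-negative.
#' @return an object of class `gene_table` (a classed matrix).
#' @export
gene_table <- function(values) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix (genes x samples)")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("gene_table requires rownames (gene IDs) and colnames (sample IDs)")
  }
  if (anyDuplicated(rownames(values))) {
    dup <- rownames(values)[duplicated(rownames(values))][1L]
    stop("duplicate gene ID: ", dup)
  }
  if (anyDuplicated(colnames(values))) {
    dup <- colnames(values)[duplicated(colnames(values))][1L]
    stop("duplicate sample ID: ", dup)
  }
  if (anyNA(values) || any(!is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite value at gene '%s', sample '%s'",
                 rownames(values)[bad[1L]], colnames(values)[bad[2L]]))
  }
  if (any(values < 0)) {
    bad <- which(values < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative value at gene '%s', sample '%s'",
                 rownames(values)[bad[1L]], colnames(values)[bad[2L]]))
  }
  structure(values, class = c("gene_table", class(values)))
}

#' @export
print.gene_table <- function(x, ...) {
  cat(sprintf("gene_table: %d genes x %d samples\n", nrow(x), ncol(x)))
  cat("column sums:", format(range(colSums(x)), digits = 4), "(min, max)\n")
  invisible(x)
}

gene_ids <- function(table) rownames(table)
sample_ids <- function(table) colnames(table)

#' Read a gene abundance table from TSV
#'
#' Reads a tab-separated table with one header row and an ID column
#' (PICRUSt / HUMAnN2 export style). Lines starting with `#` are ignored;
#' the first field of the header row labels the ID column and is skipped.
#' Values are returned as read, not normalized.
#'
#' @param path path to a TSV file.
#' @param orientation `"genes_as_rows"` (default, the common export shape)
#'   or `"samples_as_rows"`; the result is always genes x samples.
#' @return a [gene_table()].
#' @export
read_gene_table <- function(path, orientation = c("genes_as_rows", "samples_as_rows")) {
  orientation <- match.arg(orientation)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("gene table TSV needs an ID column and at least one data column: ", path)
  ids <- as.character(df[[1L]])
  body <- df[, -1L, drop = FALSE]
  for (j in seq_along(body)) {
    if (!is.numeric(body[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(body[[j]]))))[1L]
      stop(sprintf("non-numeric cell at row ID '%s', column '%s'",
                   ids[bad], names(body)[j]))
    }
  }
  m <- as.matrix(body)
  rownames(m) <- ids
  if (orientation == "samples_as_rows") m <- t(m)
  gene_table(m)
}

#' Write a gene abundance table to TSV
#'
#' Inverse of [read_gene_table()]: genes as rows, one header row whose first
#' field labels the ID column.
#'
#' @param table a [gene_table()].
#' @param path output file path.
#' @param id_label header label for the ID column.
#' @export
write_gene_table <- function(table, path, id_label = "gene_id") {
  df <- data.frame(id = rownames(table), unclass(table)[, , drop = FALSE],
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1L] <- id_label
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Normalize each sample to relative abundance
#'
#' Divides every sample column by its sum so columns sum to 1; zeros stay
#' zero. Idempotent. An all-zero sample has no defined composition and is
#' rejected by name.
#'
#' @param table a [gene_table()].
#' @return a normalized [gene_table()].
#' @export
normalize_gene_table <- function(table) {
  cs <- colSums(table)
  if (any(cs == 0)) {
    stop("all-zero sample column: ", colnames(table)[cs == 0][1L])
  }
  gene_table(sweep(unclass(table), 2L, cs, "/"))
}

#' Genes detected in a table
#'
#' A gene counts as detected when its abundance is positive in at least
#' `min_prevalence` samples. The default (1 sample) is the most permissive
#' reading of presence.
#'
#' @param table a [gene_table()].
#' @param min_prevalence integer >= 1, minimum number of samples with a
#'   positive value.
#' @return character vector of detected gene IDs (in table order).
#' @export
detected_genes <- function(table, min_prevalence = 1L) {
  if (min_prevalence < 1L) stop("min_prevalence must be >= 1")
  prev <- rowSums(unclass(table) > 0)
  rownames(table)[prev >= min_prevalence]
}

#' Study metadata: a two-group sample assignment
#'
#' Maps each sample to one of exactly two group labels with a declared
#' ordering; `group_labels[1]` is "group1" in all directional statistics
#' (the sign of the mean difference in the signed log10 P transform).
#'
#' @param assignments named character vector, names = sample IDs,
#'   values = group labels.
#' @param group_labels length-2 character vector declaring group order;
#'   defaults to the sorted unique labels found in `assignments`.
#' @return an object of class `study_metadata`.
#' @export
study_metadata <- function(assignments, group_labels = NULL) {
  if (is.null(names(assignments)) || anyDuplicated(names(assignments))) {
    stop("assignments must be named by unique sample IDs")
  }
  assignments <- vapply(assignments, as.character, character(1L))
  labs <- unique(assignments)
  if (is.null(group_labels)) group_labels <- sort(labs)
  group_labels <- as.character(group_labels)
  if (length(group_labels) != 2L || anyDuplicated(group_labels)) {
    stop("exactly two distinct group labels required")
  }
  if (!all(labs %in% group_labels)) {
    stop("assignment labels outside declared groups: ",
         paste(setdiff(labs, group_labels), collapse = ", "))
  }
  if (!all(group_labels %in% labs)) stop("both groups must be non-empty")
  structure(list(assignments = assignments, group_labels = group_labels),
            class = "study_metadata")
}

#' @export
print.study_metadata <- function(x, ...) {
  tab <- table(factor(x$assignments, levels = x$group_labels))
  cat(sprintf("study_metadata: %d samples; %s (n=%d) vs %s (n=%d)\n",
              length(x$assignments),
              x$group_labels[1L], tab[1L], x$group_labels[2L], tab[2L]))
  invisible(x)
}

#' Read study metadata from TSV
#'
#' Two columns: sample ID, group label. `#` comment lines are ignored.
#'
#' @param path TSV path.
#' @param group_labels optional declared group order (see [study_metadata()]).
#' @return a [study_metadata()].
#' @export
read_study_metadata <- function(path, group_labels = NULL) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("metadata TSV needs sample and group columns")
  study_metadata(stats::setNames(as.character(df[[2L]]), as.character(df[[1L]])),
                 group_labels = group_labels)
}

#' @rdname read_study_metadata
#' @param metadata a [study_metadata()] to write.
#' @export
write_study_metadata <- function(metadata, path) {
  df <- data.frame(sample_id = names(metadata$assignments),
                   group = unname(metadata$assignments),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

group_indices <- function(metadata, samples) {
  g <- metadata$assignments[samples]
  if (anyNA(g)) {
    stop("samples without metadata assignment: ",
         paste(samples[is.na(g)], collapse = ", "))
  }
  list(g1 = which(g == metadata$group_labels[1L]),
       g2 = which(g == metadata$group_labels[2L]))
}

#' Functional hierarchy: gene to KEGG-style category mapping
#'
#' Maps each gene to one or more (level-1, level-2) category pairs, as in
#' the two broadest tiers of the KEGG BRITE hierarchy. Multi-mapped genes
#' (common for KOs) are allowed and contribute to every category they map
#' to.
#'
#' @param entries data.frame with columns `gene_id`, `level1`, `level2`,
#'   one row per (gene, category-pair).
#' @return an object of class `functional_hierarchy`.
#' @export
functional_hierarchy <- function(entries) {
  req <- c("gene_id", "level1", "level2")
  if (!all(req %in% names(entries))) {
    stop("hierarchy needs columns: ", paste(req, collapse = ", "))
  }
  entries <- as.data.frame(entries[, req], stringsAsFactors = FALSE)
  for (col in req) entries[[col]] <- as.character(entries[[col]])
  if (any(!nzchar(entries$level1)) || any(!nzchar(entries$level2))) {
    stop("category names must be non-empty")
  }
  entries <- unique(entries)
  structure(list(entries = entries), class = "functional_hierarchy")
}

#' @export
print.functional_hierarchy <- function(x, ...) {
  cat(sprintf("functional_hierarchy: %d genes, %d level-1, %d level-2 categories\n",
              length(unique(x$entries$gene_id)),
              length(unique(x$entries$level1)),
              length(unique(x$entries$level2))))
  invisible(x)
}

#' Read a functional hierarchy from TSV
#'
#' Three or more columns; the first three are gene ID, level-1 category,
#' level-2 category, one row per (gene, category-pair).
#'
#' @param path TSV path.
#' @return a [functional_hierarchy()].
#' @export
read_functional_hierarchy <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("hierarchy TSV needs gene_id, level1, level2 columns")
  functional_hierarchy(data.frame(gene_id = as.character(df[[1L]]),
                                  level1 = as.character(df[[2L]]),
                                  level2 = as.character(df[[3L]]),
                                  stringsAsFactors = FALSE))
}

#' @rdname read_functional_hierarchy
#' @param hierarchy a [functional_hierarchy()] to write.
#' @export
write_functional_hierarchy <- function(hierarchy, path) {
  utils::write.table(hierarchy$entries, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

category_genes <- function(hierarchy, level = 2L) {
  col <- if (level == 1L) "level1" else "level2"
  split(hierarchy$entries$gene_id, hierarchy$entries[[col]])
}

#' Align a predicted and an observed gene table
#'
#' Records the gene and sample intersections between a predicted and an
#' observed table and restricts both tables to the shared samples (same
#' order). Tables keep their full-gene normalization: relative abundances
#' are compared as each method produced them, and restriction to shared
#' genes happens at statistic time, never by renormalizing the composition.
#'
#' @param predicted,observed [gene_table()] objects.
#' @param min_prevalence detection threshold used to define each table's
#'   detected gene set (see [detected_genes()]).
#' @return an object of class `aligned_pair` with elements `predicted`,
#'   `observed`, `shared_genes`, `shared_samples`.
#' @export
align_pair <- function(predicted, observed, min_prevalence = 1L) {
  shared_samples <- intersect(colnames(predicted), colnames(observed))
  if (length(shared_samples) == 0L) stop("no shared samples between tables")
  shared_genes <- intersect(detected_genes(predicted, min_prevalence),
                            detected_genes(observed, min_prevalence))
  if (length(shared_genes) == 0L) stop("no shared detected genes between tables")
  structure(list(
    predicted = gene_table(unclass(predicted)[, shared_samples, drop = FALSE]),
    observed = gene_table(unclass(observed)[, shared_samples, drop = FALSE]),
    shared_genes = shared_genes,
    shared_samples = shared_samples
  ), class = "aligned_pair")
}

#' @export
print.aligned_pair <- function(x, ...) {
  cat(sprintf("aligned_pair: %d shared genes, %d shared samples\n",
              length(x$shared_genes), length(x$shared_samples)))
  invisible(x)
}

#' Aggregate gene abundances into functional categories
#'
#' Sums member-gene abundances per sample at the chosen hierarchy level.
#' A multi-mapped gene contributes its full abundance to each of its
#' categories (the common KEGG BRITE convention, so category totals can
#' exceed 1); genes without annotation aggregate to `"Unclassified"`.
#'
#' @param table a normalized [gene_table()].
#' @param hierarchy a [functional_hierarchy()].
#' @param level 1 or 2, the hierarchy tier to aggregate at.
#' @return a [gene_table()] keyed by category.
#' @export
aggregate_by_category <- function(table, hierarchy, level = 1L) {
  if (!level %in% c(1L, 2L)) stop("level must be 1 or 2")
  groups <- category_genes(hierarchy, level)
  m <- unclass(table)
  annotated <- character(0)
  rows <- list()
  for (cat_name in names(groups)) {
    members <- intersect(groups[[cat_name]], rownames(m))
    if (length(members) == 0L) next
    annotated <- union(annotated, members)
    rows[[cat_name]] <- colSums(m[members, , drop = FALSE])
  }
  unannotated <- setdiff(rownames(m), annotated)
  if (length(unannotated) > 0L) {
    rows[["Unclassified"]] <- colSums(m[unannotated, , drop = FALSE])
  }
  out <- do.call(rbind, rows)
  colnames(out) <- colnames(m)
  gene_table(out)
}
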