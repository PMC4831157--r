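#' Per-sample lncRNA:mRNA median expression ratio
#'
#' For each sample, restricts to genes expressed above the floor (strictly
#' more than `floor` ncounts in that sample) and forms the ratio of the
#' median lncRNA level to the median mRNA level. Transcripts of uncertain
#' coding potential (TUCPs) enter neither set. When one of the two sets is
#' empty the ratio is undefined and flagged rather than raised.
#'
#' @param normalized A normalized [expression_matrix()].
#' @param genes A [gene_table()].
#' @param floor Expression floor in ncounts (strict `>`), default 2.
#' @return A tibble per sample: `sample`, `n_lncrna`, `n_mrna`,
#'   `median_lncrna`, `median_mrna`, `ratio`, `defined`.
#' @export
lncrna_mrna_ratio <- function(normalized, genes, floor = 2) {
  stopifnot(inherits(normalized, "expr_matrix"))
  m <- em_genes(normalized)
  idx <- match(rownames(m), genes$gene_id)
  if (anyNA(idx)) abort("Every gene row must appear in the gene table.")
  biotype <- genes$biotype[idx]
  purrr::map_dfr(seq_len(ncol(m)), function(j) {
    v <- m[, j]
    expressed <- v > floor
    lnc <- v[expressed & biotype == "lncRNA"]
    mrna <- v[expressed & biotype == "mRNA"]
    defined <- length(lnc) > 0 && length(mrna) > 0
    tibble(sample = colnames(m)[j],
           n_lncrna = length(lnc), n_mrna = length(mrna),
           median_lncrna = if (length(lnc)) median(lnc) else NA_real_,
           median_mrna = if (length(mrna)) median(mrna) else NA_real_,
           ratio = if (defined) median(lnc) / median(mrna) else NA_real_,
           defined = defined)
  })
}

#' Merge single cells into a pseudobulk sample
#'
#' Reconstitutes an in-silico bulk library by summing raw counts per gene
#' across the given cells. The merged column can then be normalized and
#' analysed like any other sample.
#'
#' @param raw A raw [expression_matrix()].
#' @param cells Character vector of cell ids to merge (default: all).
#' @param sample_name Name of the merged column.
#' @return A raw [expression_matrix()] with a single column.
#' @export
pseudobulk_merge <- function(raw, cells = NULL, sample_name = "pseudobulk") {
  stopifnot(inherits(raw, "expr_matrix"))
  if (raw$normalized) abort("`pseudobulk_merge()` expects raw counts.")
  if (is.null(cells)) cells <- colnames(raw$values)
  if (length(cells) == 0L) abort("Cannot merge an empty cell set.")
  missing <- setdiff(cells, colnames(raw$values))
  if (length(missing)) {
    abort(paste0("Unknown cells: ", paste(head(missing, 5), collapse = ", ")))
  }
  merged <- matrix(rowSums(raw$values[, cells, drop = FALSE]), ncol = 1,
                   dimnames = list(rownames(raw$values), sample_name))
  expression_matrix(merged, sample_kind = "bulk_polyA", normalized = FALSE,
                    feature_kind = raw$feature_kind)
}

#' Compare two ratio distributions (Mann-Whitney U)
#'
#' Two-sided rank-sum test between two sets of ratios. Undefined values
#' are removed first. With both samples of size at most 8 and no ties the
#' p-value is computed by exact enumeration; otherwise the normal
#' approximation with tie correction is used. Fully tied input returns
#' p = 1.
#'
#' @param a,b Numeric vectors (e.g. per-sample lncRNA:mRNA ratios).
#' @return The two-sided p-value.
#' @export
compare_ratio_distributions <- function(a, b) {
  a <- a[is.finite(a)]
  b <- b[is.finite(b)]
  if (length(a) == 0L || length(b) == 0L) {
    abort("Both ratio sets must be non-empty after removing undefined values.")
  }
  pooled <- c(a, b)
  if (length(unique(pooled)) == 1L) return(1)
  ties <- anyDuplicated(pooled) > 0
  exact <- length(a) <= 8 && length(b) <= 8 && !ties
  res <- suppressWarnings(
    wilcox.test(a, b, alternative = "two.sided", exact = exact,
                correct = FALSE))
  min(1, res$p.value)
}

#' Detection fractions by expression quantile
#'
#' Assigns each lncRNA and mRNA to a quantile bin of its maximum
#' expression across cells, with quantiles computed on the pooled set of
#' both biotypes, and reports each gene's detection fraction so the
#' biotype-stratified distributions can be compared within matched
#' abundance bins. TUCPs are excluded.
#'
#' @param normalized A normalized [expression_matrix()].
#' @param genes A [gene_table()].
#' @param n_quantiles Number of bins, default 10 (deciles).
#' @return A tibble per gene: `gene_id`, `biotype`, `is_housekeeping`,
#'   `max_expr`, `quantile_bin` (1 = lowest), `detection_rate`.
#' @export
detection_by_quantile <- function(normalized, genes, n_quantiles = 10) {
  stopifnot(inherits(normalized, "expr_matrix"))
  m <- em_genes(normalized)
  idx <- match(rownames(m), genes$gene_id)
  if (anyNA(idx)) abort("Every gene row must appear in the gene table.")
  keep <- genes$biotype[idx] %in% c("mRNA", "lncRNA")
  m <- m[keep, , drop = FALSE]
  info <- genes[idx[keep], ]
  max_expr <- apply(m, 1, max)
  breaks <- unique(quantile(max_expr, probs = seq(0, 1,
                                                  length.out = n_quantiles + 1)))
  bin <- if (length(breaks) > 2L) {
    as.integer(cut(max_expr, breaks = breaks, include.lowest = TRUE))
  } else {
    rep(1L, length(max_expr))
  }
  det <- rowSums(m > 1) / ncol(m)
  tibble(gene_id = rownames(m), biotype = info$biotype,
         is_housekeeping = info$is_housekeeping,
         max_expr = unname(max_expr), quantile_bin = bin,
         detection_rate = unname(det))
}

#' Dilution of cell-type-specific genes in bulk tissue
#'
#' Summarizes each gene by its maximum expression across the samples of a
#' compartment (cells or bulk libraries), then forms, per compartment, the
#' fold of the median over the cell-type-specific gene set relative to the
#' median over housekeeping genes. The dilution ratio — single-cell fold
#' divided by bulk fold — quantifies how much less abundant the specific
#' genes appear at tissue level than in the cells that express them.
#'
#' @param single_cells Expression [expression_matrix()] of the single-cell
#'   compartment (any within-compartment unit: the fold statistic is
#'   scale-free).
#' @param bulk Expression [expression_matrix()] of the bulk compartment.
#' @param specific_genes Character vector of cell-type-specific gene ids.
#' @param housekeeping Character vector of housekeeping gene ids.
#' @param cohort Label carried into the output, e.g.
#'   `"cell_type_specific_lncRNA"`.
#' @return A one-row tibble: `cohort`, `single_cell_fold`, `bulk_fold`,
#'   `dilution_ratio`.
#' @export
dilution_folds <- function(single_cells, bulk, specific_genes, housekeeping,
                           cohort = "cell_type_specific") {
  if (length(specific_genes) == 0L || length(housekeeping) == 0L) {
    abort("Both gene sets must be non-empty.")
  }
  fold_in <- function(em) {
    m <- em_genes(em)
    missing <- setdiff(c(specific_genes, housekeeping), rownames(m))
    if (length(missing)) {
      abort(paste0("Genes absent from matrix: ",
                   paste(head(missing, 5), collapse = ", ")))
    }
    gene_max <- apply(m, 1, max)
    median(gene_max[specific_genes]) / median(gene_max[housekeeping])
  }
  sc_fold <- fold_in(single_cells)
  bulk_fold <- fold_in(bulk)
  if (!is.finite(sc_fold) || !is.finite(bulk_fold) || sc_fold <= 0 ||
      bulk_fold <= 0) {
    abort("Folds must be positive; check the housekeeping medians.")
  }
  tibble(cohort = cohort, single_cell_fold = sc_fold,
         bulk_fold = bulk_fold, dilution_ratio = sc_fold / bulk_fold)
}
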