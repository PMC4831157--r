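#' Classify genes by polyA / total RNA enrichment
#'
#' A gene is called enriched in the total (rRNA-depleted) fraction — the
#' signature of a non-polyadenylated transcript — when its
#' (total TPM + eps) / (polyA TPM + eps) fold exceeds `cutoff` in every
#' paired sample; it is called polyA-enriched when the fold is below
#' `1 / cutoff` in every pair; anything else is unclassified. The
#' pseudocount keeps a gene absent from both fractions at fold 1.
#'
#' @param tpm_polya,tpm_total TPM [expression_matrix()]s sharing gene ids
#'   and paired sample columns (same column names).
#' @param cutoff Fold cutoff, default 10.
#' @param eps Pseudocount in TPM units, default 0.01.
#' @return A tibble per gene: `gene_id`, `min_fold`, `max_fold`, `call`
#'   (one of `total_enriched`, `polya_enriched`, `unclassified`).
#' @export
classify_polya_enrichment <- function(tpm_polya, tpm_total, cutoff = 10,
                                      eps = 0.01) {
  stopifnot(inherits(tpm_polya, "expr_matrix"),
            inherits(tpm_total, "expr_matrix"))
  pa <- em_genes(tpm_polya)
  tot <- em_genes(tpm_total)
  if (!identical(sort(rownames(pa)), sort(rownames(tot)))) {
    abort("The two fractions must share the same gene ids.")
  }
  tot <- tot[rownames(pa), , drop = FALSE]
  if (ncol(pa) != ncol(tot) ||
      !identical(sort(colnames(pa)), sort(colnames(tot)))) {
    abort("Samples must be paired: identical sample ids in both fractions.")
  }
  tot <- tot[, colnames(pa), drop = FALSE]
  fold <- (tot + eps) / (pa + eps)
  min_fold <- apply(fold, 1, min)
  max_fold <- apply(fold, 1, max)
  call <- ifelse(min_fold > cutoff, "total_enriched",
                 ifelse(max_fold < 1 / cutoff, "polya_enriched",
                        "unclassified"))
  tibble(gene_id = rownames(pa), min_fold = unname(min_fold),
         max_fold = unname(max_fold), call = unname(call))
}

#' Minimum coverage threshold at a target false-discovery proportion
#'
#' Given assembled transcripts with a read-coverage value and a label
#' saying whether the transcript is supported by reference annotation,
#' finds the smallest coverage threshold `t` (scanned over the observed
#' coverage values) such that among transcripts with coverage at or above
#' `t`, the fraction lacking support is at most `fdr`. Ties break toward
#' the smaller threshold. If no threshold achieves the target, the
#' threshold is `+Inf` and `feasible` is `FALSE` (with a warning).
#'
#' @param records A data frame with numeric column `coverage`
#'   (non-negative) and logical column `supported`.
#' @param fdr Target false-discovery proportion, default 0.05.
#' @return A one-row tibble: `threshold`, `fdp` (achieved proportion at
#'   the threshold), `n_retained`, `feasible`.
#' @export
optimize_coverage_threshold <- function(records, fdr = 0.05) {
  if (!all(c("coverage", "supported") %in% names(records))) {
    abort("`records` needs columns `coverage` and `supported`.")
  }
  cov <- records$coverage
  sup <- as.logical(records$supported)
  if (anyNA(cov) || any(cov < 0)) abort("Coverage must be non-negative.")
  for (t in sort(unique(cov))) {
    above <- cov >= t
    fdp <- mean(!sup[above])
    if (fdp <= fdr) {
      return(tibble(threshold = t, fdp = fdp,
                    n_retained = sum(above), feasible = TRUE))
    }
  }
  warn("No coverage threshold achieves the target false-discovery proportion.")
  tibble(threshold = Inf, fdp = NA_real_, n_retained = 0L, feasible = FALSE)
}
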