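#' Cell-level quality control
#'
#' A cell passes QC when strictly more than `min_genes` genes are detected
#' and, where the spike criterion applies, strictly more than `min_spikes`
#' spike species are detected. Detection at the QC stage means a raw count
#' strictly greater than 1. The spike criterion can be waived per cell
#' (`spike_required = FALSE`) for libraries prepared without spike-ins.
#'
#' @param raw A raw single-cell [expression_matrix()].
#' @param min_genes Minimum genes detected (strict `>`), default 1000.
#' @param min_spikes Minimum spike species detected (strict `>`), default
#'   40.
#' @param spike_required Logical scalar or per-cell vector; cells with
#'   `FALSE` pass on the gene criterion alone.
#' @return A tibble with one row per cell: `cell`, `genes_detected`,
#'   `spike_species_detected`, `spike_required`, `pass`.
#' @export
qc_cells <- function(raw, min_genes = 1000, min_spikes = 40,
                     spike_required = TRUE) {
  stopifnot(inherits(raw, "expr_matrix"))
  if (raw$normalized) abort("`qc_cells()` expects raw integer counts.")
  n <- ncol(raw$values)
  if (length(spike_required) == 1L) spike_required <- rep(spike_required, n)
  if (length(spike_required) != n) {
    abort("`spike_required` must be a scalar or one value per cell.")
  }
  genes <- em_genes(raw)
  spikes <- em_spikes(raw)
  if (nrow(spikes) == 0L && any(spike_required)) {
    abort("Matrix has no spike rows but some cells require the spike criterion.")
  }
  genes_detected <- colSums(genes > 1)
  spike_detected <- if (nrow(spikes)) colSums(spikes > 1) else rep(0L, n)
  tibble(
    cell = colnames(raw$values),
    genes_detected = as.integer(genes_detected),
    spike_species_detected = as.integer(spike_detected),
    spike_required = spike_required,
    pass = genes_detected > min_genes &
      (!spike_required | spike_detected > min_spikes)
  )
}

#' Size-factor normalization (median-of-ratios)
#'
#' Normalizes each library by the median-of-ratios size factor: the
#' per-gene reference is the geometric mean across samples (genes with any
#' zero drop out of the reference), and a sample's factor is the median
#' over genes of its count relative to the reference. Factors are computed
#' independently for endogenous genes and for spike rows, because the
#' spike content of a library does not scale with its transcriptome size.
#' The estimator is the DESeq one.
#'
#' @param raw A raw [expression_matrix()] with at least two samples.
#' @return A list with `size_factors` (tibble: `sample`,
#'   `gene_size_factor`, `spike_size_factor`) and `normalized` (the
#'   [expression_matrix()] of normalized counts, "ncounts").
#' @export
compute_size_factors <- function(raw) {
  stopifnot(inherits(raw, "expr_matrix"))
  if (ncol(raw$values) < 2L) abort("Need at least two samples.")
  genes <- em_genes(raw)
  spikes <- em_spikes(raw)
  gene_sf <- if (nrow(genes) == 0L) {
    rep(NA_real_, ncol(raw$values))
  } else {
    tryCatch(
      DESeq2::estimateSizeFactorsForMatrix(genes),
      error = function(e) {
        abort(paste0(
          "Gene size factors could not be estimated (no gene is non-zero in ",
          "every sample); consider normalizing by spike size factors. ",
          "Underlying error: ", conditionMessage(e)))
      })
  }
  spike_sf <- if (nrow(spikes) >= 1L) {
    tryCatch(DESeq2::estimateSizeFactorsForMatrix(spikes),
             error = function(e) rep(NA_real_, ncol(raw$values)))
  } else {
    rep(NA_real_, ncol(raw$values))
  }
  values <- raw$values
  gene_rows <- raw$feature_kind == "gene"
  if (any(gene_rows)) {
    values[gene_rows, ] <- sweep(values[gene_rows, , drop = FALSE], 2,
                                 gene_sf, "/")
  }
  if (any(!gene_rows)) {
    sf <- ifelse(is.na(spike_sf), gene_sf, spike_sf)
    values[!gene_rows, ] <- sweep(values[!gene_rows, , drop = FALSE], 2,
                                  sf, "/")
  }
  list(
    size_factors = tibble(sample = colnames(raw$values),
                          gene_size_factor = unname(gene_sf),
                          spike_size_factor = unname(spike_sf)),
    normalized = em_with_values(raw, values, normalized = TRUE)
  )
}

#' Calibrate normalized counts against spike molecules
#'
#' Fits an ordinary least squares regression of per-cell spike ncounts on
#' the known molecules per reaction, pooling every (cell, species) pair
#' across all cells. The fitted line converts a molecule threshold into an
#' ncount threshold: by default the expression floor is the ncount level
#' corresponding to `copies_threshold = 2` molecules per cell. Per-species
#' detection rates (fraction of cells with ncounts > 1) are reported
#' alongside. Species known to be poorly sampled (e.g. by polyA selection)
#' can be excluded from the fit via `exclude`.
#'
#' @param normalized A normalized [expression_matrix()] containing spike
#'   rows.
#' @param design A [spike_design()].
#' @param copies_threshold Molecule count defining the expression floor
#'   (default 2 copies per cell).
#' @param exclude Character vector of species ids left out of the
#'   regression (still reported in the detection table).
#' @return An object of class `calibration_model`: slope and intercept of
#'   the ncounts-molecules line, `ncount_threshold`, the per-species
#'   detection table, and the underlying `lm` fit.
#' @export
fit_ercc_calibration <- function(normalized, design, copies_threshold = 2,
                                 exclude = character()) {
  stopifnot(inherits(normalized, "expr_matrix"))
  spikes <- em_spikes(normalized)
  common <- intersect(rownames(spikes), design$species_id)
  if (length(common) == 0L) abort("No spike rows match the spike design.")
  spikes <- spikes[common, , drop = FALSE]
  mol <- design$molecules_per_reaction[match(common, design$species_id)]
  detected <- rowSums(spikes > 1) > 0
  if (sum(detected) < 10L) {
    abort("Fewer than 10 spike species detected; cannot calibrate.")
  }
  use <- !(common %in% exclude)
  if (length(unique(mol[use])) < 2L) {
    abort("Need at least two distinct molecule levels to fit a line.")
  }
  n_cells <- ncol(spikes)
  y <- as.vector(spikes[use, , drop = FALSE])
  x <- rep(mol[use], times = n_cells)
  fit <- lm(y ~ x)
  slope <- unname(coef(fit)[2])
  intercept <- unname(coef(fit)[1])
  structure(
    list(slope = slope, intercept = intercept,
         copies_threshold = copies_threshold,
         ncount_threshold = intercept + slope * copies_threshold,
         detection = tibble(species_id = common,
                            molecules = mol,
                            detection_rate = unname(rowMeans(spikes > 1)),
                            excluded = !use),
         n_cells = n_cells, fit = fit),
    class = "calibration_model"
  )
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf(
    "<calibration_model> ncounts = %.4g + %.4g * molecules (%d cells)\n",
    x$intercept, x$slope, x$n_cells))
  cat(sprintf("  expression floor: %.4g ncounts at %g copies per cell\n",
              x$ncount_threshold, x$copies_threshold))
  invisible(x)
}

#' @export
tidy.calibration_model <- function(x, ...) {
  tibble(term = c("intercept", "slope"),
         estimate = c(x$intercept, x$slope))
}

#' @export
glance.calibration_model <- function(x, ...) {
  s <- suppressWarnings(summary(x$fit))
  tibble(r.squared = s$r.squared, slope = x$slope,
         intercept = x$intercept, ncount_threshold = x$ncount_threshold,
         copies_threshold = x$copies_threshold, n_cells = x$n_cells,
         n_species = sum(!x$detection$excluded))
}

#' @rdname fit_ercc_calibration
#' @param object A `calibration_model`.
#' @param ... Ignored.
#' @export
autoplot.calibration_model <- function(object, ...) {
  d <- object$detection
  ggplot2::ggplot(d, ggplot2::aes(x = .data$molecules,
                                  y = .data$detection_rate,
                                  shape = .data$excluded)) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::geom_vline(xintercept = object$copies_threshold,
                        linetype = "dashed") +
    ggplot2::labs(x = "molecules per reaction",
                  y = "detection rate (ncounts > 1)",
                  title = "Spike-in detection and calibration floor")
}

#' Expression and detection filters for genes
#'
#' Applies the calibrated expression floor: a gene is kept when the mean of
#' its non-zero ncounts exceeds the calibration threshold and it is
#' detected (ncounts > 1) in at least `min_cells` cells, unless bulk
#' RNA-seq provides independent evidence of expression
#' (`bulk_expressed`). Genes detected in zero cells are excluded
#' unconditionally.
#'
#' @param normalized A normalized [expression_matrix()].
#' @param model A [fit_ercc_calibration()] model (or any object with an
#'   `ncount_threshold` element).
#' @param min_cells Minimum number of detecting cells, default 3.
#' @param bulk_expressed Character vector of gene ids with bulk evidence.
#' @param mean_mode `"nonzero"` (default) compares the mean over cells
#'   with ncounts > 0 against the floor; `"all"` uses the all-cell mean.
#' @return A tibble per gene: `gene_id`, `nonzero_mean`, `n_detected`,
#'   `in_bulk`, `keep`.
#' @export
apply_gene_filters <- function(normalized, model, min_cells = 3,
                               bulk_expressed = character(),
                               mean_mode = c("nonzero", "all")) {
  stopifnot(inherits(normalized, "expr_matrix"))
  mean_mode <- match.arg(mean_mode)
  genes <- em_genes(normalized)
  if (nrow(genes) == 0L || ncol(genes) == 0L) abort("Empty expression matrix.")
  nz_mean <- apply(genes, 1, function(v) {
    if (any(v > 0)) mean(v[v > 0]) else NA_real_
  })
  if (mean_mode == "all") nz_mean <- rowMeans(genes)
  n_detected <- rowSums(genes > 1)
  in_bulk <- rownames(genes) %in% bulk_expressed
  keep <- !is.na(nz_mean) & nz_mean > model$ncount_threshold &
    n_detected > 0 & (n_detected >= min_cells | in_bulk)
  tibble(gene_id = rownames(genes), nonzero_mean = unname(nz_mean),
         n_detected = as.integer(unname(n_detected)),
         in_bulk = in_bulk, keep = unname(keep))
}

#' Per-gene detection fractions
#'
#' Fraction of cells in which each gene is detected, where detection means
#' ncounts strictly greater than 1.
#'
#' @param normalized A normalized [expression_matrix()].
#' @param genes Optional character vector restricting the output.
#' @return A tibble: `gene_id`, `n_detected`, `detection_rate`.
#' @export
detection_profile <- function(normalized, genes = NULL) {
  stopifnot(inherits(normalized, "expr_matrix"))
  m <- em_genes(normalized)
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(m))
    if (length(missing)) {
      abort(paste0("Unknown genes: ", paste(head(missing, 5), collapse = ", ")))
    }
    m <- m[genes, , drop = FALSE]
  }
  n <- rowSums(m > 1)
  tibble(gene_id = rownames(m), n_detected = as.integer(unname(n)),
         detection_rate = unname(n) / ncol(m))
}

#' Transcripts-per-million normalization
#'
#' Length-normalizes raw counts to TPM per sample: each gene's count is
#' divided by its exonic length, and the rates are rescaled to sum to one
#' million. Spike rows are dropped; the denominator is over endogenous
#' genes only.
#'
#' @param raw A raw [expression_matrix()].
#' @param genes A [gene_table()] covering every gene row.
#' @return A TPM [expression_matrix()] (gene rows only,
#'   `normalized = TRUE`).
#' @export
compute_tpm <- function(raw, genes) {
  stopifnot(inherits(raw, "expr_matrix"))
  m <- em_genes(raw)
  idx <- match(rownames(m), genes$gene_id)
  if (anyNA(idx)) {
    abort("Every gene row needs an exonic length in the gene table.")
  }
  len <- genes$exonic_length[idx]
  if (any(len <= 0)) abort("Exonic lengths must be positive.")
  rate <- m / len
  tpm <- sweep(rate, 2, colSums(rate), "/") * 1e6
  expression_matrix(tpm, sample_kind = raw$sample_kind, normalized = TRUE,
                    feature_kind = rep("gene", nrow(tpm)),
                    meta = raw$meta)
}
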