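#' Assemble deconvolution inputs
#'
#' Builds the response and design of the bulk-deconvolution regression:
#' the response Y is the per-gene mean log2(ncounts + 1) over the chosen
#' bulk samples, and column t of X is the per-gene mean log2(ncounts + 1)
#' over the single cells of type t. Genes are restricted to those passing
#' the single-cell expression filter and detected above `min_bulk_counts`
#' raw counts in bulk (strict `>`, on the mean over the bulk subset by
#' default). Observed cell-type fractions are computed over exactly the
#' cells entering the design.
#'
#' @param single_cells Normalized single-cell [expression_matrix()].
#' @param clusters Cluster assignment for the cells (see
#'   [specificity_odds()] for accepted forms).
#' @param bulk_raw Raw bulk [expression_matrix()] (used for the detection
#'   filter).
#' @param bulk_normalized Normalized bulk [expression_matrix()] (the
#'   response scale); if `NULL` it is computed from `bulk_raw` by
#'   [compute_size_factors()].
#' @param passing_genes Character vector of genes passing the single-cell
#'   expression threshold.
#' @param min_bulk_counts Bulk detection floor in raw counts (strict
#'   `>`), default 5.
#' @param cell_subset,bulk_subset Optional sample subsets (character).
#' @param bulk_filter `"mean"` requires the mean over the bulk subset to
#'   exceed the floor; `"per_sample"` requires every bulk sample to.
#' @return A list: `y` (named vector), `X` (gene-by-type matrix),
#'   `observed` (named observed fractions), `genes` (ids used).
#' @export
build_deconv_inputs <- function(single_cells, clusters, bulk_raw,
                                bulk_normalized = NULL, passing_genes,
                                min_bulk_counts = 5, cell_subset = NULL,
                                bulk_subset = NULL,
                                bulk_filter = c("mean", "per_sample")) {
  stopifnot(inherits(single_cells, "expr_matrix"),
            inherits(bulk_raw, "expr_matrix"))
  bulk_filter <- match.arg(bulk_filter)
  if (is.null(bulk_normalized)) {
    bulk_normalized <- if (ncol(bulk_raw$values) >= 2L) {
      compute_size_factors(bulk_raw)$normalized
    } else {
      em_with_values(bulk_raw, bulk_raw$values, normalized = TRUE)
    }
  }
  sc <- em_genes(single_cells)
  if (!is.null(cell_subset)) sc <- sc[, cell_subset, drop = FALSE]
  labels <- cluster_labels_for(clusters, colnames(sc))
  lev <- sort(unique(labels))
  if (any(table(labels) == 0)) abort("Empty cell type after subsetting.")

  braw <- em_genes(bulk_raw)
  bnorm <- em_genes(bulk_normalized)
  if (is.null(bulk_subset)) bulk_subset <- colnames(braw)
  braw <- braw[, bulk_subset, drop = FALSE]
  bnorm <- bnorm[, bulk_subset, drop = FALSE]

  common <- intersect(rownames(sc), rownames(braw))
  detected <- if (bulk_filter == "mean") {
    rowMeans(braw[common, , drop = FALSE]) > min_bulk_counts
  } else {
    apply(braw[common, , drop = FALSE] > min_bulk_counts, 1, all)
  }
  genes <- intersect(common[detected], passing_genes)
  if (length(genes) <= length(lev)) {
    abort("Need more genes than cell types after filtering.")
  }

  lsc <- log2(sc[genes, , drop = FALSE] + 1)
  lbk <- log2(bnorm[genes, , drop = FALSE] + 1)
  X <- vapply(lev, function(t) {
    rowMeans(lsc[, labels == t, drop = FALSE])
  }, numeric(length(genes)))
  colnames(X) <- as.character(lev)
  y <- rowMeans(lbk)
  observed <- as.numeric(table(labels)[as.character(lev)]) / length(labels)
  names(observed) <- as.character(lev)
  list(y = y, X = X, observed = observed, genes = genes)
}

#' Fit the bulk deconvolution regression
#'
#' Ordinary least squares of bulk expression on the cell-type mean
#' profiles, `Y = b0 + b1 X1 + ... + bn Xn`, where the slope coefficients
#' are proportional to the relative cell-type fractions. The raw slopes
#' are normalized post hoc to sum to 1 — no non-negativity or sum
#' constraint is imposed during fitting, so negative raw coefficients
#' survive into the normalized fractions.
#'
#' @param y Response vector (mean bulk log2 expression per gene), or the
#'   list returned by [build_deconv_inputs()] (in which case `X` and
#'   `observed` are taken from it).
#' @param X Gene-by-type design matrix.
#' @param observed Optional observed cell-type fractions for agreement
#'   scoring.
#' @return An object of class `deconv_result`: `intercept`, raw `beta`,
#'   normalized `beta_hat` (expected fractions), `r_squared`, the
#'   observed fractions (if given) and the underlying `lm` fit.
#' @export
fit_deconvolution <- function(y, X = NULL, observed = NULL) {
  if (is.list(y) && !is.null(y$X)) {
    observed <- observed %||% y$observed
    X <- y$X
    y <- y$y
  }
  X <- as.matrix(X)
  if (length(y) <= ncol(X)) abort("Need more genes than cell types.")
  qrX <- qr(cbind(1, X))
  if (qrX$rank < ncol(X) + 1) {
    abort("Design matrix is rank deficient: collinear cell-type profiles.")
  }
  fit <- lm(y ~ X)
  beta <- coef(fit)[-1]
  names(beta) <- colnames(X)
  total <- sum(beta)
  if (total <= 0) {
    abort("Slope coefficients sum to a non-positive value; normalization undefined.")
  }
  structure(
    list(intercept = unname(coef(fit)[1]), beta = beta,
         beta_hat = beta / total,
         r_squared = suppressWarnings(summary(fit)$r.squared),
         observed = observed, n_genes = length(y), fit = fit),
    class = "deconv_result"
  )
}

#' @export
print.deconv_result <- function(x, ...) {
  cat(sprintf(
    "<deconv_result> %d cell types, %d genes, R^2 = %.3f\n",
    length(x$beta), x$n_genes, x$r_squared))
  print(round(x$beta_hat, 4))
  invisible(x)
}

#' @export
tidy.deconv_result <- function(x, ...) {
  tibble(cell_type = names(x$beta), beta = unname(x$beta),
         expected_fraction = unname(x$beta_hat),
         observed_fraction = if (is.null(x$observed)) NA_real_ else
           unname(x$observed[names(x$beta)]))
}

#' @export
glance.deconv_result <- function(x, ...) {
  agreement <- if (is.null(x$observed) || length(x$beta) < 3) NA_real_ else
    cor(x$beta_hat, x$observed[names(x$beta)])
  tibble(r_squared = x$r_squared, agreement_r = agreement,
         n_types = length(x$beta), n_genes = x$n_genes,
         intercept = x$intercept)
}

#' @rdname fit_deconvolution
#' @param object A `deconv_result`.
#' @param ... Ignored.
#' @export
autoplot.deconv_result <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$expected_fraction,
                                  y = .data$observed_fraction,
                                  label = .data$cell_type)) +
    ggplot2::geom_abline(linetype = "dashed", colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::geom_text(vjust = -0.6, size = 3) +
    ggplot2::labs(x = "expected fraction (normalized slopes)",
                  y = "observed fraction (cluster sizes)",
                  title = "Deconvolution: expected vs observed cell-type fractions")
}

#' Agreement between expected and observed cell-type fractions
#'
#' Pearson correlation between the normalized regression coefficients and
#' the observed cluster fractions, with the fit R-squared carried
#' through. With fewer than 3 cell types the correlation is undefined and
#' flagged `NA`.
#'
#' @param result A [fit_deconvolution()] result.
#' @param observed Observed fractions (defaults to those stored in the
#'   result).
#' @param stratum Optional label (e.g. `"lncRNA"`) carried into the
#'   output.
#' @return A one-row tibble: `stratum`, `agreement_r`, `r_squared`,
#'   `n_types`, `n_genes`.
#' @export
evaluate_agreement <- function(result, observed = NULL, stratum = "all") {
  stopifnot(inherits(result, "deconv_result"))
  observed <- observed %||% result$observed
  if (is.null(observed)) abort("No observed fractions supplied.")
  observed <- observed[names(result$beta)]
  if (abs(sum(observed) - 1) > 1e-6) {
    abort("Observed fractions must sum to 1.")
  }
  r <- if (length(observed) < 3) NA_real_ else
    cor(result$beta_hat, observed)
  tibble(stratum = stratum, agreement_r = r, r_squared = result$r_squared,
         n_types = length(observed), n_genes = result$n_genes)
}
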