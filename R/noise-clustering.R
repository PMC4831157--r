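#' Fit the spike-based technical-noise model
#'
#' Spike-in species have no biological variance, so their squared
#' coefficient of variation (CV2) as a function of mean ncounts traces the
#' technical noise of the protocol. A gamma-family generalized linear
#' model with identity link regresses the per-species CV2 on the
#' reciprocal mean, giving the fitted technical noise
#' `CV2_tech(mu) = a1 / mu + a0`. If the GLM fails to converge the model
#' falls back to ordinary least squares on the same design, with a
#' warning. The minimum biological CV of interest (default 50%) is stored
#' as `min_biol_cv2` and enters the null model used by
#' [select_variable_genes()].
#'
#' @param normalized_spikes A normalized [expression_matrix()] whose spike
#'   rows hold the spikes (a spike-only matrix works too), or a bare
#'   numeric matrix of normalized spike counts.
#' @param min_biol_cv Biological coefficient of variation defining the
#'   variability of interest, default 0.5.
#' @return An object of class `noise_model` with elements `a1`, `a0`,
#'   `min_biol_cv2` and the per-species `spike_stats` tibble.
#' @export
fit_noise_model <- function(normalized_spikes, min_biol_cv = 0.5) {
  m <- if (inherits(normalized_spikes, "expr_matrix")) {
    s <- em_spikes(normalized_spikes)
    if (nrow(s) == 0L) em_genes(normalized_spikes) else s
  } else {
    normalized_spikes
  }
  mu <- rowMeans(m)
  keep <- mu > 0
  if (sum(keep) < 10L) {
    abort("Need at least 10 spike species with non-zero mean.")
  }
  mu <- mu[keep]
  cv2 <- apply(m[keep, , drop = FALSE], 1, var) / mu^2
  df <- data.frame(cv2 = cv2, inv_mu = 1 / mu)
  fit <- tryCatch(
    glm(cv2 ~ inv_mu, family = Gamma(link = "identity"), data = df,
        start = unname(coef(lm(cv2 ~ inv_mu, data = df)))),
    error = function(e) NULL, warning = function(w) NULL)
  if (is.null(fit) || !fit$converged) {
    warn("Gamma GLM did not converge; falling back to least squares.")
    fit <- lm(cv2 ~ inv_mu, data = df)
  }
  a0 <- unname(coef(fit)[1])
  a1 <- unname(coef(fit)[2])
  structure(
    list(a1 = a1, a0 = a0, min_biol_cv2 = min_biol_cv^2,
         spike_stats = tibble(species_id = names(mu), mean = unname(mu),
                              cv2 = unname(cv2)),
         fit = fit),
    class = "noise_model"
  )
}

#' @export
print.noise_model <- function(x, ...) {
  cat(sprintf(
    "<noise_model> CV2_tech(mu) = %.4g / mu + %.4g  (min biological CV2 %.3g)\n",
    x$a1, x$a0, x$min_biol_cv2))
  invisible(x)
}

#' @export
tidy.noise_model <- function(x, ...) {
  tibble(term = c("a0", "a1"), estimate = c(x$a0, x$a1))
}

#' @export
glance.noise_model <- function(x, ...) {
  tibble(a1 = x$a1, a0 = x$a0, min_biol_cv2 = x$min_biol_cv2,
         n_species = nrow(x$spike_stats))
}

#' @rdname fit_noise_model
#' @param object A `noise_model`.
#' @param ... Ignored.
#' @export
autoplot.noise_model <- function(object, ...) {
  d <- object$spike_stats
  grid <- tibble(mean = exp(seq(log(min(d$mean)), log(max(d$mean)),
                                length.out = 200)))
  grid$cv2 <- object$a1 / grid$mean + object$a0
  ggplot2::ggplot(d, ggplot2::aes(x = .data$mean, y = .data$cv2)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "red") +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "mean ncounts", y = expression(CV^2),
                  title = "Spike-in technical noise model")
}

#' Select genes more variable than technical noise
#'
#' Tests each gene's observed CV2 against the null that its variation is
#' technical noise plus at most `min_biol_cv` biological variation: the
#' null CV2 is `a1 / mu + a0 + min_biol_cv2`, the statistic
#' `(m - 1) * CV2 / null_CV2` is referred to a chi-square distribution
#' with `m - 1` degrees of freedom (m = number of cells), and p-values are
#' Benjamini-Hochberg adjusted. Genes with zero mean are skipped.
#'
#' @param normalized A normalized [expression_matrix()].
#' @param model A [fit_noise_model()] object.
#' @param fdr Adjusted-p cutoff, default 0.01.
#' @return A tibble per testable gene: `gene_id`, `mean`, `cv2`,
#'   `null_cv2`, `statistic`, `p_value`, `p_adjusted`, `selected`.
#' @export
select_variable_genes <- function(normalized, model, fdr = 0.01) {
  stopifnot(inherits(normalized, "expr_matrix"),
            inherits(model, "noise_model"))
  m <- em_genes(normalized)
  n_cells <- ncol(m)
  if (n_cells < 3L) abort("Need at least 3 cells.")
  mu <- rowMeans(m)
  keep <- mu > 0
  m <- m[keep, , drop = FALSE]
  mu <- mu[keep]
  cv2 <- apply(m, 1, var) / mu^2
  null_cv2 <- model$a1 / mu + model$a0 + model$min_biol_cv2
  stat <- (n_cells - 1) * cv2 / null_cv2
  p <- pchisq(stat, df = n_cells - 1, lower.tail = FALSE)
  padj <- p.adjust(p, method = "BH")
  tibble(gene_id = rownames(m), mean = unname(mu), cv2 = unname(cv2),
         null_cv2 = unname(null_cv2), statistic = unname(stat),
         p_value = unname(p), p_adjusted = unname(padj),
         selected = unname(padj) < fdr)
}

#' Rank genes by principal-component loadings
#'
#' Runs PCA on the log2(ncounts + 1) expression of the variable genes
#' (cells as observations, genes centred, no unit-variance scaling) and
#' scores each gene by its largest absolute loading across the first
#' `n_pcs` components. The top `n_top` genes by that score are returned in
#' rank order; ties break by gene id.
#'
#' @param normalized A normalized [expression_matrix()].
#' @param variable_genes Character vector of gene ids (or a
#'   [select_variable_genes()] tibble, whose selected genes are used).
#' @param n_pcs Number of leading components, default 4.
#' @param n_top Number of genes to return, default 500 (all available,
#'   with a warning, if fewer).
#' @return A tibble in rank order: `gene_id`, `loading_score`, `rank`.
#' @export
pca_rank_genes <- function(normalized, variable_genes, n_pcs = 4,
                           n_top = 500) {
  stopifnot(inherits(normalized, "expr_matrix"))
  if (is.data.frame(variable_genes)) {
    variable_genes <- variable_genes$gene_id[variable_genes$selected]
  }
  m <- em_genes(normalized)
  missing <- setdiff(variable_genes, rownames(m))
  if (length(missing)) {
    abort(paste0("Unknown genes: ", paste(head(missing, 5), collapse = ", ")))
  }
  lx <- log2(m[variable_genes, , drop = FALSE] + 1)
  pca <- prcomp(t(lx), center = TRUE, scale. = FALSE)
  k <- min(n_pcs, ncol(pca$rotation))
  if (k < n_pcs) {
    warn(sprintf("Only %d principal components available; using all.", k))
  }
  score <- apply(abs(pca$rotation[, seq_len(k), drop = FALSE]), 1, max)
  ord <- order(-score, names(score))
  if (length(variable_genes) < n_top) {
    warn(sprintf("Only %d variable genes; returning all of them.",
                 length(variable_genes)))
  }
  keep <- head(ord, n_top)
  tibble(gene_id = names(score)[keep], loading_score = unname(score[keep]),
         rank = seq_along(keep))
}

#' Cluster cells by correlation distance
#'
#' Computes pairwise cell distances as 1 minus the Pearson correlation of
#' log2(ncounts + 1) over the given genes, builds a complete-linkage
#' dendrogram, and cuts it statically at a correlation inside
#' `cut_interval` (default r in \[0.8, 0.9\], i.e. height in
#' \[0.1, 0.2\]). Without a target the tree is cut at the midpoint height;
#' with `target_clusters` the cut height is chosen inside the interval so
#' the cut yields exactly that many clusters (an error if no height in
#' the interval does).
#'
#' @param normalized A normalized [expression_matrix()].
#' @param top_genes Character vector of gene ids (or a [pca_rank_genes()]
#'   tibble).
#' @param cut_interval Correlation interval for the static cut, default
#'   `c(0.8, 0.9)`.
#' @param target_clusters Optional integer; choose the cut height inside
#'   the interval that yields exactly this many clusters.
#' @return An object of class `cluster_assignment`: per-cell labels,
#'   cluster sizes, the cut height used and the `hclust` tree.
#' @export
cluster_cells <- function(normalized, top_genes,
                          cut_interval = c(0.8, 0.9),
                          target_clusters = NULL) {
  stopifnot(inherits(normalized, "expr_matrix"))
  if (is.data.frame(top_genes)) top_genes <- top_genes$gene_id
  m <- em_genes(normalized)
  missing <- setdiff(top_genes, rownames(m))
  if (length(missing)) {
    abort(paste0("Unknown genes: ", paste(head(missing, 5), collapse = ", ")))
  }
  lx <- log2(m[top_genes, , drop = FALSE] + 1)
  if (ncol(lx) < 2L) abort("Need at least 2 cells to cluster.")
  sds <- apply(lx, 2, sd)
  if (any(sds == 0)) {
    abort(paste0("Constant expression profile (correlation undefined) for: ",
                 paste(head(colnames(lx)[sds == 0], 5), collapse = ", ")))
  }
  d <- as.dist(1 - cor(lx))
  tree <- hclust(d, method = "complete")
  h_lo <- 1 - cut_interval[2]
  h_hi <- 1 - cut_interval[1]
  if (is.null(target_clusters)) {
    height <- (h_lo + h_hi) / 2
  } else {
    n <- ncol(lx)
    if (target_clusters < 1L || target_clusters > n) {
      abort("`target_clusters` must be between 1 and the number of cells.")
    }
    # cutting at height h yields n - #{merge heights <= h} clusters, so
    # exactly k clusters happen for h in [H[n - k], H[n - k + 1])
    H <- sort(tree$height)
    i <- n - target_clusters
    feas_lo <- if (i == 0L) 0 else H[i]
    feas_hi <- if (i < n - 1L) H[i + 1L] else Inf
    lo <- max(feas_lo, h_lo)
    hi <- min(feas_hi, h_hi)
    if (lo > hi || lo >= feas_hi) {
      abort(sprintf(
        "No cut height inside [%g, %g] yields %d clusters.", h_lo, h_hi,
        target_clusters))
    }
    height <- (lo + hi) / 2
  }
  labels <- cutree(tree, h = height)
  structure(
    list(labels = labels, n_clusters = length(unique(labels)),
         sizes = as.integer(table(labels)), cut_height = height,
         tree = tree),
    class = "cluster_assignment"
  )
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf(
    "<cluster_assignment> %d cells in %d clusters (cut height %.3g)\n",
    length(x$labels), x$n_clusters, x$cut_height))
  cat("  sizes:", paste(x$sizes, collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.cluster_assignment <- function(x, ...) {
  tibble(cell = names(x$labels), cluster = unname(x$labels))
}
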