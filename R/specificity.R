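# normalize the many ways a clustering can be passed in to a named vector
# of labels aligned with the matrix columns
cluster_labels_for <- function(clusters, cells) {
  labels <- if (inherits(clusters, "cluster_assignment")) {
    clusters$labels
  } else if (is.data.frame(clusters)) {
    setNames(clusters$cluster, clusters$cell)
  } else {
    clusters
  }
  if (is.null(names(labels))) {
    if (length(labels) != length(cells)) {
      abort("Unnamed cluster labels must cover every cell in order.")
    }
    names(labels) <- cells
  }
  missing <- setdiff(cells, names(labels))
  if (length(missing)) {
    abort(paste0("Cells without cluster label: ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  labels[cells]
}

#' Cell-type specificity log-odds
#'
#' For each gene i, cells are called "expressing" when their level exceeds
#' the gene's own 75th percentile across all cells (linear interpolation;
#' strict `>`, so for genes with at least 75% zeros any expression
#' counts). With `p_ij` the fraction of expressing cells inside cluster j
#' and `q_ij` the fraction outside, the specificity score is the log-odds
#' `theta_ij = log( p_ij (1 - q_ij) / (q_ij (1 - p_ij)) )` (natural log).
#' The four underlying cell counts each receive a +0.5 correction before
#' the proportions are formed, so theta is finite even when a gene is
#' expressed in every cell of a cluster or in none.
#'
#' @param expression A normalized [expression_matrix()] (theta depends
#'   only on the above-threshold indicator, so any monotone transform of
#'   the scale gives the same result).
#' @param clusters A [cluster_cells()] assignment, a tibble with `cell`
#'   and `cluster` columns, or a named label vector. Every cluster must
#'   have at least 2 cells.
#' @return A tibble per (gene, cluster): `gene_id`, `cluster`, `tau`
#'   (the gene's threshold), `p`, `q` (corrected proportions), `theta`.
#' @export
specificity_odds <- function(expression, clusters) {
  stopifnot(inherits(expression, "expr_matrix"))
  m <- em_genes(expression)
  labels <- cluster_labels_for(clusters, colnames(m))
  sizes <- table(labels)
  if (any(sizes < 2)) {
    abort("Every cluster needs at least 2 cells.")
  }
  lev <- sort(unique(labels))
  C <- ncol(m)
  M <- vapply(lev, function(j) as.numeric(labels == j), numeric(C))
  nj <- colSums(M)
  tau <- apply(m, 1, quantile, probs = 0.75, type = 7, names = FALSE)
  above <- (m > tau) * 1
  A <- above %*% M                  # expressing cells inside each cluster
  tot_above <- rowSums(above)
  a <- A
  b <- matrix(nj, nrow(m), length(lev), byrow = TRUE) - A
  cc <- tot_above - A
  d <- matrix(C - nj, nrow(m), length(lev), byrow = TRUE) - cc
  p <- (a + 0.5) / (a + b + 1)
  q <- (cc + 0.5) / (cc + d + 1)
  theta <- log(p * (1 - q) / (q * (1 - p)))
  tibble(
    gene_id = rep(rownames(m), times = length(lev)),
    cluster = rep(lev, each = nrow(m)),
    tau = rep(unname(tau), times = length(lev)),
    p = as.vector(p), q = as.vector(q), theta = as.vector(theta)
  )
}

#' Assign genes to cell types and score enrichment
#'
#' Each gene is assigned to the cluster with its maximum specificity
#' log-odds (ties broken by larger enrichment, then smaller cluster
#' label). The enrichment score `e_ij` is the mean expression of gene i
#' inside cluster j over its mean outside, with a pseudocount on both
#' means so perfectly restricted genes stay finite.
#'
#' @inheritParams specificity_odds
#' @param odds The [specificity_odds()] table for the same matrix and
#'   clustering.
#' @param eps Pseudocount added to both means (expression units),
#'   default 0.1.
#' @return The odds table extended with `enrichment`,
#'   `assigned_cluster` (per gene, repeated across its rows) and
#'   `is_assigned`.
#' @export
assign_and_enrich <- function(expression, clusters, odds, eps = 0.1) {
  stopifnot(inherits(expression, "expr_matrix"))
  m <- em_genes(expression)
  labels <- cluster_labels_for(clusters, colnames(m))
  lev <- sort(unique(labels))
  C <- ncol(m)
  M <- vapply(lev, function(j) as.numeric(labels == j), numeric(C))
  nj <- colSums(M)
  inside_sum <- m %*% M
  u <- sweep(inside_sum, 2, nj, "/")
  v <- sweep(rowSums(m) - inside_sum, 2, C - nj, "/")
  e <- (u + eps) / (v + eps)
  tbl <- odds
  tbl$enrichment <- as.vector(e)[
    match(paste(tbl$gene_id, tbl$cluster),
          paste(rep(rownames(m), length(lev)), rep(lev, each = nrow(m))))]
  assignment <- tbl |>
    group_by(.data$gene_id) |>
    arrange(desc(.data$theta), desc(.data$enrichment), .data$cluster,
            .by_group = TRUE) |>
    summarise(assigned_cluster = .data$cluster[1], .groups = "drop")
  tbl <- left_join(tbl, assignment, by = "gene_id")
  tbl$is_assigned <- tbl$cluster == tbl$assigned_cluster
  tbl
}

#' Select top marker genes per cluster
#'
#' Within each cluster, genes assigned to it are ranked by enrichment
#' score (descending, ties by gene id) separately for mRNAs and lncRNAs,
#' and the top `k` of each biotype are returned. Clusters with fewer than
#' `k` assigned genes of a biotype return what they have.
#'
#' @param result A complete [assign_and_enrich()] table.
#' @param genes A [gene_table()] supplying biotypes.
#' @param k Markers per cluster per biotype, default 15.
#' @return A tibble: `cluster`, `biotype`, `gene_id`, `enrichment`,
#'   `rank` (1 = most enriched).
#' @export
select_markers <- function(result, genes, k = 15) {
  if (!all(c("enrichment", "assigned_cluster") %in% names(result))) {
    abort("`result` must come from `assign_and_enrich()`.")
  }
  result |>
    filter(.data$is_assigned) |>
    left_join(genes[, c("gene_id", "biotype")], by = "gene_id") |>
    filter(.data$biotype %in% c("mRNA", "lncRNA")) |>
    group_by(.data$cluster, .data$biotype) |>
    arrange(desc(.data$enrichment), .data$gene_id, .by_group = TRUE) |>
    mutate(rank = row_number()) |>
    ungroup() |>
    filter(.data$rank <= k) |>
    select("cluster", "biotype", "gene_id", "enrichment", "rank") |>
    arrange(.data$cluster, .data$biotype, .data$rank)
}
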