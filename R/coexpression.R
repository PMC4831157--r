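#' Build a lncRNA-mRNA co-expression network
#'
#' Computes all pairwise Pearson correlations between the cell-type
#' specific lncRNAs and the expressed mRNAs on log2(ncounts + 1), scores
#' each mRNA by its maximum absolute correlation with any of the
#' lncRNAs, and retains the mRNAs whose score reaches the 90th percentile
#' of all scores (linear interpolation; boundary ties are all retained).
#' Zero-variance genes have undefined correlations and are dropped with a
#' warning.
#'
#' @param expression A normalized [expression_matrix()].
#' @param specific_lncrnas Character vector of specific lncRNA ids (rows
#'   of the network).
#' @param mrnas Character vector of expressed mRNA ids (columns).
#' @param retain_quantile Score percentile above which mRNAs are kept,
#'   default 0.9 (top 10%).
#' @return An object of class `coexpression_network`: the full
#'   correlation matrix `cor`, per-mRNA `scores`, the retention
#'   `threshold`, the `retained` mRNA ids and the retained `submatrix`.
#' @export
build_coexpression_network <- function(expression, specific_lncrnas, mrnas,
                                       retain_quantile = 0.9) {
  stopifnot(inherits(expression, "expr_matrix"))
  if (length(specific_lncrnas) == 0L || length(mrnas) == 0L) {
    abort("Both gene sets must be non-empty.")
  }
  m <- em_genes(expression)
  missing <- setdiff(c(specific_lncrnas, mrnas), rownames(m))
  if (length(missing)) {
    abort(paste0("Unknown genes: ", paste(head(missing, 5), collapse = ", ")))
  }
  lx <- log2(m + 1)
  drop_flat <- function(ids) {
    v <- apply(lx[ids, , drop = FALSE], 1, var)
    if (any(v == 0)) {
      warn(paste0("Dropping zero-variance gene(s): ",
                  paste(head(ids[v == 0], 5), collapse = ", ")))
    }
    ids[v > 0]
  }
  specific_lncrnas <- drop_flat(specific_lncrnas)
  mrnas <- drop_flat(mrnas)
  if (length(specific_lncrnas) == 0L || length(mrnas) == 0L) {
    abort("No genes left after dropping zero-variance profiles.")
  }
  cormat <- cor(t(lx[specific_lncrnas, , drop = FALSE]),
                t(lx[mrnas, , drop = FALSE]))
  scores <- apply(abs(cormat), 2, max)
  threshold <- unname(quantile(scores, probs = retain_quantile, type = 7))
  retained <- names(scores)[scores >= threshold]
  structure(
    list(cor = cormat, scores = scores, threshold = threshold,
         retained = retained,
         submatrix = cormat[, retained, drop = FALSE]),
    class = "coexpression_network"
  )
}

#' @export
print.coexpression_network <- function(x, ...) {
  cat(sprintf(
    "<coexpression_network> %d lncRNAs x %d mRNAs; %d mRNAs retained at |r| >= %.3f\n",
    nrow(x$cor), ncol(x$cor), length(x$retained), x$threshold))
  invisible(x)
}

#' Cluster the retained co-expression sub-matrix
#'
#' Hierarchically clusters the rows (lncRNAs) and columns (retained
#' mRNAs) of the correlation sub-matrix using Euclidean distance on the
#' correlation vectors and complete linkage, producing deterministic
#' orderings; optional cluster labels come from cutting each tree into
#' `k_rows` / `k_cols` groups.
#'
#' @param network A [build_coexpression_network()] object.
#' @param k_rows,k_cols Optional number of clusters for rows / columns.
#' @return A list: the reordered `submatrix`, `row_order`, `col_order`,
#'   the two `hclust` trees, and (if requested) `row_clusters` /
#'   `col_clusters` label vectors.
#' @export
cluster_network <- function(network, k_rows = NULL, k_cols = NULL) {
  stopifnot(inherits(network, "coexpression_network"))
  sub <- network$submatrix
  if (nrow(sub) == 0L || ncol(sub) == 0L) {
    abort("Retained sub-matrix is empty.")
  }
  order_of <- function(m) {
    if (nrow(m) < 2L) {
      list(order = seq_len(nrow(m)), tree = NULL)
    } else {
      tree <- hclust(dist(m, method = "euclidean"), method = "complete")
      list(order = tree$order, tree = tree)
    }
  }
  rows <- order_of(sub)
  cols <- order_of(t(sub))
  out <- list(
    submatrix = sub[rows$order, cols$order, drop = FALSE],
    row_order = rownames(sub)[rows$order],
    col_order = colnames(sub)[cols$order],
    row_tree = rows$tree, col_tree = cols$tree
  )
  if (!is.null(k_rows) && !is.null(rows$tree)) {
    out$row_clusters <- cutree(rows$tree, k = k_rows)
  }
  if (!is.null(k_cols) && !is.null(cols$tree)) {
    out$col_clusters <- cutree(cols$tree, k = k_cols)
  }
  out
}
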