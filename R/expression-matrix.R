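#' Expression matrix container
#'
#' A light container for a gene-by-sample expression matrix. Rows are
#' features (endogenous genes or spike-in species), columns are samples
#' (single cells or bulk libraries). Spike rows are distinguished from gene
#' rows so that gene-level statistics never silently include the synthetic
#' spike species; operations that need the spikes ask for them explicitly
#' via [em_spikes()].
#'
#' @param values Numeric matrix, features as rows and samples as columns,
#'   with unique row and column names. Raw matrices must contain
#'   non-negative integer counts; normalized matrices may hold any
#'   non-negative reals.
#' @param sample_kind Character, one of `"single_cell"`, `"bulk_polyA"`,
#'   `"bulk_total"`; either a single value recycled to all columns or one
#'   value per column.
#' @param normalized Logical flag; `FALSE` for raw fragment counts.
#' @param spike_prefix Feature ids starting with this prefix are flagged as
#'   spike rows (default `"ERCC-"`, the standard panel naming). Ignored when
#'   `feature_kind` is given.
#' @param feature_kind Optional character vector (`"gene"`/`"spike"`), one
#'   per row, overriding prefix-based detection.
#' @param meta Optional per-sample metadata (data frame with one row per
#'   column, e.g. specimen and developmental-stage labels).
#'
#' @return An object of class `expr_matrix`: a list with elements `values`,
#'   `feature_kind`, `sample_kind`, `normalized` and `meta`.
#' @export
#' @examples
#' m <- matrix(c(5L, 0L, 3L, 1L), 2, 2,
#'             dimnames = list(c("G1", "ERCC-00001"), c("cellA", "cellB")))
#' em <- expression_matrix(m)
#' em_genes(em)
#' em_spikes(em)
expression_matrix <- function(values, sample_kind = "single_cell",
                              normalized = FALSE, spike_prefix = "ERCC-",
                              feature_kind = NULL, meta = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix.")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    abort("`values` must have row names (features) and column names (samples).")
  }
  if (anyDuplicated(rownames(values))) {
    abort("Duplicate feature ids in expression matrix.")
  }
  if (anyDuplicated(colnames(values))) {
    abort("Duplicate sample ids in expression matrix.")
  }
  if (anyNA(values) || any(values < 0)) {
    abort("Expression values must be non-negative and non-missing.")
  }
  if (!normalized && any(values != round(values))) {
    abort("Raw expression matrices must contain integer counts.")
  }
  kinds <- c("single_cell", "bulk_polyA", "bulk_total")
  if (length(sample_kind) == 1L) sample_kind <- rep(sample_kind, ncol(values))
  if (length(sample_kind) != ncol(values) || !all(sample_kind %in% kinds)) {
    abort(paste0("`sample_kind` must be one value per sample, each one of: ",
                 paste(kinds, collapse = ", "), "."))
  }
  if (is.null(feature_kind)) {
    feature_kind <- ifelse(startsWith(rownames(values), spike_prefix),
                           "spike", "gene")
  }
  if (length(feature_kind) != nrow(values) ||
      !all(feature_kind %in% c("gene", "spike"))) {
    abort("`feature_kind` must be one of \"gene\"/\"spike\" per feature.")
  }
  structure(
    list(values = values, feature_kind = feature_kind,
         sample_kind = sample_kind, normalized = normalized, meta = meta),
    class = "expr_matrix"
  )
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf(
    "<expr_matrix> %d features (%d genes, %d spikes) x %d samples [%s]\n",
    nrow(x$values), sum(x$feature_kind == "gene"),
    sum(x$feature_kind == "spike"), ncol(x$values),
    if (x$normalized) "normalized" else "raw counts"))
  invisible(x)
}

#' Access the pieces of an expression matrix
#'
#' `em_values()` returns the full feature-by-sample matrix, `em_genes()`
#' the gene-row submatrix, and `em_spikes()` the spike-row submatrix.
#'
#' @param x An [expression_matrix()].
#' @return A numeric matrix.
#' @export
em_values <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  x$values
}

#' @rdname em_values
#' @export
em_genes <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  x$values[x$feature_kind == "gene", , drop = FALSE]
}

#' @rdname em_values
#' @export
em_spikes <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  x$values[x$feature_kind == "spike", , drop = FALSE]
}

#' Subset the samples of an expression matrix
#'
#' @param x An [expression_matrix()].
#' @param samples Character vector of sample ids (or logical/integer index).
#' @return An [expression_matrix()] restricted to the requested columns.
#' @export
em_select_samples <- function(x, samples) {
  stopifnot(inherits(x, "expr_matrix"))
  if (is.character(samples)) {
    missing <- setdiff(samples, colnames(x$values))
    if (length(missing)) {
      abort(paste0("Unknown samples: ", paste(missing, collapse = ", ")))
    }
    idx <- match(samples, colnames(x$values))
  } else {
    idx <- seq_len(ncol(x$values))[samples]
  }
  expression_matrix(x$values[, idx, drop = FALSE],
                    sample_kind = x$sample_kind[idx],
                    normalized = x$normalized,
                    feature_kind = x$feature_kind,
                    meta = if (!is.null(x$meta)) x$meta[idx, , drop = FALSE])
}

# internal: replace values while keeping the feature/sample bookkeeping
em_with_values <- function(x, values, normalized = x$normalized) {
  expression_matrix(values, sample_kind = x$sample_kind,
                    normalized = normalized, feature_kind = x$feature_kind,
                    meta = x$meta)
}
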