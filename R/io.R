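#' Construct and validate a gene annotation table
#'
#' The gene table drives every biotype-stratified statistic in the package:
#' each gene carries a biotype (`mRNA`, `lncRNA` or `TUCP`, a transcript of
#' uncertain coding potential), a housekeeping flag and its exonic length in
#' base pairs. Common annotation biotype strings are mapped onto the three
#' classes: `"protein_coding"` becomes `mRNA`, and the Ensembl non-coding
#' biotypes (`"3prime_overlapping_ncrna"`, `"antisense"`, `"lincRNA"`,
#' `"processed_transcript"`, `"sense_intronic"`, `"sense_overlapping"`)
#' become `lncRNA`. lncRNAs shorter than 200 nt are rejected: by definition
#' the class only contains transcripts of at least 200 nt.
#'
#' @param gene_id Character vector of unique gene ids.
#' @param biotype Character vector of biotypes (aliases allowed, see above).
#' @param is_housekeeping Logical vector.
#' @param exonic_length Positive integer vector, exonic length in bp.
#'
#' @return A tibble with columns `gene_id`, `biotype`, `is_housekeeping`,
#'   `exonic_length`.
#' @export
gene_table <- function(gene_id, biotype, is_housekeeping, exonic_length) {
  if (anyDuplicated(gene_id)) abort("Duplicate gene ids in gene table.")
  biotype <- map_biotype(biotype)
  if (!is.logical(is_housekeeping) || anyNA(is_housekeeping)) {
    abort("`is_housekeeping` must be TRUE/FALSE.")
  }
  exonic_length <- as.integer(exonic_length)
  if (anyNA(exonic_length) || any(exonic_length <= 0)) {
    abort("`exonic_length` must be a positive integer (bp).")
  }
  short <- biotype == "lncRNA" & exonic_length < 200L
  if (any(short)) {
    abort(paste0("lncRNAs must be at least 200 nt; offending genes: ",
                 paste(head(gene_id[short], 5), collapse = ", ")))
  }
  tibble(gene_id = as.character(gene_id), biotype = biotype,
         is_housekeeping = is_housekeeping, exonic_length = exonic_length)
}

# canonical biotypes plus annotation aliases
map_biotype <- function(biotype) {
  lnc_aliases <- c("3prime_overlapping_ncrna", "antisense", "lincRNA",
                   "processed_transcript", "sense_intronic",
                   "sense_overlapping")
  out <- ifelse(biotype == "protein_coding", "mRNA",
                ifelse(biotype %in% lnc_aliases, "lncRNA", biotype))
  bad <- setdiff(unique(out), c("mRNA", "lncRNA", "TUCP"))
  if (length(bad)) {
    abort(paste0("Unknown biotype(s): ", paste(bad, collapse = ", ")))
  }
  out
}

#' Read a gene annotation table from TSV
#'
#' Expects columns `gene_id`, `biotype`, `is_housekeeping`, `exonic_length`;
#' validation and biotype alias mapping follow [gene_table()].
#'
#' @param path Path to a tab-separated file with a header row.
#' @return A validated gene table tibble.
#' @export
read_gene_table <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("gene_id", "biotype", "is_housekeeping", "exonic_length")
  missing <- setdiff(need, names(tbl))
  if (length(missing)) {
    abort(paste0("Gene table is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  gene_table(tbl$gene_id, tbl$biotype, as.logical(tbl$is_housekeeping),
             tbl$exonic_length)
}

#' Construct or read an ERCC spike design table
#'
#' The spike design records how many molecules of each spike-in species are
#' present in one lysis reaction (after dilution). The standard External RNA
#' Controls Consortium (ERCC) panel has 92 species spanning several orders
#' of magnitude in concentration, but because the molecule counts in a given
#' experiment depend on the mix and dilution used, the design is an input
#' table rather than a built-in constant; [default_spike_design()] provides
#' a synthetic 92-species panel for simulation.
#'
#' @param species_id Character vector of unique spike species ids.
#' @param molecules_per_reaction Strictly positive numeric vector, expected
#'   molecules per reaction.
#' @return A tibble with columns `species_id`, `molecules_per_reaction`.
#' @export
spike_design <- function(species_id, molecules_per_reaction) {
  if (anyDuplicated(species_id)) abort("Duplicate spike species ids.")
  if (anyNA(molecules_per_reaction) || any(molecules_per_reaction <= 0)) {
    abort("`molecules_per_reaction` must be strictly positive.")
  }
  tibble(species_id = as.character(species_id),
         molecules_per_reaction = as.numeric(molecules_per_reaction))
}

#' @rdname spike_design
#' @param path Path to a TSV with columns `species_id`,
#'   `molecules_per_reaction`.
#' @export
read_spike_design <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("species_id", "molecules_per_reaction")
  missing <- setdiff(need, names(tbl))
  if (length(missing)) {
    abort(paste0("Spike design is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  spike_design(tbl$species_id, tbl$molecules_per_reaction)
}

#' Read an expression matrix from disk
#'
#' Two layouts are supported: a dense TSV (header row of sample ids, first
#' column of feature ids) and Matrix Market coordinate format with
#' companion feature-id (`<path>.rows`) and sample-id (`<path>.cols`) text
#' files, one id per line. Entries absent from a sparse file are zeros.
#'
#' @param path File path.
#' @param layout `"dense_tsv"` or `"matrix_market_triplet"`.
#' @inheritParams expression_matrix
#' @return An [expression_matrix()]; spike rows are flagged automatically
#'   by `spike_prefix`.
#' @export
read_expression_matrix <- function(path,
                                   layout = c("dense_tsv",
                                              "matrix_market_triplet"),
                                   sample_kind = "single_cell",
                                   normalized = FALSE,
                                   spike_prefix = "ERCC-") {
  layout <- match.arg(layout)
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  if (layout == "dense_tsv") {
    tbl <- readr::read_tsv(path, show_col_types = FALSE)
    ids <- as.character(tbl[[1]])
    m <- as.matrix(tbl[, -1, drop = FALSE])
    if (!is.numeric(m)) abort("Non-numeric entries in expression matrix.")
    rownames(m) <- ids
  } else {
    rows_path <- paste0(path, ".rows")
    cols_path <- paste0(path, ".cols")
    if (!file.exists(rows_path) || !file.exists(cols_path)) {
      abort("Matrix Market layout requires companion <path>.rows and <path>.cols id files.")
    }
    m <- as.matrix(Matrix::readMM(path))
    rownames(m) <- readLines(rows_path)
    colnames(m) <- readLines(cols_path)
  }
  expression_matrix(m, sample_kind = sample_kind, normalized = normalized,
                    spike_prefix = spike_prefix)
}

#' Write an expression matrix to disk
#'
#' Inverse of [read_expression_matrix()]; round-trips are lossless for
#' integer counts.
#'
#' @param x An [expression_matrix()].
#' @param path Output file path.
#' @param layout `"dense_tsv"` or `"matrix_market_triplet"`.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path,
                                    layout = c("dense_tsv",
                                               "matrix_market_triplet")) {
  layout <- match.arg(layout)
  stopifnot(inherits(x, "expr_matrix"))
  m <- x$values
  if (layout == "dense_tsv") {
    tbl <- as_tibble(m, rownames = "feature_id")
    readr::write_tsv(tbl, path)
  } else {
    Matrix::writeMM(Matrix::Matrix(m, sparse = TRUE), path)
    writeLines(rownames(m), paste0(path, ".rows"))
    writeLines(colnames(m), paste0(path, ".cols"))
  }
  invisible(path)
}

#' Write a result table as TSV with a JSON twin
#'
#' Writes any non-empty tabular result to `path` as TSV (floats at full
#' precision, well beyond 6 significant digits) and, alongside it, a
#' machine-readable JSON twin with the same basename.
#'
#' @param table A data frame with at least one row.
#' @param path Output TSV path; the JSON twin replaces the extension with
#'   `.json`.
#' @return `path`, invisibly.
#' @export
write_result_table <- function(table, path) {
  if (!is.data.frame(table) || nrow(table) == 0L) {
    abort("Result table must be a non-empty data frame.")
  }
  readr::write_tsv(table, path)
  json_path <- paste0(sub("\\.[^./\\\\]+$", "", path), ".json")
  jsonlite::write_json(table, json_path, dataframe = "rows", digits = NA,
                       na = "null")
  invisible(path)
}

#' Pipeline run configuration
#'
#' Collects the thresholds and options consumed by the downstream modules,
#' with the defaults used throughout the package. `read_run_config()` reads
#' a YAML file and overlays it on these defaults.
#'
#' @param ... Named overrides of the defaults (unknown names are rejected).
#' @return A named list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    min_genes_per_cell = 1000,
    min_spike_species = 40,
    copies_per_cell_threshold = 2,
    min_cells_per_gene = 3,
    fold_enrichment_cutoff = 10,
    n_pcs = 4,
    n_top_genes = 500,
    cut_interval = c(0.8, 0.9),
    target_clusters = NULL,
    top_k_markers = 15,
    fdr_variable_genes = 0.01,
    fdr_coverage = 0.05,
    seed = 1L
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    abort(paste0("Unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  cfg[names(dots)] <- dots
  num <- c("min_genes_per_cell", "min_spike_species",
           "copies_per_cell_threshold", "min_cells_per_gene",
           "fold_enrichment_cutoff", "n_pcs", "n_top_genes",
           "top_k_markers", "fdr_variable_genes", "fdr_coverage")
  for (k in num) {
    if (!is.numeric(cfg[[k]]) || length(cfg[[k]]) != 1L || cfg[[k]] <= 0) {
      abort(paste0("Config key `", k, "` must be a positive number."))
    }
  }
  ci <- cfg$cut_interval
  if (length(ci) != 2L || any(ci <= 0) || any(ci >= 1) || ci[1] > ci[2]) {
    abort("`cut_interval` must be an increasing pair inside (0, 1) in correlation units.")
  }
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param path Path to a YAML file whose keys override the defaults.
#' @export
read_run_config <- function(path) {
  overrides <- yaml::read_yaml(path)
  if (is.null(overrides)) overrides <- list()
  do.call(run_config, overrides)
}
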