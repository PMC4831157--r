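#' Synthetic 92-species spike design
#'
#' A synthetic stand-in for the standard 92-species ERCC panel: molecule
#' counts follow a geometric ladder from 0.5 to 5000 molecules per
#' reaction, spanning four orders of magnitude the way the real panel does
#' after a strong dilution. Species are named `ERCC-00001` ... `ERCC-00092`
#' so the default spike-id prefix recognises them.
#'
#' @param n_species Number of species (default 92, the standard panel size).
#' @return A [spike_design()] tibble.
#' @export
default_spike_design <- function(n_species = 92L) {
  molecules <- 10^seq(log10(0.5), log10(5000), length.out = n_species)
  spike_design(sprintf("ERCC-%05d", seq_len(n_species)), molecules)
}

#' Configuration for the synthetic-data generator
#'
#' Defines the statistical structure the generator plants: a fixed number
#' of cell types with type-specific mRNA markers, lncRNAs active in a small
#' subset of types at high per-cell abundance and silent elsewhere,
#' housekeeping genes expressed in all cells, Poisson-captured spike-ins,
#' and bulk samples formed as weighted mixtures of the cell-type mean
#' profiles. Defaults mirror the data structure of a developing-neocortex
#' single-cell study: 7 cell types totalling 276 cells of unequal cluster
#' sizes, 15 planted markers per type, and lncRNAs restricted to 1 of 7
#' types.
#'
#' @param n_cell_types Number of cell types.
#' @param cells_per_type Integer vector of cells per type (length
#'   `n_cell_types`).
#' @param n_mrna Number of (non-housekeeping) mRNAs; the first
#'   `markers_per_type * n_cell_types` of them are planted type markers.
#' @param n_lncrna Number of lncRNAs, assigned round-robin to active types.
#' @param n_housekeeping Number of housekeeping genes (biotype mRNA,
#'   flagged).
#' @param markers_per_type Planted mRNA markers per type.
#' @param marker_fold Fold-elevation of a marker (or active lncRNA) mean
#'   inside its type relative to `base_mean`.
#' @param lncrna_restriction Fraction of cell types in which each lncRNA is
#'   active (default 1/7: one type).
#' @param lncrna_leak Mean of an "inactive" lncRNA relative to `base_mean`
#'   (default 0: silent outside active types, making planted specificity
#'   unambiguous; raise for robustness checks).
#' @param gene_abundance_spread Log-normal sigma of the per-mRNA abundance
#'   factor. Expressed genes in a tissue span orders of magnitude in
#'   abundance; this heterogeneity is also what identifies the
#'   deconvolution regression (with every gene at one common level the
#'   cell-type profiles are nearly collinear and the intercept absorbs
#'   the signal).
#' @param lncrna_abundance_spread Log-normal sigma of the per-lncRNA
#'   abundance factor, reflecting the wide range of per-cell lncRNA
#'   abundances seen in tissue; 0 makes all active lncRNAs equally
#'   abundant (and the lncRNA-only deconvolution design nearly
#'   unidentifiable).
#' @param base_mean Baseline mean raw counts per gene per cell.
#' @param housekeeping_mean Mean raw counts of housekeeping genes.
#' @param dispersion Negative-binomial dispersion of endogenous genes
#'   (variance = mu + dispersion * mu^2); 0 gives Poisson counts.
#' @param capture_efficiency Fraction of spike molecules converted to
#'   counts (Poisson capture).
#' @param library_size_spread Log-normal sigma of the per-cell scaling
#'   factor.
#' @param n_specimens Source specimens; cells are assigned round-robin
#'   within each type so every type spans several specimens.
#' @param n_bulk Number of bulk samples.
#' @param bulk_weights Cell-type mixture weights for bulk samples: a
#'   `n_cell_types` x `n_bulk` matrix with columns summing to 1, or `NULL`
#'   to use the cell-type proportions implied by `cells_per_type` for every
#'   bulk sample.
#' @param bulk_depth Total fragments per bulk sample.
#' @param seed Integer seed; all sampling is reproducible under it.
#'
#' @return A named list of class `simulation_config`.
#' @export
simulation_config <- function(n_cell_types = 7L,
                              cells_per_type = c(20L, 60L, 30L, 50L, 25L,
                                                 55L, 36L),
                              n_mrna = 1200L,
                              n_lncrna = 140L,
                              n_housekeeping = 50L,
                              markers_per_type = 15L,
                              marker_fold = 10,
                              lncrna_restriction = 1 / 7,
                              lncrna_leak = 0,
                              gene_abundance_spread = 0.8,
                              lncrna_abundance_spread = 0.5,
                              base_mean = 20,
                              housekeeping_mean = 50,
                              dispersion = 0.15,
                              capture_efficiency = 0.1,
                              library_size_spread = 0.3,
                              n_specimens = 3L,
                              n_bulk = 4L,
                              bulk_weights = NULL,
                              bulk_depth = 2e6,
                              seed = 1L) {
  if (length(cells_per_type) != n_cell_types) {
    abort("`cells_per_type` must have one entry per cell type.")
  }
  if (any(cells_per_type < 1)) abort("`cells_per_type` must be positive.")
  for (v in list(n_mrna, n_lncrna, n_housekeeping, markers_per_type,
                 marker_fold, base_mean, housekeeping_mean, bulk_depth)) {
    if (!is.numeric(v) || v <= 0) abort("Count parameters must be positive.")
  }
  if (dispersion < 0) abort("`dispersion` must be non-negative.")
  if (capture_efficiency <= 0 || capture_efficiency > 1) {
    abort("`capture_efficiency` must be in (0, 1].")
  }
  if (lncrna_restriction <= 0 || lncrna_restriction > 1) {
    abort("`lncrna_restriction` must be in (0, 1].")
  }
  if (n_mrna < markers_per_type * n_cell_types) {
    abort("Need at least `markers_per_type * n_cell_types` mRNAs.")
  }
  if (is.null(bulk_weights)) {
    w <- cells_per_type / sum(cells_per_type)
    bulk_weights <- matrix(w, n_cell_types, n_bulk)
  }
  bulk_weights <- as.matrix(bulk_weights)
  if (nrow(bulk_weights) != n_cell_types || ncol(bulk_weights) != n_bulk) {
    abort("`bulk_weights` must be n_cell_types x n_bulk.")
  }
  if (any(bulk_weights < 0) ||
      any(abs(colSums(bulk_weights) - 1) > 1e-12)) {
    abort("Each bulk weight vector must be non-negative and sum to 1.")
  }
  structure(
    list(n_cell_types = as.integer(n_cell_types),
         cells_per_type = as.integer(cells_per_type),
         n_mrna = as.integer(n_mrna), n_lncrna = as.integer(n_lncrna),
         n_housekeeping = as.integer(n_housekeeping),
         markers_per_type = as.integer(markers_per_type),
         marker_fold = marker_fold,
         lncrna_restriction = lncrna_restriction,
         lncrna_leak = lncrna_leak,
         gene_abundance_spread = gene_abundance_spread,
         lncrna_abundance_spread = lncrna_abundance_spread,
         base_mean = base_mean,
         housekeeping_mean = housekeeping_mean, dispersion = dispersion,
         capture_efficiency = capture_efficiency,
         library_size_spread = library_size_spread,
         n_specimens = as.integer(n_specimens),
         n_bulk = as.integer(n_bulk), bulk_weights = bulk_weights,
         bulk_depth = bulk_depth, seed = as.integer(seed)),
    class = "simulation_config"
  )
}

# per-gene per-type programmed means implied by a config (genes x types)
simulation_type_means <- function(config) {
  cfg <- config
  ids <- simulation_gene_ids(cfg)
  G <- length(ids)
  mu <- matrix(cfg$base_mean, G, cfg$n_cell_types,
               dimnames = list(ids, paste0("type_", seq_len(cfg$n_cell_types))))
  # planted mRNA markers: block of markers_per_type per type
  for (t in seq_len(cfg$n_cell_types)) {
    idx <- ((t - 1) * cfg$markers_per_type + 1):(t * cfg$markers_per_type)
    mu[idx, t] <- cfg$base_mean * cfg$marker_fold
  }
  # lncRNAs: active in a consecutive run of types, round-robin start
  n_active <- max(1L, round(cfg$lncrna_restriction * cfg$n_cell_types))
  for (i in seq_len(cfg$n_lncrna)) {
    start <- ((i - 1) %% cfg$n_cell_types) + 1
    active <- ((start - 1 + seq_len(n_active) - 1) %% cfg$n_cell_types) + 1
    r <- cfg$n_mrna + i
    mu[r, ] <- cfg$base_mean * cfg$lncrna_leak
    mu[r, active] <- cfg$base_mean * cfg$marker_fold
  }
  hk <- (cfg$n_mrna + cfg$n_lncrna + 1):G
  mu[hk, ] <- cfg$housekeeping_mean
  mu
}

simulation_gene_ids <- function(cfg) {
  c(sprintf("mRNA_%04d", seq_len(cfg$n_mrna)),
    sprintf("lncRNA_%04d", seq_len(cfg$n_lncrna)),
    sprintf("HK_%04d", seq_len(cfg$n_housekeeping)))
}

simulation_gene_table <- function(cfg) {
  ids <- simulation_gene_ids(cfg)
  biotype <- rep(c("mRNA", "lncRNA", "mRNA"),
                 c(cfg$n_mrna, cfg$n_lncrna, cfg$n_housekeeping))
  hk <- rep(c(FALSE, FALSE, TRUE),
            c(cfg$n_mrna, cfg$n_lncrna, cfg$n_housekeeping))
  lengths <- ifelse(biotype == "lncRNA",
                    200L + (seq_along(ids) * 37L) %% 2800L,
                    500L + (seq_along(ids) * 91L) %% 4500L)
  gene_table(ids, biotype, hk, lengths)
}

#' Simulate spike-in counts
#'
#' Spike species carry no biological variance: per cell, the count of a
#' species is Poisson with mean `molecules x capture_efficiency x cell
#' scale`. The same molecule vector underlies every cell.
#'
#' @param design A [spike_design()].
#' @param n_cells Number of cells.
#' @param capture_efficiency Fraction in (0, 1].
#' @param seed Integer seed.
#' @param cell_scale Optional per-cell scaling factors (default all 1).
#' @param cell_names Optional cell ids.
#' @return An [expression_matrix()] of raw spike counts (spike rows only).
#' @export
simulate_spike_counts <- function(design, n_cells, capture_efficiency,
                                  seed = 1L, cell_scale = NULL,
                                  cell_names = NULL) {
  if (capture_efficiency <= 0 || capture_efficiency > 1) {
    abort("`capture_efficiency` must be in (0, 1].")
  }
  if (is.null(cell_scale)) cell_scale <- rep(1, n_cells)
  stopifnot(length(cell_scale) == n_cells)
  if (is.null(cell_names)) cell_names <- sprintf("cell_%03d", seq_len(n_cells))
  mol <- design$molecules_per_reaction
  counts <- withr::with_seed(seed, {
    vapply(seq_len(n_cells), function(c) {
      rpois(length(mol), mol * capture_efficiency * cell_scale[c])
    }, numeric(length(mol)))
  })
  counts <- matrix(counts, nrow = length(mol),
                   dimnames = list(design$species_id, cell_names))
  expression_matrix(counts, sample_kind = "single_cell", normalized = FALSE,
                    feature_kind = rep("spike", nrow(counts)))
}

#' Simulate a bulk library from cell-type mean profiles
#'
#' Models a bulk tissue library as a weighted average of cell-type
#' expression profiles: the expected contribution of gene g is
#' `sum_t weight_t * type_mean_{g,t}`, and the library is sampled
#' multinomially to the requested depth.
#'
#' @param type_means Gene-by-type matrix of mean expression profiles.
#' @param weights Non-negative mixture vector summing to 1 (one per type).
#' @param depth Total fragments to sample.
#' @param seed Integer seed.
#' @param sample_name Column name of the resulting library.
#' @return An [expression_matrix()] with one raw bulk column.
#' @export
simulate_bulk_from_profiles <- function(type_means, weights, depth,
                                        seed = 1L,
                                        sample_name = "bulk_1") {
  if (any(weights < 0)) abort("Mixture weights must be non-negative.")
  if (abs(sum(weights) - 1) > 1e-8) abort("Mixture weights must sum to 1.")
  if (length(weights) != ncol(type_means)) {
    abort("One weight per cell type is required.")
  }
  expected <- as.numeric(type_means %*% weights)
  if (sum(expected) <= 0) abort("Expected profile is all zero.")
  counts <- withr::with_seed(seed, {
    rmultinom(1, size = depth, prob = expected / sum(expected))
  })
  dimnames(counts) <- list(rownames(type_means), sample_name)
  expression_matrix(counts, sample_kind = "bulk_polyA", normalized = FALSE,
                    feature_kind = rep("gene", nrow(counts)))
}

#' Simulate a complete synthetic dataset
#'
#' Generates single-cell counts (endogenous genes from a negative binomial
#' with planted type structure, spikes from Poisson capture), bulk
#' libraries as weighted mixtures of the type mean profiles, the matching
#' gene annotation and spike design tables, and the ground truth needed to
#' score every downstream stage.
#'
#' @param config A [simulation_config()].
#' @param spikes A [spike_design()]; defaults to the synthetic 92-species
#'   panel.
#' @return A list with elements `single_cells` (raw [expression_matrix()]
#'   including spike rows), `bulk` (raw bulk matrix), `gene_table`,
#'   `spike_design`, and `truth` (cell labels, specimen labels, bulk
#'   weights, planted marker sets, per-lncRNA active types, cell scales,
#'   the config itself).
#' @export
simulate_dataset <- function(config = simulation_config(),
                             spikes = default_spike_design()) {
  cfg <- config
  mu <- simulation_type_means(cfg)
  n_cells <- sum(cfg$cells_per_type)
  type <- rep(seq_len(cfg$n_cell_types), cfg$cells_per_type)
  specimen <- unlist(lapply(cfg$cells_per_type, function(n) {
    ((seq_len(n) - 1) %% cfg$n_specimens) + 1
  }))
  cell_names <- sprintf("cell_%03d", seq_len(n_cells))

  sim <- withr::with_seed(cfg$seed, {
    # per-gene abundance factors: expressed genes span a wide range
    if (cfg$gene_abundance_spread > 0) {
      fac <- exp(rnorm(cfg$n_mrna, 0, cfg$gene_abundance_spread))
      mu[seq_len(cfg$n_mrna), ] <- mu[seq_len(cfg$n_mrna), ] * fac
    }
    if (cfg$n_lncrna > 0 && cfg$lncrna_abundance_spread > 0) {
      lnc_rows <- cfg$n_mrna + seq_len(cfg$n_lncrna)
      fac <- exp(rnorm(cfg$n_lncrna, 0, cfg$lncrna_abundance_spread))
      mu[lnc_rows, ] <- mu[lnc_rows, ] * fac
    }
    s <- exp(rnorm(n_cells, 0, cfg$library_size_spread))
    counts <- matrix(0, nrow(mu), n_cells,
                     dimnames = list(rownames(mu), cell_names))
    for (c in seq_len(n_cells)) {
      m <- mu[, type[c]] * s[c]
      counts[, c] <- if (cfg$dispersion > 0) {
        rnbinom(nrow(mu), mu = m, size = 1 / cfg$dispersion)
      } else {
        rpois(nrow(mu), m)
      }
    }
    list(counts = counts, s = s)
  })

  spike_counts <- simulate_spike_counts(
    spikes, n_cells, cfg$capture_efficiency,
    seed = cfg$seed + 1L, cell_scale = sim$s, cell_names = cell_names)

  all_counts <- rbind(sim$counts, em_values(spike_counts))
  meta <- tibble(cell = cell_names,
                 specimen = sprintf("specimen_%d", .env$specimen),
                 stage = c("GW19.5", "GW20.5", "GW23.5")[
                   ((.env$specimen - 1) %% 3) + 1])
  sc <- expression_matrix(all_counts, sample_kind = "single_cell",
                          normalized = FALSE, meta = meta)

  bulk_cols <- lapply(seq_len(cfg$n_bulk), function(j) {
    em_values(simulate_bulk_from_profiles(
      mu, cfg$bulk_weights[, j], cfg$bulk_depth,
      seed = cfg$seed + 100L + j, sample_name = sprintf("bulk_%d", j)))
  })
  bulk <- expression_matrix(do.call(cbind, bulk_cols),
                            sample_kind = "bulk_polyA", normalized = FALSE)

  marker_sets <- lapply(seq_len(cfg$n_cell_types), function(t) {
    rownames(mu)[((t - 1) * cfg$markers_per_type + 1):
                   (t * cfg$markers_per_type)]
  })
  names(marker_sets) <- colnames(mu)
  n_active <- max(1L, round(cfg$lncrna_restriction * cfg$n_cell_types))
  lnc_active <- lapply(seq_len(cfg$n_lncrna), function(i) {
    start <- ((i - 1) %% cfg$n_cell_types) + 1
    ((start - 1 + seq_len(n_active) - 1) %% cfg$n_cell_types) + 1
  })
  names(lnc_active) <- sprintf("lncRNA_%04d", seq_len(cfg$n_lncrna))

  truth <- list(
    cell_type = setNames(type, cell_names),
    specimen = setNames(specimen, cell_names),
    bulk_weights = cfg$bulk_weights,
    marker_genes = marker_sets,
    lncrna_active_types = lnc_active,
    type_means = mu,
    spike_molecules = setNames(spikes$molecules_per_reaction,
                               spikes$species_id),
    cell_scale = setNames(sim$s, cell_names),
    config = cfg
  )

  list(single_cells = sc, bulk = bulk,
       gene_table = simulation_gene_table(cfg),
       spike_design = spikes, truth = truth)
}
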