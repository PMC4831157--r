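# lncsc

Single-cell analysis of cell-type-specific long non-coding RNA (lncRNA)
expression.

## The problem

In bulk tissue RNA-seq, lncRNAs look lowly expressed relative to mRNAs.
That can mean two very different things: uniformly low expression in
every cell, or high expression confined to a subpopulation whose signal
is diluted by everything else. `lncsc` provides the statistical
machinery to distinguish these at single-cell resolution, for anyone
analysing full-length single-cell RNA-seq of a heterogeneous tissue
with ERCC spike-in controls alongside bulk RNA-seq of the same tissue.

## What it computes

- **Spike-in calibration.** Each cell receives 92 synthetic ERCC RNA
  species at known molecule counts. Pooled OLS of size-factor-normalized
  counts ("ncounts") on molecules turns a molecule floor (2 copies per
  cell) into an ncount expression threshold, and yields per-species
  detection rates.
- **Technical-noise model and variable genes.** A gamma GLM fits the
  spikes' CV² as `a1/μ + a0`; genes whose CV² exceeds that plus a 50%
  biological CV (chi-square test, Benjamini–Hochberg FDR < 0.01) are
  used for clustering.
- **Cell clustering.** Complete-linkage hierarchical clustering of
  cells on 1 − Pearson r over the top 500 PCA-loading genes of
  log2(ncounts + 1), cut statically at r ∈ [0.8, 0.9].
- **Specificity scores.** With p_ij the fraction of cells in cluster j
  expressing gene i above its own 75th percentile and q_ij the fraction
  outside,

      θ_ij = log[ p_ij (1 − q_ij) / (q_ij (1 − p_ij)) ]

  assigns genes to cell types; enrichment e_ij = (mean inside)/(mean
  outside) ranks the top 15 mRNA and lncRNA markers per type.
- **Dilution analysis.** Per-cell lncRNA:mRNA median-expression ratios,
  the in-silico pseudobulk merge, and specific-vs-housekeeping fold
  changes in cells versus bulk quantify how cell-type restriction
  depresses apparent tissue-level abundance.
- **Deconvolution.** Bulk expression is regressed on per-type mean
  profiles, `Y = β0 + β1 X1 + … + βn Xn`; slopes normalized to sum to 1
  estimate cell-type fractions, compared with observed cluster sizes.
- **Co-expression networks** between specific lncRNAs and all expressed
  mRNAs, keeping mRNAs in the top decile of maximum absolute
  correlation.
- **A synthetic-data generator** (`simulate_dataset()`) that plants
  7 cell types, type-restricted lncRNAs, housekeeping genes, Poisson
  spike capture and bulk mixtures with full ground truth, so the whole
  pipeline is testable without any external download.

## Worked example

```r
library(lncsc)

ds   <- simulate_dataset(simulation_config(seed = 1))
qc   <- qc_cells(ds$single_cells)          # >1000 genes, >40 spike species
norm <- compute_size_factors(ds$single_cells)$normalized

cal <- fit_ercc_calibration(norm, ds$spike_design)
cal
#> <calibration_model> ncounts = 0.0212 + 0.09878 * molecules (276 cells)
#>   expression floor: 0.2188 ncounts at 2 copies per cell

nm <- fit_noise_model(norm)
nm
#> <noise_model> CV2_tech(mu) = 1.045 / mu + 0.0001536  (min biological CV2 0.25)

vg <- select_variable_genes(norm, nm)      # 245 variable genes
rk <- pca_rank_genes(norm, vg)
cl <- cluster_cells(norm, rk, target_clusters = 7)
cl
#> <cluster_assignment> 276 cells in 7 clusters (cut height 0.15)
#>   sizes: 20, 60, 30, 50, 25, 55, 36

full <- assign_and_enrich(norm, cl, specificity_odds(norm, cl))
mk   <- select_markers(full, ds$gene_table, k = 15)
head(mk[mk$biotype == "lncRNA", ], 3)
#>   cluster biotype gene_id     enrichment  rank
#> 1       1 lncRNA  lncRNA_0029      6757.     1
#> 2       1 lncRNA  lncRNA_0022      4601.     2
#> 3       1 lncRNA  lncRNA_0015      4243.     3
```

The slope of the calibration line says one spike molecule yields about
0.1 ncounts here (the generator's capture efficiency), and the floor is
the ncount level of a 2-copy gene. The seven recovered clusters match
the planted cell types exactly (the sizes are the planted ones), and
the top cluster-1 lncRNA is ~6800-fold enriched there — type-restricted
lncRNAs produce exactly the extreme enrichments that make them useful
markers. Per-cell lncRNA:mRNA median ratios (median 9.6 in this run)
collapse to 1.28 in the pseudobulk merge: dilution, not low per-cell
expression, explains the bulk picture.

Deconvolving the simulated bulk tissue against the recovered clusters:

```r
filt <- apply_gene_filters(norm, cal)
inp  <- build_deconv_inputs(norm, cl, ds$bulk,
                            passing_genes = filt$gene_id[filt$keep])
glance(fit_deconvolution(inp))
#>   r_squared agreement_r n_types n_genes intercept
#> 1     0.450       0.986       7    1390      7.82
```

The normalized slopes correlate with the observed cluster fractions at
r = 0.99: tissue composition is recoverable from expression alone.

`tidy()`, `glance()` and `autoplot()` methods are provided for the
calibration model, the noise model and the deconvolution result.

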