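make_qc_matrix <- function(n_genes_detected, n_spikes_detected,
                           n_genes = 2000, n_spikes = 92) {
  # "detected" requires count > 1, so detected features get 2 counts
  g <- c(rep(2L, n_genes_detected), rep(0L, n_genes - n_genes_detected))
  s <- c(rep(2L, n_spikes_detected), rep(0L, n_spikes - n_spikes_detected))
  m <- cbind(cellA = c(g, s))
  rownames(m) <- c(sprintf("g%04d", seq_len(n_genes)),
                   sprintf("ERCC-%05d", seq_len(n_spikes)))
  expression_matrix(m)
}

test_that("QC thresholds are strict and the spike criterion can be waived", {
  # exactly 1000 genes is not enough
  expect_false(qc_cells(make_qc_matrix(1000, 50))$pass)
  expect_true(qc_cells(make_qc_matrix(1001, 50))$pass)
  # 39 spikes fail unless the requirement is waived for that cell
  em <- make_qc_matrix(1500, 39)
  expect_false(qc_cells(em, spike_required = TRUE)$pass)
  expect_true(qc_cells(em, spike_required = FALSE)$pass)
  # exactly 40 spikes still fail (strict >)
  expect_false(qc_cells(make_qc_matrix(1500, 40))$pass)
})

test_that("detection requires a count strictly greater than 1", {
  m <- mat(c(1L, 2L), 2, c("g1", "g2"), "cellA")
  m <- cbind(m, cellB = c(0L, 0L))
  qc <- qc_cells(expression_matrix(m, feature_kind = c("gene", "gene")),
                 min_genes = 0, spike_required = FALSE)
  expect_equal(qc$genes_detected, c(1L, 0L))
})

test_that("QC pass set shrinks monotonically as min_genes rises", {
  raw <- default_sim$single_cells
  passes <- vapply(c(200, 600, 1000, 1400),
                   function(k) sum(qc_cells(raw, min_genes = k)$pass),
                   numeric(1))
  expect_true(all(diff(passes) <= 0))
})

test_that("size factors match the median-of-ratios closed forms", {
  # identical cells
  m <- mat(rep(c(4L, 6L, 8L), 2), 3, c("a", "b", "c"), c("x", "y"))
  sf <- compute_size_factors(expression_matrix(m))
  expect_equal(sf$size_factors$gene_size_factor, c(1, 1))
  # cell y = 2 * cell x: factors (1/sqrt(2), sqrt(2)), equal after scaling
  m2 <- cbind(x = c(4L, 6L, 8L), y = c(8L, 12L, 16L))
  rownames(m2) <- c("a", "b", "c")
  sf2 <- compute_size_factors(expression_matrix(m2))
  expect_equal(sf2$size_factors$gene_size_factor,
               c(1 / sqrt(2), sqrt(2)))
  norm <- em_values(sf2$normalized)
  expect_equal(norm[, "x"], norm[, "y"])
})

test_that("normalization is invariant to rescaling one library", {
  raw <- em_values(default_sim$single_cells)[, 1:40]
  em1 <- expression_matrix(raw)
  scaled <- raw
  scaled[, 3] <- scaled[, 3] * 5L
  em2 <- expression_matrix(scaled)
  n1 <- em_values(compute_size_factors(em1)$normalized)
  n2 <- em_values(compute_size_factors(em2)$normalized)
  # matrices agree up to one global constant (the geometric-mean
  # reference absorbs the rescaling), so every ratio statistic is intact
  expect_equal(n1 / n1[1, 1], n2 / n2[1, 1], tolerance = 1e-12)
  # downstream statistic unchanged
  r1 <- lncrna_mrna_ratio(compute_size_factors(em1)$normalized,
                          default_genes)
  r2 <- lncrna_mrna_ratio(compute_size_factors(em2)$normalized,
                          default_genes)
  expect_equal(r1$ratio, r2$ratio, tolerance = 1e-12)
})

test_that("gene and spike size factors are computed independently", {
  sf <- compute_size_factors(default_sim$single_cells)$size_factors
  expect_false(isTRUE(all.equal(sf$gene_size_factor,
                                sf$spike_size_factor)))
  expect_true(all(sf$gene_size_factor > 0))
  expect_true(all(sf$spike_size_factor > 0))
})

test_that("noiseless calibration maps two copies onto the planted threshold", {
  # ncounts = 10.3 * molecules exactly: two copies correspond to 20.6
  design <- default_spike_design()
  ncounts <- outer(design$molecules_per_reaction * 10.3, rep(1, 20))
  dimnames(ncounts) <- list(design$species_id, sprintf("c%d", 1:20))
  em <- expression_matrix(ncounts, normalized = TRUE)
  cal <- fit_ercc_calibration(em, design)
  expect_equal(cal$slope, 10.3, tolerance = 1e-9)
  expect_equal(cal$intercept, 0, tolerance = 1e-6)
  expect_equal(cal$ncount_threshold, 20.6, tolerance = 1e-9)
  # species abundant in every cell are detected in all of them
  expect_equal(max(cal$detection$detection_rate), 1)
  expect_equal(tidy(cal)$estimate, c(0, 10.3), tolerance = 1e-6)
  expect_equal(glance(cal)$n_species, 92)
})

test_that("calibration recovers a planted slope under Poisson capture", {
  # each captured molecule yields ~10.3 counts after amplification, the
  # scale on which a 2-copy floor sits near 20.6 ncounts
  design <- default_spike_design()
  sc <- simulate_spike_counts(design, n_cells = 200,
                              capture_efficiency = 1, seed = 17,
                              cell_scale = rep(10.3, 200))
  em <- expression_matrix(em_values(sc), normalized = TRUE,
                          feature_kind = rep("spike", 92))
  cal <- fit_ercc_calibration(em, design)
  expect_lt(abs(cal$slope / 10.3 - 1), 0.05)
  expect_lt(abs(cal$ncount_threshold / 20.6 - 1), 0.05)
  # detection rises with molecules (up to sampling error at the top)
  det <- cal$detection$detection_rate
  expect_true(all(diff(det) > -0.08))
})

test_that("calibration honours exclusions and degenerate designs fail", {
  design <- default_spike_design()
  sc <- simulate_spike_counts(design, n_cells = 50,
                              capture_efficiency = 0.1, seed = 2)
  em <- expression_matrix(em_values(sc), normalized = TRUE,
                          feature_kind = rep("spike", 92))
  cal <- fit_ercc_calibration(em, design,
                              exclude = "ERCC-00092")
  expect_true(cal$detection$excluded[cal$detection$species_id ==
                                       "ERCC-00092"])
  one <- spike_design("ERCC-00001", 10)
  m1 <- matrix(5, 1, 20, dimnames = list("ERCC-00001", sprintf("c%d", 1:20)))
  expect_error(fit_ercc_calibration(
    expression_matrix(m1, normalized = TRUE), one), "10 spike species")
})

test_that("gene filters implement the threshold, min-cells and bulk rescue rules", {
  model <- list(ncount_threshold = 20.6)
  m <- rbind(
    low = c(19, 19, 19, 19),       # nonzero mean 19 < 20.6: dropped
    rare = c(30, 30, 0, 0),         # detected in 2 < 3 cells
    rescued = c(30, 30, 0, 0),      # same but with bulk evidence
    absent = c(0, 0, 0, 0),         # never detected: always dropped
    good = c(30, 30, 30, 0)         # nonzero mean 30, 3 cells
  )
  colnames(m) <- sprintf("c%d", 1:4)
  em <- expression_matrix(m, normalized = TRUE)
  res <- apply_gene_filters(em, model, min_cells = 3,
                            bulk_expressed = c("rescued", "absent"))
  keep <- setNames(res$keep, res$gene_id)
  expect_false(keep[["low"]])
  expect_false(keep[["rare"]])
  expect_true(keep[["rescued"]])
  expect_false(keep[["absent"]])
  expect_true(keep[["good"]])
})

test_that("detection profile uses a strict floor of 1 ncount", {
  m <- rbind(always = rep(5, 10), boundary = rep(1, 10))
  colnames(m) <- sprintf("c%d", 1:10)
  em <- expression_matrix(m, normalized = TRUE)
  d <- detection_profile(em)
  expect_equal(d$detection_rate[d$gene_id == "always"], 1)
  expect_equal(d$detection_rate[d$gene_id == "boundary"], 0)
})

test_that("housekeeping genes are detected more broadly than lncRNAs", {
  d <- detection_profile(default_norm)
  d <- dplyr::left_join(d, default_genes, by = "gene_id")
  hk <- d$detection_rate[d$is_housekeeping]
  lnc <- d$detection_rate[d$biotype == "lncRNA"]
  expect_gt(median(hk), median(lnc))
  expect_gt(median(hk), 0.9)
})

test_that("TPM normalization matches hand-computed values", {
  gt <- gene_table(c("g1", "g2"), c("mRNA", "mRNA"), c(FALSE, FALSE),
                   c(1000L, 2000L))
  m <- mat(c(10L, 10L), 2, c("g1", "g2"), "s1")
  tpm <- em_values(compute_tpm(expression_matrix(m), gt))
  expect_equal(unname(tpm[, 1]), c(2e6 / 3, 1e6 / 3), tolerance = 1e-8)
  # single expressed gene takes the whole million
  m2 <- mat(c(7L, 0L), 2, c("g1", "g2"), "s1")
  tpm2 <- em_values(compute_tpm(expression_matrix(m2), gt))
  expect_equal(unname(tpm2[, 1]), c(1e6, 0))
  # identity: every column sums to one million
  tpm3 <- compute_tpm(default_sim$bulk, default_genes)
  expect_equal(unname(colSums(em_values(tpm3))), rep(1e6, 4),
               tolerance = 1e-6)
})
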