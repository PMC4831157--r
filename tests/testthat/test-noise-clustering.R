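spike_matrix_with_cv2 <- function(mu, omega, n_cells, seed) {
  # gamma draws hit a prescribed mean/CV2 exactly in expectation
  withr::with_seed(seed, {
    m <- t(vapply(seq_along(mu), function(i) {
      rgamma(n_cells, shape = 1 / omega[i], scale = mu[i] * omega[i])
    }, numeric(n_cells)))
  })
  dimnames(m) <- list(sprintf("ERCC-%05d", seq_along(mu)),
                      sprintf("c%d", seq_len(n_cells)))
  m
}

test_that("noise model recovers planted coefficients", {
  mu <- 10^seq(0, 3, length.out = 92)
  m <- spike_matrix_with_cv2(mu, 5 / mu + 0.1, 300, seed = 11)
  nm <- fit_noise_model(m)
  expect_lt(abs(nm$a1 / 5 - 1), 0.1)
  expect_lt(abs(nm$a0 / 0.1 - 1), 0.1)
  expect_equal(nm$min_biol_cv2, 0.25)
  expect_equal(tidy(nm)$estimate, c(nm$a0, nm$a1))
})

test_that("Poisson spikes give a vanishing asymptotic CV2", {
  mu <- 10^seq(0, 3, length.out = 92)
  m <- withr::with_seed(4, t(vapply(mu, function(x) rpois(300, x),
                                    numeric(300))))
  dimnames(m) <- list(sprintf("ERCC-%05d", 1:92), sprintf("c%d", 1:300))
  nm <- fit_noise_model(m)
  expect_lt(abs(nm$a0), 0.02)
  expect_lt(abs(nm$a1 - 1), 0.15)
})

test_that("a single spike species cannot support a fit", {
  m <- matrix(rpois(50, 20), 1, 50,
              dimnames = list("ERCC-00001", sprintf("c%d", 1:50)))
  expect_error(fit_noise_model(m), "10 spike species")
})

test_that("genes at exactly the null CV2 sit mid-distribution", {
  n_cells <- 200
  mu <- rep(100, 50)
  nm <- structure(list(a1 = 1, a0 = 0.01, min_biol_cv2 = 0.25),
                  class = "noise_model")
  omega <- nm$a1 / mu + nm$a0 + nm$min_biol_cv2
  m <- spike_matrix_with_cv2(mu, omega, n_cells, seed = 7)
  rownames(m) <- sprintf("g%02d", 1:50)
  em <- expression_matrix(m, normalized = TRUE,
                          feature_kind = rep("gene", 50))
  res <- select_variable_genes(em, nm)
  expect_gt(median(res$p_value), 0.3)
  expect_lt(median(res$p_value), 0.7)
  expect_equal(sum(res$selected), 0)
})

test_that("null calibration: technical-only genes are rarely selected", {
  # spikes define the model; genes are then drawn from that same model
  mu_s <- 10^seq(0, 3, length.out = 92)
  nm <- fit_noise_model(spike_matrix_with_cv2(mu_s, 1 / mu_s + 0.02, 200,
                                              seed = 13))
  mu_g <- 10^runif(1000, 0.5, 2.5)
  omega <- nm$a1 / mu_g + max(nm$a0, 0)
  m <- spike_matrix_with_cv2(mu_g, omega, 200, seed = 14)
  rownames(m) <- sprintf("g%04d", seq_along(mu_g))
  em <- expression_matrix(m, normalized = TRUE,
                          feature_kind = rep("gene", length(mu_g)))
  res <- select_variable_genes(em, nm, fdr = 0.01)
  expect_lte(mean(res$selected), 0.02)
})

test_that("strong biological variation is detected with high power", {
  mu_s <- 10^seq(0, 3, length.out = 92)
  nm <- fit_noise_model(spike_matrix_with_cv2(mu_s, 1 / mu_s + 0.02, 200,
                                              seed = 15))
  mu_g <- rep(200, 100)
  omega <- 1 / mu_g + 0.02 + 1.5^2    # biological CV 1.5
  m <- spike_matrix_with_cv2(mu_g, omega, 200, seed = 16)
  rownames(m) <- sprintf("g%03d", 1:100)
  em <- expression_matrix(m, normalized = TRUE,
                          feature_kind = rep("gene", 100))
  res <- select_variable_genes(em, nm, fdr = 0.01)
  expect_gt(mean(res$selected), 0.9)
})

test_that("PCA ranking surfaces discriminating genes and honours contracts", {
  # two groups of cells separated by one gene; others pure noise
  set.seed(21)
  n <- 40
  m <- rbind(
    sep = rep(c(0, 100), each = n / 2),
    matrix(rpois(9 * n, 20), 9))
  rownames(m) <- c("sep", sprintf("noise%d", 1:9))
  colnames(m) <- sprintf("c%d", 1:n)
  m <- rbind(m, flat = rep(7, n))
  em <- expression_matrix(m, normalized = TRUE,
                          feature_kind = rep("gene", nrow(m)))
  rk <- suppressWarnings(pca_rank_genes(em, rownames(m), n_pcs = 2,
                                        n_top = 11))
  expect_equal(rk$gene_id[1], "sep")
  expect_equal(rk$gene_id[nrow(rk)], "flat")   # zero variance ranks last
  expect_equal(nrow(rk), 11)
  rk5 <- suppressWarnings(pca_rank_genes(em, rownames(m), n_top = 5))
  expect_equal(nrow(rk5), 5)
})

test_that("identical cells collapse into one cluster at any positive cut", {
  m <- matrix(rep(c(5, 1, 9, 2, 7), 4), 5,
              dimnames = list(sprintf("g%d", 1:5), sprintf("c%d", 1:4)))
  em <- expression_matrix(m, normalized = TRUE,
                          feature_kind = rep("gene", 5))
  cl <- cluster_cells(em, rownames(m))
  expect_equal(cl$n_clusters, 1)
  # constant profiles are reported, not silently dropped
  m2 <- m
  m2[, 2] <- 3
  expect_error(cluster_cells(expression_matrix(
    m2, normalized = TRUE, feature_kind = rep("gene", 5)), rownames(m2)),
    "Constant expression")
})

test_that("clustering recovers planted types and is order invariant", {
  cfg <- simulation_config(n_cell_types = 3, cells_per_type = rep(25L, 3),
                           n_mrna = 200L, n_lncrna = 30L,
                           n_housekeeping = 10L, seed = 6)
  ds <- simulate_dataset(cfg)
  norm <- compute_size_factors(ds$single_cells)$normalized
  # at 75 cells the gamma GLM may hand over to its least-squares fallback
  nm <- suppressWarnings(fit_noise_model(norm))
  vg <- select_variable_genes(norm, nm)
  rk <- suppressWarnings(pca_rank_genes(norm, vg))
  cl <- cluster_cells(norm, rk, target_clusters = 3)
  expect_equal(mclust::adjustedRandIndex(cl$labels, ds$truth$cell_type), 1)

  # permuting cells and genes leaves memberships unchanged
  v <- em_values(norm)
  perm_cells <- sample(ncol(v))
  perm_genes <- sample(rk$gene_id)
  em2 <- expression_matrix(v[, perm_cells], normalized = TRUE,
                           feature_kind = norm$feature_kind)
  cl2 <- cluster_cells(em2, perm_genes, target_clusters = 3)
  expect_equal(mclust::adjustedRandIndex(cl2$labels[names(cl$labels)],
                                         cl$labels), 1)
})

test_that("lowering the cut height only refines the partition", {
  norm <- default_norm
  nm <- fit_noise_model(norm)
  vg <- select_variable_genes(norm, nm)
  rk <- suppressWarnings(pca_rank_genes(norm, vg))
  m <- em_genes(norm)
  lx <- log2(m[rk$gene_id, ] + 1)
  tree <- hclust(as.dist(1 - cor(lx)), method = "complete")
  coarse <- cutree(tree, h = 0.2)
  fine <- cutree(tree, h = 0.1)
  # nested: every fine cluster lies inside one coarse cluster
  expect_true(all(tapply(coarse, fine,
                         function(x) length(unique(x))) == 1))
  expect_gte(length(unique(fine)), length(unique(coarse)))
})

test_that("an unreachable target cluster count is an error", {
  m <- matrix(rep(c(5, 1, 9, 2, 7), 4), 5,
              dimnames = list(sprintf("g%d", 1:5), sprintf("c%d", 1:4)))
  m <- m + matrix(rpois(20, 1), 5)
  em <- expression_matrix(m, normalized = TRUE,
                          feature_kind = rep("gene", 5))
  expect_error(cluster_cells(em, rownames(m), target_clusters = 4),
               "No cut height")
})

test_that("seven balanced specimens spread across every recovered cluster", {
  cl <- cluster_cells(default_norm,
                      suppressWarnings(pca_rank_genes(
                        default_norm,
                        select_variable_genes(default_norm,
                                              fit_noise_model(default_norm)))),
                      target_clusters = 7)
  specimens <- default_sim$single_cells$meta$specimen[
    match(names(cl$labels), default_sim$single_cells$meta$cell)]
  per_cluster <- tapply(specimens, cl$labels,
                        function(s) length(unique(s)))
  expect_true(all(per_cluster >= 2))
})
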