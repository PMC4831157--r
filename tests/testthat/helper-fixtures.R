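# Shared fixtures, built once per test run.

# small expression matrix with explicit values
small_em <- function(values, ..., normalized = FALSE) {
  expression_matrix(values, normalized = normalized, ...)
}

mat <- function(v, nrow, rn, cn) {
  matrix(v, nrow = nrow, dimnames = list(rn, cn))
}

# the default synthetic dataset used by many property tests
default_sim <- simulate_dataset(simulation_config(seed = 42))
default_norm <- compute_size_factors(default_sim$single_cells)$normalized
default_genes <- default_sim$gene_table

# independent brute-force evaluation of the specificity log-odds on counts
brute_force_theta <- function(expr_row, labels, cluster) {
  tau <- unname(quantile(expr_row, probs = 0.75, type = 7))
  inside <- labels == cluster
  a <- sum(expr_row[inside] > tau)
  b <- sum(inside) - a
  cc <- sum(expr_row[!inside] > tau)
  d <- sum(!inside) - cc
  p <- (a + 0.5) / (a + b + 1)
  q <- (cc + 0.5) / (cc + d + 1)
  log(p * (1 - q) / (q * (1 - p)))
}

# exact two-sided Mann-Whitney p by enumeration of all group splits
brute_force_mwu <- function(a, b) {
  pooled <- c(a, b)
  n <- length(a)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  splits <- utils::combn(length(pooled), n)
  us <- apply(splits, 2, function(idx) {
    sum(r[idx]) - n * (n + 1) / 2
  })
  mu <- n * length(b) / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}

random_specificity_instance <- function(seed) {
  withr::with_seed(seed, {
    n_clusters <- sample(2:4, 1)
    sizes <- sample(2:6, n_clusters, replace = TRUE)
    n_cells <- sum(sizes)
    labels <- rep(seq_len(n_clusters), sizes)
    n_genes <- sample(3:8, 1)
    m <- matrix(rpois(n_genes * n_cells, 3), n_genes,
                dimnames = list(sprintf("g%d", seq_len(n_genes)),
                                sprintf("c%d", seq_len(n_cells))))
    list(em = expression_matrix(m, normalized = TRUE,
                                feature_kind = rep("gene", n_genes)),
         labels = setNames(labels, colnames(m)))
  })
}
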