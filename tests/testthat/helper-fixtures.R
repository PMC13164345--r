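# shared fixtures, built in code and memoised across test files

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

# well-separated Gaussian point clouds in `dims` dimensions
gaussian_clusters <- function(sizes, sep = 10, sd = 0.5, dims = 10, seed = 42) {
  set.seed(seed)
  k <- length(sizes)
  centers <- matrix(stats::rnorm(k * dims), k, dims)
  centers <- centers / sqrt(rowSums(centers^2)) * sep
  x <- do.call(rbind, lapply(seq_len(k), function(c)
    matrix(stats::rnorm(sizes[c] * dims, sd = sd), sizes[c], dims) +
      matrix(centers[c, ], sizes[c], dims, byrow = TRUE)))
  rownames(x) <- sprintf("P%03d", seq_len(nrow(x)))
  attr(x, "labels") <- rep(seq_len(k), sizes)
  x
}

# a small simulated dataset shared by several test files
small_sim <- function() {
  memo("small_sim", {
    cfg <- sim_config(n_genes = 500, controls_per_subgroup = c(30, 30, 30, 36, 60),
                      n_treated = 15, seed = 11)
    list(cfg = cfg, sim = simulate_counts(cfg))
  })
}

# stratify a simulation and annotate its sample table with cluster labels
# and projected PC covariates, as the pipeline does
annotate_samples <- function(sim, k = 5, n_pcs = 15, seed = 3) {
  sf <- estimate_size_factors(sim$counts)
  lm2 <- log_transform(sim$counts, sf)
  veh <- sim$samples$sample_id[sim$samples$treatment == "DMSO"]
  vg <- select_variable_genes(lm2[, veh, drop = FALSE], 0.10)
  emb <- run_pca(lm2[, veh, drop = FALSE], vg, n_pcs = n_pcs)
  sol <- kmeans_cluster(emb$scores, k, seed = seed)
  other <- setdiff(colnames(lm2), veh)
  scores <- rbind(emb$scores,
                  if (length(other)) project_samples(emb, lm2[, other, drop = FALSE]))
  scores <- scores[sim$samples$sample_id, , drop = FALSE]
  s <- sim$samples
  s[paste0("PC", 1:3)] <- scores[, 1:3]
  s$cluster <- NA_integer_
  s$cluster[match(veh, s$sample_id)] <- sol$assignment[veh]
  list(samples = s, embedding = emb, solution = sol)
}

# tiny deterministic count fixture
tiny_counts <- function() {
  m <- matrix(c(10L, 0L, 5L, 3L, 8L, 1L), nrow = 3,
              dimnames = list(c("gA", "gB", "gC"), c("s1", "s2")))
  m
}

# simple two-group NB count generator for DE engine tests
nb_two_group <- function(n_genes, n1, n2, log2fc = 0, alpha = 0.1,
                         mean_log2_range = c(3, 9), seed = 1) {
  set.seed(seed)
  mu <- 2^stats::runif(n_genes, mean_log2_range[1], mean_log2_range[2])
  grp <- rep(c(0, 1), c(n1, n2))
  m <- vapply(grp, function(t)
    stats::rnbinom(n_genes, mu = mu * 2^(t * log2fc), size = 1 / alpha),
    numeric(n_genes))
  storage.mode(m) <- "integer"
  dimnames(m) <- list(sprintf("G%04d", seq_len(n_genes)),
                      sprintf("S%03d", seq_len(n1 + n2)))
  samples <- data.frame(sample_id = colnames(m),
                        treatment = rep(c("DMSO", "drug"), c(n1, n2)),
                        stringsAsFactors = FALSE)
  list(counts = m, samples = samples, mu = mu)
}

# adjusted Rand index between two labelings (independent of any package)
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  exp_idx <- si * sj / n2
  (sij - exp_idx) / ((si + sj) / 2 - exp_idx)
}
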