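test_that("variable-gene selection ranks by variance with lexicographic ties", {
  m <- matrix(5, 10, 4, dimnames = list(sprintf("g%02d", 1:10), sprintf("s%d", 1:4)))
  m["g04", ] <- c(0, 10, 0, 10)
  expect_equal(select_variable_genes(m, 0.1), "g04")
  expect_setequal(select_variable_genes(m, 1.0), rownames(m))
  # two genes tied at the top: lexicographically smaller id wins
  m["g09", ] <- c(0, 10, 0, 10)
  m["g02", ] <- c(10, 0, 10, 0)
  expect_equal(select_variable_genes(m, 0.1), "g02")
  expect_error(select_variable_genes(matrix(1, 10, 3,
    dimnames = list(letters[1:10], c("a", "b", "c")))), "zero variance")
  expect_error(select_variable_genes(m, 0), "fraction")
})

test_that("PCA explains rank-1 data with one component and reconstructs data", {
  # samples on a line in gene space
  t_ <- seq(-2, 2, length.out = 12)
  m <- rbind(g1 = 3 * t_, g2 = -1 * t_, g3 = 0.5 * t_ + 4)
  colnames(m) <- sprintf("s%02d", 1:12)
  emb <- run_pca(m, n_pcs = 2)
  expect_equal(emb$var_explained[1], 1.0, tolerance = 1e-12)

  set.seed(14)
  r <- matrix(rnorm(30 * 9), 30, 9,
              dimnames = list(sprintf("g%02d", 1:30), sprintf("s%d", 1:9)))
  emb <- run_pca(r, n_pcs = 8)
  expect_true(all(diff(emb$var_explained) <= 1e-12))
  expect_equal(sum(emb$var_explained_all), 1, tolerance = 1e-9)
  # full-rank reconstruction: scores %*% t(loadings) gives centered data
  centered <- t(r) - matrix(emb$center, 9, 30, byrow = TRUE)
  expect_equal(emb$scores %*% t(emb$loadings), centered, tolerance = 1e-8)
  expect_error(run_pca(r, n_pcs = 20), "rank bound")
})

test_that("projection reproduces training scores and respects the subspace", {
  set.seed(3)
  m <- matrix(rnorm(40 * 20), 40, 20,
              dimnames = list(sprintf("g%02d", 1:40), sprintf("s%02d", 1:20)))
  vg <- sprintf("g%02d", 1:25)
  emb <- run_pca(m, variable_genes = vg, n_pcs = 5)
  proj <- project_samples(emb, m[, 3, drop = FALSE])
  expect_equal(proj[1, ], emb$scores[3, ], tolerance = 1e-8)
  # the training mean profile maps to the origin
  mean_prof <- matrix(rowMeans(m), 40, 1, dimnames = list(rownames(m), "mean"))
  expect_equal(as.numeric(project_samples(emb, mean_prof)), rep(0, 5),
               tolerance = 1e-8)
  # samples differing only outside the variable genes project identically
  a <- m[, 5, drop = FALSE]; b <- a
  b[setdiff(rownames(m), vg), ] <- b[setdiff(rownames(m), vg), ] + 100
  colnames(b) <- "alt"
  expect_equal(as.numeric(project_samples(emb, a)),
               as.numeric(project_samples(emb, b)), tolerance = 1e-10)
  expect_error(project_samples(emb, m[1:10, , drop = FALSE]), "lack variable genes")
})

test_that("k-means recovers planted pairs with a recomputable WCSS", {
  x <- rbind(c(0, 0), c(0, 1), c(10, 0), c(10, 1))
  rownames(x) <- c("a", "b", "c", "d")
  sol <- kmeans_cluster(x, 2, seed = 1)
  expect_equal(sol$assignment[["a"]], sol$assignment[["b"]])
  expect_equal(sol$assignment[["c"]], sol$assignment[["d"]])
  expect_false(sol$assignment[["a"]] == sol$assignment[["c"]])
  # each pair deviates 0.5 from its center in one coordinate: 4 * 0.25
  expect_equal(sol$wcss, 1.0)

  sol1 <- kmeans_cluster(x, 1, seed = 1)
  expect_equal(sol1$wcss, sum(scale(x, scale = FALSE)^2))

  set.seed(8)
  y <- matrix(rnorm(60 * 3), 60, 3, dimnames = list(sprintf("p%02d", 1:60), NULL))
  expect_identical(kmeans_cluster(y, 4, seed = 7), kmeans_cluster(y, 4, seed = 7))
  expect_error(kmeans_cluster(y, 0, seed = 1), "k must lie")
})

test_that("silhouette matches the direct four-point computation", {
  # two clusters of 2 points on a line, within-distance 1, centers 10 apart
  x <- matrix(c(0, 1, 10, 11), 4, 1, dimnames = list(letters[1:4], NULL))
  sol <- kmeans_cluster(x, 2, seed = 1)
  ii <- internal_indices(x, sol)
  # hand evaluation: s = (b - a)/max(a, b) per point
  s_hand <- c((mean(c(10, 11)) - 1) / mean(c(10, 11)),
              (mean(c(9, 10)) - 1) / mean(c(9, 10)),
              (mean(c(10, 9)) - 1) / mean(c(10, 9)),
              (mean(c(11, 10)) - 1) / mean(c(11, 10)))
  expect_equal(ii$mean_silhouette, mean(s_hand), tolerance = 1e-12)
  expect_equal(ii$mean_silhouette, 0.900, tolerance = 1e-3)
  expect_equal(ii$wcss, sol$wcss, tolerance = 1e-12)

  # duplicate points forming perfect clusters: a = 0 gives s = 1
  d <- rbind(matrix(0, 3, 2), matrix(5, 3, 2))
  rownames(d) <- sprintf("p%d", 1:6)
  sol_d <- kmeans_cluster(d, 2, seed = 2)
  expect_equal(internal_indices(d, sol_d)$mean_silhouette, 1)
})

test_that("choose_k applies the prediction-strength rule with PAC tie-break", {
  rep_ <- data.frame(k = c(3, 4, 5),
                     wcss = c(30, 20, 10), mean_silhouette = c(0.4, 0.5, 0.45),
                     mean_bootstrap_jaccard = c(0.8, 0.9, 0.85),
                     prediction_strength = c(0.7, 0.9, 0.7),
                     pac = c(0.2, 0.1, 0.0),
                     min_cluster_size = c(20, 20, 20),
                     admissible = c(TRUE, TRUE, TRUE))
  class(rep_) <- c("stability_report", "data.frame")
  expect_equal(suppressMessages(choose_k(rep_)), 4L)
  # tie on prediction strength: lower PAC wins
  rep_$prediction_strength <- c(0.7, 0.9, 0.9)
  expect_equal(suppressMessages(choose_k(rep_)), 5L)
  # fixed mode must be admissible
  expect_equal(choose_k(rep_, mode = "fixed", k_fixed = 3), 3L)
  rep_$admissible[1] <- FALSE
  expect_error(choose_k(rep_, mode = "fixed", k_fixed = 3), "not admissible")
  rep_$admissible[] <- FALSE
  expect_error(choose_k(rep_), "no admissible k")
})
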