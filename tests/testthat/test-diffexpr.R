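test_that("median-of-ratios size factors match hand computations", {
  m <- matrix(c(4L, 10L, 20L, 4L, 10L, 20L), 3, 2,
              dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  expect_equal(unname(estimate_size_factors(m)), c(1, 1))

  m2 <- m; m2[, 2] <- 2L * m[, 1]
  # geometric mean per gene = sqrt(2) * col1, so ratios are 1/sqrt(2), sqrt(2)
  expect_equal(unname(estimate_size_factors(m2)), c(1 / sqrt(2), sqrt(2)),
               tolerance = 1e-12)

  set.seed(2)
  m3 <- matrix(rpois(50 * 4, 30) + 1L, 50, 4,
               dimnames = list(sprintf("g%02d", 1:50), sprintf("s%d", 1:4)))
  perm <- c(3, 1, 4, 2)
  expect_equal(unname(estimate_size_factors(m3[, perm])),
               unname(estimate_size_factors(m3)[perm]))

  z <- matrix(c(0L, 1L, 1L, 0L), 2, 2,
              dimnames = list(c("a", "b"), c("x", "y")))
  expect_error(estimate_size_factors(z), "positive counts in all samples")
})

test_that("dispersion estimation recovers Poisson and NB regimes", {
  X <- cbind(1, rep(0:1, c(50, 50)))
  fx <- nb_two_group(300, 50, 50, alpha = 0.2, seed = 2)
  d <- estimate_dispersions(fx$counts, estimate_size_factors(fx$counts), X)
  expect_gt(median(d$alpha), 0.1)
  expect_lt(median(d$alpha), 0.3)

  fxp <- nb_two_group(300, 50, 50, alpha = 1e-9, seed = 3)
  dp <- estimate_dispersions(fxp$counts, estimate_size_factors(fxp$counts), X)
  expect_lt(median(dp$alpha), 0.01)

  # constant-zero gene flagged unusable
  fx$counts[1, ] <- 0L
  d0 <- estimate_dispersions(fx$counts, estimate_size_factors(fx$counts), X)
  expect_false(d0$usable[1])
  expect_true(all(d0$alpha[d0$usable] >= 1e-8 & d0$alpha[d0$usable] <= 10))
})

test_that("the NB GLM is offset-invariant and recovers planted effects", {
  fx <- nb_two_group(60, 30, 30, alpha = 0.1, seed = 7)
  X <- cbind(`(Intercept)` = 1, treatment = rep(0:1, c(30, 30)))
  sf <- rep(1, 60)
  y <- fx$counts[5, ]
  f1 <- fit_nb_glm(y, X, sf, alpha = 0.1)
  expect_true(f1$converged)
  # rescaling one sample's counts together with its size factor leaves the
  # mean model unchanged; the NB likelihood is not exactly scale-invariant
  # (a doubled count carries more information at fixed dispersion), so the
  # fit is equal only up to that small information effect
  y2 <- y; y2[12] <- 2L * y[12]
  sf2 <- sf; sf2[12] <- 2
  f2 <- fit_nb_glm(y2, X, sf2, alpha = 0.1)
  expect_equal(f1$coef_log2, f2$coef_log2, tolerance = 0.01)
  expect_equal(f1$se_log2, f2$se_log2, tolerance = 0.01)
  expect_error(fit_nb_glm(y, X, sf, alpha = 0), "positive")

  # sign-balanced planted log2fc = +/-1 on a 10% minority: median estimates
  # within 0.1 of the truth in both directions
  set.seed(1)
  fx2 <- nb_two_group(800, 50, 50, log2fc = 0, alpha = 0.1, seed = 6)
  up <- sample(800, 40); dn <- sample(setdiff(1:800, up), 40)
  fx2$counts[up, 51:100] <-
    matrix(rnbinom(40 * 50, mu = 2 * fx2$mu[up], size = 10), 40, 50)
  fx2$counts[dn, 51:100] <-
    matrix(rnbinom(40 * 50, mu = 0.5 * fx2$mu[dn], size = 10), 40, 50)
  de <- external_de(fx2$counts, fx2$samples, "drug")
  expect_lt(abs(median(de$log2fc[up]) - 1), 0.1)
  expect_lt(abs(median(de$log2fc[dn]) + 1), 0.1)
})

test_that("null Wald p-values are approximately uniform", {
  fx <- nb_two_group(2000, 60, 20, log2fc = 0, alpha = 0.1, seed = 4)
  de <- external_de(fx$counts, fx$samples, "drug")
  expect_gt(stats::ks.test(de$p, "punif")$p.value, 0.01)
  frac <- mean(de$p < 0.05, na.rm = TRUE)
  expect_gt(frac, 0.03); expect_lt(frac, 0.07)
})

test_that("BH adjustment matches the exhaustive step-up oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.03), 0.03)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  # NA passthrough: excluded from m, missing out
  expect_equal(bh_adjust(c(0.02, NA, 0.04)), c(0.04, NA, 0.04))

  # independent oracle: direct step-up definition
  bh_oracle <- function(p) {
    m <- length(p); o <- order(p); out <- numeric(m)
    prev <- 1
    for (i in m:1) {
      prev <- min(prev, m * p[o[i]] / i)
      out[o[i]] <- prev
    }
    out
  }
  set.seed(12)
  for (rep_ in 1:5) {
    p <- runif(6)
    for (perm in list(1:6, 6:1, sample(6))) {
      expect_equal(bh_adjust(p[perm]), bh_oracle(p[perm]), tolerance = 1e-12)
    }
  }
})

test_that("contrasts restrict to the cluster, skip underpowered ones, and are scale-equivariant", {
  fx <- small_sim()
  ann <- annotate_samples(fx$sim)
  de <- run_contrast(fx$sim$counts, ann$samples, cluster_id = 1,
                     drug_label = "drug")
  expect_true(all(c("gene", "base_mean", "log2fc", "se", "p", "fdr",
                    "contrast_id", "converged") %in% names(de)))
  expect_true(all(de$fdr >= 0 & de$fdr <= 1, na.rm = TRUE))
  expect_identical(de, run_contrast(fx$sim$counts, ann$samples, 1, "drug"))

  # one treated sample: skipped with a message, not an error
  s1 <- ann$samples
  drop <- s1$sample_id[s1$treatment == "drug"][-1]
  s1 <- s1[!s1$sample_id %in% drop, ]
  expect_message(
    out <- run_contrast(fx$sim$counts[, s1$sample_id], s1, 1, "drug"),
    "skipped")
  expect_null(out)

  # doubling sequencing depth (all counts; size factors re-estimated double
  # automatically): effect estimates are preserved up to the genuine
  # information gain of deeper counts at NB dispersion > 0
  de2 <- run_contrast(fx$sim$counts * 2L, ann$samples, 1, "drug")
  ok <- de$converged & de2$converged
  expect_gt(cor(de$log2fc[ok], de2$log2fc[ok]), 0.99)
  expect_lt(median(abs(de$log2fc[ok] - de2$log2fc[ok])), 0.02)
})

test_that("planted cluster effects are recovered with high recall", {
  cfg <- sim_config(n_genes = 400, n_subgroups = 1, controls_per_subgroup = 60,
                    n_treated = 20, frac_de = 0.1, effect_mean_log2 = 2,
                    subgroup_shift_sd = 0, dispersion_meanlog = log(0.1),
                    dispersion_sdlog = 0, seed = 15)
  sim <- simulate_counts(cfg)
  de <- external_de(sim$counts, sim$samples, "drug")
  sig <- de$gene[!is.na(de$fdr) & de$fdr < 0.05]
  truth <- names(sim$truth$is_de)[sim$truth$is_de]
  expect_gt(mean(truth %in% sig), 0.8)
})
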