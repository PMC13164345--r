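test_that("fixed-effect pooling matches closed forms and scaling laws", {
  fe <- fixed_effect_pool(c(1, 1), c(0.5, 0.5))
  expect_equal(fe$b, 1.0, tolerance = 1e-12)
  expect_equal(fe$se, sqrt(1 / 8), tolerance = 1e-12)  # 0.35355...

  one <- fixed_effect_pool(0.7, 0.2)
  expect_equal(one$b, 0.7); expect_equal(one$se, 0.2)

  set.seed(3)
  b <- rnorm(4); se <- runif(4, 0.1, 1)
  f1 <- fixed_effect_pool(b, se)
  f2 <- fixed_effect_pool(b, 3 * se)
  expect_equal(f2$b, f1$b, tolerance = 1e-12)
  expect_equal(f2$se, 3 * f1$se, tolerance = 1e-12)
  expect_equal(f2$z, f1$z / 3, tolerance = 1e-12)
  expect_error(fixed_effect_pool(c(1, 2), c(0.5, 0)), "positive")
  expect_error(fixed_effect_pool(numeric(0), numeric(0)), "at least one")
})

test_that("heterogeneity matches the hand-computed Q and clamps I2 at zero", {
  # w = 4 each, pooled 2.0: Q = 4*1 + 4*1 = 8; I2 = (8-1)/8 = 87.5%
  pooled <- fixed_effect_pool(c(1, 3), c(0.5, 0.5))$b
  het <- heterogeneity(c(1, 3), c(0.5, 0.5), pooled)
  expect_equal(het$Q, 8.0, tolerance = 1e-12)
  expect_equal(het$i2_percent, 87.5, tolerance = 1e-12)

  het0 <- heterogeneity(c(2, 2, 2), c(0.3, 0.3, 0.3), 2)
  expect_equal(het0$Q, 0); expect_equal(het0$i2_percent, 0)

  # Q below n-1 clamps to zero
  hetc <- heterogeneity(c(1.0, 1.01), c(1, 1), 1.005)
  expect_lt(hetc$Q, 1)
  expect_equal(hetc$i2_percent, 0)
  expect_error(heterogeneity(1, 0.5, 1), ">= 2")
})

test_that("pooling agrees with an independent formula implementation and metafor", {
  ivw_oracle <- function(b, se) {
    # independent two-pass implementation of the same closed forms
    w <- 1 / se^2
    mu <- sum(b * w) / sum(w)
    list(b = mu, se = 1 / sqrt(sum(w)),
         Q = sum(w * (b - mu)^2))
  }
  set.seed(9)
  for (i in 1:200) {
    n <- sample(2:8, 1)
    b <- rnorm(n, 0, 2); se <- runif(n, 0.05, 2)
    fe <- fixed_effect_pool(b, se)
    or_ <- ivw_oracle(b, se)
    expect_equal(fe$b, or_$b, tolerance = 1e-12)
    expect_equal(fe$se, or_$se, tolerance = 1e-12)
    expect_equal(heterogeneity(b, se, fe$b)$Q, or_$Q, tolerance = 1e-12)
  }
  skip_if_not_installed("metafor")
  set.seed(10)
  for (i in 1:10) {
    b <- rnorm(5); se <- runif(5, 0.1, 1)
    fe <- fixed_effect_pool(b, se)
    rma <- metafor::rma(yi = b, sei = se, method = "FE")
    expect_equal(fe$b, as.numeric(rma$beta), tolerance = 1e-8)
    expect_equal(fe$se, rma$se, tolerance = 1e-8)
    expect_equal(fe$p, rma$pval, tolerance = 1e-8)
    expect_equal(heterogeneity(b, se, fe$b)$Q, rma$QE, tolerance = 1e-8)
  }
})

make_table <- function(genes, log2fc, se, fdr, id) {
  data.frame(gene = genes, base_mean = 10, log2fc = log2fc, se = se,
             p = 2 * pnorm(-abs(log2fc / se)), fdr = fdr,
             contrast_id = id, converged = TRUE, stringsAsFactors = FALSE)
}

test_that("retention criteria are applied literally, jointly", {
  crit <- meta_criteria()
  # 5 consistent contrasts, low I2, tiny p: retained
  t5 <- lapply(1:5, function(i)
    make_table(c("g1", "g2"), c(1, 0.02), c(0.1, 0.5), c(0.01, 0.9),
               paste0("c", i)))
  meta <- run_meta(t5, crit)
  g1 <- meta[meta$gene == "g1", ]
  expect_true(g1$retained)
  expect_equal(g1$n_contrasts, 5L)
  expect_equal(g1$class, "meta-overlapping")

  # 3 contrasts, all consistent: criterion 2 (>= 4) fails as written
  t3 <- t5[1:3]
  m3 <- run_meta(t3, crit)
  expect_false(m3[m3$gene == "g1", "retained"])
  expect_true(m3[m3$gene == "g1", "pass_min_contrasts"])
  expect_false(m3[m3$gene == "g1", "pass_sign_consistency"])
  # the relaxation flag turns criterion 2 into min(4, available)
  m3r <- run_meta(t3, meta_criteria(relax_sign_to_available = TRUE))
  expect_true(m3r[m3r$gene == "g1", "retained"])

  # high heterogeneity blocks retention
  th <- lapply(1:5, function(i)
    make_table("g1", c(1, 3, 1, 3, 1)[i], 0.2, 0.01, paste0("c", i)))
  mh <- run_meta(th, crit)
  expect_gt(mh$i2_percent, 50)
  expect_false(mh$retained)
})

test_that("meta-only classification separates pooled-only discoveries", {
  retained <- c(g1 = TRUE, g2 = TRUE, g3 = FALSE)
  sets <- list(c("g2", "g3"), character(0))
  cls <- classify_meta_degs(retained, sets)
  expect_equal(unname(cls), c("meta-only", "meta-overlapping", "not-retained"))
})

test_that("run_meta aligns genes, is order-invariant, and bounds pooled SE", {
  ta <- make_table(c("g1", "g2", "g3"), c(1, -1, 0.5), c(0.2, 0.3, 0.4),
                   c(0.01, 0.2, 0.5), "cA")
  tb <- make_table(c("g2", "g3", "g4"), c(-1.2, 0.6, 2), c(0.25, 0.5, 0.3),
                   c(0.01, 0.6, 0.01), "cB")
  tc_ <- make_table(c("g1", "g3"), c(0.9, 0.4), c(0.3, 0.2),
                    c(0.04, 0.9), "cC")
  m1 <- run_meta(list(ta, tb, tc_))
  m2 <- run_meta(list(tc_, ta, tb))
  expect_identical(as.data.frame(m1), as.data.frame(m2))
  expect_equal(m1$gene, c("g1", "g2", "g3", "g4"))
  # g4 observed once: emitted with flags, not dropped
  g4 <- m1[m1$gene == "g4", ]
  expect_equal(g4$n_contrasts, 1L)
  expect_false(g4$pass_min_contrasts)
  expect_true(is.na(g4$i2_percent))
  expect_false(g4$retained)
  # pooled SE never exceeds any contributing SE
  for (g in c("g1", "g2", "g3")) {
    ses <- c(ta$se[ta$gene == g], tb$se[tb$gene == g], tc_$se[tc_$gene == g])
    expect_lte(m1$pooled_se[m1$gene == g], min(ses))
  }
  expect_error(run_meta(list(ta)), ">= 2 contrast tables")
})

test_that("zero estimates count as sign-inconsistent", {
  tz <- lapply(1:4, function(i)
    make_table("g1", c(1, 1, 0, 1)[i], 0.2, 0.01, paste0("c", i)))
  mz <- run_meta(tz)
  expect_equal(mz$n_sign_consistent, 3L)
  expect_false(mz$pass_sign_consistency)
})
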