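---
title: "Stratified-control meta-analysis of transcriptomic drug response"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stratified-control meta-analysis of transcriptomic drug response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Large drug-perturbation RNA-seq screens often pair a small treated group
(~20 samples) with a vehicle (DMSO) control pool more than twenty times
larger, assembled across many cell lines or batches. The control pool is
then not one population: principal component analysis typically reveals
several latent transcriptional subgroups tracking cell-line identity and
baseline state. Comparing the treated samples against the pooled controls
mixes the drug effect with whatever subgroup composition the pool happens
to have; applying a single linear batch correction (ComBat-style) risks
removing biology that is entangled with that structure.

`stratmeta` implements the alternative this package is built around:
*stratify* the controls into transcriptionally coherent subgroups, estimate
the drug effect against each subgroup separately, and *pool* the
per-subgroup estimates with an inverse-variance fixed-effect meta-analysis
under explicit retention criteria. A synthetic-data generator with known
ground truth makes every stage testable without any external download.

## Control stratification

Stratification works on `log2(count / size factor + 1)` values
(median-of-ratios size factors). The top 10% most variable genes (variance
of log-expression across the vehicle samples; ties broken by gene id) define
the embedding subspace; PCA retains the first 20 components by default.
Genes are centered but *not* scaled to unit variance: variance-based gene
selection deliberately privileges high-variance genes, and unit scaling
would undo that choice. `run_pca(scale_genes = TRUE)` switches the behavior
for users who prefer correlation-PCA.

K-means runs in the PC space with k-means++ seeding, Lloyd iterations, and
25 restarts, keeping the lowest within-cluster sum of squares; all
randomness flows from one integer seed. Treated samples are **projected**
onto the control embedding (training centering and loadings) and never
influence it.

The number of clusters is evaluated with:

* **WCSS** and **mean silhouette width** (Euclidean distances in PC space;
  a singleton cluster's point gets silhouette 0; a point with zero distance
  to its own cluster gets 1 unless the neighboring distance is also 0);
* **bootstrap Jaccard** stability (`B = 200` resamples; per reference
  cluster, the best-matching Jaccard over the distinct samples present in
  the resample, averaged over resamples, then over clusters);
* **prediction strength** (100 random half-splits, both fold directions;
  minimum over test clusters of size ≥ 2 of the fraction of point pairs
  co-assigned by the training-centroid classifier; `k = 1` is exactly 1);
* **PAC**, the proportion of ambiguous clustering from consensus
  clustering (80% subsampling, 200 iterations; consensus entries strictly
  between 0.1 and 0.9 count as ambiguous; the thresholds are the common
  convention and are configurable; pairs never co-sampled are excluded with
  a warning).

A candidate `k` is *admissible* only if its smallest cluster has at least
15 samples — small strata cannot support a within-stratum contrast.
`choose_k(mode = "fixed")` reproduces an analyst's choice after checking
admissibility; `mode = "auto"` is an explicit stand-in for that judgment:
maximize prediction strength among admissible `k`, break ties by lower PAC,
then by smaller `k`.

One behavior worth knowing: PAC near 1 requires the *base clusterer* to be
unstable on the data. K-means on structureless data still splits along a
stable principal direction, so PAC on uniform noise is mild (~0.1), not
near 1. The discriminating signal is the ordering — PAC is 0 on cleanly
separated structure, larger on noise, and larger at the wrong `k` than at
the true `k` — and that ordering is what the test suite asserts.

## Per-stratum differential expression

Within each stratum, the drug samples are compared against that stratum's
vehicle samples with a negative-binomial generalized linear model on raw
counts:

* mean model `log mu = log(sf) + X b` with design
  `~ PC1 + PC2 + PC3 + treatment` (vehicle reference); the PC covariates
  are the *global* control-embedding scores, projected for treated samples,
  and absorb residual within-stratum structure. We deliberately do not
  re-compute PCs within each stratum: that would give each contrast
  covariates with a different meaning and break the like-for-like pooling
  of the treatment coefficients.
* variance `mu + alpha * mu^2` — the single dispersion convention used
  package-wide, including the generator;
* per-gene dispersion by Cox–Reid adjusted profile likelihood on
  `log(alpha)` in `[1e-8, 10]`, with Poisson-fitted means, a log-linear
  mean–dispersion trend across genes, and fixed-weight (0.5) shrinkage of
  the gene estimate toward the trend on the log scale. This is a simplified
  stand-in for DESeq2's empirical-Bayes machinery, validated by parameter
  recovery (Poisson data gives estimates near the floor; alpha = 0.2 data
  is recovered within [0.1, 0.3]) rather than by matching any external
  implementation bit-for-bit. Genes whose optimization fails fall back to a
  flagged method-of-moments estimate.
* fitting by Fisher scoring (IRLS) with relative tolerance 1e-8, at most
  100 iterations; coefficient covariance from the expected information;
  treatment effects reported in log2 units; Wald `z = log2FC / se` with
  two-sided normal p-values; Benjamini–Hochberg adjustment across converged
  genes. No independent filtering, no fold-change shrinkage, no outlier
  replacement, and no |log2FC| threshold at the testing step.

Contrasts with fewer than two vehicle or two treated samples are skipped
with a logged reason rather than aborting — a stratum contributing no
contrast simply drops out of pooling.

Exact scale invariance does not hold for a true NB likelihood: doubling a
count together with its size factor leaves the mean model unchanged but
increases the Poisson-level information at fixed dispersion, so estimates
move by ~1e-2, not 0. The tests assert this property at its actual
magnitude.

## Fixed-effect pooling and retention

Per gene, available stratum estimates `b_i ± se_i` are pooled with inverse
-variance weights `w_i = se_i^-2`:

```
b_pooled = sum(w b) / sum(w),  se_pooled = sum(w)^(-1/2),
Q = sum(w (b - b_pooled)^2),   I^2 = max(0, (Q - (n-1)) / Q) * 100.
```

A gene is retained as a **meta-DEG** iff it has (1) estimates in ≥ 2
contrasts, (2) ≥ 4 available estimates sharing the pooled sign (exact
zeros count as inconsistent — the sign is compared to the pooled estimate
because no external reference direction exists), (3) `I^2 < 50%`, and (4)
two-sided meta `p < 0.05`. Criteria (1) and (2) are applied literally, so
the sign rule dominates for genes measured in 2–3 strata;
`meta_criteria(relax_sign_to_available = TRUE)` relaxes (2) to
`min(4, n_available)` for sensitivity analyses. Retained genes significant
in no single-stratum list (FDR < 0.05) are labeled **meta-only**; genes
with one estimate are emitted with their flags, never silently dropped.

### The independence caveat

Every stratum contrast uses the *same* treated samples — only the control
side changes. The per-stratum estimates therefore share the treated-arm
sampling noise and are strongly positively correlated, while fixed-effect
pooling weights them as if independent. Two consequences, both computed by
the package's own acceptance script on synthetic data:

* under a global null the retained fraction is on the order of a few
  percent, not the nominal level — the pooled SE is understated;
* for true effects, subgroup baseline offsets leak into the treatment
  coefficient differently per contrast (three PC covariates cannot span
  the between-subgroup space of five strata, and they are fitted from the
  narrow PC range of one stratum's controls), inflating `I^2` and blocking
  retention of genuinely regulated genes.

The retained set should therefore be read as a *prioritization* of
reproducibly concordant genes, not as an FDR-controlled discovery set.
This is a property of the procedure itself, reproduced faithfully here;
the cross-dataset validation step exists precisely to compensate.

## Signatures, networks, enrichment

Cross-stratum concordance is summarized by pairwise Pearson correlations
of genome-wide log2 fold-change vectors (pairwise-complete genes; 95% CI by
Fisher z), a complete weighted graph with edge weight `|r|` and shortest
-path betweenness on the distance `1 - |r|` (the distance transform is
configurable), the intersection of all per-stratum DEG lists with sign
patterns, cross-dataset overlap (retained ∩ externally significant,
partitioned by sign agreement), and drug-specific set differences guarded
by a criteria-equality check.

Over-representation uses the upper-tail hypergeometric test against a
user-supplied GMT collection, with the universe defaulting to the genes
tested in the source analysis (the conservative convention; configurable).
Up- and downregulated queries are tested separately; the downregulated
meta-signature additionally applies a `log2FC < -1` magnitude filter.
Comparator specificity keeps terms significant for the primary drug
(FDR < 0.05, overlap ≥ 10) and not significant for the comparator, with an
optional looser annotation threshold reported as a column only.

## The synthetic generator

`simulate_counts()` emulates the structure of a large imbalanced
kinase-inhibitor screen: 464 vehicle controls hiding five latent subgroups
(sizes 60, 60, 60, 72, 212 — spanning 60–212 with median 60), 20 treated
samples apportioned to subgroups proportionally (largest-remainder), 2500
genes by default. Counts are NB with gene-wise dispersions
`LogNormal(-2.3, 0.6)`, baselines uniform on log2 `[0, 10]` (means
~1–1000), log-normal library sizes (sdlog 0.2), and per-gene subgroup
baseline offsets `N(0, 0.5)` on log2 — large enough for k-means to recover
the subgroups, which the tests verify. True effects hit a `frac_de = 0.1`
fraction of genes with magnitudes `Uniform(0.5, 1.5) * effect_mean_log2`
(default mean 1.0 log2, the strong-responder regime) and random signs;
subgroup heterogeneity `eta ~ N(0, tau)` is added to true-DE genes only,
so `is_de` remains equivalent to a nonzero shared effect.

What it does **not** emulate: gene–gene correlation, GC/length effects,
batch-specific technical noise, or any real annotation. Passing tests
demonstrate the statistical machinery under the model's own assumptions;
they do not certify performance on real data.

## Problem sizes and determinism

The test suite runs the full workflow at the generator's default
paper-like sizes (2500 genes, 464 + 20 samples) for the recovery checks
and smaller configurations (200–500 genes, ~100 samples) for orchestration
and determinism checks; resampling metrics use reduced replicate counts
(B = 50, 50 half-splits, 100 consensus iterations) in the heavier checks,
with the full `B = 200 / 100 / 200` defaults remaining routine on a
laptop. All stochastic stages derive their seeds from one global integer
via stage-name hashing, so identical configurations reproduce
byte-identical artifact directories (asserted in the tests) and individual
stages can be rerun in isolation.

## Known limitations

* Fixed-effect pooling ignores the shared-treated-arm correlation (see
  above); no random-effects or correlation-aware pooling is provided.
* The dispersion estimator is a simplified approximation; on very small
  strata its shrinkage weight (0.5) is a fixed compromise, not tuned.
* Gene identifiers are opaque strings; no symbol/Ensembl mapping.
* No GEO/SRA retrieval, no alignment or quantification, and no plot
  rendering — figures' underlying tables are exported instead.
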