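#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median over reference genes of
#' `count / geometric mean across samples`, where reference genes are those
#' with strictly positive counts in every sample.
#'
#' @param counts count matrix (genes x samples).
#' @return named positive numeric vector, one factor per sample.
#' @export
estimate_size_factors <- function(counts) {
  pos <- rowSums(counts <= 0) == 0
  if (!any(pos))
    stop("no gene has positive counts in all samples; filter genes or samples first")
  logg <- rowMeans(log(counts[pos, , drop = FALSE]))
  sf <- apply(log(counts[pos, , drop = FALSE]) - logg, 2,
              function(r) exp(stats::median(r)))
  stats::setNames(sf, colnames(counts))
}

# negative binomial log-likelihood with Cox-Reid adjustment, mu fixed
cr_apl <- function(alpha, y, mu, X) {
  ll <- sum(stats::dnbinom(y, size = 1 / alpha, mu = mu, log = TRUE))
  w <- mu / (1 + alpha * mu)
  xtwx <- crossprod(X * sqrt(w))
  ll - 0.5 * determinant(xtwx, logarithm = TRUE)$modulus[1]
}

#' Per-gene NB dispersion estimation
#'
#' For each gene, fitted means come from a Poisson GLM under `design` with
#' `log(size_factor)` offsets; the dispersion `alpha` (variance convention
#' `mu + alpha * mu^2`) then maximizes the Cox-Reid adjusted profile
#' likelihood on `log(alpha)` within `[1e-8, 10]`. Genes whose optimization
#' fails fall back to a method-of-moments estimate and are flagged. A
#' log-linear mean-dispersion trend is fitted across genes and per-gene
#' estimates are shrunk toward it on the log scale with weight
#' `shrink_weight`, which stabilizes small contrasts.
#'
#' @param counts count matrix (genes x samples), all samples in the contrast.
#' @param sf size factors for those samples.
#' @param design design matrix (samples x coefficients), full rank.
#' @param shrink_weight weight of the gene-wise estimate vs the trend on the
#'   log scale (default 0.5).
#' @return data.frame: `gene, base_mean, alpha_gene, alpha_trend, alpha,
#'   fallback, usable`. All-zero genes get `usable = FALSE`.
#' @export
estimate_dispersions <- function(counts, sf, design, shrink_weight = 0.5) {
  n <- ncol(counts)
  if (n - ncol(design) < 2) stop("need >= 2 residual degrees of freedom")
  off <- log(sf)
  G <- nrow(counts)
  base_mean <- rowMeans(sweep(counts, 2, sf, "/"))
  alpha_gene <- rep(NA_real_, G)
  fallback <- logical(G)
  usable <- base_mean > 0
  for (g in which(usable)) {
    y <- counts[g, ]
    fit <- tryCatch(
      suppressWarnings(stats::glm.fit(design, y, family = stats::poisson(),
                                      offset = off)),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged) { fallback[g] <- TRUE }
    mu <- if (is.null(fit)) rep(mean(y), n) else pmax(fit$fitted.values, 1e-8)
    mom <- sum((y - mu)^2 - mu) / sum(mu^2)
    mom <- min(max(mom, 1e-8), 10)
    opt <- tryCatch(
      stats::optimize(function(la) cr_apl(exp(la), y, mu, design),
                      interval = log(c(1e-8, 10)), maximum = TRUE),
      error = function(e) NULL)
    if (is.null(opt)) {
      alpha_gene[g] <- mom
      fallback[g] <- TRUE
    } else {
      alpha_gene[g] <- exp(opt$maximum)
    }
  }
  # mean-dispersion trend: log(alpha) ~ log(base_mean), fitted on genes away
  # from the box bounds to avoid floor/cap artifacts
  trend_ok <- usable & !is.na(alpha_gene) & alpha_gene > 2e-8 & alpha_gene < 9
  alpha_trend <- rep(NA_real_, G)
  if (sum(trend_ok) >= 10) {
    tdf <- data.frame(la = log(alpha_gene[trend_ok]), lbm = log(base_mean[trend_ok]))
    tfit <- stats::lm(la ~ lbm, data = tdf)
    alpha_trend[usable] <- exp(stats::predict(
      tfit, newdata = data.frame(lbm = log(base_mean[usable]))))
  } else {
    alpha_trend[usable] <- exp(mean(log(alpha_gene[usable]), na.rm = TRUE))
  }
  alpha_trend <- pmin(pmax(alpha_trend, 1e-8), 10)
  alpha <- exp(shrink_weight * log(alpha_gene) +
                 (1 - shrink_weight) * log(alpha_trend))
  alpha <- pmin(pmax(alpha, 1e-8), 10)
  data.frame(gene = rownames(counts), base_mean = base_mean,
             alpha_gene = alpha_gene, alpha_trend = alpha_trend,
             alpha = alpha, fallback = fallback, usable = usable,
             stringsAsFactors = FALSE)
}

#' Fit a negative-binomial GLM for one gene
#'
#' Log-link NB regression with fixed dispersion and `log(size_factor)`
#' offset, fitted by iteratively reweighted least squares (Fisher scoring,
#' relative tolerance 1e-8, at most 100 iterations). The coefficient
#' covariance comes from the expected information at the optimum.
#' Coefficients and standard errors are reported in log2 units.
#'
#' @param y integer counts, one per sample.
#' @param design design matrix (samples x coefficients), full rank.
#' @param sf size factors.
#' @param alpha NB dispersion (> 0).
#' @return list: `coef_log2`, `se_log2` (named by design columns),
#'   `converged`, `fitted`.
#' @export
fit_nb_glm <- function(y, design, sf, alpha) {
  if (alpha <= 0) stop("alpha must be positive")
  fam <- MASS::negative.binomial(theta = 1 / alpha, link = "log")
  fit <- tryCatch(
    suppressWarnings(stats::glm.fit(design, y, family = fam, offset = log(sf),
                                    control = stats::glm.control(epsilon = 1e-8,
                                                                 maxit = 100))),
    error = function(e) NULL)
  if (is.null(fit) || !fit$converged || any(!is.finite(fit$coefficients))) {
    return(list(coef_log2 = stats::setNames(rep(NA_real_, ncol(design)),
                                            colnames(design)),
                se_log2 = stats::setNames(rep(NA_real_, ncol(design)),
                                          colnames(design)),
                converged = FALSE, fitted = NULL))
  }
  w <- fit$weights
  info <- crossprod(design * sqrt(w))
  cov <- tryCatch(solve(info), error = function(e) NULL)
  if (is.null(cov)) {
    return(list(coef_log2 = stats::setNames(rep(NA_real_, ncol(design)),
                                            colnames(design)),
                se_log2 = stats::setNames(rep(NA_real_, ncol(design)),
                                          colnames(design)),
                converged = FALSE, fitted = NULL))
  }
  list(coef_log2 = stats::setNames(fit$coefficients / log(2), colnames(design)),
       se_log2 = stats::setNames(sqrt(diag(cov)) / log(2), colnames(design)),
       converged = TRUE, fitted = fit$fitted.values)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment with monotonicity enforcement; missing p-values
#' are excluded from the procedure and stay missing in the output.
#'
#' @param p p-values in \[0, 1\] (NA allowed).
#' @return adjusted values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Run one treatment-vs-control differential-expression contrast
#'
#' Restricts the data to the vehicle samples of one control cluster (or all
#' vehicle samples when `cluster_id` is `NULL`) plus every sample carrying
#' `drug_label`, re-estimates size factors on that subset, drops genes with
#' all-zero counts in it, estimates dispersions under the contrast design,
#' fits the NB GLM per gene and Wald-tests the treatment coefficient
#' (`z = log2fc / se`, two-sided normal p), with BH adjustment across
#' converged genes.
#'
#' The design is `~ covariates + treatment` with vehicle as reference; the
#' covariates (typically `PC1..PC3` embedding scores, projected for treated
#' samples) must be columns of `samples`.
#'
#' Contrasts violating the preconditions (>= 2 vehicle and >= 2 treated
#' samples) are skipped: a message is emitted and `NULL` returned, so a
#' cluster yielding no usable contrast is dropped from pooling rather than
#' aborting the run.
#'
#' @param counts full count matrix.
#' @param samples sample table with `sample_id`, `treatment`, optionally
#'   `cluster` and covariate columns.
#' @param cluster_id control cluster to use, or `NULL` for all vehicles.
#' @param drug_label treatment label of the treated group.
#' @param covariates character vector of covariate column names (may be
#'   empty).
#' @param vehicle_label treatment label of the controls (default `"DMSO"`).
#' @param shrink_weight passed to [estimate_dispersions()].
#' @return data.frame: `gene, base_mean, log2fc, se, p, fdr, contrast_id,
#'   converged` — or `NULL` when skipped.
#' @export
run_contrast <- function(counts, samples, cluster_id = NULL, drug_label,
                         covariates = c("PC1", "PC2", "PC3"),
                         vehicle_label = "DMSO", shrink_weight = 0.5) {
  stopifnot(all(c("sample_id", "treatment") %in% names(samples)))
  is_vehicle <- samples$treatment == vehicle_label
  if (!is.null(cluster_id)) {
    if (!"cluster" %in% names(samples))
      stop("samples table lacks a 'cluster' column")
    is_vehicle <- is_vehicle & !is.na(samples$cluster) &
      samples$cluster == cluster_id
  }
  is_drug <- samples$treatment == drug_label
  contrast_id <- if (is.null(cluster_id)) paste0(drug_label, "_vs_all") else
    paste0(drug_label, "_vs_cluster", cluster_id)
  if (sum(is_vehicle) < 2 || sum(is_drug) < 2) {
    message(sprintf("contrast %s skipped: %d vehicle / %d treated samples",
                    contrast_id, sum(is_vehicle), sum(is_drug)))
    return(NULL)
  }
  keep <- samples[is_vehicle | is_drug, , drop = FALSE]
  if (length(covariates) > 0 && !all(covariates %in% names(keep)))
    stop("missing covariate columns: ",
         paste(setdiff(covariates, names(keep)), collapse = ", "))
  m <- counts[, keep$sample_id, drop = FALSE]
  m <- m[rowSums(m) > 0, , drop = FALSE]
  if (nrow(m) == 0) {
    message("contrast ", contrast_id, " skipped: no nonzero genes")
    return(NULL)
  }
  sf <- estimate_size_factors(m)
  trt <- as.numeric(keep$treatment == drug_label)
  X <- cbind(`(Intercept)` = 1,
             if (length(covariates) > 0)
               as.matrix(keep[, covariates, drop = FALSE]),
             treatment = trt)
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient")
  disp <- estimate_dispersions(m, sf, X, shrink_weight = shrink_weight)
  G <- nrow(m)
  log2fc <- se <- p <- rep(NA_real_, G)
  converged <- logical(G)
  for (g in seq_len(G)) {
    if (!disp$usable[g]) next
    fit <- fit_nb_glm(m[g, ], X, sf, disp$alpha[g])
    if (!fit$converged) next
    converged[g] <- TRUE
    log2fc[g] <- fit$coef_log2["treatment"]
    se[g] <- fit$se_log2["treatment"]
    z <- log2fc[g] / se[g]
    p[g] <- 2 * stats::pnorm(-abs(z))
  }
  out <- data.frame(gene = rownames(m), base_mean = disp$base_mean,
                    log2fc = log2fc, se = se, p = p,
                    fdr = bh_adjust(p),
                    contrast_id = contrast_id, converged = converged,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Single-contrast DE with a treatment-only design
#'
#' Convenience wrapper for external validation datasets: identical to
#' [run_contrast()] with no clustering and no covariates.
#'
#' @inheritParams run_contrast
#' @export
external_de <- function(counts, samples, drug_label, vehicle_label = "DMSO",
                        shrink_weight = 0.5) {
  run_contrast(counts, samples, cluster_id = NULL, drug_label = drug_label,
               covariates = character(0), vehicle_label = vehicle_label,
               shrink_weight = shrink_weight)
}
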