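#' Configuration for the synthetic perturbation-screen generator
#'
#' Describes a dataset with one drug-treated group facing a much larger pool
#' of vehicle (DMSO) controls that hides several latent transcriptional
#' subgroups — the situation the stratified workflow is designed for.
#'
#' Counts are negative binomial with gene-wise dispersion `alpha` under the
#' variance convention `var = mu + alpha * mu^2` (the same convention the DE
#' model uses). For gene g in subgroup c, sample j:
#' `count ~ NB(mean = s_j * 2^(mu_g + delta_gc + t_j * beta_gc), alpha_g)`
#' where `t_j` is the treatment indicator, `delta_gc ~ N(0, subgroup_shift_sd)`
#' is the subgroup baseline offset, `beta_gc = beta_g + eta_gc` the realized
#' drug effect with `eta_gc ~ N(0, effect_heterogeneity_tau)` drawn for true
#' DE genes, and `s_j` a log-normal library-size factor.
#'
#' @param n_genes number of genes (>= 10).
#' @param n_subgroups number of latent control subgroups.
#' @param controls_per_subgroup integer vector of control sample counts, one
#'   per subgroup.
#' @param n_treated number of drug-treated samples.
#' @param frac_de fraction of genes with a nonzero shared drug effect.
#' @param effect_mean_log2 mean absolute shared effect (log2 scale). Realized
#'   magnitudes are uniform on `[0.5, 1.5] * effect_mean_log2` with random
#'   sign.
#' @param effect_heterogeneity_tau SD of the subgroup-specific effect
#'   deviation (log2 scale), applied to true DE genes.
#' @param subgroup_shift_sd SD of per-gene subgroup baseline offsets (log2).
#' @param dispersion_meanlog,dispersion_sdlog log-normal parameters of the
#'   gene-wise dispersion draw.
#' @param libsize_log_sd SD of log library-size factors.
#' @param baseline_log2_range range of gene baseline log2 means.
#' @param vehicle_label,treated_label treatment labels written to the sample
#'   table.
#' @param seed integer RNG seed; the generator is deterministic given it.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_genes = 2500,
                       n_subgroups = 5,
                       controls_per_subgroup = c(60, 60, 60, 72, 212),
                       n_treated = 20,
                       frac_de = 0.1,
                       effect_mean_log2 = 1.0,
                       effect_heterogeneity_tau = 0,
                       subgroup_shift_sd = 0.5,
                       dispersion_meanlog = -2.3,
                       dispersion_sdlog = 0.6,
                       libsize_log_sd = 0.2,
                       baseline_log2_range = c(0, 10),
                       vehicle_label = "DMSO",
                       treated_label = "drug",
                       seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              n_subgroups = as.integer(n_subgroups),
              controls_per_subgroup = as.integer(controls_per_subgroup),
              n_treated = as.integer(n_treated),
              frac_de = frac_de,
              effect_mean_log2 = effect_mean_log2,
              effect_heterogeneity_tau = effect_heterogeneity_tau,
              subgroup_shift_sd = subgroup_shift_sd,
              dispersion_meanlog = dispersion_meanlog,
              dispersion_sdlog = dispersion_sdlog,
              libsize_log_sd = libsize_log_sd,
              baseline_log2_range = as.numeric(baseline_log2_range),
              vehicle_label = vehicle_label,
              treated_label = treated_label,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.na(cfg$n_genes) || cfg$n_genes < 10) stop("n_genes must be >= 10")
  if (cfg$n_subgroups < 1) stop("n_subgroups must be positive")
  if (length(cfg$controls_per_subgroup) != cfg$n_subgroups)
    stop("controls_per_subgroup must have one entry per subgroup")
  if (any(is.na(cfg$controls_per_subgroup)) || any(cfg$controls_per_subgroup < 1))
    stop("controls_per_subgroup must be positive integers")
  if (is.na(cfg$n_treated) || cfg$n_treated < 1)
    stop("n_treated must be a positive integer")
  if (cfg$frac_de < 0 || cfg$frac_de > 1) stop("frac_de must lie in [0, 1]")
  if (cfg$effect_heterogeneity_tau < 0) stop("tau must be non-negative")
  if (cfg$subgroup_shift_sd < 0) stop("subgroup_shift_sd must be non-negative")
  if (cfg$libsize_log_sd < 0) stop("libsize_log_sd must be non-negative")
  cfg
}

#' Default configuration emulating a large imbalanced kinase-inhibitor screen
#'
#' Five latent control subgroups with sizes 60, 60, 60, 72 and 212 (464
#' vehicle samples in total, sizes spanning 60-212) against 20 treated
#' samples, 2500 genes — the group structure of the discovery dataset the
#' stratified workflow targets, at a gene count small enough for routine
#' testing.
#'
#' @param seed integer RNG seed.
#' @param ... overrides passed to [sim_config()].
#' @return a `sim_config`.
#' @export
default_sim_config <- function(seed = 1L, ...) {
  sim_config(seed = seed, ...)
}

#' Write / read a simulation configuration as YAML
#' @param cfg a `sim_config`.
#' @param path file path.
#' @export
write_sim_config <- function(cfg, path) {
  validate_sim_config(cfg)
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(sim_config, x)
}

#' Simulate a synthetic perturbation dataset with ground truth
#'
#' @param cfg a `sim_config`.
#' @return list with components:
#'   \describe{
#'     \item{counts}{integer count matrix, genes x samples.}
#'     \item{samples}{data.frame: `sample_id`, `treatment`, `latent_subgroup`,
#'       `size_factor_true`.}
#'     \item{truth}{list: `is_de` (logical per gene), `true_effect_log2`
#'       (shared effect per gene), `subgroup_effects_log2` (genes x
#'       subgroups realized effects), `baseline_log2`, `dispersion`,
#'       `subgroup_of_sample`.}
#'   }
#' @export
simulate_counts <- function(cfg) {
  cfg <- validate_sim_config(cfg)
  set.seed(cfg$seed)
  G <- cfg$n_genes
  S <- cfg$n_subgroups
  genes <- sprintf("G%05d", seq_len(G))

  mu <- stats::runif(G, cfg$baseline_log2_range[1], cfg$baseline_log2_range[2])
  alpha <- stats::rlnorm(G, cfg$dispersion_meanlog, cfg$dispersion_sdlog)
  delta <- matrix(stats::rnorm(G * S, 0, cfg$subgroup_shift_sd), G, S)

  n_de <- round(cfg$frac_de * G)
  beta <- numeric(G)
  if (n_de > 0) {
    de_idx <- sample.int(G, n_de)
    sgn <- sample(c(-1, 1), n_de, replace = TRUE)
    mag <- stats::runif(n_de, 0.5, 1.5) * cfg$effect_mean_log2
    beta[de_idx] <- sgn * mag
  }
  eta <- matrix(0, G, S)
  if (cfg$effect_heterogeneity_tau > 0 && n_de > 0) {
    eta[de_idx, ] <- stats::rnorm(n_de * S, 0, cfg$effect_heterogeneity_tau)
  }
  subgroup_effects <- (beta + eta) * (beta != 0)

  # treated samples follow the control subgroup proportions (largest-remainder
  # apportionment so the sizes sum exactly to n_treated)
  ctrl_sub <- rep(seq_len(S), cfg$controls_per_subgroup)
  prop <- cfg$controls_per_subgroup / sum(cfg$controls_per_subgroup)
  raw <- prop * cfg$n_treated
  n_trt_sub <- floor(raw)
  rem <- cfg$n_treated - sum(n_trt_sub)
  if (rem > 0) {
    extra <- order(raw - floor(raw), decreasing = TRUE)[seq_len(rem)]
    n_trt_sub[extra] <- n_trt_sub[extra] + 1L
  }
  trt_sub <- rep(seq_len(S), n_trt_sub)

  subgroup <- c(ctrl_sub, trt_sub)
  treated <- c(rep(FALSE, length(ctrl_sub)), rep(TRUE, length(trt_sub)))
  n_samples <- length(subgroup)
  sample_ids <- sprintf("S%04d", seq_len(n_samples))
  sf <- stats::rlnorm(n_samples, 0, cfg$libsize_log_sd)

  counts <- matrix(0L, G, n_samples, dimnames = list(genes, sample_ids))
  for (j in seq_len(n_samples)) {
    c_j <- subgroup[j]
    log2mean <- mu + delta[, c_j] + if (treated[j]) subgroup_effects[, c_j] else 0
    m_j <- sf[j] * 2^log2mean
    counts[, j] <- stats::rnbinom(G, mu = m_j, size = 1 / alpha)
  }

  samples <- data.frame(
    sample_id = sample_ids,
    treatment = ifelse(treated, cfg$treated_label, cfg$vehicle_label),
    latent_subgroup = subgroup,
    size_factor_true = sf,
    stringsAsFactors = FALSE)

  truth <- list(
    is_de = stats::setNames(beta != 0, genes),
    true_effect_log2 = stats::setNames(beta, genes),
    subgroup_effects_log2 = `dimnames<-`(subgroup_effects,
                                         list(genes, paste0("subgroup", seq_len(S)))),
    subgroup_baseline_log2 = `dimnames<-`(delta,
                                          list(genes, paste0("subgroup", seq_len(S)))),
    baseline_log2 = stats::setNames(mu, genes),
    dispersion = stats::setNames(alpha, genes),
    subgroup_of_sample = stats::setNames(subgroup, sample_ids))

  list(counts = validate_counts(counts), samples = samples, truth = truth)
}

#' Simulate an external validation dataset sharing a discovery ground truth
#'
#' Generates a single-batch dataset (no latent subgroups) whose true drug
#' effects are the shared effects of an existing simulation, scaled by
#' `effect_scale`. Emulates an independent model system (e.g. cardiomyocytes)
#' re-exposed to the same drug.
#'
#' @param truth the `truth` component of a [simulate_counts()] result.
#' @param n_controls,n_treated group sizes.
#' @param effect_scale multiplier on the shared effects.
#' @param concordant_frac fraction of true DE genes whose effect keeps its
#'   sign in the external system (the rest are sign-flipped).
#' @param cfg a `sim_config` providing nuisance parameters (dispersion,
#'   library sizes, baselines are redrawn).
#' @param seed RNG seed.
#' @return list as [simulate_counts()].
#' @export
simulate_external <- function(truth, n_controls = 60, n_treated = 20,
                              effect_scale = 1, concordant_frac = 1,
                              cfg = default_sim_config(), seed = 1L) {
  set.seed(as.integer(seed))
  genes <- names(truth$true_effect_log2)
  G <- length(genes)
  beta <- truth$true_effect_log2 * effect_scale
  de <- which(beta != 0)
  if (concordant_frac < 1 && length(de) > 0) {
    flip <- sample(de, round((1 - concordant_frac) * length(de)))
    beta[flip] <- -beta[flip]
  }
  mu <- stats::runif(G, cfg$baseline_log2_range[1], cfg$baseline_log2_range[2])
  alpha <- stats::rlnorm(G, cfg$dispersion_meanlog, cfg$dispersion_sdlog)
  n <- n_controls + n_treated
  treated <- rep(c(FALSE, TRUE), c(n_controls, n_treated))
  sf <- stats::rlnorm(n, 0, cfg$libsize_log_sd)
  sample_ids <- sprintf("E%04d", seq_len(n))
  counts <- matrix(0L, G, n, dimnames = list(genes, sample_ids))
  for (j in seq_len(n)) {
    m_j <- sf[j] * 2^(mu + if (treated[j]) beta else 0)
    counts[, j] <- stats::rnbinom(G, mu = m_j, size = 1 / alpha)
  }
  samples <- data.frame(
    sample_id = sample_ids,
    treatment = ifelse(treated, cfg$treated_label, cfg$vehicle_label),
    stringsAsFactors = FALSE)
  truth_ext <- list(is_de = beta != 0,
                    true_effect_log2 = beta,
                    baseline_log2 = stats::setNames(mu, genes),
                    dispersion = stats::setNames(alpha, genes))
  list(counts = validate_counts(counts), samples = samples, truth = truth_ext)
}

#' Add a comparator drug arm to a simulated dataset
#'
#' Draws additional treated samples for a second drug on the same genes,
#' subgroup structure, baselines and dispersions as an existing simulation,
#' with its own (typically null) effect configuration — the setting for
#' like-for-like drug-specificity comparisons.
#'
#' @param sim result of [simulate_counts()] run with `cfg`.
#' @param cfg the `sim_config` that produced `sim`.
#' @param label treatment label for the comparator samples.
#' @param frac_de fraction of genes with a nonzero comparator effect.
#' @param effect_mean_log2 mean absolute comparator effect.
#' @param seed RNG seed for the comparator draws.
#' @return `sim` with comparator columns appended to `counts`, rows appended
#'   to `samples`, and `truth$comparator_effect_log2` added.
#' @export
simulate_comparator_arm <- function(sim, cfg, label = "comparator",
                                    frac_de = 0, effect_mean_log2 = 1.0,
                                    seed = 2L) {
  set.seed(as.integer(seed))
  genes <- rownames(sim$counts)
  G <- length(genes)
  S <- cfg$n_subgroups
  beta <- numeric(G)
  n_de <- round(frac_de * G)
  if (n_de > 0) {
    idx <- sample.int(G, n_de)
    beta[idx] <- sample(c(-1, 1), n_de, replace = TRUE) *
      stats::runif(n_de, 0.5, 1.5) * effect_mean_log2
  }
  prop <- cfg$controls_per_subgroup / sum(cfg$controls_per_subgroup)
  raw <- prop * cfg$n_treated
  n_sub <- floor(raw)
  rem <- cfg$n_treated - sum(n_sub)
  if (rem > 0) {
    extra <- order(raw - floor(raw), decreasing = TRUE)[seq_len(rem)]
    n_sub[extra] <- n_sub[extra] + 1L
  }
  sub <- rep(seq_len(S), n_sub)
  n_new <- length(sub)
  sf <- stats::rlnorm(n_new, 0, cfg$libsize_log_sd)
  ids <- sprintf("C%04d", seq_len(n_new))
  mu <- sim$truth$baseline_log2
  alpha <- sim$truth$dispersion
  delta <- sim$truth$subgroup_baseline_log2
  newc <- matrix(0L, G, n_new, dimnames = list(genes, ids))
  for (j in seq_len(n_new)) {
    m_j <- sf[j] * 2^(mu + delta[, sub[j]] + beta)
    newc[, j] <- stats::rnbinom(G, mu = m_j, size = 1 / alpha)
  }
  sim$counts <- validate_counts(cbind(sim$counts, newc))
  sim$samples <- rbind(sim$samples,
                       data.frame(sample_id = ids, treatment = label,
                                  latent_subgroup = sub, size_factor_true = sf,
                                  stringsAsFactors = FALSE))
  sim$truth$comparator_effect_log2 <- stats::setNames(beta, genes)
  sim$truth$subgroup_of_sample <- c(sim$truth$subgroup_of_sample,
                                    stats::setNames(sub, ids))
  sim
}

#' Random gene-set collection over a gene universe
#'
#' Convenience generator for exercising over-representation analysis on
#' synthetic data; set sizes are uniform on `size_range`.
#'
#' @param genes character vector of gene ids.
#' @param n_terms number of sets.
#' @param size_range integer range of set sizes.
#' @param seed RNG seed.
#' @return collection in the [read_gmt()] format.
#' @export
random_gene_sets <- function(genes, n_terms = 50, size_range = c(10, 60),
                             seed = 1L) {
  set.seed(as.integer(seed))
  out <- list()
  for (i in seq_len(n_terms)) {
    sz <- sample(seq(size_range[1], size_range[2]), 1)
    out[[sprintf("T%04d", i)]] <- list(description = sprintf("synthetic term %d", i),
                                       genes = sample(genes, min(sz, length(genes))))
  }
  out
}
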