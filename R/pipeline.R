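# simple 31-bit rolling hash; used for run ids and stage seed derivation
# (a reproducibility fingerprint, not a cryptographic digest)
string_hash31 <- function(s) {
  h <- 7
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 2147483629
  as.integer(h)
}

#' Derive a per-stage RNG seed from the global seed
#'
#' Deterministic hash of the stage name combined with the global seed, kept
#' below 2^31 so stages can be rerun in isolation with the same stream.
#'
#' @param seed global integer seed.
#' @param stage stage name.
#' @return integer seed.
#' @export
stage_seed <- function(seed, stage) {
  as.integer((string_hash31(stage) + as.numeric(seed) * 48271) %% 2147483629 + 1)
}

#' Pipeline configuration
#'
#' All stage parameters with their workflow defaults: top 10 percent
#' variable genes, 20 PCs, candidate k 2-8 with minimum cluster size 15,
#' bootstrap Jaccard B = 200, prediction strength 100 repetitions, consensus
#' PAC 200 iterations at 80 percent subsampling, PC1-PC3 as DE covariates,
#' and the four retention criteria. Unknown keys are rejected (any
#' misspelled YAML key fails loudly via [read_pipeline_config()]).
#'
#' @param sim a `sim_config` to generate the input, or `NULL` to read files.
#' @param counts_path,samples_path input files when `sim` is `NULL`.
#' @param gmt_path gene-set collection for enrichment; in simulation mode a
#'   synthetic collection is generated when `NULL`.
#' @param vehicle_label,drug_label,comparator_label treatment labels; the
#'   comparator is optional.
#' @param comparator_frac_de,comparator_effect_mean_log2 comparator effect
#'   configuration in simulation mode.
#' @param external_sim simulate an external validation dataset (simulation
#'   mode only).
#' @param external_counts_path,external_samples_path external dataset files.
#' @param var_frac,n_pcs variable-gene fraction and retained PCs.
#' @param k_range,min_cluster_size,kmeans_restarts clustering parameters.
#' @param stability_B,ps_repetitions,pac_iterations,subsample_frac
#'   resampling-stability parameters.
#' @param compute_stability compute the stability report (needed for
#'   `k_mode = "auto"`).
#' @param k_mode,k_fixed cluster-number selection (see [choose_k()]).
#' @param n_covariate_pcs number of leading PCs used as DE covariates.
#' @param criteria a [meta_criteria()].
#' @param cluster_fdr_max,external_fdr,down_lfc_max,ora_fdr_max,ora_min_count
#'   downstream thresholds.
#' @param shrink_weight dispersion-shrinkage weight.
#' @param seed global seed; every stochastic stage derives its own seed from
#'   it via [stage_seed()].
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(sim = NULL,
                            counts_path = NULL, samples_path = NULL,
                            gmt_path = NULL,
                            vehicle_label = "DMSO", drug_label = "drug",
                            comparator_label = NULL,
                            comparator_frac_de = 0,
                            comparator_effect_mean_log2 = 1.0,
                            external_sim = TRUE,
                            external_counts_path = NULL,
                            external_samples_path = NULL,
                            var_frac = 0.10, n_pcs = 20,
                            k_range = 2:8, min_cluster_size = 15,
                            kmeans_restarts = 25,
                            stability_B = 200, ps_repetitions = 100,
                            pac_iterations = 200, subsample_frac = 0.8,
                            compute_stability = TRUE,
                            k_mode = "auto", k_fixed = NULL,
                            n_covariate_pcs = 3,
                            criteria = meta_criteria(),
                            cluster_fdr_max = 0.05, external_fdr = 0.05,
                            down_lfc_max = -1.0, ora_fdr_max = 0.05,
                            ora_min_count = 10,
                            shrink_weight = 0.5,
                            seed = 1L) {
  if (is.null(sim) && (is.null(counts_path) || is.null(samples_path)))
    stop("provide either a sim_config or counts_path + samples_path")
  if (!is.null(sim) && !inherits(sim, "sim_config"))
    stop("sim must be a sim_config")
  if (!inherits(criteria, "meta_criteria")) stop("criteria must be meta_criteria()")
  if (!compute_stability && k_mode != "fixed")
    stop("k_mode = 'auto' requires compute_stability = TRUE")
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read / write a pipeline configuration as YAML
#'
#' Unknown keys in the file are rejected by construction (they become
#' unused arguments of [pipeline_config()]).
#'
#' @param path YAML file.
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  if (!is.null(x$sim)) x$sim <- do.call(sim_config, x$sim)
  if (!is.null(x$criteria)) x$criteria <- do.call(meta_criteria, x$criteria)
  do.call(pipeline_config, x)
}

#' @rdname read_pipeline_config
#' @param cfg a `pipeline_config`.
#' @export
write_pipeline_config <- function(cfg, path) {
  x <- unclass(cfg)
  if (!is.null(x$sim)) x$sim <- unclass(x$sim)
  x$criteria <- unclass(x$criteria)
  yaml::write_yaml(x, path)
  invisible(path)
}

config_run_id <- function(cfg) {
  x <- unclass(cfg)
  x$sim <- if (!is.null(x$sim)) unclass(x$sim)
  x$criteria <- unclass(x$criteria)
  sprintf("%08x", string_hash31(yaml::as.yaml(x)))
}

# run one drug through per-cluster DE + meta + signature
run_drug_arm <- function(counts, samples, drug_label, clusters, cfg) {
  covs <- paste0("PC", seq_len(cfg$n_covariate_pcs))
  tables <- lapply(clusters, function(cl)
    run_contrast(counts, samples, cluster_id = cl, drug_label = drug_label,
                 covariates = covs, vehicle_label = cfg$vehicle_label,
                 shrink_weight = cfg$shrink_weight))
  names(tables) <- paste0("cluster", clusters)
  meta <- run_meta(tables, criteria = cfg$criteria,
                   cluster_fdr_max = cfg$cluster_fdr_max)
  profile <- fc_profile(tables)
  corr <- fc_correlations(profile)
  network <- if (sum(!vapply(tables, is.null, logical(1))) >= 3)
    build_network(corr) else NULL
  intersection <- if (sum(!vapply(tables, is.null, logical(1))) >= 2)
    intersect_cluster_degs(tables, fdr_max = cfg$cluster_fdr_max) else NULL
  list(tables = tables, meta = meta, profile = profile, corr = corr,
       network = network, intersection = intersection)
}

#' Run the full stratified meta-analysis workflow
#'
#' Stages: input (simulate or read), control stratification (variable genes,
#' PCA, k-means with stability-based or fixed k, projection of treated
#' samples), per-cluster NB differential expression, fixed-effect
#' meta-analysis with retention criteria, signature analyses (fold-change
#' correlations, network, all-cluster intersection, cross-dataset overlap,
#' drug-specific genes when a comparator is configured), over-representation
#' analysis, and a manifest with file checksums. All result tables are TSVs
#' carrying the run id and global seed in their header comment.
#'
#' @param cfg a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with all in-memory stage results plus
#'   `manifest`.
#' @export
run_pipeline <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  run_id <- config_run_id(cfg)
  seed <- cfg$seed
  wr <- function(df, name) write_result_table(df, file.path(out_dir, name),
                                              seed = seed, run_id = run_id)

  # ---- input ----
  external <- NULL
  if (!is.null(cfg$sim)) {
    sim_cfg <- cfg$sim
    sim_cfg$seed <- stage_seed(seed, "simulate")
    sim_cfg$vehicle_label <- cfg$vehicle_label
    sim_cfg$treated_label <- cfg$drug_label
    sim <- simulate_counts(sim_cfg)
    if (!is.null(cfg$comparator_label)) {
      sim <- simulate_comparator_arm(
        sim, sim_cfg, label = cfg$comparator_label,
        frac_de = cfg$comparator_frac_de,
        effect_mean_log2 = cfg$comparator_effect_mean_log2,
        seed = stage_seed(seed, "simulate_comparator"))
    }
    counts <- sim$counts
    samples <- sim$samples
    truth <- sim$truth
    if (isTRUE(cfg$external_sim)) {
      ext <- simulate_external(truth, cfg = sim_cfg,
                               seed = stage_seed(seed, "simulate_external"))
      external <- list(counts = ext$counts, samples = ext$samples,
                       truth = ext$truth)
    }
    wr(data.frame(gene = names(truth$is_de), is_de = truth$is_de,
                  true_effect_log2 = truth$true_effect_log2), "ground_truth.tsv")
  } else {
    counts <- read_counts(cfg$counts_path)
    samples <- read_samples(cfg$samples_path)
    truth <- NULL
  }
  if (!is.null(cfg$external_counts_path)) {
    external <- list(counts = read_counts(cfg$external_counts_path),
                     samples = read_samples(cfg$external_samples_path))
  }

  # ---- stratification ----
  sf <- estimate_size_factors(counts)
  logmat <- log_transform(counts, sf)
  is_vehicle <- samples$treatment == cfg$vehicle_label
  veh_ids <- samples$sample_id[is_vehicle]
  veh_log <- logmat[, veh_ids, drop = FALSE]
  var_genes <- select_variable_genes(veh_log, fraction = cfg$var_frac)
  n_pcs <- min(cfg$n_pcs, length(veh_ids) - 1L, length(var_genes))
  emb <- run_pca(veh_log, variable_genes = var_genes, n_pcs = n_pcs)

  report <- NULL
  if (cfg$compute_stability) {
    report <- build_stability_report(
      emb$scores, k_range = cfg$k_range,
      min_cluster_size = cfg$min_cluster_size,
      seed = stage_seed(seed, "stability"), B = cfg$stability_B,
      ps_repetitions = cfg$ps_repetitions,
      pac_iterations = cfg$pac_iterations,
      subsample_frac = cfg$subsample_frac, n_restarts = cfg$kmeans_restarts)
    wr(as.data.frame(report), "stability_report.tsv")
    k <- choose_k(report, mode = cfg$k_mode, k_fixed = cfg$k_fixed)
  } else {
    k <- cfg$k_fixed
    if (is.null(k)) stop("compute_stability = FALSE requires k_fixed")
  }
  sol <- kmeans_cluster(emb$scores, k, seed = stage_seed(seed, "kmeans"),
                        n_restarts = cfg$kmeans_restarts)

  # projected scores for all non-vehicle samples; covariate columns for DE
  other_ids <- samples$sample_id[!is_vehicle]
  proj <- if (length(other_ids) > 0)
    project_samples(emb, logmat[, other_ids, drop = FALSE]) else NULL
  scores_all <- rbind(emb$scores, proj)[samples$sample_id, , drop = FALSE]
  covs <- paste0("PC", seq_len(cfg$n_covariate_pcs))
  samples[covs] <- scores_all[, seq_len(cfg$n_covariate_pcs), drop = FALSE]
  samples$cluster <- NA_integer_
  samples$cluster[match(veh_ids, samples$sample_id)] <- sol$assignment[veh_ids]
  wr(data.frame(sample_id = rownames(scores_all), scores_all,
                check.names = FALSE), "embedding_scores.tsv")
  wr(samples, "samples_annotated.tsv")

  # ---- per-cluster DE + meta + signature, primary drug ----
  clusters <- sort(unique(sol$assignment))
  primary <- run_drug_arm(counts, samples, cfg$drug_label, clusters, cfg)
  for (nm in names(primary$tables))
    if (!is.null(primary$tables[[nm]]))
      wr(primary$tables[[nm]], paste0("de_", cfg$drug_label, "_", nm, ".tsv"))
  wr(as.data.frame(primary$meta), paste0("meta_", cfg$drug_label, ".tsv"))
  wr(fc_distribution_summary(primary$profile), "fc_summary.tsv")
  wr(data.frame(contrast = rownames(primary$corr$r), primary$corr$r,
                check.names = FALSE), "correlations.tsv")
  if (!is.null(primary$network)) {
    wr(primary$network$nodes, "network_nodes.tsv")
    wr(primary$network$edges, "network_edges.tsv")
  }
  if (!is.null(primary$intersection)) {
    wr(data.frame(gene = primary$intersection$genes,
                  primary$intersection$signs,
                  concordant = primary$intersection$concordant,
                  check.names = FALSE), "cluster_intersection.tsv")
  }

  comparator <- NULL
  specific <- NULL
  if (!is.null(cfg$comparator_label)) {
    comparator <- run_drug_arm(counts, samples, cfg$comparator_label,
                               clusters, cfg)
    wr(as.data.frame(comparator$meta),
       paste0("meta_", cfg$comparator_label, ".tsv"))
    specific <- drug_specific_genes(primary$meta, comparator$meta)
    writeLines(c(output_header(seed, run_id), specific$specific),
               file.path(out_dir, "specific_genes.txt"))
  }

  # ---- external validation ----
  overlap <- NULL
  ext_de <- NULL
  if (!is.null(external)) {
    ext_de <- external_de(external$counts, external$samples,
                          drug_label = cfg$drug_label,
                          vehicle_label = cfg$vehicle_label,
                          shrink_weight = cfg$shrink_weight)
    wr(ext_de, "external_de.tsv")
    overlap <- cross_dataset_overlap(primary$meta, ext_de,
                                     external_fdr = cfg$external_fdr)
    wr(overlap$table, "overlap.tsv")
  }

  # ---- enrichment ----
  ora <- NULL
  collection <- NULL
  if (!is.null(cfg$gmt_path)) {
    collection <- read_gmt(cfg$gmt_path)
  } else if (!is.null(cfg$sim)) {
    collection <- random_gene_sets(rownames(counts),
                                   seed = stage_seed(seed, "gene_sets"))
  }
  if (!is.null(collection)) {
    q <- meta_deg_queries(primary$meta, down_lfc_max = cfg$down_lfc_max)
    ora <- list(up = run_ora(q$up, collection, q$universe),
                down = run_ora(q$down, collection, q$universe))
    wr(as.data.frame(ora$up), "ora_up.tsv")
    wr(as.data.frame(ora$down), "ora_down.tsv")
    if (!is.null(comparator)) {
      qc <- meta_deg_queries(comparator$meta, down_lfc_max = cfg$down_lfc_max)
      ora$comparator_up <- run_ora(qc$up, collection, qc$universe)
      ora$specific <- specificity_filter(ora$up, ora$comparator_up,
                                         fdr_max = cfg$ora_fdr_max,
                                         min_count = cfg$ora_min_count)
      wr(as.data.frame(ora$specific), "ora_specific.tsv")
    }
  }

  # ---- manifest ----
  files <- sort(list.files(out_dir, full.names = FALSE))
  files <- setdiff(files, "manifest.yaml")
  checksums <- as.list(tools::md5sum(file.path(out_dir, files)))
  names(checksums) <- files
  manifest <- list(run_id = run_id, seed = seed,
                   package_version = as.character(utils::packageVersion("stratmeta")),
                   k_selected = as.integer(k),
                   parameters = list(
                     var_frac = cfg$var_frac, n_pcs = n_pcs,
                     k_range = cfg$k_range,
                     min_cluster_size = cfg$min_cluster_size,
                     stability_B = cfg$stability_B,
                     ps_repetitions = cfg$ps_repetitions,
                     pac_iterations = cfg$pac_iterations,
                     subsample_frac = cfg$subsample_frac,
                     n_covariate_pcs = cfg$n_covariate_pcs,
                     criteria = unclass(cfg$criteria),
                     cluster_fdr_max = cfg$cluster_fdr_max,
                     external_fdr = cfg$external_fdr,
                     down_lfc_max = cfg$down_lfc_max),
                   checksums = checksums)
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))

  invisible(list(counts = counts, samples = samples, truth = truth,
                 embedding = emb, stability_report = report, k = k,
                 solution = sol, primary = primary, comparator = comparator,
                 specific = specific, external_de = ext_de, overlap = overlap,
                 ora = ora, manifest = manifest))
}
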