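#' Build a genes x contrasts fold-change profile
#'
#' @param tables list of [run_contrast()] tables.
#' @return numeric matrix of log2 fold-changes, genes x contrasts; entries
#'   missing where a gene was not estimated in a contrast.
#' @export
fc_profile <- function(tables) {
  tables <- Filter(Negate(is.null), tables)
  genes <- sort(unique(unlist(lapply(tables, `[[`, "gene"))))
  out <- matrix(NA_real_, length(genes), length(tables),
                dimnames = list(genes, vapply(tables, function(t_i)
                  t_i$contrast_id[1], character(1))))
  for (i in seq_along(tables)) {
    t_i <- tables[[i]]
    ok <- t_i$converged & is.finite(t_i$log2fc)
    out[t_i$gene[ok], i] <- t_i$log2fc[ok]
  }
  out
}

#' Pairwise Pearson correlations of fold-change profiles
#'
#' Each pair of contrasts is correlated over its pairwise-complete genes;
#' the 95 percent confidence interval uses the Fisher z transform,
#' `tanh(atanh(r) +/- 1.96 / sqrt(n - 3))`. Pairs with fewer than `min_n`
#' complete genes, or with a constant vector, are reported missing.
#'
#' @param profile matrix from [fc_profile()].
#' @param min_n minimum pairwise-complete genes (default 4).
#' @return list of matrices: `r`, `n`, `ci_low`, `ci_high`.
#' @export
fc_correlations <- function(profile, min_n = 4) {
  k <- ncol(profile)
  ids <- colnames(profile)
  r <- n <- lo <- hi <- matrix(NA_real_, k, k, dimnames = list(ids, ids))
  diag(r) <- 1; diag(n) <- colSums(!is.na(profile))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    ok <- stats::complete.cases(profile[, c(i, j)])
    nij <- sum(ok)
    n[i, j] <- n[j, i] <- nij
    if (nij < min_n) next
    x <- profile[ok, i]; y <- profile[ok, j]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) next
    rij <- stats::cor(x, y)
    r[i, j] <- r[j, i] <- rij
    if (nij > 3 && abs(rij) < 1) {
      zz <- atanh(rij); hw <- 1.96 / sqrt(nij - 3)
      lo[i, j] <- lo[j, i] <- tanh(zz - hw)
      hi[i, j] <- hi[j, i] <- tanh(zz + hw)
    }
  }
  list(r = r, n = n, ci_low = lo, ci_high = hi)
}

#' Correlation network with betweenness centrality
#'
#' Complete weighted graph over contrasts with edge weight `|r|`; shortest
#' -path betweenness is computed on the distance transform `1 - |r|`
#' (configurable). Missing correlations drop the edge.
#'
#' @param corr result of [fc_correlations()] (or a plain correlation
#'   matrix).
#' @param distance function mapping `|r|` to a non-negative path length
#'   (default `1 - |r|`).
#' @return list: `graph` (igraph object), `nodes` (data.frame with
#'   `id, betweenness`), `edges` (data.frame with `from, to, r, abs_r,
#'   ci_low, ci_high`).
#' @export
build_network <- function(corr, distance = function(a) 1 - a) {
  rmat <- if (is.list(corr)) corr$r else corr
  k <- nrow(rmat)
  if (k < 3) stop("network needs >= 3 contrasts")
  ids <- rownames(rmat)
  ef <- et <- character(0); er <- numeric(0)
  lo <- hi <- numeric(0)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    if (is.na(rmat[i, j])) next
    ef <- c(ef, ids[i]); et <- c(et, ids[j]); er <- c(er, rmat[i, j])
    lo <- c(lo, if (is.list(corr)) corr$ci_low[i, j] else NA_real_)
    hi <- c(hi, if (is.list(corr)) corr$ci_high[i, j] else NA_real_)
  }
  edges <- data.frame(from = ef, to = et, r = er, abs_r = abs(er),
                      ci_low = lo, ci_high = hi, stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = ids))
  d <- distance(abs(er))
  if (any(d < 0)) stop("distance transform produced negative lengths")
  btw <- igraph::betweenness(g, weights = d)
  nodes <- data.frame(id = ids, betweenness = as.numeric(btw[ids]),
                      stringsAsFactors = FALSE)
  list(graph = g, nodes = nodes, edges = edges)
}

#' Genes significant in every cluster-wise contrast
#'
#' Intersects the per-cluster FDR < `fdr_max` DEG lists and reports each
#' common gene's per-contrast effect sign pattern.
#'
#' @param tables list of [run_contrast()] tables (>= 2).
#' @param fdr_max per-contrast significance threshold.
#' @return list: `genes` (character), `signs` (genes x contrasts matrix of
#'   -1/0/1), `concordant` (logical per gene: all signs equal and nonzero).
#' @export
intersect_cluster_degs <- function(tables, fdr_max = 0.05) {
  tables <- Filter(Negate(is.null), tables)
  if (length(tables) < 2) stop("need >= 2 contrast tables")
  sets <- lapply(tables, function(t_i)
    t_i$gene[!is.na(t_i$fdr) & t_i$fdr < fdr_max])
  common <- Reduce(intersect, sets)
  common <- sort(common)
  signs <- matrix(0L, length(common), length(tables),
                  dimnames = list(common, vapply(tables, function(t_i)
                    t_i$contrast_id[1], character(1))))
  for (i in seq_along(tables)) {
    t_i <- tables[[i]]
    idx <- match(common, t_i$gene)
    signs[, i] <- sign(t_i$log2fc[idx])
  }
  concordant <- apply(signs, 1, function(s) all(s == s[1]) && s[1] != 0)
  list(genes = common, signs = signs,
       concordant = stats::setNames(as.logical(concordant), common))
}

#' Cross-dataset overlap of a retained meta-signature with external DE
#'
#' `shared` genes are those retained in the meta-analysis and significant
#' (FDR < `external_fdr`) in the external analysis; they are partitioned
#' into `concordant` (pooled and external effects agree in sign) and
#' `discordant`.
#'
#' @param meta a `meta_result` from [run_meta()].
#' @param external a [run_contrast()] / [external_de()] table.
#' @param external_fdr external significance threshold (default 0.05).
#' @return list: `shared`, `concordant`, `discordant` (character vectors),
#'   `table` (per-gene data.frame with both effects).
#' @export
cross_dataset_overlap <- function(meta, external, external_fdr = 0.05) {
  if (length(intersect(meta$gene, external$gene)) == 0)
    stop("meta and external tables share no gene ids")
  retained <- meta$gene[meta$retained]
  ext_sig <- external$gene[!is.na(external$fdr) & external$fdr < external_fdr]
  shared <- sort(intersect(retained, ext_sig))
  mi <- match(shared, meta$gene); ei <- match(shared, external$gene)
  tab <- data.frame(gene = shared,
                    pooled_log2fc = meta$pooled_log2fc[mi],
                    external_log2fc = external$log2fc[ei],
                    stringsAsFactors = FALSE)
  conc <- sign(tab$pooled_log2fc) == sign(tab$external_log2fc) &
    sign(tab$pooled_log2fc) != 0
  list(shared = shared,
       concordant = shared[conc],
       discordant = shared[!conc],
       table = tab)
}

#' Drug-specific genes between two meta-analyses
#'
#' Genes retained under the primary drug but not under the comparator, both
#' analyzed with identical retention criteria (a criteria mismatch is an
#' error to guard like-for-like comparison). The symmetric difference is
#' also reported.
#'
#' @param meta_primary,meta_comparator `meta_result` tables.
#' @return list: `specific` (primary-only retained genes),
#'   `comparator_specific`, `symmetric_difference`.
#' @export
drug_specific_genes <- function(meta_primary, meta_comparator) {
  ca <- attr(meta_primary, "criteria"); cb <- attr(meta_comparator, "criteria")
  if (!identical(unclass(ca), unclass(cb)))
    stop("retention criteria differ between the two meta-analyses")
  a <- meta_primary$gene[meta_primary$retained]
  b <- meta_comparator$gene[meta_comparator$retained]
  list(specific = sort(setdiff(a, b)),
       comparator_specific = sort(setdiff(b, a)),
       symmetric_difference = sort(union(setdiff(a, b), setdiff(b, a))))
}

#' Per-contrast fold-change distribution summary
#'
#' Data behind violin/IQR displays: per contrast, the number of estimated
#' genes, quartiles and IQR of the log2 fold-changes.
#'
#' @param profile matrix from [fc_profile()].
#' @return data.frame, one row per contrast.
#' @export
fc_distribution_summary <- function(profile) {
  do.call(rbind, lapply(colnames(profile), function(id) {
    x <- profile[, id]; x <- x[is.finite(x)]
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(contrast_id = id, n = length(x), q25 = q[1], median = q[2],
               q75 = q[3], iqr = q[3] - q[1], stringsAsFactors = FALSE)
  }))
}
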