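#' Retention criteria for pooled effects
#'
#' The four rules a gene must pass jointly to be retained as a meta-DEG:
#' an estimate in at least `min_contrasts` contrasts, at least
#' `min_sign_consistent` available estimates sharing the pooled estimate's
#' sign (exact zeros count as inconsistent), heterogeneity `I^2 <
#' i2_max_percent`, and two-sided meta p below `meta_p_max`. Applied
#' literally, the sign rule dominates the contrast-count rule for genes
#' measured in fewer than `min_sign_consistent` contrasts;
#' `relax_sign_to_available = TRUE` replaces the sign threshold by
#' `min(min_sign_consistent, n_available)` for sensitivity analyses.
#'
#' @param min_contrasts minimum number of contrasts with an estimate.
#' @param min_sign_consistent minimum number of sign-consistent estimates.
#' @param i2_max_percent heterogeneity ceiling (percent).
#' @param meta_p_max meta p-value threshold.
#' @param relax_sign_to_available relax the sign rule as described.
#' @return a `meta_criteria` list.
#' @export
meta_criteria <- function(min_contrasts = 2, min_sign_consistent = 4,
                          i2_max_percent = 50, meta_p_max = 0.05,
                          relax_sign_to_available = FALSE) {
  stopifnot(min_contrasts >= 1, min_sign_consistent >= 1,
            i2_max_percent > 0, meta_p_max > 0)
  structure(list(min_contrasts = min_contrasts,
                 min_sign_consistent = min_sign_consistent,
                 i2_max_percent = i2_max_percent,
                 meta_p_max = meta_p_max,
                 relax_sign_to_available = relax_sign_to_available),
            class = "meta_criteria")
}

#' Inverse-variance-weighted fixed-effect pooling
#'
#' Weights `w_i = se_i^-2`; pooled effect `sum(w b) / sum(w)`, pooled
#' standard error `sum(w)^-1/2`, `z = b / se`, two-sided normal p.
#'
#' @param b effect estimates (at least one).
#' @param se positive standard errors, same length.
#' @return list: `b`, `se`, `z`, `p`.
#' @export
fixed_effect_pool <- function(b, se) {
  if (length(b) == 0) stop("need at least one estimate")
  if (length(b) != length(se)) stop("b and se lengths differ")
  if (any(!is.finite(se)) || any(se <= 0)) stop("standard errors must be positive")
  w <- se^-2
  pooled <- sum(w * b) / sum(w)
  pse <- sum(w)^-0.5
  z <- pooled / pse
  list(b = pooled, se = pse, z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Cochran's Q and I-squared heterogeneity
#'
#' `Q = sum(w_i (b_i - pooled)^2)` with `w_i = se_i^-2`;
#' `I^2 = max(0, (Q - (n - 1)) / Q) * 100`, defined as 0 when `Q = 0`.
#'
#' @param b effect estimates (at least two).
#' @param se positive standard errors.
#' @param pooled the fixed-effect pooled estimate.
#' @return list: `Q`, `i2_percent`.
#' @export
heterogeneity <- function(b, se, pooled) {
  if (length(b) < 2) stop("heterogeneity needs >= 2 estimates")
  w <- se^-2
  Q <- sum(w * (b - pooled)^2)
  i2 <- if (Q == 0) 0 else max(0, (Q - (length(b) - 1)) / Q) * 100
  list(Q = Q, i2_percent = i2)
}

# evaluate the four retention flags for one gene
apply_criteria_row <- function(n_contrasts, n_sign_consistent, i2, meta_p,
                               criteria) {
  sign_needed <- if (isTRUE(criteria$relax_sign_to_available))
    min(criteria$min_sign_consistent, n_contrasts) else
      criteria$min_sign_consistent
  c1 <- n_contrasts >= criteria$min_contrasts
  c2 <- n_sign_consistent >= sign_needed
  c3 <- !is.na(i2) && i2 < criteria$i2_max_percent
  c4 <- !is.na(meta_p) && meta_p < criteria$meta_p_max
  c(pass_min_contrasts = c1, pass_sign_consistency = c2,
    pass_low_heterogeneity = c3, pass_meta_p = c4,
    retained = c1 && c2 && c3 && c4)
}

#' Classify retained genes against per-cluster DEG lists
#'
#' A retained gene significant in no single-cluster comparison is a
#' "meta-only" DEG; retained and in at least one cluster list,
#' "meta-overlapping"; everything else, "not-retained".
#'
#' @param retained logical vector, names = gene ids.
#' @param cluster_sets list of character vectors of per-cluster significant
#'   genes (FDR < 0.05 in that contrast).
#' @return character vector of classes, named by gene.
#' @export
classify_meta_degs <- function(retained, cluster_sets) {
  in_any <- names(retained) %in% unique(unlist(cluster_sets))
  cls <- ifelse(!retained, "not-retained",
                ifelse(in_any, "meta-overlapping", "meta-only"))
  stats::setNames(cls, names(retained))
}

#' Pool per-cluster differential-expression tables
#'
#' Aligns genes across the per-contrast tables (a gene absent from a
#' contrast, or non-converged there, simply contributes no estimate),
#' applies fixed-effect pooling and heterogeneity per gene, evaluates the
#' retention criteria, and classifies retained genes against the
#' per-cluster FDR < 0.05 lists. Genes with fewer than two estimates are
#' kept in the output with their flags rather than dropped. The result is
#' invariant to the order of the input tables.
#'
#' @param tables list of [run_contrast()] tables (NULL entries, e.g. skipped
#'   contrasts, are removed).
#' @param criteria a [meta_criteria()].
#' @param cluster_fdr_max FDR threshold defining per-cluster DEG lists
#'   (default 0.05).
#' @return data.frame of class `meta_result`: `gene, pooled_log2fc,
#'   pooled_se, z, meta_p, Q, i2_percent, n_contrasts, n_sign_consistent`,
#'   the four criterion flags, `retained`, `class`. The criteria are stored
#'   in `attr(, "criteria")`.
#' @export
run_meta <- function(tables, criteria = meta_criteria(),
                     cluster_fdr_max = 0.05) {
  tables <- Filter(Negate(is.null), tables)
  if (length(tables) < 2) stop("meta-analysis needs >= 2 contrast tables")
  genes <- sort(unique(unlist(lapply(tables, `[[`, "gene"))))
  if (length(genes) == 0) stop("no genes shared across contrast tables")
  k <- length(tables)
  B <- SE <- matrix(NA_real_, length(genes), k,
                    dimnames = list(genes, NULL))
  ids <- character(k)
  for (i in seq_len(k)) {
    t_i <- tables[[i]]
    ok <- t_i$converged & is.finite(t_i$log2fc) & is.finite(t_i$se) & t_i$se > 0
    B[t_i$gene[ok], i] <- t_i$log2fc[ok]
    SE[t_i$gene[ok], i] <- t_i$se[ok]
    ids[i] <- t_i$contrast_id[1]
  }
  # order-invariance: align contrast columns by id
  ord <- order(ids)
  B <- B[, ord, drop = FALSE]; SE <- SE[, ord, drop = FALSE]
  cluster_sets <- lapply(tables, function(t_i)
    t_i$gene[!is.na(t_i$fdr) & t_i$fdr < cluster_fdr_max])

  n_g <- length(genes)
  pooled <- pse <- z <- meta_p <- Q <- i2 <- rep(NA_real_, n_g)
  n_contrasts <- n_cons <- integer(n_g)
  flags <- matrix(NA, n_g, 5,
                  dimnames = list(NULL, c("pass_min_contrasts",
                                          "pass_sign_consistency",
                                          "pass_low_heterogeneity",
                                          "pass_meta_p", "retained")))
  for (g in seq_len(n_g)) {
    av <- which(!is.na(B[g, ]))
    n_contrasts[g] <- length(av)
    if (length(av) >= 1) {
      fe <- fixed_effect_pool(B[g, av], SE[g, av])
      pooled[g] <- fe$b; pse[g] <- fe$se; z[g] <- fe$z; meta_p[g] <- fe$p
      n_cons[g] <- sum(sign(B[g, av]) == sign(fe$b) & B[g, av] != 0)
      if (length(av) >= 2) {
        het <- heterogeneity(B[g, av], SE[g, av], fe$b)
        Q[g] <- het$Q; i2[g] <- het$i2_percent
      }
    }
    flags[g, ] <- apply_criteria_row(n_contrasts[g], n_cons[g], i2[g],
                                     meta_p[g], criteria)
  }
  retained <- stats::setNames(as.logical(flags[, "retained"]), genes)
  cls <- classify_meta_degs(retained, cluster_sets)
  out <- data.frame(gene = genes, pooled_log2fc = pooled, pooled_se = pse,
                    z = z, meta_p = meta_p, Q = Q, i2_percent = i2,
                    n_contrasts = n_contrasts, n_sign_consistent = n_cons,
                    flags, retained = retained, class = unname(cls),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("meta_result", "data.frame")
  attr(out, "criteria") <- criteria
  attr(out, "contrast_ids") <- ids[ord]
  out
}
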