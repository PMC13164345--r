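#' Upper-tail hypergeometric p-value
#'
#' `P(X >= k)` when drawing `n` genes from a universe of `N` containing `K`
#' set members; evaluated in log space via the upper-tail CDF for numerical
#' stability.
#'
#' @param k observed overlap.
#' @param K set size within the universe.
#' @param n query size.
#' @param N universe size.
#' @return p-value in (0, 1].
#' @export
hypergeom_p <- function(k, K, n, N) {
  if (any(c(k, K, n, N) < 0) || k > min(K, n) || K > N || n > N)
    stop("inconsistent hypergeometric arguments")
  if (k == 0) return(1.0)
  exp(stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE))
}

#' Hypergeometric over-representation analysis
#'
#' Tests each term of a gene-set collection for over-representation in a
#' query list against a universe (conventionally the genes tested in the
#' source analysis). Query genes outside the universe are an error; term
#' members are first intersected with the universe, and only terms with at
#' least one universe member are tested. BH adjustment runs across tested
#' terms. Direction-split analyses (up vs down) are separate calls on the
#' corresponding queries.
#'
#' @param query character vector of genes (subset of `universe`).
#' @param collection gene-set collection as from [read_gmt()].
#' @param universe character vector of background genes.
#' @return data.frame of class `enrichment_table`, sorted by p: `term_id,
#'   description, k, K, n, N, gene_ratio, p, fdr, genes` (overlap ids,
#'   `;`-separated).
#' @export
run_ora <- function(query, collection, universe) {
  universe <- unique(universe)
  query <- unique(query)
  outside <- setdiff(query, universe)
  if (length(outside) > 0)
    stop("query genes outside the universe: ", paste(outside, collapse = ", "))
  N <- length(universe); n <- length(query)
  rows <- lapply(names(collection), function(id) {
    members <- intersect(collection[[id]]$genes, universe)
    if (length(members) == 0) return(NULL)
    ov <- intersect(query, members)
    data.frame(term_id = id, description = collection[[id]]$description,
               k = length(ov), K = length(members), n = n, N = N,
               gene_ratio = if (n > 0) length(ov) / n else NA_real_,
               p = hypergeom_p(length(ov), length(members), n, N),
               genes = paste(sort(ov), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0 || n == 0) {
    out <- data.frame(term_id = character(0), description = character(0),
                      k = integer(0), K = integer(0), n = integer(0),
                      N = integer(0), gene_ratio = numeric(0), p = numeric(0),
                      fdr = numeric(0), genes = character(0),
                      stringsAsFactors = FALSE)
  } else {
    out <- do.call(rbind, rows)
    out$fdr <- bh_adjust(out$p)
    out <- out[order(out$p, out$term_id), ]
    out <- out[, c("term_id", "description", "k", "K", "n", "N",
                   "gene_ratio", "p", "fdr", "genes")]
    rownames(out) <- NULL
  }
  class(out) <- c("enrichment_table", "data.frame")
  attr(out, "collection_terms") <- sort(names(collection))
  out
}

#' Comparator-specificity filter on enrichment tables
#'
#' Terms significant in the primary table (`fdr < fdr_max` and overlap
#' `k >= min_count`) that are not significant in the comparator table
#' (absence from the comparator counts as not significant). Both tables
#' must come from the same collection. The comparator's statistics are
#' reported side by side; `comparator_fdr_annotation` adds a flag column for
#' a secondary, looser reporting threshold without affecting the filter.
#'
#' @param table_primary,table_comparator `enrichment_table`s from [run_ora()].
#' @param fdr_max significance threshold (default 0.05).
#' @param min_count minimum overlap count in the primary table (default 10).
#' @param comparator_fdr_annotation optional secondary threshold; when given,
#'   a logical column `comparator_fdr_above_<x>` is added.
#' @return data.frame of primary-specific terms with comparator columns.
#' @export
specificity_filter <- function(table_primary, table_comparator,
                               fdr_max = 0.05, min_count = 10,
                               comparator_fdr_annotation = NULL) {
  ta <- attr(table_primary, "collection_terms")
  tb <- attr(table_comparator, "collection_terms")
  if (!identical(ta, tb))
    stop("enrichment tables come from different gene-set collections")
  sig_a <- !is.na(table_primary$fdr) & table_primary$fdr < fdr_max &
    table_primary$k >= min_count
  keep <- table_primary[sig_a, , drop = FALSE]
  bi <- match(keep$term_id, table_comparator$term_id)
  comp_fdr <- table_comparator$fdr[bi]
  comp_sig <- !is.na(comp_fdr) & comp_fdr < fdr_max
  out <- keep[!comp_sig, , drop = FALSE]
  out$comparator_fdr <- comp_fdr[!comp_sig]
  out$comparator_k <- table_comparator$k[bi][!comp_sig]
  if (!is.null(comparator_fdr_annotation)) {
    out[[paste0("comparator_fdr_above_", comparator_fdr_annotation)]] <-
      is.na(out$comparator_fdr) | out$comparator_fdr > comparator_fdr_annotation
  }
  rownames(out) <- NULL
  out
}

#' Direction-split query lists from a meta-analysis
#'
#' Upregulated query: retained genes with positive pooled effect.
#' Downregulated query: retained genes with pooled effect below
#' `down_lfc_max` (default -1.0), the stricter magnitude filter used for
#' downregulated-signature enrichment.
#'
#' @param meta a `meta_result`.
#' @param down_lfc_max log2 fold-change ceiling for the down query.
#' @return list: `up`, `down` (character vectors), `universe` (all genes in
#'   the meta table).
#' @export
meta_deg_queries <- function(meta, down_lfc_max = -1.0) {
  ret <- meta[meta$retained & !is.na(meta$pooled_log2fc), , drop = FALSE]
  list(up = sort(ret$gene[ret$pooled_log2fc > 0]),
       down = sort(ret$gene[ret$pooled_log2fc < down_lfc_max]),
       universe = sort(meta$gene))
}
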