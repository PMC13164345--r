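#' Validate a gene-by-sample count matrix
#'
#' A count matrix is an integer-valued, non-negative matrix with unique gene
#' ids as rownames and unique sample ids as colnames, and at least two
#' samples. Missing values are not allowed; inputs with `NA` fail fast.
#'
#' @param counts numeric matrix, genes in rows, samples in columns.
#' @return the validated matrix (storage mode integer), invisibly usable.
#' @export
validate_counts <- function(counts) {
  if (!is.matrix(counts)) stop("counts must be a matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate gene ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  if (ncol(counts) < 2) stop("count matrix needs at least 2 samples")
  bad <- which(is.na(counts) | counts < 0 | counts != round(counts), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf(
      "invalid count at gene '%s', sample '%s': %s (counts must be non-negative integers)",
      rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]],
      format(counts[bad[1, 1], bad[1, 2]])))
  }
  storage.mode(counts) <- "integer"
  counts
}

# Header comment recording provenance; prefixed lines are skipped on read.
output_header <- function(seed = NULL, run_id = NULL) {
  v <- as.character(utils::packageVersion("stratmeta"))
  h <- sprintf("# stratmeta %s", v)
  if (!is.null(seed)) h <- paste0(h, "; seed=", seed)
  if (!is.null(run_id)) h <- paste0(h, "; run=", run_id)
  h
}

#' Read a count matrix from TSV or MatrixMarket
#'
#' TSV layout: comment lines starting with `#`, then a header row
#' `gene<TAB>sample1<TAB>...`, one gene per row. MatrixMarket input expects
#' `<path>` plus `<path>.rownames` / `<path>.colnames` sidecar files holding
#' one id per line.
#'
#' Duplicated ids and negative, missing or non-integer entries are errors;
#' duplicates are never collapsed.
#'
#' @param path file path.
#' @param format `"tsv"` or `"mtx"`.
#' @return validated integer matrix, genes x samples.
#' @export
read_counts <- function(path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tsv") {
    df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                            stringsAsFactors = FALSE)
    if (ncol(df) < 3) stop("count TSV needs a gene column and >=2 samples")
    genes <- as.character(df[[1]])
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- genes
  } else {
    m <- as.matrix(Matrix::readMM(path))
    rn <- readLines(paste0(path, ".rownames"))
    cn <- readLines(paste0(path, ".colnames"))
    if (length(rn) != nrow(m) || length(cn) != ncol(m))
      stop("sidecar id files do not match matrix dimensions")
    dimnames(m) <- list(rn, cn)
  }
  validate_counts(m)
}

#' Write a count matrix
#'
#' @param counts validated count matrix.
#' @param path output path.
#' @param format `"tsv"` or `"mtx"` (MTX writes `.rownames`/`.colnames`
#'   sidecars next to the matrix file).
#' @param seed,run_id optional provenance recorded in the header comment.
#' @export
write_counts <- function(counts, path, format = c("tsv", "mtx"),
                         seed = NULL, run_id = NULL) {
  format <- match.arg(format)
  counts <- validate_counts(counts)
  if (format == "tsv") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(output_header(seed, run_id), con)
    writeLines(paste(c("gene", colnames(counts)), collapse = "\t"), con)
    utils::write.table(data.frame(gene = rownames(counts), counts,
                                  check.names = FALSE),
                       con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  } else {
    Matrix::writeMM(Matrix::Matrix(counts, sparse = TRUE), path)
    writeLines(rownames(counts), paste0(path, ".rownames"))
    writeLines(colnames(counts), paste0(path, ".colnames"))
  }
  invisible(path)
}

#' Read / write a sample metadata table
#'
#' Columns: `sample_id`, `treatment`, then optional `cluster`,
#' `latent_subgroup` and covariate score columns (e.g. `PC1..PC3`).
#'
#' @param path file path.
#' @return data.frame with one row per sample.
#' @export
read_samples <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!all(c("sample_id", "treatment") %in% names(df)))
    stop("sample table needs 'sample_id' and 'treatment' columns")
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids in sample table")
  df
}

#' @rdname read_samples
#' @param samples sample data.frame.
#' @param seed,run_id optional provenance recorded in the header comment.
#' @export
write_samples <- function(samples, path, seed = NULL, run_id = NULL) {
  write_result_table(samples, path, seed = seed, run_id = run_id)
}

#' Write a result table as TSV with a provenance header
#'
#' @param df data.frame.
#' @param path output path.
#' @param seed,run_id optional provenance recorded in the header comment.
#' @export
write_result_table <- function(df, path, seed = NULL, run_id = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(output_header(seed, run_id), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a result table written by [write_result_table()]
#' @param path file path.
#' @export
read_result_table <- function(path) {
  utils::read.delim(path, comment.char = "#", check.names = FALSE,
                    stringsAsFactors = FALSE)
}

#' Log-transform normalized counts
#'
#' Computes `log2(count / size_factor + 1)` entrywise, the transform used for
#' all exploratory steps (variable-gene selection, PCA, clustering). Testing
#' is done on raw counts by the NB model, never on these values.
#'
#' @param counts count matrix.
#' @param size_factors positive per-sample scaling factors, one per column
#'   (recycled scalar allowed).
#' @return real matrix, same dimensions.
#' @export
log_transform <- function(counts, size_factors = 1) {
  if (length(size_factors) == 1) size_factors <- rep(size_factors, ncol(counts))
  if (length(size_factors) != ncol(counts))
    stop("need one size factor per sample")
  if (any(!is.finite(size_factors)) || any(size_factors <= 0))
    stop("size factors must be positive and finite")
  log2(sweep(counts, 2, size_factors, "/") + 1)
}

#' Read a gene-set collection in GMT format
#'
#' One set per line: `term<TAB>description<TAB>member1<TAB>member2...`.
#' Blank member fields (e.g. from trailing tabs) are dropped.
#'
#' @param path file path.
#' @return named list; each element has `description` and `genes`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop("GMT line ", i, " has fewer than 3 fields")
    genes <- f[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0) stop("GMT line ", i, " has an empty member list")
    if (f[1] %in% names(out)) stop("duplicate GMT term id: ", f[1])
    out[[f[1]]] <- list(description = f[2], genes = genes)
  }
  out
}

#' Write a gene-set collection in GMT format
#' @param collection named list as returned by [read_gmt()].
#' @param path file path.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection), function(id) {
    paste(c(id, collection[[id]]$description, collection[[id]]$genes),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
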