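# Count normalization to log2 RPKM and minimum-subtracted relative profiles.

#' Per-sample library normalization factors
#'
#' Holds the three quantities used to normalize counts from a competitively
#' mapped metatranscriptome: the raw sequencing depth (total unmerged reads),
#' the number of merged reads surviving rRNA filtering, and the fraction of
#' those that aligned to the target genome. The effective library size is
#' `merged_filtered_reads * mapped_fraction`; total unmerged reads are kept
#' as provenance for cross-run comparison.
#'
#' @param sample_id character vector of sample names.
#' @param total_unmerged_reads,merged_filtered_reads positive counts.
#' @param mapped_fraction proportion in (0, 1].
#' @return a data frame of class `library_factors` with one row per sample
#'   and an `n_eff` column.
#' @export
library_factors <- function(sample_id, total_unmerged_reads,
                            merged_filtered_reads, mapped_fraction) {
  df <- data.frame(sample_id = as.character(sample_id),
                   total_unmerged_reads = as.numeric(total_unmerged_reads),
                   merged_filtered_reads = as.numeric(merged_filtered_reads),
                   mapped_fraction = as.numeric(mapped_fraction),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id", call. = FALSE)
  if (any(df$merged_filtered_reads < 1)) {
    stop("merged_filtered_reads must be >= 1", call. = FALSE)
  }
  if (any(df$mapped_fraction <= 0 | df$mapped_fraction > 1)) {
    stop("mapped_fraction must be in (0, 1]", call. = FALSE)
  }
  df$n_eff <- df$merged_filtered_reads * df$mapped_fraction
  class(df) <- c("library_factors", "data.frame")
  df
}

#' Convert raw gene counts to log2 RPKM
#'
#' RPKM here is reads per kilobase of gene per million *effective* library
#' reads, where the effective library `N_eff` for a sample is the number of
#' merged, rRNA-filtered reads multiplied by the fraction mapping to the
#' target genome. A pseudocount (default 1 read) keeps the log2 defined at
#' zero counts:
#'
#' `log2RPKM = log2( (count + pseudocount) * 1e9 / (length_bp * N_eff) )`
#'
#' @param counts non-negative integer matrix, genes x samples, with
#'   dimnames.
#' @param factors a [library_factors()] table covering every sample.
#' @param gene_lengths named numeric vector of gene lengths in bp (>= 1),
#'   covering every gene.
#' @param pseudocount reads added to every count before scaling (default 1).
#' @return a numeric matrix of log2 RPKM with the input dimnames and
#'   attributes `pseudocount` and `library_factors` (provenance, including
#'   total unmerged reads).
#' @export
compute_log2_rpkm <- function(counts, factors, gene_lengths, pseudocount = 1) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)),
            !is.null(colnames(counts)))
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  assert_scalar_number(pseudocount, "pseudocount", lower = 0)
  idx <- match(colnames(counts), factors$sample_id)
  if (anyNA(idx)) {
    stop("missing library factors for sample(s): ",
         paste(colnames(counts)[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  len <- gene_lengths[rownames(counts)]
  if (anyNA(len)) {
    stop("missing gene length for: ",
         paste(rownames(counts)[is.na(len)], collapse = ", "), call. = FALSE)
  }
  if (any(len < 1)) stop("gene lengths must be >= 1 bp", call. = FALSE)
  n_eff <- factors$n_eff[idx]
  if (any(n_eff <= 0)) stop("effective library size must be positive", call. = FALSE)
  rpkm <- sweep((counts + pseudocount) * 1e9, 1L, as.numeric(len), "/")
  rpkm <- sweep(rpkm, 2L, n_eff, "/")
  out <- log2(rpkm)
  attr(out, "pseudocount") <- pseudocount
  attr(out, "library_factors") <- factors[idx, , drop = FALSE]
  out
}

#' Minimum-subtracted relative expression profile
#'
#' Subtracts each gene's minimum over the cycle from its per-timepoint
#' values so that profiles report induction relative to the gene's own
#' baseline (delta log2 RPKM); the minimum entry is exactly 0. Idempotent
#' and invariant to adding a constant.
#'
#' @param values a numeric vector (one gene) or matrix (genes x timepoints)
#'   of finite log2 RPKM values; at least 2 timepoints.
#' @return object of the same shape with per-gene minima subtracted.
#' @export
relative_to_min <- function(values) {
  if (is.matrix(values)) {
    if (ncol(values) < 2L) stop("need >= 2 timepoints", call. = FALSE)
    if (!all(is.finite(values))) stop("non-finite expression values", call. = FALSE)
    return(sweep(values, 1L, apply(values, 1L, min), "-"))
  }
  if (length(values) < 2L) stop("need >= 2 timepoints", call. = FALSE)
  if (!all(is.finite(values))) stop("non-finite expression values", call. = FALSE)
  values - min(values)
}

#' Pearson correlation with an explicit undefined sentinel
#'
#' Standard product-moment correlation, except that a constant series makes
#' the correlation undefined and returns `NA_real_` rather than 0 or an
#' error; callers (e.g. the operon caller) decide how to treat it.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return correlation in `[-1, 1]`, or `NA_real_` when either series is
#'   constant.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("series lengths differ", call. = FALSE)
  if (length(x) < 3L) stop("need series of length >= 3", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("non-finite values in series", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y, method = "pearson")
}

#' Read a gene count table from TSV
#'
#' First column is the gene id; remaining columns are per-sample counts.
#'
#' @param path TSV file path.
#' @return an integer matrix with gene ids as rownames.
#' @export
read_count_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "numeric"
  rownames(m) <- as.character(df[[1]])
  m
}

#' Read per-sample library factors from TSV
#'
#' Expects columns `sample_id`, `total_unmerged_reads`,
#' `merged_filtered_reads`, `mapped_fraction`.
#'
#' @param path TSV file path.
#' @return a [library_factors()] table.
#' @export
read_factors_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  library_factors(df$sample_id, df$total_unmerged_reads,
                  df$merged_filtered_reads, df$mapped_fraction)
}

#' Write an expression matrix to TSV (6-decimal values)
#'
#' @param expr numeric matrix with dimnames.
#' @param path output TSV path.
#' @return invisibly, `path`.
#' @export
write_expression_tsv <- function(expr, path) {
  df <- data.frame(gene_id = rownames(expr),
                   format(round(expr, 6), nsmall = 6, trim = TRUE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
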