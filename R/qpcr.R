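# RT-qPCR analysis: primer/amplicon arithmetic, reference-gene
# normalization, fold change, verdicts, and the no-RT contamination check.

#' RT-qPCR primer pairs for the UW-LDO-IC respiration panel
#'
#' The primer coordinate table for the six respiration genes plus the rpoN
#' reference assayed in the anaerobic/microaerobic EBPR enrichment:
#' forward/reverse target-site coordinates on the gene (1-based) and the
#' declared amplicon length. Two rows (narG and rpoN) are internally
#' inconsistent between coordinates and declared length;
#' [check_primer_table()] surfaces this.
#'
#' @return data frame with columns `gene_id`, `gene_length_bp`,
#'   `forward_start`, `forward_end`, `forward_seq`, `reverse_start`,
#'   `reverse_end`, `reverse_seq`, `declared_amplicon_bp`.
#' @export
respiration_primer_panel <- function() {
  data.frame(
    gene_id = c("nirS-1", "narG", "norZ", "nosZ", "ccoN", "ctaD", "rpoN"),
    gene_length_bp = c(1739L, 3819L, 2282L, 2297L, 1428L, 1611L, 1440L),
    forward_start = c(147L, 336L, 1846L, 591L, 241L, 816L, 153L),
    forward_end = c(164L, 353L, 1864L, 616L, 260L, 834L, 170L),
    forward_seq = c("GTCGGCGATCGCGCAAT", "CCGATGGTTCGCGGTCA",
                    "CTTTGGGCTGGGTGGGT", "AAGAAATTCGAGCCACTAGAGGAAT",
                    "CCTGCCATACGCGACTTTT", "TCGCATGTCATCCCTGCC",
                    "GAGTACGCGCGGACGGA"),
    reverse_start = c(291L, 403L, 2204L, 935L, 344L, 932L, 594L),
    reverse_end = c(311L, 424L, 2221L, 954L, 365L, 951L, 611L),
    reverse_seq = c("AGCGTTTTGTCCGTAGTCAGA", "CGGACTCGACGATCGATGTCC",
                    "CGCGATCGGCGCTCAAAC", "AACATCCAGCGGCAATACG",
                    "TCGGCATACTCTTTGGACTGG", "GGTCAGCGGAATACCGGTC",
                    "TGTGCGCTGCGAGCCCC"),
    declared_amplicon_bp = c(164L, 91L, 375L, 363L, 124L, 135L, 487L),
    stringsAsFactors = FALSE
  )
}

#' Amplicon length from primer target-site coordinates
#'
#' Uses the convention `reverse_end - forward_start` (not `+ 1`), the
#' coordinate arithmetic under which a primer's printed span equals its
#' length; this reproduces the declared amplicon length for the five
#' internally consistent panel rows. A mismatch against a declared length
#' is for the caller to report ([check_primer_table()]), never fatal.
#'
#' @param forward_start,reverse_end 1-based coordinates on the target gene;
#'   vectors are allowed.
#' @return amplicon length(s) in bp.
#' @export
amplicon_length <- function(forward_start, reverse_end) {
  if (any(reverse_end <= forward_start)) {
    stop("reverse_end must be greater than forward_start", call. = FALSE)
  }
  as.integer(reverse_end - forward_start)
}

#' Check a primer table for coordinate/amplicon consistency
#'
#' @param primers data frame in the layout of [respiration_primer_panel()].
#' @return the table with added `computed_amplicon_bp` and `consistent`
#'   columns; inconsistent rows are reported via a message.
#' @export
check_primer_table <- function(primers) {
  primers$computed_amplicon_bp <- amplicon_length(primers$forward_start,
                                                  primers$reverse_end)
  primers$consistent <- primers$computed_amplicon_bp ==
    primers$declared_amplicon_bp
  if (any(!primers$consistent)) {
    message("declared vs computed amplicon mismatch for: ",
            paste(primers$gene_id[!primers$consistent], collapse = ", "))
  }
  primers
}

#' Normalize a target qPCR series by a reference gene
#'
#' Elementwise `target / reference` copy-number ratio, the standard
#' reference-gene (e.g. rpoN) normalization.
#'
#' @param target,reference positive numeric vectors with identical
#'   timepoint names.
#' @return the ratio series (named like the inputs).
#' @export
normalize_to_reference <- function(target, reference) {
  if (length(target) != length(reference) ||
      !identical(names(target), names(reference))) {
    stop("target and reference timepoints do not match", call. = FALSE)
  }
  if (any(reference <= 0)) stop("reference copies must be positive", call. = FALSE)
  if (any(target <= 0)) stop("target copies must be positive", call. = FALSE)
  target / reference
}

#' Normalize a series to its minimum across the cycle
#'
#' Divides elementwise by the series minimum so the minimum entry is
#' exactly 1; scale-invariant.
#'
#' @param series positive numeric vector.
#' @return the min-normalized series.
#' @export
relative_to_min_copies <- function(series) {
  if (any(!is.finite(series)) || any(series <= 0)) {
    stop("series must be positive and finite", call. = FALSE)
  }
  series / min(series)
}

#' Max/min fold change of a series
#'
#' @param series positive numeric vector.
#' @return `max(series) / min(series)` (>= 1).
#' @export
fold_change <- function(series) {
  if (any(series <= 0)) stop("series must be positive", call. = FALSE)
  max(series) / min(series)
}

#' Cross-validate a qPCR series against an RNA-seq profile
#'
#' Implements the narrative rule set: when the qPCR fold change is below
#' `fc_min` the gene shows no significant change and the correlation is
#' reported but not judged; otherwise the profile is `validated` iff the
#' Pearson correlation between log2 of the normalized qPCR series and the
#' RNA-seq delta log2 RPKM profile exceeds `r_min`, and `not_validated`
#' otherwise. The verdict is invariant to multiplicative rescaling of the
#' qPCR series.
#'
#' @param qpcr positive numeric vector: reference-normalized (and
#'   optionally min-normalized) qPCR series.
#' @param rnaseq numeric vector: the gene's delta log2 RPKM profile at the
#'   matching timepoints.
#' @param r_min correlation threshold (default 0.5).
#' @param fc_min fold-change threshold for a significant change
#'   (default 2).
#' @return list of class `validation_result`: `pearson_r`, `fold_change`,
#'   `verdict` in `{validated, no_significant_change, not_validated}`.
#' @export
validate_qpcr <- function(qpcr, rnaseq, r_min = 0.5, fc_min = 2) {
  if (length(qpcr) != length(rnaseq)) {
    stop("qPCR and RNA-seq series lengths differ", call. = FALSE)
  }
  fc <- fold_change(qpcr)
  r <- pearson(log2(qpcr), rnaseq)
  verdict <- if (fc < fc_min) {
    "no_significant_change"
  } else if (!is.na(r) && r > r_min) {
    "validated"
  } else {
    "not_validated"
  }
  structure(list(pearson_r = r, fold_change = fc, verdict = verdict),
            class = "validation_result")
}

#' Mean CT difference between cDNA and no-RT control reactions
#'
#' The no-reverse-transcription control (NRTC) bounds genomic-DNA
#' contamination: the mean of `ct_nrtc - ct_cdna` over paired reactions
#' should be large (late NRTC amplification). A mean below the advisory
#' threshold raises a contamination advisory flag.
#'
#' @param ct_cdna,ct_nrtc paired numeric vectors of threshold cycles.
#' @param advisory_threshold cycles below which contamination is flagged
#'   (default 5).
#' @return list with `mean_delta_ct` and `contamination_advisory`
#'   (logical).
#' @export
nrtc_delta_ct <- function(ct_cdna, ct_nrtc, advisory_threshold = 5) {
  if (length(ct_cdna) != length(ct_nrtc) || length(ct_cdna) == 0L) {
    stop("cDNA and NRTC CT vectors must be paired", call. = FALSE)
  }
  m <- mean(ct_nrtc - ct_cdna)
  list(mean_delta_ct = m, contamination_advisory = m < advisory_threshold)
}

#' Read a long-format qPCR series TSV (gene, timepoint, copies)
#'
#' @param path TSV file path.
#' @return a named list of numeric copy-number vectors, one per gene, with
#'   timepoint names.
#' @export
read_qpcr_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("gene", "timepoint", "copies") %in% names(df)))
  split_df <- split(df, df$gene)
  lapply(split_df, function(d) stats::setNames(d$copies, d$timepoint))
}

#' Write a validation report (gene, r, fold_change, verdict) to TSV
#'
#' @param results named list of `validation_result` objects.
#' @param path output TSV path.
#' @return invisibly, `path`.
#' @export
write_validation_tsv <- function(results, path) {
  df <- data.frame(gene = names(results),
                   r = vapply(results, function(x) x$pearson_r, numeric(1)),
                   fold_change = vapply(results, function(x) x$fold_change,
                                        numeric(1)),
                   verdict = vapply(results, function(x) x$verdict, ""),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
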