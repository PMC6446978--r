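# Operon calling from strand, intergenic distance, and co-expression.

#' Operon-calling configuration
#'
#' Defaults follow the rule set used for anaerobic/microaerobic EBPR
#' transcriptomes: adjacent same-strand genes are merged when their
#' expression profiles correlate at Pearson >= 0.7 and the intergenic
#' region between them is 1,000 bp or fewer.
#'
#' @param min_pearson minimum Pearson correlation between profiles
#'   (default 0.7).
#' @param max_gap_bp maximum intergenic gap in bp (default 1000);
#'   overlapping genes (negative gap) always satisfy the gap rule.
#' @param chaining `"adjacent"` (default) requires each gene to correlate
#'   with its predecessor only; `"all_pairs"` requires correlation with
#'   every current member.
#' @return a list of class `operon_config`.
#' @export
operon_config <- function(min_pearson = 0.7, max_gap_bp = 1000L,
                          chaining = c("adjacent", "all_pairs")) {
  assert_scalar_number(min_pearson, "min_pearson", lower = -1, upper = 1)
  assert_scalar_number(max_gap_bp, "max_gap_bp", lower = 0)
  structure(list(min_pearson = min_pearson,
                 max_gap_bp = as.integer(max_gap_bp),
                 chaining = match.arg(chaining)),
            class = "operon_config")
}

#' Partition a genome's genes into putative operons
#'
#' Scans genes in genomic order per contig and merges gene i+1 into the
#' current operon iff it lies on the same contig and strand, the intergenic
#' gap `start(i+1) - end(i) - 1` is at most `max_gap_bp`, and the expression
#' profiles of the two genes (adjacent-pair chaining; all members under
#' `"all_pairs"`) correlate at Pearson >= `min_pearson` with a defined
#' value. Genes lacking a profile, and undefined (constant-profile)
#' correlations, never merge. The result is a partition: every gene belongs
#' to exactly one operon.
#'
#' @param genome a [genome_record()].
#' @param profiles numeric matrix of per-gene expression profiles
#'   (genes x timepoints) with gene ids as rownames; Pearson correlation is
#'   shift-invariant, so log2 RPKM and minimum-subtracted profiles are
#'   equivalent here.
#' @param config an [operon_config()].
#' @return a data frame with one row per operon: `operon_id`, `contig_id`,
#'   `strand`, `members` (list-column of gene ids ordered 5'->3' in
#'   transcription order), `anchor_gene_id` (the 5'-most member), `n_genes`.
#' @export
call_operons <- function(genome, profiles, config = operon_config()) {
  stopifnot(inherits(genome, "genome_record"), inherits(config, "operon_config"))
  g <- genome$genes
  if (nrow(g) == 0L) {
    return(data.frame(operon_id = character(), contig_id = character(),
                      strand = character(), anchor_gene_id = character(),
                      n_genes = integer()))
  }
  has_profile <- g$gene_id %in% rownames(profiles)
  if (!all(has_profile)) {
    message(sum(!has_profile), " gene(s) lack expression profiles; kept as singletons")
  }
  cor_ok <- function(a, b) {
    if (!(a %in% rownames(profiles)) || !(b %in% rownames(profiles))) return(FALSE)
    r <- pearson(profiles[a, ], profiles[b, ])
    !is.na(r) && r >= config$min_pearson
  }
  groups <- list()
  current <- integer(0)
  flush <- function() {
    if (length(current)) groups[[length(groups) + 1L]] <<- current
    current <<- integer(0)
  }
  for (i in seq_len(nrow(g))) {
    if (length(current) == 0L) {
      current <- i
      next
    }
    prev <- current[length(current)]
    gap <- g$start[i] - g$end[prev] - 1L
    mergeable <- g$contig_id[i] == g$contig_id[prev] &&
      g$strand[i] == g$strand[prev] &&
      gap <= config$max_gap_bp
    if (mergeable) {
      partners <- if (config$chaining == "adjacent") prev else current
      mergeable <- all(vapply(partners, function(j) {
        cor_ok(g$gene_id[i], g$gene_id[j])
      }, logical(1)))
    }
    if (mergeable) current <- c(current, i) else { flush(); current <- i }
  }
  flush()
  rows <- lapply(seq_along(groups), function(k) {
    idx <- groups[[k]]
    strand <- g$strand[idx[1]]
    members <- g$gene_id[idx]            # genomic order (by start)
    if (strand == "-") members <- rev(members)  # transcription order 5'->3'
    data.frame(operon_id = sprintf("operon_%04d", k),
               contig_id = g$contig_id[idx[1]],
               strand = strand,
               anchor_gene_id = members[1],
               n_genes = length(members),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$members <- lapply(seq_along(groups), function(k) {
    idx <- groups[[k]]
    m <- g$gene_id[idx]
    if (g$strand[idx[1]] == "-") rev(m) else m
  })
  out[, c("operon_id", "contig_id", "strand", "members", "anchor_gene_id",
          "n_genes")]
}

#' 5'-most gene of an operon
#'
#' The anchor is the first member in transcription order: the lowest-start
#' gene on the plus strand, the highest-end gene on the minus strand. Its
#' promoter is the operon's promoter.
#'
#' @param genome a [genome_record()].
#' @param member_gene_ids character vector of operon member gene ids.
#' @return the anchor `gene_id`.
#' @export
operon_anchor <- function(genome, member_gene_ids) {
  stopifnot(length(member_gene_ids) >= 1L)
  g <- genome$genes[genome$genes$gene_id %in% member_gene_ids, , drop = FALSE]
  if (nrow(g) != length(member_gene_ids)) {
    stop("unknown gene id(s) among operon members", call. = FALSE)
  }
  if (length(unique(g$strand)) != 1L) {
    stop("operon members must share a strand", call. = FALSE)
  }
  if (g$strand[1] == "+") g$gene_id[which.min(g$start)] else g$gene_id[which.max(g$end)]
}

#' Write an operon table to TSV
#'
#' Members are comma-joined in transcription order.
#'
#' @param operons output of [call_operons()].
#' @param path output TSV path.
#' @return invisibly, `path`.
#' @export
write_operons_tsv <- function(operons, path) {
  df <- data.frame(operon_id = operons$operon_id,
                   contig = operons$contig_id,
                   strand = operons$strand,
                   members = vapply(operons$members, paste, "", collapse = ","),
                   anchor = operons$anchor_gene_id,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
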