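# Genome sequences, annotations, and strand-aware promoter extraction.
#
# External files use the GFF3 dialect (1-based inclusive coordinates);
# all conversion happens at the I/O boundary so internal arithmetic is
# unambiguous.

#' Construct a genome record
#'
#' Bundles contig sequences with an ordered gene table. Genes are sorted by
#' (contig, start); coordinates are 1-based inclusive as in GFF3.
#'
#' @param genome_id character identifier.
#' @param contigs named character vector of upper-case nucleotide sequences.
#' @param genes data frame with columns `gene_id`, `contig_id`, `start`,
#'   `end`, `strand` (`"+"`/`"-"`), and optionally `product`.
#' @return an object of class `genome_record` with elements `genome_id`,
#'   `contigs`, and `genes` (gains a `length_bp` column).
#' @export
genome_record <- function(genome_id, contigs, genes) {
  stopifnot(is.character(genome_id), length(genome_id) == 1L)
  contigs <- toupper(unlist(contigs))
  if (is.null(names(contigs)) && length(contigs) > 0) {
    stop("contigs must be named", call. = FALSE)
  }
  if (is.null(genes) || nrow(genes) == 0L) {
    genes <- data.frame(gene_id = character(), contig_id = character(),
                        start = integer(), end = integer(),
                        strand = character(), product = character(),
                        stringsAsFactors = FALSE)
  }
  if (!"product" %in% names(genes)) genes$product <- NA_character_
  needed <- c("gene_id", "contig_id", "start", "end", "strand")
  if (!all(needed %in% names(genes))) {
    stop("genes table must have columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  genes$start <- as.integer(genes$start)
  genes$end <- as.integer(genes$end)
  if (anyDuplicated(genes$gene_id)) {
    stop("duplicate gene_id values: ",
         paste(unique(genes$gene_id[duplicated(genes$gene_id)]), collapse = ", "),
         call. = FALSE)
  }
  bad_strand <- !genes$strand %in% c("+", "-")
  if (any(bad_strand)) {
    stop("unknown strand symbol for gene(s): ",
         paste(genes$gene_id[bad_strand], collapse = ", "), call. = FALSE)
  }
  if (any(genes$start > genes$end)) {
    stop("gene start > end for: ",
         paste(genes$gene_id[genes$start > genes$end], collapse = ", "),
         call. = FALSE)
  }
  missing_contig <- !genes$contig_id %in% names(contigs)
  if (any(missing_contig)) {
    stop("gene(s) on unknown contig: ",
         paste(genes$gene_id[missing_contig], collapse = ", "), call. = FALSE)
  }
  clen <- nchar(contigs)[genes$contig_id]
  over <- genes$end > clen
  if (any(over)) {
    stop("gene(s) extend beyond contig end: ",
         paste(genes$gene_id[over], collapse = ", "), call. = FALSE)
  }
  genes$length_bp <- genes$end - genes$start + 1L
  genes <- genes[order(genes$contig_id, genes$start, genes$end), , drop = FALSE]
  rownames(genes) <- NULL
  structure(list(genome_id = genome_id, contigs = contigs, genes = genes),
            class = "genome_record")
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s: %d contig(s), %d gene(s), %s bp total\n",
              x$genome_id, length(x$contigs), nrow(x$genes),
              format(sum(nchar(x$contigs)), big.mark = ",")))
  invisible(x)
}

#' Read a genome from FASTA and GFF3
#'
#' Sequences are upper-cased; letters outside ACGTN are kept but reported
#' with a warning. Gene features are taken from rows whose `type` matches
#' `feature_type` and identified by the `id_attribute` GFF3 attribute.
#'
#' @param fasta_path path to a (multi-)FASTA file.
#' @param gff_path path to a GFF3 annotation file.
#' @param genome_id identifier for the record; defaults to the FASTA
#'   file name without extension.
#' @param feature_type GFF3 feature type(s) treated as genes.
#' @param id_attribute GFF3 attribute key holding gene identifiers.
#' @return a [genome_record()].
#' @export
read_genome <- function(fasta_path, gff_path, genome_id = NULL,
                        feature_type = c("gene", "CDS"),
                        id_attribute = "ID") {
  stopifnot(file.exists(fasta_path), file.exists(gff_path))
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  contigs <- toupper(as.character(seqs))
  names(contigs) <- sub("\\s.*$", "", names(contigs))
  odd <- gsub("[ACGTN]", "", contigs)
  if (any(nchar(odd) > 0)) {
    warning("non-ACGTN letters present in contig(s): ",
            paste(names(contigs)[nchar(odd) > 0], collapse = ", "))
  }
  gff <- rtracklayer::import(gff_path, format = "gff3")
  gff <- gff[as.character(gff$type) %in% feature_type]
  if (length(gff) == 0L) {
    warning("no gene features of type ", paste(feature_type, collapse = "/"),
            " found in ", gff_path)
    genes <- NULL
  } else {
    ids <- S4Vectors::mcols(gff)[[id_attribute]]
    if (is.null(ids) || anyNA(ids)) {
      stop("GFF3 attribute `", id_attribute, "` missing for some features",
           call. = FALSE)
    }
    product <- S4Vectors::mcols(gff)[["product"]]
    genes <- data.frame(
      gene_id = as.character(ids),
      contig_id = as.character(GenomicRanges::seqnames(gff)),
      start = GenomicRanges::start(gff),
      end = GenomicRanges::end(gff),
      strand = as.character(GenomicRanges::strand(gff)),
      product = if (is.null(product)) NA_character_ else as.character(product),
      stringsAsFactors = FALSE
    )
  }
  genome_record(genome_id %||% sub("\\.(fa|fasta|fna)$", "", basename(fasta_path)),
                contigs, genes)
}

#' Write a genome record to FASTA and GFF3
#'
#' FASTA is wrapped at 60 columns; gene features are written with type
#' `gene` and an `ID` attribute, so [read_genome()] round-trips.
#'
#' @param genome a [genome_record()].
#' @param fasta_path,gff_path output paths.
#' @return invisibly, the genome.
#' @export
write_genome <- function(genome, fasta_path, gff_path) {
  stopifnot(inherits(genome, "genome_record"))
  seqs <- Biostrings::DNAStringSet(genome$contigs)
  Biostrings::writeXStringSet(seqs, fasta_path, width = 60L)
  g <- genome$genes
  gr <- GenomicRanges::GRanges(
    seqnames = g$contig_id,
    ranges = IRanges::IRanges(start = g$start, end = g$end),
    strand = g$strand
  )
  S4Vectors::mcols(gr)$type <- "gene"
  S4Vectors::mcols(gr)$ID <- g$gene_id
  if (!all(is.na(g$product))) S4Vectors::mcols(gr)$product <- g$product
  rtracklayer::export(gr, gff_path, format = "gff3")
  invisible(genome)
}

#' Reverse-complement a nucleotide sequence
#'
#' Alphabet is restricted to ACGTN (case-insensitive). Applying the function
#' twice returns the input.
#'
#' @param seq a single character string.
#' @return the reverse complement, upper-cased.
#' @export
reverse_complement <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  s <- toupper(seq)
  if (grepl("[^ACGTN]", s)) {
    stop("sequence contains letters outside ACGTN", call. = FALSE)
  }
  if (nchar(s) == 0L) return("")
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Extract the upstream intergenic promoter region of a gene
#'
#' Returns up to `window_bp` bases immediately upstream of the gene's
#' annotated start (its 5' end), truncated at the nearest annotated feature
#' on either strand and at the contig edge, so the region is strictly
#' intergenic. For minus-strand genes the downstream-in-forward-coordinates
#' slice is reverse-complemented so the returned sequence reads 5'->3'
#' relative to the gene. Genes whose upstream flank is fully covered by
#' another feature (including overlapping anchors) get an empty promoter.
#'
#' @param genome a [genome_record()].
#' @param anchor_gene a `gene_id` present in the genome.
#' @param window_bp maximum promoter length in bp (default 300).
#' @return a one-row data frame with columns `anchor_id`, `contig_id`,
#'   `start`, `end`, `strand`, `sequence`, `window_bp`. Empty promoters have
#'   `start` > `end` and `sequence` equal to `""`.
#' @export
extract_promoter <- function(genome, anchor_gene, window_bp = 300L) {
  stopifnot(inherits(genome, "genome_record"))
  assert_scalar_number(window_bp, "window_bp", lower = 1)
  g <- genome$genes
  i <- match(anchor_gene, g$gene_id)
  if (is.na(i)) stop("unknown gene_id: ", anchor_gene, call. = FALSE)
  contig <- g$contig_id[i]
  clen <- nchar(genome$contigs[[contig]])
  same <- which(g$contig_id == contig)
  same <- setdiff(same, i)
  if (g$strand[i] == "+") {
    hi <- g$start[i] - 1L
    lo <- max(1L, g$start[i] - as.integer(window_bp))
    if (length(same)) {
      ov <- same[g$start[same] <= hi & g$end[same] >= lo]
      if (length(ov)) lo <- max(lo, max(g$end[ov]) + 1L)
    }
  } else {
    lo <- g$end[i] + 1L
    hi <- min(clen, g$end[i] + as.integer(window_bp))
    if (length(same)) {
      ov <- same[g$end[same] >= lo & g$start[same] <= hi]
      if (length(ov)) hi <- min(hi, min(g$start[ov]) - 1L)
    }
  }
  if (lo > hi) {
    seqc <- ""
    lo <- 1L; hi <- 0L
  } else {
    seqc <- substr(genome$contigs[[contig]], lo, hi)
    if (g$strand[i] == "-") seqc <- reverse_complement(seqc)
  }
  data.frame(anchor_id = anchor_gene, contig_id = contig,
             start = lo, end = hi, strand = g$strand[i],
             sequence = seqc, window_bp = as.integer(window_bp),
             stringsAsFactors = FALSE)
}

#' Extract promoters for a set of anchor genes
#'
#' Anchors with empty promoters (fully overlapped upstream) are retained in
#' the table with zero-length sequences and reported via a message so callers
#' can exclude them from scanning.
#'
#' @param genome a [genome_record()].
#' @param anchors character vector of gene ids; defaults to every gene.
#' @param window_bp maximum promoter length (default 300).
#' @return a data frame, one row per anchor (see [extract_promoter()]).
#' @export
extract_promoters <- function(genome, anchors = NULL, window_bp = 300L) {
  anchors <- anchors %||% genome$genes$gene_id
  out <- do.call(rbind, lapply(anchors, extract_promoter, genome = genome,
                               window_bp = window_bp))
  n_empty <- sum(nchar(out$sequence) == 0L)
  if (n_empty > 0) {
    message(n_empty, " promoter(s) are empty (no intergenic upstream sequence)")
  }
  out
}
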