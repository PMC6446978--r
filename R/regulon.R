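# Multi-genome regulon conservation: three-state matrix and summaries.

CONSERVATION_STATES <- c("absent", "present_no_motif", "present_with_motif")

#' Build the genome x gene-family regulon-conservation matrix
#'
#' For every (genome, family) pair exactly one of three states holds:
#' `absent` when the family has no member gene in that genome,
#' `present_with_motif` when any member gene (or operon anchor) has a motif
#' hit in its promoter, and `present_no_motif` otherwise. Genes appearing
#' in hits but missing from the family map are bucketed under family
#' `"unassigned"` with a message.
#'
#' @param hits_by_genome named list, one element per genome, each a
#'   character vector of anchor gene ids whose promoters carry a motif hit.
#' @param genomes named list of [genome_record()] objects (names must cover
#'   `names(hits_by_genome)`).
#' @param family_map named character vector mapping `gene_id` to a
#'   family id (orthology is an input, never inferred).
#' @return a character matrix of class `conservation_matrix`
#'   (genomes x families) with entries among the three states.
#' @export
build_conservation_matrix <- function(hits_by_genome, genomes, family_map) {
  stopifnot(is.list(genomes), !is.null(names(genomes)))
  genome_ids <- names(genomes)
  if (!all(names(hits_by_genome) %in% genome_ids)) {
    stop("hits_by_genome names must match genome names", call. = FALSE)
  }
  fam_of <- function(gene_ids) {
    fams <- unname(family_map[gene_ids])
    un <- is.na(fams)
    if (any(un)) fams[un] <- "unassigned"
    fams
  }
  all_genes <- lapply(genomes, function(g) g$genes$gene_id)
  unmapped <- unlist(lapply(hits_by_genome, function(h) h[!h %in% names(family_map)]))
  if (length(unmapped)) {
    message(length(unmapped),
            " hit anchor(s) absent from family_map; bucketed as 'unassigned'")
  }
  families <- sort(unique(c(unlist(lapply(all_genes, fam_of)),
                            unlist(lapply(hits_by_genome, fam_of)))))
  m <- matrix("absent", nrow = length(genome_ids), ncol = length(families),
              dimnames = list(genome_ids, families))
  for (gid in genome_ids) {
    present <- unique(fam_of(all_genes[[gid]]))
    m[gid, intersect(present, families)] <- "present_no_motif"
    hits <- hits_by_genome[[gid]]
    if (!is.null(hits) && length(hits)) {
      with_motif <- unique(fam_of(hits))
      # a hit implies the gene is present in that genome
      m[gid, intersect(with_motif, families)] <- "present_with_motif"
    }
  }
  class(m) <- c("conservation_matrix", class(m))
  m
}

#' Restrict a conservation matrix to well-supported families
#'
#' Keeps families whose `present_with_motif` count across genomes is at
#' least `min_genomes` (default 4).
#'
#' @param matrix a `conservation_matrix`.
#' @param min_genomes minimum number of genomes with a motif (default 4).
#' @return the restricted `conservation_matrix`.
#' @export
filter_by_support <- function(matrix, min_genomes = 4L) {
  assert_scalar_number(min_genomes, "min_genomes", lower = 1)
  support <- colSums(matrix == "present_with_motif")
  out <- matrix[, support >= min_genomes, drop = FALSE]
  class(out) <- c("conservation_matrix", "matrix", "array")
  out
}

#' Tally retained families by functional category
#'
#' The category mapping (e.g. KEGG level-III categories) is an external
#' input; no database lookup is performed. Families without a category are
#' tallied under `"unassigned"`.
#'
#' @param retained_families character vector of family ids.
#' @param category_map named character vector mapping family id to
#'   category.
#' @return a named integer vector of counts per category (empty for an
#'   empty input).
#' @export
summarize_categories <- function(retained_families, category_map) {
  if (length(retained_families) == 0L) {
    return(integer(0))
  }
  cats <- unname(category_map[retained_families])
  cats[is.na(cats)] <- "unassigned"
  tab <- table(cats)
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}

#' Write a conservation matrix as TSV with 0/1/2 state encoding
#'
#' A legend header comment maps 0 = absent, 1 = present without motif,
#' 2 = present with motif.
#'
#' @param matrix a `conservation_matrix`.
#' @param path output TSV path.
#' @return invisibly, `path`.
#' @export
write_conservation_tsv <- function(matrix, path) {
  enc <- matrix(match(unclass(matrix), CONSERVATION_STATES) - 1L,
                nrow = nrow(matrix), dimnames = dimnames(matrix))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# states: 0=", CONSERVATION_STATES[1],
                    " 1=", CONSERVATION_STATES[2],
                    " 2=", CONSERVATION_STATES[3]), con)
  df <- data.frame(genome_id = rownames(enc), enc, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
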