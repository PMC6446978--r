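test_that("reading FASTA + GFF3 reproduces a hand-written genome", {
  g <- toy_genome()
  fa <- withr::local_tempfile(fileext = ".fa")
  gff <- withr::local_tempfile(fileext = ".gff3")
  write_genome(g, fa, gff)
  back <- read_genome(fa, gff, genome_id = "toy")
  expect_identical(back$contigs, g$contigs)
  expect_identical(back$genes[, c("gene_id", "contig_id", "start", "end",
                                  "strand", "length_bp")],
                   g$genes[, c("gene_id", "contig_id", "start", "end",
                               "strand", "length_bp")])
  # genes arrive sorted by (contig, start) regardless of file order
  expect_false(is.unsorted(back$genes$start))
})

test_that("annotation problems are hard errors naming the gene", {
  contig <- strrep("ACGT", 750)  # 3,000 bp
  expect_error(
    genome_record("x", c(chr1 = contig),
                  data.frame(gene_id = "gX", contig_id = "chr1",
                             start = 2900L, end = 3200L, strand = "+")),
    "gX")
  expect_error(
    genome_record("x", c(chr1 = contig),
                  data.frame(gene_id = "gY", contig_id = "chr1",
                             start = 10L, end = 90L, strand = "?")),
    "strand")
  expect_error(
    genome_record("x", c(chr1 = contig),
                  data.frame(gene_id = c("gZ", "gZ"), contig_id = "chr1",
                             start = c(1L, 200L), end = c(100L, 300L),
                             strand = "+")),
    "duplicate")
})

test_that("a GFF3 with no gene features yields an empty table with a warning", {
  fa <- withr::local_tempfile(fileext = ".fa")
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(">chr1", strrep("ACGT", 25)), fa)
  writeLines(c("##gff-version 3",
               "chr1\ttest\tregion\t1\t100\t.\t+\t.\tID=r1"), gff)
  expect_warning(g <- read_genome(fa, gff), "no gene features")
  expect_identical(nrow(g$genes), 0L)
})

test_that("reverse_complement is an involution and rejects bad letters", {
  expect_identical(reverse_complement("ACGT"), "ACGT")
  expect_identical(reverse_complement(""), "")
  expect_identical(reverse_complement("AAGCT"), "AGCTT")
  expect_identical(reverse_complement("ANNGT"), "ACNNT")
  set.seed(11)
  for (i in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T", "N"), sample(0:40, 1),
                      replace = TRUE), collapse = "")
    expect_identical(reverse_complement(reverse_complement(s)), s)
  }
  expect_error(reverse_complement("ACGU"), "ACGTN")
})

test_that("promoter extraction obeys window, truncation, and contig edges", {
  set.seed(302)
  contig <- paste(sample(c("A", "C", "G", "T"), 3000, replace = TRUE),
                  collapse = "")
  mk <- function(genes) genome_record("p", c(chr1 = contig), genes)

  # + strand gene starting at 1: empty promoter
  g <- mk(data.frame(gene_id = "a", contig_id = "chr1", start = 1L,
                     end = 200L, strand = "+"))
  expect_identical(nchar(extract_promoter(g, "a")$sequence), 0L)

  # full 300-bp window when the preceding feature is far upstream
  g <- mk(data.frame(gene_id = c("up", "a"), contig_id = "chr1",
                     start = c(101L, 1001L), end = c(400L, 1500L),
                     strand = "+"))
  p <- extract_promoter(g, "a")
  expect_identical(c(p$start, p$end), c(701L, 1000L))
  expect_identical(p$sequence, substr(contig, 701, 1000))

  # truncation at a near feature (either strand counts)
  g <- mk(data.frame(gene_id = c("up", "a"), contig_id = "chr1",
                     start = c(800L, 1001L), end = c(950L, 1500L),
                     strand = c("-", "+")))
  p <- extract_promoter(g, "a")
  expect_identical(c(p$start, p$end), c(951L, 1000L))
  expect_identical(nchar(p$sequence), 50L)

  # minus-strand mirror: promoter downstream in forward coordinates,
  # reverse-complemented
  g <- mk(data.frame(gene_id = c("a", "dn"), contig_id = "chr1",
                     start = c(1001L, 2500L), end = c(2000L, 2900L),
                     strand = c("-", "+")))
  p <- extract_promoter(g, "a")
  expect_identical(c(p$start, p$end), c(2001L, 2300L))
  expect_identical(p$sequence, reverse_complement(substr(contig, 2001, 2300)))

  # overlapping anchor: empty promoter, not an error
  g <- mk(data.frame(gene_id = c("up", "a"), contig_id = "chr1",
                     start = c(500L, 1001L), end = c(1200L, 1500L),
                     strand = "+"))
  expect_identical(nchar(extract_promoter(g, "a")$sequence), 0L)

  expect_error(extract_promoter(g, "nope"), "unknown gene_id")
})

test_that("promoters never exceed the window or overlap a gene body", {
  sc <- synthetic_scenario(seed = 77, n_genes = 40)
  lay <- generate_genome_layout(sc)
  proms <- suppressMessages(extract_promoters(lay$genome))
  g <- lay$genome$genes
  for (i in seq_len(nrow(proms))) {
    p <- proms[i, ]
    expect_lte(nchar(p$sequence), p$window_bp)
    if (nchar(p$sequence) == 0) next
    overlap <- g$start <= p$end & g$end >= p$start
    expect_false(any(overlap), info = p$anchor_id)
  }
})

test_that("reverse-complementing the contig mirrors every promoter", {
  sc <- synthetic_scenario(seed = 78, n_genes = 30)
  lay <- generate_genome_layout(sc)
  g <- lay$genome
  L <- nchar(g$contigs[["contig_1"]])
  flipped <- genome_record(
    "flipped",
    c(contig_1 = reverse_complement(g$contigs[["contig_1"]])),
    data.frame(gene_id = g$genes$gene_id, contig_id = "contig_1",
               start = L - g$genes$end + 1L, end = L - g$genes$start + 1L,
               strand = ifelse(g$genes$strand == "+", "-", "+"),
               stringsAsFactors = FALSE))
  for (id in g$genes$gene_id) {
    expect_identical(extract_promoter(flipped, id)$sequence,
                     extract_promoter(g, id)$sequence, info = id)
  }
})
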