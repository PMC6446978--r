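# Shared fixture builders: everything is generated in code at test time.

# Small three-gene genome on one 3-kb contig, used across I/O tests.
toy_genome <- function() {
  set.seed(301)
  contig <- paste(sample(c("A", "C", "G", "T"), 3000, replace = TRUE),
                  collapse = "")
  genome_record(
    "toy",
    c(chr1 = contig),
    data.frame(gene_id = c("geneA", "geneB", "geneC"),
               contig_id = "chr1",
               start = c(101L, 1001L, 2001L),
               end = c(400L, 1600L, 2600L),
               strand = c("+", "+", "-"),
               stringsAsFactors = FALSE)
  )
}

# Sample a site sequence from a PWM.
sample_site <- function(pwm) {
  paste(c("A", "C", "G", "T")[apply(pwm$prob, 2L, function(col)
    sample(1:4, 1L, prob = col))], collapse = "")
}

# Promoter set with a planted site in every sequence at a random offset;
# returns sequences plus the truth table.
planted_promoters <- function(pwm, n = 20L, length_bp = 300L,
                              composition = rep(0.25, 4), seed = 1L) {
  w <- pwm$width
  set.seed(seed)
  offs <- sample(length_bp - w + 1L, n, replace = TRUE) - 1L
  strands <- sample(c("+", "-"), n, replace = TRUE)
  seqs <- vapply(seq_len(n), function(i) {
    x <- generate_background(length_bp, composition, seed = seed * 10000L + i)
    site <- sample_site(pwm)
    oriented <- if (strands[i] == "-") reverse_complement(site) else site
    substr(x, offs[i] + 1L, offs[i] + w) <- oriented
    x
  }, character(1))
  list(promoters = data.frame(anchor_id = sprintf("p%02d", seq_len(n)),
                              sequence = seqs, stringsAsFactors = FALSE),
       truth = data.frame(anchor_id = sprintf("p%02d", seq_len(n)),
                          offset = offs, strand = strands,
                          stringsAsFactors = FALSE))
}

# Fraction of consensus columns agreeing between two PWMs, taking the
# better of the forward and reverse-complement alignment.
consensus_agreement <- function(pwm_true, pwm_found) {
  a <- strsplit(pwm_consensus(pwm_true), "")[[1]]
  b <- strsplit(pwm_consensus(pwm_found), "")[[1]]
  rc <- strsplit(reverse_complement(pwm_consensus(pwm_found)), "")[[1]]
  max(mean(a == b), mean(a == rc))
}

# Random PWM of a given width (columns Dirichlet-ish via normalized
# exponentials).
random_pwm <- function(width, seed) {
  set.seed(seed)
  p <- matrix(stats::rexp(4L * width), nrow = 4L)
  fnrscan:::new_pwm(sweep(p, 2L, colSums(p), "/"))
}

# Independent operon oracle: decide every adjacent boundary directly from
# the gene table and raw profile correlations (stats::cor on the raw
# log2 values), then split runs at non-merging boundaries.
oracle_operon_partition <- function(genome, raw_log2, min_pearson = 0.7,
                                    max_gap_bp = 1000L) {
  g <- genome$genes
  n <- nrow(g)
  if (n == 0L) return(list())
  merge_ok <- vapply(seq_len(n - 1L), function(i) {
    j <- i + 1L
    if (g$contig_id[i] != g$contig_id[j]) return(FALSE)
    if (g$strand[i] != g$strand[j]) return(FALSE)
    if (g$start[j] - g$end[i] - 1L > max_gap_bp) return(FALSE)
    a <- g$gene_id[i]; b <- g$gene_id[j]
    if (!(a %in% rownames(raw_log2)) || !(b %in% rownames(raw_log2))) return(FALSE)
    if (stats::sd(raw_log2[a, ]) == 0 || stats::sd(raw_log2[b, ]) == 0) return(FALSE)
    stats::cor(raw_log2[a, ], raw_log2[b, ]) >= min_pearson
  }, logical(1))
  group <- cumsum(c(1L, !merge_ok))
  unname(split(g$gene_id, group))
}
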