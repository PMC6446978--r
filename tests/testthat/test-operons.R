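# Hand-built layouts for rule checks: genes on one 10-kb contig.
mk_layout <- function(starts, ends, strands) {
  genome_record("op", c(chr = strrep("ACGT", 5000)),
                data.frame(gene_id = sprintf("g%d", seq_along(starts)),
                           contig_id = "chr", start = starts, end = ends,
                           strand = strands, stringsAsFactors = FALSE))
}

# Profiles engineered to have exact pairwise correlations.
prof <- function(...) {
  m <- rbind(...)
  rownames(m) <- sprintf("g%d", seq_len(nrow(m)))
  m
}

test_that("strand, gap, and correlation rules split operons as specified", {
  up <- c(1, 2, 3, 4, 5, 6)
  # opposite strands, r = 1, gap 10 -> two singletons
  g <- mk_layout(c(101L, 611L), c(600L, 1100L), c("+", "-"))
  ops <- call_operons(g, prof(up, up))
  expect_identical(ops$n_genes, c(1L, 1L))

  # gaps 500 and 1,500, all r high -> {g1,g2},{g3}
  g <- mk_layout(c(101L, 1101L, 3101L), c(600L, 1600L, 3600L), rep("+", 3))
  ops <- call_operons(g, prof(up, up + 1, up * 2))
  expect_identical(lapply(ops$members, identity), list(c("g1", "g2"), "g3"))

  # gaps small but r(g2,g3) low -> {g1,g2},{g3}
  lowcor <- c(1, 6, 2, 5, 3, 4)
  stopifnot(cor(up, lowcor) < 0.7)
  g <- mk_layout(c(101L, 701L, 1301L), c(600L, 1200L, 1800L), rep("+", 3))
  ops <- call_operons(g, prof(up, up + 2, lowcor))
  expect_identical(lapply(ops$members, identity), list(c("g1", "g2"), "g3"))

  # overlapping genes (negative gap) merge when co-expressed
  g <- mk_layout(c(101L, 551L), c(600L, 1000L), c("+", "+"))
  ops <- call_operons(g, prof(up, up))
  expect_identical(ops$n_genes, 2L)

  # constant profile: undefined correlation never merges
  g <- mk_layout(c(101L, 701L), c(600L, 1200L), c("+", "+"))
  ops <- call_operons(g, prof(up, rep(3, 6)))
  expect_identical(ops$n_genes, c(1L, 1L))
})

test_that("genes lacking profiles stay singletons and the output partitions", {
  up <- c(1, 2, 3, 4, 5, 6)
  g <- mk_layout(c(101L, 701L, 1301L), c(600L, 1200L, 1800L), rep("+", 3))
  p <- prof(up, up)  # g3 missing
  expect_message(ops <- call_operons(g, p), "lack expression profiles")
  expect_setequal(unlist(ops$members), g$genes$gene_id)
  expect_identical(anyDuplicated(unlist(ops$members)), 0L)
})

test_that("anchor is the 5'-most member in transcription order", {
  up <- c(1, 2, 3, 4, 5, 6)
  g <- mk_layout(c(101L, 901L), c(800L, 1700L), c("+", "+"))
  expect_identical(call_operons(g, prof(up, up))$anchor_gene_id, "g1")
  g <- mk_layout(c(101L, 901L), c(800L, 1700L), c("-", "-"))
  expect_identical(call_operons(g, prof(up, up))$anchor_gene_id, "g2")
  expect_identical(operon_anchor(g, c("g1", "g2")), "g2")
  expect_identical(operon_anchor(g, "g1"), "g1")
})

test_that("caller equals the brute-force oracle on random synthetic layouts", {
  cfg <- operon_config()  # published defaults: r >= 0.7, gap <= 1,000 bp
  for (seed in 1:100) {
    sc <- synthetic_scenario(seed = seed, n_genes = 25,
                             inter_operon_gap_bp = c(300L, 1400L))
    lay <- generate_genome_layout(sc)
    sim <- simulate_expression(lay, sc)
    expr <- compute_log2_rpkm(sim$counts, sim$factors,
                              setNames(lay$genome$genes$length_bp,
                                       lay$genome$genes$gene_id))
    ops <- call_operons(lay$genome, relative_to_min(expr), cfg)
    # oracle works on raw log2 values; members compared in genomic order
    called <- unname(Map(function(m, s) if (s == "-") rev(m) else m,
                         ops$members, ops$strand))
    oracle <- oracle_operon_partition(lay$genome, expr)
    expect_identical(called, oracle, info = paste("seed", seed))
  }
})

test_that("raising min_pearson or lowering max_gap_bp only refines the partition", {
  sc <- synthetic_scenario(seed = 9, n_genes = 40)
  lay <- generate_genome_layout(sc)
  sim <- simulate_expression(lay, sc)
  expr <- compute_log2_rpkm(sim$counts, sim$factors,
                            setNames(lay$genome$genes$length_bp,
                                     lay$genome$genes$gene_id))
  profs <- relative_to_min(expr)
  part_id <- function(ops) {
    lab <- rep(seq_len(nrow(ops)), ops$n_genes)
    names(lab) <- unlist(ops$members)
    lab
  }
  base <- part_id(call_operons(lay$genome, profs, operon_config(0.5, 1500L)))
  for (cfg in list(operon_config(0.8, 1500L), operon_config(0.5, 400L),
                   operon_config(0.95, 200L))) {
    fine <- part_id(call_operons(lay$genome, profs, cfg))
    # refinement: genes separated in `base` stay separated in `fine`
    for (g1 in names(base)) {
      same_base <- names(base)[base == base[g1]]
      same_fine <- names(fine)[fine == fine[g1]]
      expect_true(all(same_fine %in% same_base))
    }
  }
})

test_that("all-pairs chaining is at least as strict as adjacent chaining", {
  up <- c(1, 2, 3, 4, 5, 6)
  mid <- c(1.5, 2.1, 3.4, 4.0, 5.5, 5.7)
  far <- c(3, 3.5, 4, 4.5, 5, 10)
  stopifnot(cor(up, mid) >= 0.7, cor(mid, far) >= 0.7, cor(up, far) < 0.95)
  g <- mk_layout(c(101L, 701L, 1301L), c(600L, 1200L, 1800L), rep("+", 3))
  p <- prof(up, mid, far)
  adj <- call_operons(g, p, operon_config(0.7, 1000L, chaining = "adjacent"))
  strict <- call_operons(g, p, operon_config(0.95, 1000L, chaining = "all_pairs"))
  expect_gte(nrow(strict), nrow(adj))
})
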