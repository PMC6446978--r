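test_that("generators are pure functions of (scenario, seed)", {
  sc <- synthetic_scenario(seed = 10, n_genes = 20)
  a <- generate_genome_layout(sc)
  b <- generate_genome_layout(sc)
  expect_identical(a, b)
  expect_identical(generate_background(500, seed = 3),
                   generate_background(500, seed = 3))
  sim1 <- simulate_expression(a, sc)
  sim2 <- simulate_expression(a, sc)
  expect_identical(sim1$counts, sim2$counts)
})

test_that("an empty scenario yields an empty genome", {
  sc <- synthetic_scenario(seed = 1, n_genes = 0)
  lay <- generate_genome_layout(sc)
  expect_identical(nrow(lay$genome$genes), 0L)
  expect_identical(lay$truth$operons, list())
  expect_identical(generate_background(0), "")
})

test_that("background sequences match their composition within 3-sigma", {
  comp <- c(0.1875, 0.3125, 0.3125, 0.1875)
  s <- generate_background(1e5, comp, seed = 12)
  chars <- strsplit(s, "")[[1]]
  for (i in 1:4) {
    obs <- sum(chars == c("A", "C", "G", "T")[i])
    expect_lt(abs(obs - 1e5 * comp[i]), 3 * sqrt(1e5 * comp[i] * (1 - comp[i])))
  }
})

test_that("truth operons obey the operon-caller gap and strand rules", {
  for (seed in 1:50) {
    sc <- synthetic_scenario(seed = seed, n_genes = 30)
    lay <- generate_genome_layout(sc)
    g <- lay$genome$genes
    for (members in lay$truth$operons) {
      rows <- g[match(members, g$gene_id), ]
      expect_identical(length(unique(rows$strand)), 1L)
      rows <- rows[order(rows$start), ]
      if (nrow(rows) > 1) {
        gaps <- rows$start[-1] - rows$end[-nrow(rows)] - 1L
        expect_true(all(gaps <= 1000L))
      }
    }
  }
})

test_that("consensus_pwm hits its information-content target", {
  bg <- background_model(c(0.1875, 0.3125, 0.3125, 0.1875))
  for (ic in c(1.0, 1.5)) {
    p <- consensus_pwm("TTGATCGGGATCAA", ic, bg)
    expect_equal(information_content(p, bg)$per_column, rep(ic, 14),
                 tolerance = 1e-6)
  }
  # a C/G column against a GC-rich background can carry at most
  # log2(1/0.3125) ~ 1.678 bits: higher targets are capped there
  p <- consensus_pwm("TTGATCGGGATCAA", 1.9, bg)
  percol <- information_content(p, bg)$per_column
  at <- strsplit("TTGATCGGGATCAA", "")[[1]] %in% c("A", "T")
  expect_equal(percol[at], rep(1.9, sum(at)), tolerance = 1e-6)
  expect_equal(percol[!at], rep(log2(1 / 0.3125), sum(!at)), tolerance = 1e-6)
  # N columns carry no information
  p <- consensus_pwm("TTGNNATC", 1.8, bg)
  expect_equal(information_content(p, bg)$per_column[4:5], c(0, 0))
})

test_that("plant_motif respects occupancy and records retrievable sites", {
  sc <- synthetic_scenario(seed = 21, n_genes = 30)
  lay <- generate_genome_layout(sc)
  bg <- background_model(sc$background_composition)
  pwm <- consensus_pwm(sc$motif_consensus, 1.8, bg)
  anchors <- vapply(lay$truth$operons, function(m) operon_anchor(lay$genome, m), "")

  # occupancy 0: genome unchanged
  p0 <- plant_motif(lay$genome, anchors, pwm, occupancy = 0, seed = 5)
  expect_identical(p0$genome$contigs, lay$genome$contigs)
  expect_identical(nrow(p0$sites), 0L)

  # occupancy 1: every long-enough promoter receives exactly one site
  p1 <- plant_motif(lay$genome, anchors, pwm, occupancy = 1, seed = 5)
  proms <- suppressMessages(extract_promoters(lay$genome))
  eligible <- proms$anchor_id[proms$anchor_id %in% anchors &
                                nchar(proms$sequence) >= pwm$width]
  expect_setequal(p1$sites$anchor_id, eligible)
  expect_identical(anyDuplicated(p1$sites$anchor_id), 0L)

  # planted sites sit inside their promoter and are retrievable by scanning
  found <- 0L
  for (i in seq_len(nrow(p1$sites))) {
    site <- p1$sites[i, ]
    pr <- extract_promoter(p1$genome, site$anchor_id)
    expect_lte(site$offset + pwm$width, nchar(pr$sequence))
    window <- substr(pr$sequence, site$offset + 1, site$offset + pwm$width)
    if (site$strand == "-") window <- reverse_complement(window)
    expect_identical(window, site$site)
  }
})

test_that("planted sites are found by the scanner in nearly all promoters", {
  found <- 0L; total <- 0L
  for (seed in 1:20) {
    sc <- synthetic_scenario(seed = seed, n_genes = 25)
    bg <- background_model(sc$background_composition)
    pwm <- consensus_pwm(sc$motif_consensus, 1.8, bg)
    lay <- generate_genome_layout(sc)
    anchors <- vapply(lay$truth$operons, function(m) operon_anchor(lay$genome, m), "")
    pl <- plant_motif(lay$genome, anchors, pwm, occupancy = 1, seed = seed)
    proms <- suppressMessages(extract_promoters(pl$genome, pl$sites$anchor_id))
    hits <- scan_promoters(pwm, proms, background = bg, alpha = 1e-5)
    key <- paste(hits$anchor_id, hits$offset, hits$strand)
    truth_key <- paste(pl$sites$anchor_id, pl$sites$offset, pl$sites$strand)
    found <- found + sum(truth_key %in% key)
    total <- total + length(truth_key)
  }
  expect_gte(found / total, 0.95)
})

test_that("null-scenario (fold 1) regulated genes are indistinguishable", {
  n_sig <- 0L
  for (seed in 1:20) {
    sc <- synthetic_scenario(seed = seed, n_genes = 40, induction_fold = 1)
    lay <- generate_genome_layout(sc)
    sim <- simulate_expression(lay, sc)
    expr <- compute_log2_rpkm(sim$counts, sim$factors,
                              setNames(lay$genome$genes$length_bp,
                                       lay$genome$genes$gene_id))
    profs <- relative_to_min(expr)
    low <- sim$phase_labels == "low_oxygen"
    contrast <- rowMeans(profs[, low, drop = FALSE]) -
      rowMeans(profs[, !low, drop = FALSE])
    # collapse to operon level: members share the baseline profile, so
    # genes are not independent observations
    fam <- lay$truth$family_of[rownames(profs)]
    op_contrast <- tapply(contrast, fam, mean)
    op_sign <- lay$truth$sign_of_family[names(op_contrast)]
    reg <- op_contrast[op_sign != "unregulated"]
    bgc <- op_contrast[op_sign == "unregulated"]
    p <- stats::wilcox.test(reg, bgc)$p.value
    if (p < 0.01) n_sig <- n_sig + 1L
  }
  expect_lte(n_sig, 2L)
})

test_that("operon co-members share relative profiles at low dispersion", {
  pass <- 0L; total <- 0L
  for (seed in 1:20) {
    sc <- synthetic_scenario(seed = seed, n_genes = 30, dispersion = 0.005)
    lay <- generate_genome_layout(sc)
    sim <- simulate_expression(lay, sc)
    expr <- compute_log2_rpkm(sim$counts, sim$factors,
                              setNames(lay$genome$genes$length_bp,
                                       lay$genome$genes$gene_id))
    profs <- relative_to_min(expr)
    for (members in lay$truth$operons) {
      if (length(members) < 2) next
      for (i in seq_len(length(members) - 1L)) {
        r <- pearson(profs[members[i], ], profs[members[i + 1L], ])
        total <- total + 1L
        if (!is.na(r) && r >= 0.7) pass <- pass + 1L
      }
    }
  }
  expect_gte(pass / total, 0.9)
})

test_that("equal-expression genes of different lengths have matching RPKM", {
  # two genes with identical true expression, lengths L and 2L: the length
  # term cancels, so pre-log RPKM agrees within 10% at high counts
  sc <- synthetic_scenario(seed = 31, dispersion = 0,
                           baseline_temporal_sd_log2 = 0,
                           operon_jitter_sd_log2 = 0)
  genome <- genome_record(
    "two", c(c1 = generate_background(6000, seed = 31)),
    data.frame(gene_id = c("gShort", "gLong"), contig_id = "c1",
               start = c(501L, 2501L), end = c(1700L, 4900L), strand = "+",
               stringsAsFactors = FALSE))
  lay <- list(genome = genome,
              truth = list(
                operons = list("gShort", "gLong"),
                family_of = c(gShort = "fam001", gLong = "fam001"),
                sign_of_family = c(fam001 = "unregulated"),
                gene_sign = c(gShort = "unregulated", gLong = "unregulated")))
  sim <- simulate_expression(lay, sc)
  expr <- compute_log2_rpkm(sim$counts, sim$factors,
                            setNames(lay$genome$genes$length_bp,
                                     lay$genome$genes$gene_id))
  ratio <- 2^(expr["gShort", ] - expr["gLong", ])
  expect_lt(abs(mean(ratio) - 1), 0.1)
})

test_that("emitted files round-trip through the pipeline readers", {
  sc <- synthetic_scenario(seed = 41, n_genes = 15)
  lay <- generate_genome_layout(sc)
  fa <- withr::local_tempfile(fileext = ".fa")
  gff <- withr::local_tempfile(fileext = ".gff3")
  write_genome(lay$genome, fa, gff)
  back <- read_genome(fa, gff, genome_id = lay$genome$genome_id)
  expect_identical(back$contigs, lay$genome$contigs)
  expect_identical(back$genes$start, lay$genome$genes$start)

  sim <- simulate_expression(lay, sc)
  expr <- compute_log2_rpkm(sim$counts, sim$factors,
                            setNames(lay$genome$genes$length_bp,
                                     lay$genome$genes$gene_id))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression_tsv(expr, path)
  df <- utils::read.delim(path)
  expect_identical(df$gene_id, rownames(expr))
  expect_equal(as.matrix(df[, -1]), unname(expr)[, ], tolerance = 1e-5,
               ignore_attr = TRUE)
})
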