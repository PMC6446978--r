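test_that("amplicon arithmetic reproduces the five consistent primer rows", {
  panel <- suppressMessages(check_primer_table(respiration_primer_panel()))
  expected <- c(`nirS-1` = 164L, norZ = 375L, nosZ = 363L,
                ccoN = 124L, ctaD = 135L)
  for (g in names(expected)) {
    row <- panel[panel$gene_id == g, ]
    expect_identical(row$computed_amplicon_bp, expected[[g]], info = g)
    expect_true(row$consistent, info = g)
  }
  # the two internally inconsistent rows are flagged, not corrected
  incon <- panel[!panel$consistent, ]
  expect_setequal(incon$gene_id, c("narG", "rpoN"))
  expect_identical(incon$computed_amplicon_bp[incon$gene_id == "narG"], 88L)
  expect_identical(incon$computed_amplicon_bp[incon$gene_id == "rpoN"], 458L)
  expect_message(check_primer_table(respiration_primer_panel()), "mismatch")
  expect_error(amplicon_length(100, 50), "greater than")
})

test_that("reference normalization and min-normalization behave as ratios", {
  tgt <- c(t1 = 100, t2 = 400)
  ref <- c(t1 = 50, t2 = 100)
  expect_equal(normalize_to_reference(tgt, ref), c(t1 = 2, t2 = 4))
  expect_equal(unname(normalize_to_reference(ref, ref)), c(1, 1))
  expect_error(normalize_to_reference(tgt, c(t1 = 50, t3 = 100)),
               "do not match")
  expect_error(normalize_to_reference(tgt, c(t1 = 0, t2 = 100)), "positive")

  expect_equal(relative_to_min_copies(c(10, 20, 40)), c(1, 2, 4))
  expect_equal(relative_to_min_copies(c(3, 3, 3)), c(1, 1, 1))
  x <- c(4.2, 9.8, 5.1)
  expect_equal(relative_to_min_copies(x * 1e6), relative_to_min_copies(x))
  expect_error(relative_to_min_copies(c(1, 0, 2)), "positive")
})

test_that("fold change is max over min", {
  expect_equal(fold_change(c(5, 5, 5)), 1)
  expect_equal(fold_change(c(1, 2, 4)), 4)
})

test_that("validation verdicts implement the r/fold-change rule set", {
  rnaseq <- c(0, 1, 2.5, 2.0, 0.5, 0.2)
  # qPCR exactly tracking RNA-seq: r = 1, validated
  qpcr <- 2^rnaseq
  v <- validate_qpcr(qpcr, rnaseq)
  expect_identical(v$verdict, "validated")
  expect_equal(v$pearson_r, 1)

  # flat series with fold change 1.5: no significant change (norZ analogue)
  flatq <- c(1, 1.2, 1.5, 1.3, 1.1, 1.0)
  expect_lt(fold_change(flatq), 2)
  v <- validate_qpcr(flatq, rnaseq)
  expect_identical(v$verdict, "no_significant_change")

  # anti-correlated with fold change >= 2: not validated
  anti <- 2^(max(rnaseq) - rnaseq)
  v <- validate_qpcr(anti, rnaseq)
  expect_identical(v$verdict, "not_validated")
  expect_lt(v$pearson_r, 0)

  # verdicts are invariant to multiplicative rescaling of the qPCR series
  for (series in list(qpcr, flatq, anti)) {
    expect_identical(validate_qpcr(series * 1e4, rnaseq)$verdict,
                     validate_qpcr(series, rnaseq)$verdict)
  }
  expect_error(validate_qpcr(qpcr, rnaseq[-1]), "lengths differ")
})

test_that("NRTC delta-CT averages pairs and raises the advisory flag", {
  expect_equal(nrtc_delta_ct(c(20, 22), c(20, 22))$mean_delta_ct, 0)
  res <- nrtc_delta_ct(c(20, 22), c(30, 32))
  expect_equal(res$mean_delta_ct, 10)
  expect_false(res$contamination_advisory)
  expect_true(nrtc_delta_ct(c(20, 22), c(23, 25))$contamination_advisory)
  expect_error(nrtc_delta_ct(c(20, 22), 30), "paired")
})

test_that("simulated qPCR series validate against their own truth", {
  ok <- 0L
  for (seed in 1:100) {
    truth <- c(1, 1, 4.2, 4.0, 1.1, 1)  # induced gene, fold >= 4
    names(truth) <- sprintf("t%d", 1:6)
    series <- simulate_qpcr(truth, noise_cv = 0.1, seed = seed)
    ratio <- normalize_to_reference(series$target, series$reference)
    v <- validate_qpcr(relative_to_min_copies(ratio), log2(truth))
    if (v$verdict == "validated") ok <- ok + 1L
  }
  expect_gte(ok / 100, 0.95)
})

test_that("noise-free qPCR is exactly proportional to truth", {
  truth <- c(t1 = 1, t2 = 2, t3 = 8)
  s <- simulate_qpcr(truth, noise_cv = 0, seed = 4)
  expect_equal(unname(s$target / truth), rep(1e4, 3))
  expect_equal(unname(s$reference), rep(1e5, 3))
  s2 <- simulate_qpcr(truth, noise_cv = 0.2, seed = 9)
  s3 <- simulate_qpcr(truth, noise_cv = 0.2, seed = 9)
  expect_identical(s2, s3)  # seed reproducibility
})

test_that("qPCR long-format TSV reads back into named series", {
  df <- data.frame(gene = rep(c("narG", "rpoN"), each = 3),
                   timepoint = rep(c("t1", "t2", "t3"), 2),
                   copies = c(10, 40, 20, 100, 110, 95))
  path <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  series <- read_qpcr_tsv(path)
  expect_setequal(names(series), c("narG", "rpoN"))
  expect_equal(series$narG, c(t1 = 10, t2 = 40, t3 = 20))
})
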