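# Synthetic-data generators with recorded ground truth. Every generator is
# a pure function of (scenario, seed): per-component seeds are derived from
# the scenario seed so changing one knob does not reshuffle the others.

#' Default synthetic scenario
#'
#' Emulates the study design the pipeline targets: one bacterial genome
#' with genes laid out in same-strand operons, GC-rich background
#' (62.5% GC), promoters carrying a planted 14-bp palindromic binding site
#' (TTGAT-N4-ATCAA core, the canonical FNR box shape) at controlled
#' information content and occupancy, and a six-timepoint
#' anaerobic/microaerobic count series: two anaerobic samples, four
#' microaerobic samples of which the last two are at elevated dissolved
#' oxygen. Genes in positive-regulon operons are induced (x `induction_fold`)
#' at low-oxygen timepoints, negative-regulon genes at high-oxygen
#' timepoints; counts are negative-binomial with per-sample library
#' factors.
#'
#' @param seed master integer seed.
#' @param n_genes genes per genome (default 80).
#' @param n_genomes genomes in a conservation panel (default 8).
#' @param operon_size_probs probabilities of operon sizes 1..4
#'   (default c(0.55, 0.2, 0.15, 0.1)).
#' @param intra_operon_gap_bp range of gaps within operons (default
#'   20-200 bp, comfortably under the 1,000-bp operon rule).
#' @param inter_operon_gap_bp range of gaps between operons (default
#'   320-900 bp so most leaders have a full 300-bp promoter).
#' @param gene_length_bp range of gene lengths (default 600-1500).
#' @param background_composition A/C/G/T probabilities (default GC 62.5%).
#' @param motif_consensus planted consensus (default
#'   `"TTGATCGGGATCAA"`, width 14).
#' @param motif_ic_bits_per_column information content per column of the
#'   planted PWM (default 1.8 bits).
#' @param occupancy probability a regulon promoter carries a site
#'   (default 0.8).
#' @param n_positive_operons,n_negative_operons operons assigned to the
#'   positive/negative regulon (defaults 8 and 6).
#' @param phase_labels per-timepoint oxygen phase (default 4 low, 2 high).
#' @param induction_fold linear fold induction of regulated genes in their
#'   active phase (default 4).
#' @param dispersion negative-binomial dispersion (default 0.02; 0 gives
#'   Poisson).
#' @param baseline_temporal_sd_log2 per-operon temporal variation of the
#'   baseline (default 1 log2 unit): operon members share it, so
#'   co-expression is informative for operon calling even for unregulated
#'   operons.
#' @param operon_jitter_sd_log2 within-operon lognormal jitter (default
#'   0.05).
#' @param library_depth_range range of merged, rRNA-filtered reads per
#'   sample (default 5e6-2e7).
#' @param mapped_fraction_range range of genome-mapped fractions (default
#'   0.48-0.50).
#' @param qpcr_noise_cv coefficient of variation of qPCR lognormal noise
#'   (default 0.1).
#' @param family_presence_prob probability a gene family is present in a
#'   panel genome (default 0.9).
#' @return a list of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(seed = 1L,
                               n_genes = 80L,
                               n_genomes = 8L,
                               operon_size_probs = c(0.55, 0.2, 0.15, 0.1),
                               intra_operon_gap_bp = c(20L, 200L),
                               inter_operon_gap_bp = c(320L, 900L),
                               gene_length_bp = c(600L, 1500L),
                               background_composition = c(0.1875, 0.3125,
                                                          0.3125, 0.1875),
                               motif_consensus = "TTGATCGGGATCAA",
                               motif_ic_bits_per_column = 1.8,
                               occupancy = 0.8,
                               n_positive_operons = 8L,
                               n_negative_operons = 6L,
                               phase_labels = c("low_oxygen", "low_oxygen",
                                                "low_oxygen", "low_oxygen",
                                                "high_oxygen", "high_oxygen"),
                               induction_fold = 4,
                               dispersion = 0.02,
                               baseline_temporal_sd_log2 = 1,
                               operon_jitter_sd_log2 = 0.05,
                               library_depth_range = c(5e6, 2e7),
                               mapped_fraction_range = c(0.48, 0.50),
                               qpcr_noise_cv = 0.1,
                               family_presence_prob = 0.9) {
  stopifnot(abs(sum(operon_size_probs) - 1) < 1e-9,
            induction_fold >= 1,
            occupancy >= 0, occupancy <= 1,
            dispersion >= 0,
            all(phase_labels %in% c("low_oxygen", "high_oxygen")))
  background_model(background_composition)  # validates
  sc <- as.list(environment())
  class(sc) <- "synthetic_scenario"
  sc
}

#' Generate an iid background sequence
#'
#' @param length sequence length in bp (>= 0).
#' @param composition A/C/G/T probabilities.
#' @param seed integer seed.
#' @return a character string.
#' @export
generate_background <- function(length, composition = rep(0.25, 4), seed = 1L) {
  stopifnot(length >= 0)
  if (length == 0) return("")
  background_model(composition)
  with_seed(seed, paste(sample(DNA_BASES, length, replace = TRUE,
                               prob = composition), collapse = ""))
}

#' PWM with a given consensus and per-column information content
#'
#' Solves for the consensus-base probability p (other bases equal) whose
#' Kullback-Leibler information against the background matches the target;
#' consensus positions given as `N` get background columns (0 bits).
#'
#' @param consensus character string over ACGTN.
#' @param ic_bits_per_column target information content per non-N column.
#' @param background a [background_model()].
#' @return a `pwm` object.
#' @export
consensus_pwm <- function(consensus, ic_bits_per_column = 1.8,
                          background = background_model()) {
  bases <- strsplit(toupper(consensus), "")[[1]]
  stopifnot(all(bases %in% c(DNA_BASES, "N")))
  bg <- as.numeric(background)
  col_for <- function(b) {
    if (b == "N") return(bg)
    bi <- match(b, DNA_BASES)
    others <- setdiff(1:4, bi)
    ic_of <- function(p) {
      q <- (1 - p) / 3
      p * log2(p / bg[bi]) + sum(q * log2(q / bg[others]))
    }
    # information grows monotonically in p above the background frequency
    hi <- 1 - 1e-9
    if (ic_of(hi) < ic_bits_per_column) {
      p <- hi
    } else {
      p <- stats::uniroot(function(p) ic_of(p) - ic_bits_per_column,
                          lower = max(bg[bi], 0.26), upper = hi,
                          tol = 1e-12)$root
    }
    col <- rep((1 - p) / 3, 4)
    col[bi] <- p
    col
  }
  prob <- vapply(bases, col_for, numeric(4))
  new_pwm(matrix(prob, nrow = 4L))
}

#' Generate a synthetic genome layout with planted operons
#'
#' Genes are laid out left to right on one contig: operon sizes are drawn
#' from `operon_size_probs`, members share a strand and are separated by
#' intra-operon gaps (always within the 1,000-bp operon rule), and operons
#' are separated by larger intergenic gaps. The contig sequence is iid
#' background; the truth records operon membership, per-gene family ids
#' (one family per truth operon), and regulation signs for the designated
#' positive/negative regulon operons.
#'
#' @param scenario a [synthetic_scenario()].
#' @param genome_id identifier (default `"synthetic_genome"`).
#' @param seed integer seed; defaults to streams derived from
#'   `scenario$seed`.
#' @return list with `genome` (a [genome_record()]) and `truth` (list:
#'   `operons` list of gene-id vectors, `family_of` named vector,
#'   `sign_of_family` named vector with values
#'   positive/negative/unregulated, `gene_sign` named per-gene vector).
#' @export
generate_genome_layout <- function(scenario, genome_id = "synthetic_genome",
                                   seed = NULL) {
  sc <- scenario
  seed <- seed %||% derive_seed(sc$seed, paste0("layout_", genome_id))
  n <- sc$n_genes
  if (n == 0L) {
    genome <- genome_record(genome_id,
                            stats::setNames(generate_background(
                              1000L, sc$background_composition,
                              derive_seed(seed, "sequence")), "contig_1"),
                            NULL)
    return(list(genome = genome,
                truth = list(operons = list(), family_of = character(),
                             sign_of_family = character(),
                             gene_sign = character())))
  }
  layout <- with_seed(seed, {
    sizes <- integer(0)
    while (sum(sizes) < n) {
      sizes <- c(sizes, sample(seq_along(sc$operon_size_probs), 1L,
                               prob = sc$operon_size_probs))
    }
    sizes[length(sizes)] <- sizes[length(sizes)] - (sum(sizes) - n)
    sizes <- sizes[sizes > 0L]
    strands <- sample(c("+", "-"), length(sizes), replace = TRUE)
    lens <- sample(sc$gene_length_bp[1]:sc$gene_length_bp[2], n, replace = TRUE)
    inter <- sample(sc$inter_operon_gap_bp[1]:sc$inter_operon_gap_bp[2],
                    length(sizes), replace = TRUE)
    intra <- sample(sc$intra_operon_gap_bp[1]:sc$intra_operon_gap_bp[2],
                    max(n - 1L, 1L), replace = TRUE)
    list(sizes = sizes, strands = strands, lens = lens, inter = inter,
         intra = intra)
  })
  gene_id <- sprintf("%s_g%03d", genome_id, seq_len(n))
  start <- integer(n); end <- integer(n); strand <- character(n)
  operons <- vector("list", length(layout$sizes))
  pos <- 0L
  gi <- 0L
  ii <- 0L
  for (k in seq_along(layout$sizes)) {
    pos <- pos + layout$inter[k]
    members <- integer(0)
    for (m in seq_len(layout$sizes[k])) {
      gi <- gi + 1L
      if (m > 1L) {
        ii <- ii + 1L
        pos <- pos + layout$intra[ii]
      }
      start[gi] <- pos + 1L
      end[gi] <- pos + layout$lens[gi]
      strand[gi] <- layout$strands[k]
      pos <- end[gi]
      members <- c(members, gi)
    }
    operons[[k]] <- gene_id[members]
  }
  contig_len <- pos + 500L
  contig <- generate_background(contig_len, sc$background_composition,
                                derive_seed(seed, "sequence"))
  genome <- genome_record(genome_id,
                          stats::setNames(contig, "contig_1"),
                          data.frame(gene_id = gene_id, contig_id = "contig_1",
                                     start = start, end = end, strand = strand,
                                     stringsAsFactors = FALSE))
  fam_ids <- sprintf("fam%03d", seq_along(operons))
  family_of <- stats::setNames(rep(fam_ids, lengths(operons)),
                               unlist(operons))
  n_ops <- length(operons)
  n_pos <- min(sc$n_positive_operons, n_ops)
  n_neg <- min(sc$n_negative_operons, max(n_ops - n_pos, 0L))
  regulated <- with_seed(derive_seed(seed, "regulon"),
                         sample(n_ops, n_pos + n_neg))
  sign_of_family <- stats::setNames(rep("unregulated", n_ops), fam_ids)
  sign_of_family[regulated[seq_len(n_pos)]] <- "positive"
  if (n_neg > 0L) sign_of_family[regulated[n_pos + seq_len(n_neg)]] <- "negative"
  gene_sign <- stats::setNames(sign_of_family[family_of], names(family_of))
  list(genome = genome,
       truth = list(operons = operons, family_of = family_of,
                    sign_of_family = sign_of_family, gene_sign = gene_sign))
}

#' Plant motif sites into a genome's promoter regions
#'
#' For each anchor gene (Bernoulli `occupancy`), a site sampled from the
#' PWM replaces a uniformly chosen window of the anchor's promoter, on a
#' uniformly chosen strand; the contig sequence is edited in place and the
#' planted position/strand (promoter-relative, 0-based offset) recorded.
#' Promoters shorter than the motif are skipped with a message.
#'
#' @param genome a [genome_record()].
#' @param anchors gene ids whose promoters receive sites.
#' @param pwm the planted `pwm`.
#' @param occupancy probability in \[0, 1\] that a promoter gets a site.
#' @param seed integer seed.
#' @param window_bp promoter window (default 300).
#' @return list with `genome` (edited) and `sites` (data frame:
#'   `anchor_id`, `offset`, `strand`, `site`).
#' @export
plant_motif <- function(genome, anchors, pwm, occupancy = 1, seed = 1L,
                        window_bp = 300L) {
  w <- pwm$width
  sites <- list()
  skipped <- 0L
  with_seed(seed, {
    for (a in anchors) {
      if (stats::runif(1) > occupancy) next
      p <- extract_promoter(genome, a, window_bp)
      L <- nchar(p$sequence)
      if (L < w) { skipped <- skipped + 1L; next }
      off <- sample(L - w + 1L, 1L) - 1L
      site <- paste(DNA_BASES[apply(pwm$prob, 2L, function(col)
        sample(1:4, 1L, prob = col))], collapse = "")
      strand_rel <- sample(c("+", "-"), 1L)
      oriented <- if (strand_rel == "-") reverse_complement(site) else site
      # map the promoter-relative window back to forward contig coordinates
      if (p$strand == "+") {
        fstart <- p$start + off
        fseq <- oriented
      } else {
        fstart <- p$end - off - w + 1L
        fseq <- reverse_complement(oriented)
      }
      contig <- genome$contigs[[p$contig_id]]
      substr(contig, fstart, fstart + w - 1L) <- fseq
      genome$contigs[[p$contig_id]] <- contig
      sites[[length(sites) + 1L]] <- data.frame(
        anchor_id = a, offset = off, strand = strand_rel, site = site,
        stringsAsFactors = FALSE)
    }
  })
  if (skipped > 0L) message(skipped, " promoter(s) too short for the motif; skipped")
  sites_df <- if (length(sites)) do.call(rbind, sites) else
    data.frame(anchor_id = character(), offset = integer(),
               strand = character(), site = character(),
               stringsAsFactors = FALSE)
  list(genome = genome, sites = sites_df)
}

#' Simulate a phase-structured expression count matrix
#'
#' Each operon draws one baseline log2 expression level; positive-regulon
#' genes are multiplied by `induction_fold` at low-oxygen timepoints,
#' negative-regulon genes at high-oxygen timepoints. Operon members share
#' the profile up to small lognormal jitter. Counts are negative-binomial
#' with mean proportional to expression x gene length x effective library
#' size; per-sample library factors are drawn from the scenario ranges and
#' emitted alongside.
#'
#' @param layout output of [generate_genome_layout()].
#' @param scenario the [synthetic_scenario()].
#' @param seed integer seed; defaults to a stream derived from
#'   `scenario$seed`.
#' @return list with `counts` (genes x samples integer matrix), `factors`
#'   (a [library_factors()] table), `true_log2_expr` (genes x samples
#'   matrix of noise-free log2 relative expression), `phase_labels`.
#' @export
simulate_expression <- function(layout, scenario, seed = NULL) {
  sc <- scenario
  seed <- seed %||% derive_seed(sc$seed, "counts")
  genes <- layout$genome$genes
  n <- nrow(genes)
  tp <- length(sc$phase_labels)
  samples <- sprintf("t%d", seq_len(tp))
  low <- sc$phase_labels == "low_oxygen"
  fam <- layout$truth$family_of[genes$gene_id]
  sign <- layout$truth$gene_sign[genes$gene_id]
  out <- with_seed(seed, {
    fams <- unique(fam)
    base_fam <- stats::setNames(
      stats::rnorm(length(fams), mean = 5, sd = 1.5), fams)
    # shared per-operon temporal deviation: all members move together. The
    # deviation is centered within each oxygen phase so that unregulated
    # operons have exactly zero realized phase contrast (being unregulated
    # means no oxygen response by construction); the induction term below is
    # the only source of phase signal
    dev_fam <- matrix(stats::rnorm(length(fams) * tp, 0,
                                   sc$baseline_temporal_sd_log2),
                      nrow = length(fams), dimnames = list(fams, samples))
    for (ph in unique(sc$phase_labels)) {
      cols <- sc$phase_labels == ph
      dev_fam[, cols] <- dev_fam[, cols, drop = FALSE] -
        rowMeans(dev_fam[, cols, drop = FALSE])
    }
    log2_expr <- matrix(rep(base_fam[fam], tp), nrow = n,
                        dimnames = list(genes$gene_id, samples)) +
      dev_fam[fam, , drop = FALSE]
    lfold <- log2(sc$induction_fold)
    log2_expr[sign == "positive", low] <- log2_expr[sign == "positive", low] + lfold
    log2_expr[sign == "negative", !low] <- log2_expr[sign == "negative", !low] + lfold
    depth <- stats::runif(tp, sc$library_depth_range[1], sc$library_depth_range[2])
    mapped <- stats::runif(tp, sc$mapped_fraction_range[1],
                           sc$mapped_fraction_range[2])
    factors <- library_factors(samples,
                               total_unmerged_reads = round(depth * 4),
                               merged_filtered_reads = round(depth),
                               mapped_fraction = mapped)
    jitter <- matrix(stats::rnorm(n * tp, 0, sc$operon_jitter_sd_log2),
                     nrow = n)
    mu <- 2^(log2_expr + jitter) *
      (genes$length_bp / 1000) *
      matrix(rep(factors$n_eff / 1e6, each = n), nrow = n)
    counts <- if (sc$dispersion > 0) {
      matrix(stats::rnbinom(n * tp, mu = mu, size = 1 / sc$dispersion),
             nrow = n, dimnames = dimnames(log2_expr))
    } else {
      matrix(stats::rpois(n * tp, lambda = mu),
             nrow = n, dimnames = dimnames(log2_expr))
    }
    list(counts = counts, factors = factors, true_log2_expr = log2_expr)
  })
  out$phase_labels <- sc$phase_labels
  out
}

#' Simulate a qPCR copy-number series (plus reference gene)
#'
#' Copies are proportional to the linear relative truth with lognormal
#' noise of coefficient of variation `noise_cv`; a constant-truth
#' reference series is generated likewise.
#'
#' @param true_relative positive numeric vector: the gene's true linear
#'   relative profile (e.g. `2^delta_log2`).
#' @param noise_cv coefficient of variation (>= 0).
#' @param seed integer seed.
#' @param scale copy-number scale of the target (default 1e4).
#' @param reference_scale copy-number scale of the reference (default 1e5).
#' @return list with `target` and `reference` named copy vectors.
#' @export
simulate_qpcr <- function(true_relative, noise_cv = 0.1, seed = 1L,
                          scale = 1e4, reference_scale = 1e5) {
  stopifnot(noise_cv >= 0, all(true_relative > 0))
  tp <- names(true_relative) %||% sprintf("t%d", seq_along(true_relative))
  sdlog <- sqrt(log(1 + noise_cv^2))
  with_seed(seed, {
    noise_t <- if (noise_cv > 0) stats::rlnorm(length(true_relative), 0, sdlog) else 1
    noise_r <- if (noise_cv > 0) stats::rlnorm(length(true_relative), 0, sdlog) else 1
    list(target = stats::setNames(scale * true_relative * noise_t, tp),
         reference = stats::setNames(rep(reference_scale, length(true_relative)) *
                                       noise_r, tp))
  })
}

#' Simulate a multi-genome panel for regulon conservation
#'
#' Generates `n_genomes` genomes with a shared family structure (same
#' scenario layout stream, so operon/family k corresponds across genomes),
#' drops each family from each genome with probability
#' `1 - family_presence_prob`, and plants motif sites in the promoters of
#' regulon-family operon leaders at the scenario occupancy.
#'
#' @param scenario a [synthetic_scenario()].
#' @return list with `genomes` (named list of [genome_record()]),
#'   `family_map` (gene -> family over all genomes), `truth` (per-genome
#'   planted sites and the shared `sign_of_family`), and `pwm` (the planted
#'   PWM).
#' @export
simulate_regulon_panel <- function(scenario) {
  sc <- scenario
  pwm <- consensus_pwm(sc$motif_consensus, sc$motif_ic_bits_per_column,
                       background_model(sc$background_composition))
  base <- generate_genome_layout(sc, genome_id = "panel_template",
                                 seed = derive_seed(sc$seed, "panel_layout"))
  sign_of_family <- base$truth$sign_of_family
  regulon_fams <- names(sign_of_family)[sign_of_family != "unregulated"]
  genomes <- list()
  family_map <- character(0)
  sites <- list()
  for (g in seq_len(sc$n_genomes)) {
    gid <- sprintf("genome%02d", g)
    # same layout stream => same operon/family structure, new sequence
    lay <- generate_genome_layout(sc, genome_id = gid,
                                  seed = derive_seed(sc$seed, "panel_layout"))
    # re-key gene ids already carry the genome id; re-derive sequence so
    # genomes differ
    lay$genome$contigs[["contig_1"]] <- generate_background(
      nchar(lay$genome$contigs[["contig_1"]]), sc$background_composition,
      derive_seed(sc$seed, paste0("panel_seq_", g)))
    keep_fams <- with_seed(derive_seed(sc$seed, paste0("panel_presence_", g)), {
      fams <- names(sign_of_family)
      fams[stats::runif(length(fams)) <= sc$family_presence_prob]
    })
    keep_genes <- names(lay$truth$family_of)[lay$truth$family_of %in% keep_fams]
    genes <- lay$genome$genes[lay$genome$genes$gene_id %in% keep_genes, ]
    genome <- genome_record(gid, lay$genome$contigs, genes)
    fam_of <- lay$truth$family_of[keep_genes]
    # operon leaders among retained genes for regulon families
    anchors <- vapply(lay$truth$operons, function(members) {
      members <- members[members %in% keep_genes]
      if (length(members) == 0L) return(NA_character_)
      operon_anchor(genome, members)
    }, character(1))
    reg_anchor <- anchors[!is.na(anchors) &
                            names(sign_of_family) %in% regulon_fams]
    planted <- plant_motif(genome, reg_anchor, pwm, occupancy = sc$occupancy,
                           seed = derive_seed(sc$seed, paste0("panel_plant_", g)))
    genomes[[gid]] <- planted$genome
    family_map <- c(family_map, fam_of)
    sites[[gid]] <- planted$sites
  }
  list(genomes = genomes, family_map = family_map,
       truth = list(sites = sites, sign_of_family = sign_of_family),
       pwm = pwm)
}
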