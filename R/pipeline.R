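# End-to-end orchestration: normalize -> operons -> promoters ->
# discover/scan -> regulon -> cluster -> (optional) qPCR validation.

#' Pipeline configuration
#'
#' Collects every numeric threshold of the analysis with its published
#' default: 300-bp promoter window, scan p-value 1e-5, operon rules
#' (Pearson 0.7, gap 1,000 bp), regulon support of 4 genomes, qPCR rules
#' (r 0.5, 2-fold). Unknown arguments are rejected.
#'
#' @param promoter_window_bp promoter window (default 300).
#' @param scan_alpha motif-scan p-value threshold (default 1e-5).
#' @param min_pearson,max_gap_bp operon-calling rules (defaults 0.7, 1000).
#' @param min_genomes regulon support threshold (default 4).
#' @param motif_width discovery width (default 14; allowed 6-30).
#' @param n_restarts EM restarts (default 5).
#' @param cluster_k number of profile clusters (default 2: one positively,
#'   one negatively regulated group); `NULL` with `cut_height` set cuts the
#'   tree at a height instead.
#' @param cut_height optional dendrogram cut height.
#' @param linkage clustering linkage (default `"average"`).
#' @param sign_tolerance flat-call tolerance in delta log2 RPKM
#'   (default 0.5).
#' @param r_min,fc_min qPCR validation rules (defaults 0.5, 2).
#' @param pseudocount RPKM pseudocount in reads (default 1).
#' @param seed master seed fanned out to per-component streams.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(promoter_window_bp = 300L,
                            scan_alpha = 1e-5,
                            min_pearson = 0.7,
                            max_gap_bp = 1000L,
                            min_genomes = 4L,
                            motif_width = 14L,
                            n_restarts = 5L,
                            cluster_k = 2L,
                            cut_height = NULL,
                            linkage = "average",
                            sign_tolerance = 0.5,
                            r_min = 0.5,
                            fc_min = 2,
                            pseudocount = 1,
                            seed = 1L) {
  assert_scalar_number(promoter_window_bp, "promoter_window_bp", lower = 1)
  if (!is.numeric(scan_alpha) || length(scan_alpha) != 1L ||
      scan_alpha <= 0 || scan_alpha > 1) {
    stop("scan_alpha must be in (0, 1]", call. = FALSE)
  }
  assert_scalar_number(min_pearson, "min_pearson", lower = -1, upper = 1)
  assert_scalar_number(max_gap_bp, "max_gap_bp", lower = 0)
  assert_scalar_number(min_genomes, "min_genomes", lower = 1)
  assert_scalar_number(motif_width, "motif_width", lower = 6, upper = 30)
  if (!is.null(cluster_k)) assert_scalar_number(cluster_k, "cluster_k", lower = 1)
  cfg <- list(promoter_window_bp = as.integer(promoter_window_bp),
              scan_alpha = scan_alpha,
              min_pearson = min_pearson,
              max_gap_bp = as.integer(max_gap_bp),
              min_genomes = as.integer(min_genomes),
              motif_width = as.integer(motif_width),
              n_restarts = as.integer(n_restarts),
              cluster_k = cluster_k,
              cut_height = cut_height,
              linkage = linkage,
              sign_tolerance = sign_tolerance,
              r_min = r_min,
              fc_min = fc_min,
              pseudocount = pseudocount,
              seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full regulon-inference pipeline on a synthetic scenario
#'
#' Executes the stages end to end with a single configuration:
#' simulate -> normalize (log2 RPKM, minimum-subtracted profiles) ->
#' operon calling -> promoter extraction -> motif discovery on
#' regulon-leader promoters -> both-strand scanning of all promoters ->
#' multi-genome conservation matrix -> profile clustering with
#' oxygen-phase sign calls -> qPCR cross-validation of selected genes.
#' All stage outputs are written under `out_dir`; the run is deterministic
#' given `(scenario, config)`.
#'
#' @param scenario a [synthetic_scenario()].
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if missing).
#' @param run_panel build the multi-genome conservation matrix
#'   (default TRUE).
#' @param run_qpcr simulate and validate qPCR for up to `n_qpcr_genes`
#'   regulated genes (default TRUE).
#' @param n_qpcr_genes genes to cross-validate (default 6, mirroring a
#'   six-gene assay panel).
#' @return a list of class `run_report`: per-stage record counts, the
#'   parameter echo, seed, and the output-file manifest. Stage results are
#'   attached in `$results`.
#' @export
run_pipeline <- function(scenario, config = pipeline_config(),
                         out_dir = tempfile("fnrscan_run_"),
                         run_panel = TRUE, run_qpcr = TRUE,
                         n_qpcr_genes = 6L) {
  stopifnot(inherits(scenario, "synthetic_scenario"),
            inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- character(0)
  emit <- function(writer, obj, name, ...) {
    path <- file.path(out_dir, name)
    writer(obj, path, ...)
    manifest <<- c(manifest, path)
    path
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  # -- simulate ------------------------------------------------------------
  bg <- background_model(scenario$background_composition)
  planted_pwm <- consensus_pwm(scenario$motif_consensus,
                               scenario$motif_ic_bits_per_column, bg)
  layout <- stage("simulate", generate_genome_layout(scenario))
  regulon_fams <- names(layout$truth$sign_of_family)[
    layout$truth$sign_of_family != "unregulated"]
  reg_anchors <- vapply(layout$truth$operons[
    layout$truth$family_of[vapply(layout$truth$operons, `[`, "", 1L)] %in%
      regulon_fams],
    function(m) operon_anchor(layout$genome, m), character(1))
  planted <- stage("simulate", plant_motif(
    layout$genome, reg_anchors, planted_pwm, occupancy = scenario$occupancy,
    seed = derive_seed(scenario$seed, "plant"),
    window_bp = config$promoter_window_bp))
  layout$genome <- planted$genome
  sim <- stage("simulate", simulate_expression(layout, scenario))
  emit(function(o, p) write_genome(o, p, sub("\\.fa$", ".gff3", p)),
       layout$genome, "genome.fa")
  manifest <- c(manifest, file.path(out_dir, "genome.gff3"))

  # -- normalize -----------------------------------------------------------
  expr <- stage("normalize", compute_log2_rpkm(
    sim$counts, sim$factors,
    stats::setNames(layout$genome$genes$length_bp, layout$genome$genes$gene_id),
    pseudocount = config$pseudocount))
  profiles <- relative_to_min(expr)
  emit(write_expression_tsv, profiles, "profiles.tsv")

  # -- operons -------------------------------------------------------------
  operons <- stage("operons", call_operons(
    layout$genome, profiles,
    operon_config(config$min_pearson, config$max_gap_bp)))
  emit(write_operons_tsv, operons, "operons.tsv")

  # -- promoters -----------------------------------------------------------
  promoters <- stage("promoters", suppressMessages(extract_promoters(
    layout$genome, window_bp = config$promoter_window_bp)))
  scannable <- promoters[nchar(promoters$sequence) >= config$motif_width, ]

  # -- discover ------------------------------------------------------------
  train <- promoters[promoters$anchor_id %in% reg_anchors &
                       nchar(promoters$sequence) >= config$motif_width, ]
  motif <- stage("discover", discover_motif(
    train, width = config$motif_width, n_restarts = config$n_restarts,
    seed = derive_seed(config$seed, "em"), background = bg))
  emit(function(o, p) write_meme_motif(o, p, background = bg, nsites = nrow(train)),
       motif, "motif.meme.txt")

  # -- scan ----------------------------------------------------------------
  hits <- stage("scan", scan_promoters(
    motif, scannable, background = bg, alpha = config$scan_alpha))
  emit(write_hits_tsv, hits, "hits.tsv")

  # -- regulon (conservation panel) ----------------------------------------
  conservation <- NULL
  if (run_panel) {
    panel <- stage("regulon", simulate_regulon_panel(scenario))
    panel_hits <- lapply(names(panel$genomes), function(gid) {
      pr <- suppressMessages(extract_promoters(
        panel$genomes[[gid]], window_bp = config$promoter_window_bp))
      pr <- pr[nchar(pr$sequence) >= motif$width, ]
      unique(scan_promoters(motif, pr, background = bg,
                            alpha = config$scan_alpha)$anchor_id)
    })
    names(panel_hits) <- names(panel$genomes)
    conservation <- stage("regulon", filter_by_support(
      build_conservation_matrix(panel_hits, panel$genomes, panel$family_map),
      min_genomes = config$min_genomes))
    emit(write_conservation_tsv, conservation, "conservation.tsv")
  }

  # -- cluster -------------------------------------------------------------
  regulon_genes <- names(layout$truth$gene_sign)[
    layout$truth$gene_sign != "unregulated"]
  hit_anchors <- unique(hits$anchor_id)
  hit_operons <- operons[operons$anchor_gene_id %in% hit_anchors, ]
  cluster_items <- unique(c(unlist(hit_operons$members)))
  cluster_items <- intersect(rownames(profiles), cluster_items)
  clust <- NULL
  signs <- NULL
  if (length(cluster_items) >= 2L) {
    k_use <- if (is.null(config$cluster_k)) NULL else
      min(config$cluster_k, length(cluster_items))
    clust <- stage("cluster", suppressMessages(cluster_profiles(
      profiles[cluster_items, , drop = FALSE],
      k = k_use, cut_height = config$cut_height,
      linkage = config$linkage)))
    means <- cluster_mean_profiles(profiles[cluster_items, , drop = FALSE], clust)
    signs <- classify_regulation_sign(means, sim$phase_labels,
                                      tolerance = config$sign_tolerance)
    emit(function(o, p) write_cluster_tsv(o$clust, o$signs, p),
         list(clust = clust, signs = signs), "clusters.tsv")
  }

  # -- qPCR validation -----------------------------------------------------
  qpcr <- NULL
  qpcr_skipped <- TRUE
  if (run_qpcr && length(regulon_genes) > 0L) {
    qpcr_skipped <- FALSE
    genes <- utils::head(sort(regulon_genes), n_qpcr_genes)
    qpcr <- lapply(genes, function(g) {
      truth_lin <- 2^(sim$true_log2_expr[g, ] - min(sim$true_log2_expr[g, ]))
      series <- simulate_qpcr(truth_lin, scenario$qpcr_noise_cv,
                              seed = derive_seed(scenario$seed, paste0("qpcr_", g)))
      ratio <- normalize_to_reference(series$target, series$reference)
      validate_qpcr(relative_to_min_copies(ratio), profiles[g, ],
                    r_min = config$r_min, fc_min = config$fc_min)
    })
    names(qpcr) <- genes
    emit(write_validation_tsv, qpcr, "qpcr_validation.tsv")
  }

  # -- truth + report ------------------------------------------------------
  truth_path <- file.path(out_dir, "truth.json")
  jsonlite::write_json(list(
    operons = layout$truth$operons,
    planted_sites = planted$sites,
    sign_of_family = as.list(layout$truth$sign_of_family)
  ), truth_path, auto_unbox = TRUE, digits = NA)
  manifest <- c(manifest, truth_path)

  report <- structure(list(
    seed = config$seed,
    scenario_seed = scenario$seed,
    parameters = unclass(config),
    counts = list(genes = nrow(layout$genome$genes),
                  operons = nrow(operons),
                  promoters_scanned = nrow(scannable),
                  motif_hits = nrow(hits),
                  conserved_families = if (is.null(conservation)) NA_integer_
                                       else ncol(conservation),
                  clustered_items = length(cluster_items),
                  qpcr_genes = if (qpcr_skipped) 0L else length(qpcr)),
    stages_skipped = c(regulon = !run_panel, qpcr = qpcr_skipped),
    manifest = manifest,
    results = list(genome = layout$genome, truth = layout$truth,
                   planted_sites = planted$sites, expression = expr,
                   profiles = profiles, operons = operons, motif = motif,
                   hits = hits, conservation = conservation,
                   clusters = clust, signs = signs, qpcr = qpcr,
                   phase_labels = sim$phase_labels)
  ), class = "run_report")
  missing <- manifest[!file.exists(manifest)]
  if (length(missing)) {
    stop("pipeline manifest lists missing file(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  cat("  seed:", x$seed, "(scenario", paste0(x$scenario_seed, ")"), "\n")
  for (nm in names(x$counts)) cat(sprintf("  %s: %s\n", nm, x$counts[[nm]]))
  cat("  outputs:", length(x$manifest), "file(s)\n")
  invisible(x)
}
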