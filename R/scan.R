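# FIMO-style promoter scanning on both strands with exact p-values.

#' @noRd
encode_bases <- function(seq) {
  match(strsplit(toupper(seq), "")[[1]], DNA_BASES)  # NA for ambiguous
}

#' Integer window scores for every offset of a sequence
#'
#' Sums the discretized column scores used by the exact null distribution,
#' so window p-values looked up from the distribution are exact for the
#' discretized statistic. Windows containing ambiguous bases return NA.
#'
#' @noRd
window_int_scores <- function(idx, iscore) {
  w <- ncol(iscore)
  m <- length(idx) - w + 1L
  if (m < 1L) return(integer(0))
  s <- rep(0L, m)
  na <- rep(FALSE, m)
  for (j in seq_len(w)) {
    b <- idx[j:(j + m - 1L)]
    na <- na | is.na(b)
    s <- s + ifelse(is.na(b), 0L, iscore[cbind(ifelse(is.na(b), 1L, b), j)])
  }
  s[na] <- NA_integer_
  s
}

#' Scan promoters for motif occurrences
#'
#' Slides the PWM over each promoter (and, when `both_strands`, over its
#' reverse complement) and reports every window whose exact p-value is at
#' most `alpha`. Overlapping hits are all reported; windows containing
#' ambiguous bases are skipped. For minus-strand hits, `offset` is the
#' 0-based position of the window's leftmost base in the promoter's own
#' (5'->3') orientation, so scanning a reverse-complemented promoter yields
#' the strand-swapped, offset-mirrored hit set.
#'
#' The p-value is computed per strand separately (single-strand null, no
#' doubling). By default the 0-order background is estimated from the
#' scanned promoter set itself.
#'
#' @param pwm a `pwm` object.
#' @param promoters data frame with columns `anchor_id` and `sequence`
#'   (e.g. from [extract_promoters()]), or a named character vector of
#'   sequences.
#' @param background a [background_model()]; `NULL` (default) estimates it
#'   from the promoter sequences.
#' @param alpha p-value threshold (default 1e-5).
#' @param both_strands scan the reverse complement too (default TRUE).
#' @param granularity discretization steps per bit (default 1000).
#' @return data frame of hits: `anchor_id`, `offset` (0-based),
#'   `strand` (relative to the promoter), `score` (log2-odds bits),
#'   `p_value`, `matched_sequence` (as read on the hit strand).
#' @export
scan_promoters <- function(pwm, promoters, background = NULL, alpha = 1e-5,
                           both_strands = TRUE, granularity = 1000L) {
  if (is.character(promoters)) {
    promoters <- data.frame(anchor_id = names(promoters) %||%
                              paste0("seq", seq_along(promoters)),
                            sequence = unname(promoters),
                            stringsAsFactors = FALSE)
  }
  stopifnot(nrow(promoters) >= 1L)
  if (is.null(background)) background <- estimate_background(promoters$sequence)
  thr <- score_threshold_for_pvalue(pwm, background, alpha, granularity)
  dist <- thr$dist
  iscore <- dist$int_scores
  real_score <- log2(sweep(pwm$prob, 1L, as.numeric(background), "/"))
  w <- pwm$width
  hits <- vector("list", nrow(promoters) * 2L)
  hn <- 0L
  emit <- function(anchor, seqc, idx, strand, L) {
    ints <- window_int_scores(idx, iscore)
    keep <- which(!is.na(ints) & ints >= thr$threshold_int)
    if (length(keep) == 0L) return(NULL)
    offs <- if (strand == "+") keep - 1L else L - w - (keep - 1L)
    matched <- substring(seqc, keep, keep + w - 1L)
    real <- vapply(keep, function(k) {
      b <- idx[k:(k + w - 1L)]
      sum(real_score[cbind(b, seq_len(w))])
    }, numeric(1))
    data.frame(anchor_id = anchor, offset = offs, strand = strand,
               score = real, p_value = pwm_pvalue(dist, ints[keep]),
               matched_sequence = matched, stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(promoters))) {
    seqf <- toupper(promoters$sequence[i])
    L <- nchar(seqf)
    if (L < w) next
    idxf <- encode_bases(seqf)
    hn <- hn + 1L
    hits[[hn]] <- emit(promoters$anchor_id[i], seqf, idxf, "+", L)
    if (both_strands) {
      seqr <- reverse_complement(gsub("[^ACGTN]", "N", seqf))
      idxr <- encode_bases(seqr)
      hn <- hn + 1L
      hits[[hn]] <- emit(promoters$anchor_id[i], seqr, idxr, "-", L)
    }
  }
  out <- do.call(rbind, hits[seq_len(hn)])
  if (is.null(out)) {
    out <- data.frame(anchor_id = character(), offset = integer(),
                      strand = character(), score = numeric(),
                      p_value = numeric(), matched_sequence = character(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out[order(out$anchor_id, out$offset, out$strand), , drop = FALSE]
}

#' Write motif hits as a FIMO-style TSV
#'
#' Columns: motif_id, sequence_name, start, stop, strand, score, p-value,
#' matched_sequence. Start/stop are 1-based inclusive within the promoter.
#'
#' @param hits data frame from [scan_promoters()].
#' @param path output TSV path.
#' @param motif_id motif identifier to stamp on every row.
#' @return invisibly, `path`.
#' @export
write_hits_tsv <- function(hits, path, motif_id = "motif_1") {
  w <- nchar(hits$matched_sequence)
  df <- data.frame(motif_id = motif_id,
                   sequence_name = hits$anchor_id,
                   start = hits$offset + 1L,
                   stop = hits$offset + w,
                   strand = hits$strand,
                   score = hits$score,
                   `p-value` = hits$p_value,
                   matched_sequence = hits$matched_sequence,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a PWM in MEME minimal motif text format
#'
#' @param pwm a `pwm` object.
#' @param path output path.
#' @param motif_id motif name.
#' @param background a [background_model()] recorded in the header.
#' @param nsites number of contributing sites recorded in the header.
#' @return invisibly, `path`.
#' @export
write_meme_motif <- function(pwm, path, motif_id = "motif_1",
                             background = background_model(), nsites = 20L) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "",
               "Background letter frequencies",
               paste(sprintf("%s %.5f", DNA_BASES, as.numeric(background)),
                     collapse = " "),
               "",
               paste("MOTIF", motif_id),
               sprintf("letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
                       pwm$width, nsites)), con)
  for (j in seq_len(pwm$width)) {
    writeLines(paste(sprintf("%.6f", pwm$prob[, j]), collapse = "  "), con)
  }
  invisible(path)
}

#' Read a MEME minimal-format motif back into a PWM
#'
#' Only the first motif in the file is read.
#'
#' @param path MEME motif text file.
#' @return a `pwm` object.
#' @export
read_meme_motif <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^letter-probability matrix", lines)[1]
  if (is.na(hdr)) stop("no letter-probability matrix found", call. = FALSE)
  w <- as.integer(sub(".*w= *([0-9]+).*", "\\1", lines[hdr]))
  rows <- lines[(hdr + 1L):(hdr + w)]
  prob <- t(vapply(strsplit(trimws(rows), "[[:space:]]+"),
                   function(x) as.numeric(x), numeric(4)))
  prob <- prob / rowSums(prob)  # renormalize printed rounding
  new_pwm(t(prob))
}
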