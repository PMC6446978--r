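# Position weight matrices: estimation, information content, log-odds
# scoring, and exact p-values for the scanning statistic.
#
# The null distribution of the log-odds score is computed exactly (up to
# integer discretization of column scores) by dynamic programming over
# column score distributions under a 0-order background -- the same
# construction FIMO uses. Discretization granularity is expressed in steps
# per bit (default 1000), the sole approximation in the p-value machinery.

#' Uniform or empirical 0-order background model
#'
#' @param probs numeric vector of 4 positive probabilities summing to 1, in
#'   A, C, G, T order. Defaults to uniform.
#' @return a named numeric vector of class `background`.
#' @export
background_model <- function(probs = rep(0.25, 4)) {
  probs <- as.numeric(probs)
  stopifnot(length(probs) == 4L)
  if (any(probs <= 0) || abs(sum(probs) - 1) > 1e-9) {
    stop("background probabilities must be positive and sum to 1", call. = FALSE)
  }
  names(probs) <- DNA_BASES
  class(probs) <- "background"
  probs
}

#' Estimate a 0-order background from sequences
#'
#' Counts A/C/G/T over all sequences (other letters ignored) with a +1
#' pseudocount per base so all probabilities are positive.
#'
#' @param sequences character vector of nucleotide sequences.
#' @return a [background_model()].
#' @export
estimate_background <- function(sequences) {
  chars <- unlist(strsplit(toupper(paste(sequences, collapse = "")), ""))
  counts <- vapply(DNA_BASES, function(b) sum(chars == b), numeric(1)) + 1
  background_model(counts / sum(counts))
}

#' Build a position weight matrix from aligned sites
#'
#' Column probabilities are `(count_j(b) + w * bg(b)) / (n + w)` where `w`
#' is the pseudocount weight distributed according to the background.
#'
#' @param sites character vector of equal-length ACGT sequences (>= 1).
#' @param pseudocount_weight total pseudocount weight per column
#'   (default 1); 0 gives raw frequencies.
#' @param background a [background_model()] used to apportion pseudocounts.
#' @return an object of class `pwm`: list with `width`, `prob` (4 x width
#'   matrix, rows A/C/G/T), `pseudocount_weight`, `sites`.
#' @export
build_pwm <- function(sites, pseudocount_weight = 1,
                      background = background_model()) {
  stopifnot(length(sites) >= 1L)
  sites <- toupper(sites)
  if (length(unique(nchar(sites))) != 1L) {
    stop("sites must have equal lengths", call. = FALSE)
  }
  if (any(grepl("[^ACGT]", sites))) {
    stop("sites must contain only ACGT", call. = FALSE)
  }
  assert_scalar_number(pseudocount_weight, "pseudocount_weight", lower = 0)
  w <- nchar(sites[1])
  mat <- do.call(rbind, strsplit(sites, ""))
  prob <- vapply(seq_len(w), function(j) {
    cnt <- vapply(DNA_BASES, function(b) sum(mat[, j] == b), numeric(1))
    (cnt + pseudocount_weight * as.numeric(background)) /
      (length(sites) + pseudocount_weight)
  }, numeric(4))
  rownames(prob) <- DNA_BASES
  new_pwm(prob, pseudocount_weight = pseudocount_weight, sites = sites)
}

#' Construct a PWM from a 4 x width probability matrix
#'
#' Rows are A, C, G, T; every column must sum to 1.
#'
#' @param prob numeric matrix, 4 x width.
#' @param pseudocount_weight recorded pseudocount weight (default 0).
#' @return a `pwm` object.
#' @export
pwm_from_matrix <- function(prob, pseudocount_weight = 0) {
  new_pwm(prob, pseudocount_weight = pseudocount_weight)
}

#' @noRd
new_pwm <- function(prob, pseudocount_weight = 0, sites = NULL) {
  stopifnot(is.matrix(prob), nrow(prob) == 4L)
  rownames(prob) <- DNA_BASES
  sums <- colSums(prob)
  if (any(abs(sums - 1) > 1e-9)) {
    stop("PWM columns must sum to 1", call. = FALSE)
  }
  structure(list(width = ncol(prob), prob = prob,
                 pseudocount_weight = pseudocount_weight, sites = sites),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm> width %d, consensus %s\n", x$width, pwm_consensus(x)))
  invisible(x)
}

#' Consensus sequence of a PWM (most probable base per column)
#'
#' @param pwm a `pwm` object.
#' @return a character string of length `pwm$width`.
#' @export
pwm_consensus <- function(pwm) {
  paste(DNA_BASES[apply(pwm$prob, 2L, which.max)], collapse = "")
}

#' Reverse complement of a PWM
#'
#' @param pwm a `pwm` object.
#' @return a `pwm` scoring the opposite strand.
#' @export
pwm_reverse_complement <- function(pwm) {
  prob <- pwm$prob[4:1, rev(seq_len(pwm$width)), drop = FALSE]
  new_pwm(prob, pseudocount_weight = pwm$pseudocount_weight)
}

#' Information content of a PWM
#'
#' Per column, `sum_b p(b) * log2(p(b) / bg(b))` (Kullback-Leibler
#' divergence from the background, in bits); zero-probability entries
#' contribute zero.
#'
#' @param pwm a `pwm` object.
#' @param background a [background_model()].
#' @return list with `per_column` (bits) and `total`.
#' @export
information_content <- function(pwm, background = background_model()) {
  bg <- as.numeric(background)
  per_col <- apply(pwm$prob, 2L, function(p) {
    nz <- p > 0
    sum(p[nz] * log2(p[nz] / bg[nz]))
  })
  list(per_column = per_col, total = sum(per_col))
}

#' Log-odds score of a window against a PWM
#'
#' `sum_j log2( p_j(window_j) / bg(window_j) )` in bits. Windows containing
#' ambiguous bases have an undefined score and return `NA` (scanners skip
#' them).
#'
#' @param pwm a `pwm` object.
#' @param window character string of length `pwm$width`.
#' @param background a [background_model()].
#' @return score in bits, or `NA_real_` for ambiguous windows.
#' @export
log_odds_score <- function(pwm, window, background = background_model()) {
  window <- toupper(window)
  if (nchar(window) != pwm$width) {
    stop("window length must equal PWM width", call. = FALSE)
  }
  idx <- match(strsplit(window, "")[[1]], DNA_BASES)
  if (anyNA(idx)) return(NA_real_)
  bg <- as.numeric(background)
  sum(log2(pwm$prob[cbind(idx, seq_len(pwm$width))] / bg[idx]))
}

#' Integer-discretized column score matrix
#'
#' @noRd
pwm_int_scores <- function(pwm, background, granularity) {
  bg <- as.numeric(background)
  real <- log2(sweep(pwm$prob, 1L, bg, "/"))
  if (any(!is.finite(real))) {
    # zero-probability entries: effectively -Inf; cap far below any
    # attainable threshold so such windows can never pass
    floor_val <- min(real[is.finite(real)], 0) - 100
    real[!is.finite(real)] <- floor_val
  }
  round(real * granularity)
}

#' Exact null distribution of the discretized log-odds score
#'
#' Dynamic programming over columns: the distribution of the total integer
#' score under the 0-order background is the convolution of the per-column
#' score distributions. Exact up to the integer discretization of column
#' scores (`granularity` steps per bit).
#'
#' @param pwm a `pwm` object.
#' @param background a [background_model()].
#' @param granularity discretization steps per bit (default 1000).
#' @return list of class `pwm_score_dist` with `offset` (integer score of
#'   the first cell), `prob` (probability vector over consecutive integer
#'   scores), `tail` (upper-tail probabilities, same indexing),
#'   `int_scores` (4 x width integer column scores), `granularity`.
#' @export
pwm_score_distribution <- function(pwm, background = background_model(),
                                   granularity = 1000L) {
  assert_scalar_number(granularity, "granularity", lower = 1)
  granularity <- as.integer(granularity)
  iscore <- pwm_int_scores(pwm, background, granularity)
  bg <- as.numeric(background)
  lo <- sum(apply(iscore, 2L, min))
  hi <- sum(apply(iscore, 2L, max))
  # prob[k] holds P(partial score == lo_partial + k - 1) where lo_partial is
  # the running sum of per-column minima; after the last column that running
  # minimum equals `lo`, so indices line up with the full score grid.
  prob <- numeric(hi - lo + 1L)
  for (b in 1:4) {
    k <- iscore[b, 1] - min(iscore[, 1]) + 1L
    prob[k] <- prob[k] + bg[b]
  }
  if (pwm$width > 1L) {
    for (j in 2:pwm$width) {
      nxt <- numeric(hi - lo + 1L)
      nzi <- which(prob > 0)
      minj <- min(iscore[, j])
      for (b in 1:4) {
        sh <- iscore[b, j] - minj
        nxt[nzi + sh] <- nxt[nzi + sh] + prob[nzi] * bg[b]
      }
      prob <- nxt
    }
  }
  tail_p <- rev(cumsum(rev(prob)))
  structure(list(offset = lo, prob = prob, tail = tail_p,
                 int_scores = iscore, granularity = granularity),
            class = "pwm_score_dist")
}

#' Upper-tail p-value of an integer score
#'
#' `P(score >= s)` under the background null, from a precomputed
#' [pwm_score_distribution()].
#'
#' @param dist a `pwm_score_dist`.
#' @param int_score integer score(s) on the distribution's discretized
#'   scale.
#' @return p-value(s) in (0, 1]; scores above the attainable maximum give 0,
#'   scores below the minimum give 1.
#' @export
pwm_pvalue <- function(dist, int_score) {
  n <- length(dist$tail)
  idx <- int_score - dist$offset + 1L
  out <- numeric(length(idx))
  out[idx < 1L] <- 1
  out[idx > n] <- 0
  ok <- idx >= 1L & idx <= n
  out[ok] <- dist$tail[idx[ok]]
  out
}

#' Score threshold attaining a target p-value
#'
#' Returns the smallest score `s` such that `P(score >= s) <= alpha` under
#' the exact discretized null. With `alpha = 1` the threshold is the
#' minimum attainable score (every window passes). If even the maximum
#' attainable score has tail probability above `alpha`, no window can pass
#' and the threshold is one discretization step above the maximum.
#'
#' @param pwm a `pwm` object.
#' @param background a [background_model()].
#' @param alpha target p-value in (0, 1] (default 1e-5).
#' @param granularity discretization steps per bit (default 1000).
#' @return list with `threshold_bits`, `threshold_int`, `p_value` (the
#'   attained tail probability at the threshold), and `dist` (the
#'   [pwm_score_distribution()], reusable by scanners).
#' @export
score_threshold_for_pvalue <- function(pwm, background = background_model(),
                                       alpha = 1e-5, granularity = 1000L) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha > 1) {
    stop("alpha must be in (0, 1]", call. = FALSE)
  }
  dist <- pwm_score_distribution(pwm, background, granularity)
  scores <- dist$offset + seq_along(dist$prob) - 1L
  pass <- which(dist$tail <= alpha)
  if (length(pass) == 0L) {
    thr <- max(scores) + 1L
    attained <- 0
  } else {
    thr_idx <- min(pass)  # tail is monotone non-increasing in the score
    thr <- scores[thr_idx]
    attained <- dist$tail[thr_idx]
  }
  list(threshold_bits = thr / dist$granularity,
       threshold_int = thr,
       p_value = attained,
       dist = dist)
}
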