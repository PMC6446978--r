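# De novo motif discovery: ZOOPS expectation-maximization over both strands.
#
# The model: each promoter carries zero or one motif occurrence. With prior
# occupancy gamma, an occurrence is uniform over positions and strands; the
# occurrence window is emitted by the PWM and everything else by a fixed
# 0-order background. The E-step computes the per-sequence posterior over
# (position, strand, none); the M-step re-estimates the PWM columns and
# gamma. The background is estimated once from the input and held fixed, so
# the log-likelihood is guaranteed non-decreasing across iterations.

#' Discover a motif by ZOOPS expectation-maximization
#'
#' Runs `n_restarts` seeded initializations, each seeded from a randomly
#' chosen promoter subsequence (a near-indicator PWM around that window),
#' and returns the model with the highest final log-likelihood. The
#' per-iteration log-likelihood trace of every restart is retained in the
#' result.
#'
#' @param promoters data frame with `anchor_id`/`sequence` columns, or a
#'   character vector of sequences; at least 4.
#' @param width motif width (default 14; must not exceed the shortest
#'   promoter).
#' @param n_restarts number of seeded initializations (default 5).
#' @param seed integer seed for reproducibility.
#' @param max_iter maximum EM iterations per restart (default 200).
#' @param tol absolute log-likelihood convergence tolerance (default 1e-6).
#' @param background a [background_model()]; `NULL` (default) estimates it
#'   from the promoters.
#' @param pseudocount_weight per-column pseudocount weight in the M-step
#'   (default 0.5), apportioned by the background.
#' @param occupancy_init initial occurrence prior (default 0.5).
#' @return a `pwm` object with extra fields `occupancy` (fitted gamma),
#'   `log_likelihood` (final EM objective: data log-likelihood plus the
#'   pseudocount prior), `ll_trace` (list, one numeric vector per restart),
#'   `converged` (logical per restart), `best_restart`, and
#'   `background`.
#' @export
discover_motif <- function(promoters, width = 14L, n_restarts = 5L, seed = 1L,
                           max_iter = 200L, tol = 1e-6, background = NULL,
                           pseudocount_weight = 0.5, occupancy_init = 0.5) {
  if (is.character(promoters)) {
    promoters <- data.frame(anchor_id = paste0("seq", seq_along(promoters)),
                            sequence = promoters, stringsAsFactors = FALSE)
  }
  seqs <- toupper(promoters$sequence)
  seqs <- seqs[nchar(seqs) >= width]
  if (length(seqs) < 4L) {
    stop("need >= 4 promoters at least `width` bp long", call. = FALSE)
  }
  width <- as.integer(width)
  if (is.null(background)) background <- estimate_background(seqs)
  bg <- as.numeric(background)
  log_bg <- log(bg)

  # Precompute per-sequence base-index matrices for all windows, both
  # strands; ambiguous bases get index NA and their windows are excluded.
  prep <- lapply(seqs, function(s) {
    idxf <- encode_bases(s)
    idxr <- encode_bases(reverse_complement(gsub("[^ACGTN]", "N", s)))
    m <- length(idxf) - width + 1L
    win <- function(idx) {
      mat <- vapply(seq_len(width), function(j) idx[j:(j + m - 1L)],
                    integer(m))
      if (m == 1L) mat <- matrix(mat, nrow = 1L)
      mat
    }
    Wf <- win(idxf); Wr <- win(idxr)
    ok <- !apply(is.na(Wf), 1L, any)
    okr <- !apply(is.na(Wr), 1L, any)
    # log background probability of the full sequence (ambiguous bases
    # contribute a flat 1/4)
    lb <- sum(ifelse(is.na(idxf), log(0.25), log_bg[idxf]))
    list(Wf = Wf[ok, , drop = FALSE], Wr = Wr[okr, , drop = FALSE],
         n_windows = sum(ok) + sum(okr), log_bg_seq = lb)
  })

  em_run <- function(pwm0, gamma0) {
    prob <- pwm0
    gamma <- gamma0
    ll_trace <- numeric(0)
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      log_ratio <- log(sweep(prob, 1L, bg, "/"))
      counts <- matrix(0, nrow = 4L, ncol = width)
      occ_post <- numeric(length(prep))
      ll <- 0
      for (s in seq_along(prep)) {
        p <- prep[[s]]
        if (p$n_windows == 0L) { ll <- ll + p$log_bg_seq; next }
        lr_f <- window_log_ratio(p$Wf, log_ratio)
        lr_r <- window_log_ratio(p$Wr, log_ratio)
        lr <- c(lr_f, lr_r)
        # posterior over options; no-site option has log-ratio 0
        prior_site <- gamma / p$n_windows
        mx <- max(lr, 0)
        wts <- exp(lr - mx) * prior_site
        w0 <- exp(-mx) * (1 - gamma)
        z <- sum(wts) + w0
        ll <- ll + p$log_bg_seq + mx + log(z)
        wts <- wts / z
        occ_post[s] <- sum(wts)
        counts <- counts + window_counts(p$Wf, wts[seq_len(nrow(p$Wf))], width) +
          window_counts(p$Wr, wts[nrow(p$Wf) + seq_len(nrow(p$Wr))], width)
      }
      # trace the penalized objective (log-likelihood plus the Dirichlet
      # pseudocount prior on columns): this is the quantity EM with a MAP
      # M-step provably never decreases
      ll_pen <- ll + pseudocount_weight * sum(bg * log(prob))
      ll_trace <- c(ll_trace, ll_pen)
      if (it > 1L && abs(ll_pen - ll_trace[it - 1L]) < tol) {
        converged <- TRUE
        break
      }
      # M-step
      prob <- sweep(counts + pseudocount_weight * bg, 2L,
                    colSums(counts) + pseudocount_weight, "/")
      gamma <- min(max(mean(occ_post), 1e-4), 1 - 1e-4)
    }
    list(prob = prob, gamma = gamma, ll = ll_trace[length(ll_trace)],
         ll_trace = ll_trace, converged = converged)
  }

  runs <- with_seed(seed, {
    lapply(seq_len(n_restarts), function(r) {
      s <- sample(seq_along(seqs), 1L)
      L <- nchar(seqs[s])
      pos <- sample(L - width + 1L, 1L)
      site <- encode_bases(substr(seqs[s], pos, pos + width - 1L))
      pwm0 <- matrix(0.1 / 3, nrow = 4L, ncol = width)
      for (j in seq_len(width)) {
        b <- site[j]
        if (is.na(b)) pwm0[, j] <- 0.25 else pwm0[b, j] <- 0.9
      }
      em_run(pwm0, occupancy_init)
    })
  })
  lls <- vapply(runs, `[[`, numeric(1), "ll")
  best <- which.max(lls)

  # Phase-shift refinement: EM can lock onto a column-shifted version of
  # the motif (the likelihood surface has near-optimal ridges offset by a
  # few columns). Re-seed EM from shifted copies of the best model
  # (vacated columns filled with background) and keep the best objective.
  shift_pwm <- function(prob, s) {
    out <- matrix(bg, nrow = 4L, ncol = width)
    if (s > 0) {
      out[, seq_len(width - s)] <- prob[, (s + 1L):width]
    } else {
      out[, (1L - s):width] <- prob[, seq_len(width + s)]
    }
    out
  }
  improved <- TRUE
  rounds <- 0L
  while (improved && rounds < 6L) {
    improved <- FALSE
    rounds <- rounds + 1L
    for (s in c(-2L, -1L, 1L, 2L)) {
      if (abs(s) >= width) next
      r2 <- em_run(shift_pwm(runs[[best]]$prob, s), runs[[best]]$gamma)
      runs[[length(runs) + 1L]] <- r2
      if (r2$ll > runs[[best]]$ll + 1e-9) {
        best <- length(runs)
        improved <- TRUE
      }
    }
  }
  if (!all(vapply(runs, `[[`, logical(1), "converged"))) {
    warning("EM did not converge within max_iter for ",
            sum(!vapply(runs, `[[`, logical(1), "converged")),
            " restart(s); best-so-far model returned")
  }
  out <- new_pwm(runs[[best]]$prob)
  out$occupancy <- runs[[best]]$gamma
  out$log_likelihood <- runs[[best]]$ll
  out$ll_trace <- lapply(runs, `[[`, "ll_trace")
  out$converged <- vapply(runs, `[[`, logical(1), "converged")
  out$best_restart <- best
  out$background <- background
  out
}

#' @noRd
window_log_ratio <- function(W, log_ratio) {
  if (nrow(W) == 0L) return(numeric(0))
  s <- numeric(nrow(W))
  for (j in seq_len(ncol(W))) s <- s + log_ratio[W[, j], j]
  s
}

#' @noRd
window_counts <- function(W, wts, width) {
  counts <- matrix(0, nrow = 4L, ncol = width)
  if (nrow(W) == 0L || sum(wts) == 0) return(counts)
  for (j in seq_len(width)) {
    counts[, j] <- counts[, j] +
      vapply(1:4, function(b) sum(wts[W[, j] == b]), numeric(1))
  }
  counts
}
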