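# Expression-profile clustering and oxygen-phase regulation-sign calls.

#' Cluster expression profiles by Pearson similarity
#'
#' Agglomerative hierarchical clustering with distance `1 - Pearson`
#' between profiles, cut either into `k` groups or at `cut_height`.
#' Constant (flat) profiles have undefined correlation: they are set aside
#' in a dedicated extra cluster and reported via a message. The result is
#' deterministic given the inputs and invariant to input order (hclust ties
#' are resolved on the sorted distance structure; items are sorted by id
#' internally).
#'
#' @param profiles numeric matrix, items x timepoints (>= 2 items,
#'   >= 3 timepoints), with item ids as rownames.
#' @param k number of clusters among non-flat items (mutually exclusive
#'   with `cut_height`).
#' @param cut_height dendrogram cut height on the `1 - r` scale.
#' @param linkage `"average"` (default), `"complete"`, or `"single"`.
#' @return a list of class `cluster_assignment`: `labels` (named integer
#'   vector, contiguous `1..n_clusters`), `n_clusters`, `flat_cluster`
#'   (integer label of the flat cluster, or `NA` if none), `linkage`,
#'   `hclust` (the tree over non-flat items).
#' @export
cluster_profiles <- function(profiles, k = NULL, cut_height = NULL,
                             linkage = c("average", "complete", "single")) {
  linkage <- match.arg(linkage)
  stopifnot(is.matrix(profiles), nrow(profiles) >= 2L, ncol(profiles) >= 3L,
            !is.null(rownames(profiles)))
  if (is.null(k) == is.null(cut_height)) {
    stop("supply exactly one of `k` or `cut_height`", call. = FALSE)
  }
  ids <- rownames(profiles)
  ord <- order(ids)
  profiles <- profiles[ord, , drop = FALSE]
  flat <- apply(profiles, 1L, function(x) stats::sd(x) == 0)
  if (any(flat)) {
    message(sum(flat), " constant profile(s) placed in a dedicated flat cluster")
  }
  live <- profiles[!flat, , drop = FALSE]
  if (nrow(live) < 2L) {
    stop("need >= 2 non-constant profiles to cluster", call. = FALSE)
  }
  if (!is.null(k)) {
    assert_scalar_number(k, "k", lower = 1)
    if (k > nrow(live)) stop("k exceeds number of clusterable items", call. = FALSE)
  }
  d <- stats::as.dist(1 - stats::cor(t(live)))
  hc <- stats::hclust(d, method = linkage)
  lab <- if (!is.null(k)) stats::cutree(hc, k = k) else stats::cutree(hc, h = cut_height)
  n_real <- max(lab)
  labels <- integer(nrow(profiles))
  names(labels) <- rownames(profiles)
  labels[!flat] <- lab
  flat_cluster <- NA_integer_
  if (any(flat)) {
    flat_cluster <- n_real + 1L
    labels[flat] <- flat_cluster
  }
  structure(list(labels = labels,
                 n_clusters = n_real + as.integer(any(flat)),
                 flat_cluster = flat_cluster,
                 linkage = linkage,
                 hclust = hc),
            class = "cluster_assignment")
}

#' Mean profile of each cluster
#'
#' @param profiles items x timepoints matrix.
#' @param assignment a [cluster_profiles()] result.
#' @return a clusters x timepoints matrix (rownames are cluster labels).
#' @export
cluster_mean_profiles <- function(profiles, assignment) {
  labs <- assignment$labels[rownames(profiles)]
  cls <- sort(unique(labs))
  m <- t(vapply(cls, function(cl) {
    colMeans(profiles[names(labs)[labs == cl], , drop = FALSE])
  }, numeric(ncol(profiles))))
  rownames(m) <- cls
  m
}

#' Classify clusters as positively or negatively regulated
#'
#' An oxygen-sensing regulator of the CRP/FNR family is active at low
#' oxygen, so genes it activates peak in low-oxygen timepoints and genes it
#' represses peak at high oxygen. The contrast for each cluster is
#' `mean(low-oxygen timepoints) - mean(high-oxygen timepoints)` of the
#' cluster's mean relative profile (delta log2 RPKM): at or above
#' `tolerance` the call is `positive` (activated), at or below
#' `-tolerance` it is `negative` (repressed), otherwise `flat`.
#'
#' @param cluster_means clusters x timepoints matrix (e.g. from
#'   [cluster_mean_profiles()]).
#' @param phase_labels character vector per timepoint with values
#'   `"low_oxygen"` or `"high_oxygen"`; both phases must be represented.
#' @param tolerance delta log2 RPKM below which a contrast is called flat
#'   (default 0.5).
#' @return data frame with `cluster`, `contrast`, `sign`
#'   (`positive`/`negative`/`flat`).
#' @export
classify_regulation_sign <- function(cluster_means, phase_labels,
                                     tolerance = 0.5) {
  stopifnot(is.matrix(cluster_means),
            length(phase_labels) == ncol(cluster_means))
  if (!all(phase_labels %in% c("low_oxygen", "high_oxygen"))) {
    stop("phase_labels must be 'low_oxygen' or 'high_oxygen'", call. = FALSE)
  }
  if (length(unique(phase_labels)) < 2L) {
    stop("both oxygen phases must be represented among timepoints", call. = FALSE)
  }
  assert_scalar_number(tolerance, "tolerance", lower = 0)
  lo <- phase_labels == "low_oxygen"
  contrast <- rowMeans(cluster_means[, lo, drop = FALSE]) -
    rowMeans(cluster_means[, !lo, drop = FALSE])
  sign <- ifelse(contrast >= tolerance, "positive",
                 ifelse(contrast <= -tolerance, "negative", "flat"))
  data.frame(cluster = rownames(cluster_means) %||%
               as.character(seq_len(nrow(cluster_means))),
             contrast = unname(contrast), sign = unname(sign),
             stringsAsFactors = FALSE)
}

#' Write a cluster table (item, cluster, sign) to TSV
#'
#' @param assignment a [cluster_profiles()] result.
#' @param signs data frame from [classify_regulation_sign()].
#' @param path output TSV path.
#' @return invisibly, `path`.
#' @export
write_cluster_tsv <- function(assignment, signs, path) {
  sign_of <- stats::setNames(signs$sign, signs$cluster)
  df <- data.frame(item_id = names(assignment$labels),
                   cluster = unname(assignment$labels),
                   sign = unname(sign_of[as.character(assignment$labels)]),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
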