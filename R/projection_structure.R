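# Clustering of single-cell projection profiles, motif enumeration and motif
# enrichment against the independence null.

#' Hierarchical clustering of projection profiles
#'
#' Projecting cells are clustered on `log1p` of their row-relative projection
#' intensity (so profiles compare projection *pattern*, not total UMI yield).
#' A single agglomerative tree is cut at `n_clusters` fine projection
#' clusters and (optionally) at `n_classes` coarse projection classes, so the
#' classes partition the clusters by construction.
#'
#' @param profiles a `projection_profiles` object.
#' @param n_clusters number of projection clusters.
#' @param n_classes number of projection classes (`NULL` to skip).
#' @param method agglomeration method passed to [stats::hclust()]; Ward
#'   linkage by default -- average linkage tends to peel off single outlier
#'   cells instead of separating the main profile groups at coarse cuts.
#' @param metric distance metric passed to [stats::dist()].
#' @return A `projection_clustering` list: `cell_id`, `cluster_id`,
#'   `class_id`, and the `hclust` tree.
#' @export
cluster_projections <- function(profiles, n_clusters, n_classes = NULL,
                                method = "ward.D2", metric = "euclidean") {
  proj <- rowSums(profiles$binary) > 0
  X <- log1p(normalize_intensity(profiles, "relative"))[proj, , drop = FALSE]
  if (n_clusters > nrow(X))
    stop("n_clusters (", n_clusters, ") exceeds number of projecting cells (", nrow(X), ")")
  if (!is.null(n_classes) && n_classes > n_clusters)
    stop("n_classes must be <= n_clusters")
  tree <- hclust(dist(X, method = metric), method = method)
  cluster_id <- cutree(tree, k = n_clusters)
  class_id <- if (!is.null(n_classes)) cutree(tree, k = n_classes) else NULL
  structure(list(cell_id = rownames(X),
                 cluster_id = unname(cluster_id),
                 class_id = if (is.null(class_id)) NULL else unname(class_id),
                 tree = tree),
            class = "projection_clustering")
}

#' Cluster-by-target projection summary
#'
#' For every cluster and target: the mean relative projection intensity,
#' z-scored across clusters within each target, and the percentage of the
#' cluster's cells that project to the target. This is the numerical backbone
#' of the standard cluster-by-target dot plot.
#'
#' @param clustering a `projection_clustering`.
#' @param profiles the `projection_profiles` it was computed from.
#' @return List of matrices `mean_intensity`, `z` and `percent`
#'   (clusters x targets), plus `single_cluster` flag.
#' @export
cluster_summary <- function(clustering, profiles) {
  rel <- normalize_intensity(profiles, "relative")[clustering$cell_id, , drop = FALSE]
  bin <- profiles$binary[clustering$cell_id, , drop = FALSE]
  cl <- clustering$cluster_id
  sizes <- table(cl)
  if (any(sizes == 0)) warning("empty cluster excluded")
  ids <- sort(unique(cl))
  mean_int <- t(vapply(ids, function(k) colMeans(rel[cl == k, , drop = FALSE]),
                       numeric(ncol(rel))))
  percent <- t(vapply(ids, function(k) 100 * colMeans(bin[cl == k, , drop = FALSE]),
                      numeric(ncol(bin))))
  rownames(mean_int) <- rownames(percent) <- ids
  single <- length(ids) < 2
  z <- if (single) mean_int * 0 else
    apply(mean_int, 2, function(x) if (sd(x) > 0) (x - mean(x)) / sd(x) else x * 0)
  if (single) warning("single cluster: z-scores undefined, set to 0")
  list(mean_intensity = mean_int, z = z, percent = percent,
       single_cluster = single)
}

#' Cross-tabulated label composition
#'
#' Contingency counts of two per-cell label vectors and the row-normalized
#' proportions (each row of `labels_a` sums to 1 over `labels_b` levels).
#'
#' @param labels_a,labels_b equal-length label vectors.
#' @return List with `counts` and `proportions` matrices.
#' @export
composition_table <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    stop("alignment error: label vectors differ in length")
  counts <- table(labels_a, labels_b)
  proportions <- counts / pmax(rowSums(counts), 1)
  list(counts = unclass(counts), proportions = unclass(proportions))
}

motif_signature <- function(binary_rows, target_ids) {
  apply(binary_rows, 1, function(r) paste(target_ids[r > 0], collapse = "+"))
}

#' Enumerate binarized projection motifs
#'
#' A motif is a distinct nonzero binary projection pattern; cells are counted
#' per motif. All-zero rows (non-projecting cells) are excluded and reported.
#'
#' @param binary 0/1 cells x targets matrix with target column names.
#' @param top_n number of motifs to return, by descending count; ties broken
#'   lexicographically on the signature string.
#' @return A data frame `signature`, `count`, plus the motif target-indicator
#'   matrix as attribute `"signatures"` and the number of excluded all-zero
#'   rows as attribute `"n_zero"`.
#' @export
enumerate_motifs <- function(binary, top_n = 50L) {
  stopifnot(top_n >= 1)
  zero <- rowSums(binary) == 0
  if (all(zero)) {
    warning("all rows are zero: no motifs")
    out <- data.frame(signature = character(0), count = integer(0))
    attr(out, "n_zero") <- sum(zero)
    return(out)
  }
  b <- binary[!zero, , drop = FALSE]
  sig <- motif_signature(b, colnames(binary))
  tab <- table(sig)
  ord <- order(-as.integer(tab), names(tab))
  tab <- tab[ord]
  keep <- head(seq_along(tab), top_n)
  out <- data.frame(signature = names(tab)[keep],
                    count = as.integer(tab[keep]),
                    stringsAsFactors = FALSE)
  sig_mat <- t(vapply(strsplit(out$signature, "+", fixed = TRUE),
                      function(s) as.integer(colnames(binary) %in% s),
                      integer(ncol(binary))))
  colnames(sig_mat) <- colnames(binary)
  rownames(sig_mat) <- out$signature
  attr(out, "signatures") <- sig_mat
  attr(out, "n_zero") <- sum(zero)
  out
}

#' Motif enrichment against the target-independence null
#'
#' Per-target marginals `p_t` are the column means of the binary matrix over
#' projecting cells. Under independence the expected cell count of a motif
#' with target set S is `N * prod_{t in S} p_t * prod_{t notin S} (1 - p_t)`.
#' Each motif observed at least `min_observed` times is tested with a
#' two-sided exact binomial test (minimum-likelihood method: the p-value sums
#' the binomial pmf over outcomes no more probable than the observed count)
#' of its observed count against success probability `expected / N` over `N`
#' trials; q-values are Benjamini-Hochberg across tested motifs, and motifs
#' are labeled over-/underrepresented by `q <= alpha` and the sign of
#' `observed - expected`.
#'
#' Motifs touching a degenerate marginal (`p_t` of 0 or 1) are structurally
#' fixed: they get p-value 1, label `not significant`, and a `degenerate`
#' flag.
#'
#' @param binary 0/1 cells x targets matrix.
#' @param alpha FDR level for the enrichment call.
#' @param min_observed minimum observed count for a motif to be tested.
#' @return A `projection_motif_table` data frame: `signature`, `observed`,
#'   `expected`, `p_value`, `q_value`, `label`, `degenerate`; marginals in
#'   attribute `"marginals"`, number of projecting cells in attribute `"n"`.
#' @export
motif_enrichment <- function(binary, alpha = 0.05, min_observed = 5L) {
  stopifnot(alpha > 0, alpha < 1)
  zero <- rowSums(binary) == 0
  b <- binary[!zero, , drop = FALSE]
  N <- nrow(b)
  if (N < 1) stop("no projecting cells")
  p_t <- colMeans(b)
  motifs <- enumerate_motifs(b, top_n = .Machine$integer.max)
  sig_mat <- attr(motifs, "signatures")
  expected <- vapply(seq_len(nrow(motifs)), function(i) {
    s <- sig_mat[i, ] > 0
    N * prod(p_t[s]) * prod(1 - p_t[!s])
  }, numeric(1))
  # a motif is structurally degenerate when a marginal in its expectation is
  # 0 or 1: forced presence/absence rather than a testable association
  degen <- vapply(seq_len(nrow(motifs)), function(i) {
    s <- sig_mat[i, ] > 0
    any(p_t[s] %in% c(0, 1)) || any(p_t[!s] == 1)
  }, logical(1))
  tab <- data.frame(signature = motifs$signature, observed = motifs$count,
                    expected = expected, p_value = NA_real_,
                    q_value = NA_real_, label = "not significant",
                    degenerate = degen, stringsAsFactors = FALSE)
  test_idx <- which(tab$observed >= min_observed)
  for (i in test_idx) {
    if (tab$degenerate[i]) { tab$p_value[i] <- 1; next }
    tab$p_value[i] <- binom.test(tab$observed[i], N,
                                 p = min(tab$expected[i] / N, 1),
                                 alternative = "two.sided")$p.value
  }
  tested <- test_idx[!tab$degenerate[test_idx]]
  tab$q_value[tested] <- p.adjust(tab$p_value[tested], method = "BH")
  sig <- tested[!is.na(tab$q_value[tested]) & tab$q_value[tested] <= alpha]
  tab$label[sig] <- ifelse(tab$observed[sig] > tab$expected[sig],
                           "overrepresented", "underrepresented")
  attr(tab, "marginals") <- p_t
  attr(tab, "n") <- N
  attr(tab, "signatures") <- sig_mat
  class(tab) <- c("projection_motif_table", "data.frame")
  tab
}
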