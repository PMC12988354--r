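# Spatial organization of the projectome: axis-binned target proportions,
# group centroids, region enrichment, and motif-level distance correlations.

#' Axis-binned projection-target proportions
#'
#' Bins cells along one spatial axis into equal-width bins over the observed
#' coordinate range, and for each target computes the proportion of that
#' target's projecting cells falling in each bin, z-scored across bins within
#' the target (row normalization).
#'
#' @param binary 0/1 cells x targets matrix.
#' @param coords data frame with `ap_mm`, `dv_mm`, `ml_mm` aligned to rows of
#'   `binary`.
#' @param axis one of `"ap"`, `"dv"`, `"ml"`.
#' @param n_bins number of bins (>= 2).
#' @return An `axis_profile`: `edges`, `proportions` and `z` matrices
#'   (targets x bins); targets with no projecting cells are dropped with a
#'   warning.
#' @export
axis_binned_proportions <- function(binary, coords, axis = c("dv", "ap", "ml"),
                                    n_bins = 10L) {
  axis <- match.arg(axis)
  stopifnot(n_bins >= 2)
  x <- coords[[paste0(axis, "_mm")]]
  if (any(!is.finite(x))) stop("non-finite coordinate")
  edges <- seq(min(x), max(x), length.out = n_bins + 1)
  # half-open [lo, hi) bins, last bin closed
  bin <- pmin(findInterval(x, edges, rightmost.closed = TRUE), n_bins)
  keep <- colSums(binary) > 0
  if (any(!keep))
    warning("target(s) with no projecting cells dropped: ",
            paste(colnames(binary)[!keep], collapse = ", "))
  b <- binary[, keep, drop = FALSE]
  prop <- t(vapply(seq_len(ncol(b)), function(j) {
    cells <- b[, j] > 0
    as.numeric(table(factor(bin[cells], levels = seq_len(n_bins)))) / sum(cells)
  }, numeric(n_bins)))
  rownames(prop) <- colnames(b)
  colnames(prop) <- sprintf("bin%02d", seq_len(n_bins))
  z <- t(apply(prop, 1, function(r) if (sd(r) > 0) (r - mean(r)) / sd(r) else r * 0))
  structure(list(axis = axis, edges = edges, proportions = prop, z = z),
            class = "axis_profile")
}

#' Per-group coordinate centroids
#'
#' @param groups per-cell group labels.
#' @param coords data frame with `ap_mm`, `dv_mm`, `ml_mm`.
#' @return Matrix groups x (ap_mm, dv_mm, ml_mm) of arithmetic means; empty
#'   groups are excluded with a warning.
#' @export
group_centroids <- function(groups, coords) {
  stopifnot(length(groups) == nrow(coords))
  groups <- as.character(groups)
  lv <- unique(groups)
  cm <- as.matrix(coords[, c("ap_mm", "dv_mm", "ml_mm")])
  out <- t(vapply(lv, function(g) colMeans(cm[groups == g, , drop = FALSE]),
                  numeric(3)))
  rownames(out) <- lv
  out
}

#' Spatial / transcriptome vs projection distance across motifs
#'
#' For every unordered pair of projection motifs: the projection distance is
#' the Euclidean distance between the binary motif signatures; the spatial
#' distance is the Euclidean distance between the motifs' soma centroids
#' (mm); the transcriptome distance is the Euclidean distance between the
#' motifs' mean log-normalized expression vectors. Pearson correlations of
#' each x-axis against projection distance quantify how strongly spatial
#' position and gene expression track projection pattern.
#'
#' @param signatures motifs x targets 0/1 matrix.
#' @param centroids motifs x 3 coordinate matrix aligned to signatures.
#' @param expr_means motifs x genes mean-expression matrix (optional,
#'   `NULL` to skip the transcriptome axis).
#' @return List with `pairs` (per-pair distances) and `spatial_r`,
#'   `transcriptome_r` (`NA` with a flag when an axis is degenerate).
#' @export
motif_distance_correlation <- function(signatures, centroids, expr_means = NULL) {
  n <- nrow(signatures)
  if (n < 3) stop("insufficient data: fewer than 3 motifs")
  dproj <- as.matrix(dist(signatures))
  dspace <- as.matrix(dist(centroids))
  pr <- upper_pairs(rownames(signatures) %||% as.character(seq_len(n)))
  ij <- which(upper.tri(dproj), arr.ind = TRUE)
  pairs <- data.frame(motif_a = pr$a, motif_b = pr$b,
                      projection_dist = dproj[ij],
                      spatial_dist = dspace[ij], stringsAsFactors = FALSE)
  degenerate <- character(0)
  spatial_r <- if (sd(pairs$spatial_dist) > 0 && sd(pairs$projection_dist) > 0)
    cor(pairs$spatial_dist, pairs$projection_dist) else { degenerate <- c(degenerate, "spatial"); NA_real_ }
  transcriptome_r <- NA_real_
  if (!is.null(expr_means)) {
    dexpr <- as.matrix(dist(expr_means))
    pairs$transcriptome_dist <- dexpr[ij]
    transcriptome_r <- if (sd(pairs$transcriptome_dist) > 0 && sd(pairs$projection_dist) > 0)
      cor(pairs$transcriptome_dist, pairs$projection_dist) else { degenerate <- c(degenerate, "transcriptome"); NA_real_ }
  }
  list(pairs = pairs, spatial_r = spatial_r,
       transcriptome_r = transcriptome_r, degenerate = degenerate)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Group-by-region proportion table with highlight flags
#'
#' Row-normalized proportions of each group's cells across anatomical
#' regions, flagging entries above a highlight threshold.
#'
#' @param groups,regions aligned per-cell label vectors.
#' @param highlight_threshold proportion above which an entry is flagged.
#' @return List with `proportions` and logical `highlight` matrices.
#' @export
region_enrichment <- function(groups, regions, highlight_threshold = 0.25) {
  if (length(groups) != length(regions))
    stop("alignment error: label vectors differ in length")
  ct <- composition_table(groups, regions)
  list(proportions = ct$proportions,
       highlight = ct$proportions > highlight_threshold)
}
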