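# Gene co-expression networks, module detection, module eigengenes,
# module-projection correlation and projection-group differential expression.

#' Gene-gene co-expression network
#'
#' Pairwise Pearson correlation of panel genes across cells; edges below
#' `edge_threshold` in absolute value are zeroed. Constant genes get zero
#' rows/columns with a warning.
#'
#' @param expr_panel cells x genes log-normalized matrix.
#' @param edge_threshold minimum `|r|` for a retained edge.
#' @return List with `adjacency` (thresholded, zero diagonal) and the full
#'   `correlation` matrix.
#' @export
correlation_network <- function(expr_panel, edge_threshold = 0.3) {
  if (ncol(expr_panel) < 2) stop("panel needs >= 2 genes")
  const <- apply(expr_panel, 2, function(x) sd(x) == 0)
  if (any(const))
    warning("constant gene(s): ", paste(colnames(expr_panel)[const], collapse = ", "))
  r <- suppressWarnings(cor(expr_panel))
  r[!is.finite(r)] <- 0
  adj <- r
  adj[abs(adj) < edge_threshold] <- 0
  diag(adj) <- 0
  diag(r)[const] <- 0
  list(adjacency = adj, correlation = r)
}

#' Detect co-expression modules and hub genes
#'
#' Average-linkage hierarchical clustering on the dissimilarity `1 - |r|`,
#' cut at `k` modules (or, with `k = "auto"`, at the `k` in 2..10 maximizing
#' the mean silhouette width). Modules are labeled `M1..Mk` by decreasing
#' size. Hub genes are the top `hub_n` genes per module by within-module sum
#' of absolute adjacency (intramodular connectivity).
#'
#' @param network output of [correlation_network()], or a correlation matrix.
#' @param k number of modules, or `"auto"`.
#' @param hub_n hub genes reported per module.
#' @return A `gene_module_set`: `modules` (named gene -> module vector),
#'   `hubs` (list of character vectors per module), `k`, `tree`.
#' @export
detect_modules <- function(network, k = "auto", hub_n = 10L) {
  if (is.matrix(network)) network <- list(correlation = network, adjacency = network)
  r <- network$correlation
  ngene <- ncol(r)
  if (is.numeric(k) && k > ngene) stop("k exceeds panel size")
  d <- as.dist(1 - abs(r))
  tree <- hclust(d, method = "average")
  if (identical(k, "auto")) {
    ks <- 2:min(10, ngene - 1)
    sil <- vapply(ks, function(kk) {
      cl <- cutree(tree, k = kk)
      mean(cluster::silhouette(cl, d)[, "sil_width"])
    }, numeric(1))
    k <- ks[which.max(sil)]
  }
  cl <- cutree(tree, k = k)
  # relabel M1..Mk by decreasing module size (ties: lower original id first)
  sizes <- table(cl)
  ord <- order(-as.integer(sizes), as.integer(names(sizes)))
  relabel <- setNames(paste0("M", seq_along(ord)), names(sizes)[ord])
  modules <- setNames(relabel[as.character(cl)], colnames(r))
  adj <- abs(network$adjacency)
  hubs <- lapply(split(names(modules), modules), function(genes) {
    conn <- rowSums(adj[genes, genes, drop = FALSE])
    names(sort(conn, decreasing = TRUE))[seq_len(min(hub_n, length(genes)))]
  })
  structure(list(modules = modules, hubs = hubs, k = k, tree = tree),
            class = "gene_module_set")
}

#' Module eigengenes
#'
#' The module eigengene (ME) is the first principal-component score of the
#' module's gene-standardized expression submatrix, rescaled to unit sample
#' variance, with its sign fixed so that it correlates non-negatively with
#' the module's mean expression. Single-gene modules fall back to the
#' standardized gene and are flagged.
#'
#' @param expr_panel cells x genes log-normalized matrix.
#' @param modules named gene -> module vector (from [detect_modules()] or
#'   planted truth); genes labeled `"M0"` are skipped.
#' @return Cells x modules ME matrix; single-gene modules are listed in
#'   attribute `"single_gene"`.
#' @export
module_eigengenes <- function(expr_panel, modules) {
  if (inherits(modules, "gene_module_set")) modules <- modules$modules
  modules <- modules[names(modules) %in% colnames(expr_panel) & modules != "M0"]
  mods <- sort(unique(modules))
  if (!length(mods)) stop("no module genes present in panel")
  single <- character(0)
  me <- vapply(mods, function(m) {
    genes <- names(modules)[modules == m]
    X <- expr_panel[, genes, drop = FALSE]
    sds <- apply(X, 2, sd)
    X <- X[, sds > 0, drop = FALSE]
    if (ncol(X) == 0) return(rep(0, nrow(expr_panel)))
    Xs <- scale(X)
    if (ncol(Xs) == 1) {
      single <<- c(single, m)
      return(as.numeric(Xs))
    }
    score <- prcomp(Xs, center = FALSE, scale. = FALSE, rank. = 1)$x[, 1]
    score <- score / sd(score)
    if (cor(score, rowMeans(Xs)) < 0) score <- -score
    score
  }, numeric(nrow(expr_panel)))
  rownames(me) <- rownames(expr_panel)
  colnames(me) <- mods
  attr(me, "single_gene") <- single
  me
}

#' Module-projection correlation table
#'
#' Correlates each module eigengene with the projection intensity of each
#' target. `pearson_t` reports the Pearson coefficient with its two-sided
#' t-test p-value; `fisher_discrete` dichotomizes the ME at its median and
#' the intensity at zero and applies a two-sided Fisher's exact test on the
#' 2x2 table. Benjamini-Hochberg q-values are computed across the whole
#' table per method.
#'
#' @param me cells x modules eigengene matrix.
#' @param intensity cells x targets projection intensity matrix.
#' @param method `"pearson_t"`, `"fisher_discrete"` or `"both"`.
#' @return Long data frame: `module`, `target`, and per method the statistic,
#'   `p_value`/`q_value` columns; undefined entries (constant columns) are
#'   `NA` and flagged in `degenerate`.
#' @export
module_projection_correlation <- function(me, intensity,
                                          method = c("pearson_t", "fisher_discrete", "both")) {
  method <- match.arg(method)
  stopifnot(nrow(me) == nrow(intensity))
  grid <- expand.grid(module = colnames(me), target = colnames(intensity),
                      stringsAsFactors = FALSE)
  out <- grid
  out$degenerate <- FALSE
  if (method %in% c("pearson_t", "both")) {
    res <- lapply(seq_len(nrow(grid)), function(i) {
      x <- me[, grid$module[i]]; y <- intensity[, grid$target[i]]
      if (sd(x) == 0 || sd(y) == 0) return(c(NA_real_, NA_real_))
      ct <- cor.test(x, y, method = "pearson")
      c(unname(ct$estimate), ct$p.value)
    })
    out$r <- vapply(res, `[`, numeric(1), 1)
    out$p_value <- vapply(res, `[`, numeric(1), 2)
    out$q_value <- p.adjust(out$p_value, method = "BH")
    out$degenerate <- out$degenerate | is.na(out$r)
  }
  if (method %in% c("fisher_discrete", "both")) {
    res <- lapply(seq_len(nrow(grid)), function(i) {
      x <- me[, grid$module[i]] >= median(me[, grid$module[i]])
      y <- intensity[, grid$target[i]] > 0
      if (length(unique(x)) < 2 || length(unique(y)) < 2)
        return(c(NA_real_, NA_real_))
      ft <- fisher.test(table(x, y))
      c(unname(ft$estimate), ft$p.value)
    })
    out$odds_ratio <- vapply(res, `[`, numeric(1), 1)
    out$fisher_p <- vapply(res, `[`, numeric(1), 2)
    out$fisher_q <- p.adjust(out$fisher_p, method = "BH")
    out$degenerate <- out$degenerate | is.na(out$odds_ratio)
  }
  out
}

#' Differential expression between two projection groups
#'
#' Per-gene log2 fold change of linear-scale group means (with a 1e-9
#' pseudo-rate) and a two-sided Wilcoxon rank-sum test on the log-normalized
#' values, Benjamini-Hochberg corrected across genes.
#'
#' @param expr an [expression_matrix()] (log_normalized layer) or matrix.
#' @param cells_a,cells_b disjoint cell-id vectors, each >= 3 cells.
#' @return Data frame `gene`, `log2fc`, `p_value`, `q_value`.
#' @export
differential_expression <- function(expr, cells_a, cells_b) {
  vals <- if (inherits(expr, "expression_matrix")) expr$values else expr
  if (length(intersect(cells_a, cells_b))) stop("groups overlap")
  if (length(cells_a) < 3 || length(cells_b) < 3) stop("each group needs >= 3 cells")
  A <- vals[cells_a, , drop = FALSE]
  B <- vals[cells_b, , drop = FALSE]
  eps <- 1e-9
  mean_a <- colMeans(expm1(A))
  mean_b <- colMeans(expm1(B))
  l2fc <- log2((mean_a + eps) / (mean_b + eps))
  p <- vapply(seq_len(ncol(vals)), function(j)
    suppressWarnings(wilcox.test(A[, j], B[, j], exact = FALSE)$p.value),
    numeric(1))
  data.frame(gene = colnames(vals), log2fc = l2fc, p_value = p,
             q_value = p.adjust(p, method = "BH"),
             row.names = NULL, stringsAsFactors = FALSE)
}
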