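# Target-target co-projection structure and its coupling with external
# circuit connectivity.

#' Co-projection (phi) matrix
#'
#' Pearson correlation of every pair of binary target columns across
#' projecting cells -- equal to the phi coefficient of the pair's 2x2
#' contingency table. The tendency of two targets to be innervated by the
#' same neurons.
#'
#' @param binary 0/1 cells x targets matrix.
#' @return A `coprojection_matrix`: symmetric `phi` matrix with `NA` on the
#'   diagonal and at targets with constant columns (marginal 0 or 1).
#' @export
coprojection_matrix <- function(binary) {
  zero <- rowSums(binary) == 0
  b <- binary[!zero, , drop = FALSE]
  if (nrow(b) < 2) stop("need at least 2 projecting cells")
  const <- apply(b, 2, function(x) length(unique(x)) == 1)
  if (any(const))
    warning("constant binary column(s): ", paste(colnames(b)[const], collapse = ", "),
            "; phi undefined there")
  phi <- suppressWarnings(cor(b))
  phi[const, ] <- NA
  phi[, const] <- NA
  diag(phi) <- NA
  structure(list(target_ids = colnames(b), phi = phi),
            class = "coprojection_matrix")
}

upper_pairs <- function(ids) {
  idx <- which(upper.tri(diag(length(ids))), arr.ind = TRUE)
  data.frame(a = ids[idx[, 1]], b = ids[idx[, 2]], stringsAsFactors = FALSE)
}

#' Within- vs across-class contrast of a target-pair matrix
#'
#' Splits the off-diagonal upper-triangle entries of a (symmetrized) target x
#' target matrix into pairs belonging to the same projection class versus
#' pairs spanning classes, and compares the two sets with a Wilcoxon
#' rank-sum test.
#'
#' @param m square numeric matrix with target dimnames; asymmetric input is
#'   symmetrized as `(m + t(m)) / 2`.
#' @param class_map named character vector target_id -> class_id.
#' @param alternative passed to [stats::wilcox.test()]; `"greater"` tests
#'   within > across.
#' @return List with `within`, `across` value vectors, `statistic`, `p_value`.
#' @export
block_contrast <- function(m, class_map, alternative = "greater") {
  m <- (m + t(m)) / 2
  ids <- rownames(m)
  cls <- class_map[ids]
  if (length(unique(cls[!is.na(cls)])) < 2) stop("need >= 2 classes")
  singles <- names(which(table(cls) == 1))
  if (length(singles))
    warning("class(es) with a single target contribute no within pairs: ",
            paste(singles, collapse = ", "))
  pr <- upper_pairs(ids)
  vals <- m[cbind(match(pr$a, ids), match(pr$b, ids))]
  same <- !is.na(cls[pr$a]) & !is.na(cls[pr$b]) & cls[pr$a] == cls[pr$b]
  ok <- !is.na(vals)
  within <- vals[same & ok]
  across <- vals[!same & ok]
  if (!length(within)) stop("test undefined: no within-class pairs")
  if (sd(c(within, across)) == 0) {
    # no separation at all: rank-sum carries no evidence either way
    return(list(within = within, across = across,
                statistic = length(within) * length(across) / 2, p_value = 1))
  }
  wt <- wilcox.test(within, across, alternative = alternative, exact = FALSE)
  list(within = within, across = across,
       statistic = unname(wt$statistic), p_value = wt$p.value)
}

#' Correlation between co-projection and circuit connectivity
#'
#' Pairs co-projection phi values with an external target x target
#' connectivity matrix (e.g. axonal projection density between the traced
#' downstream nuclei) over the targets present in both, and reports the
#' Pearson correlation across unordered target pairs.
#'
#' @param cp a [coprojection_matrix()].
#' @param conn square nonnegative connectivity matrix with target dimnames;
#'   directed input is symmetrized as `(A + t(A)) / 2`.
#' @return List with `r`, `p_value` and the pair-level table `pairs`
#'   (target_a, target_b, phi, connectivity).
#' @export
coupling_correlation <- function(cp, conn) {
  conn <- as.matrix(conn)
  conn <- (conn + t(conn)) / 2
  shared <- intersect(cp$target_ids, rownames(conn))
  if (length(shared) < 3) stop("insufficient data: fewer than 3 shared targets")
  phi <- cp$phi[shared, shared]
  cn <- conn[shared, shared]
  pr <- upper_pairs(shared)
  ij <- cbind(match(pr$a, shared), match(pr$b, shared))
  tab <- data.frame(target_a = pr$a, target_b = pr$b,
                    phi = phi[ij], connectivity = cn[ij],
                    stringsAsFactors = FALSE)
  tab <- tab[complete.cases(tab), , drop = FALSE]
  if (nrow(tab) < 3) stop("insufficient data: fewer than 3 valid pairs")
  ct <- cor.test(tab$phi, tab$connectivity, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, pairs = tab)
}
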