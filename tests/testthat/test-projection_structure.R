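test_that("clustering separates orthogonal profile groups perfectly", {
  m <- rbind(matrix(rep(c(100, 80, 0, 0), each = 20), 20),
             matrix(rep(c(0, 0, 100, 80), each = 20), 20))
  dimnames(m) <- list(sprintf("c%02d", 1:40), c("A-I", "B-I", "C-I", "D-I"))
  p <- projection_profiles(m)
  cl <- cluster_projections(p, n_clusters = 2)
  expect_equal(adjusted_rand(cl$cluster_id, rep(1:2, each = 20)), 1)
  # degenerate cut: every cell its own cluster
  cl_all <- cluster_projections(p, n_clusters = 40)
  expect_equal(length(unique(cl_all$cluster_id)), 40)
  expect_error(cluster_projections(p, n_clusters = 41), "exceeds")
  expect_error(cluster_projections(p, n_clusters = 2, n_classes = 3), "<=")
})

test_that("clustering is invariant to cell order", {
  sim <- simulate_dataset(cfg8(n_cells = 300), seed = 15)
  prof <- filter_background(sim$dataset$barcode)
  cl <- cluster_projections(prof, 8, 2)
  perm <- sample(nrow(prof$intensity))
  prof_p <- projection_profiles(prof$intensity[perm, ])
  cl_p <- cluster_projections(prof_p, 8, 2)
  ord <- match(cl$cell_id, cl_p$cell_id)
  expect_equal(adjusted_rand(cl$cluster_id, cl_p$cluster_id[ord]), 1)
  expect_equal(adjusted_rand(cl$class_id, cl_p$class_id[ord]), 1)
})

test_that("cluster summary z-scores means across clusters within target", {
  m <- rbind(matrix(rep(c(10, 0), each = 5), 5), matrix(rep(c(20, 20), each = 5), 5),
             matrix(rep(c(30, 60), each = 5), 5))
  dimnames(m) <- list(sprintf("c%02d", 1:15), c("A-I", "B-I"))
  p <- projection_profiles(m)
  cl <- cluster_projections(p, 3)
  cs <- cluster_summary(cl, p)
  for (j in 1:2) {
    expect_equal(mean(cs$z[, j]), 0, tolerance = 1e-12)
    expect_equal(sd(cs$z[, j]), 1, tolerance = 1e-12)
  }
  expect_true(all(cs$percent >= 0 & cs$percent <= 100))
  # single cluster: z undefined, flagged zero
  cl1 <- cluster_projections(p, 1)
  cs1 <- suppressWarnings(cluster_summary(cl1, p))
  expect_true(cs1$single_cluster)
  expect_true(all(cs1$z == 0))
})

test_that("composition tables are row-normalized contingency proportions", {
  a <- rep(c("x", "y"), each = 50)
  ct <- composition_table(a, a)
  expect_equal(unname(diag(ct$proportions)), c(1, 1))
  set.seed(1)
  b <- sample(c("p", "q", "r"), 100, TRUE, prob = c(0.5, 0.3, 0.2))
  ct2 <- composition_table(a, b)
  expect_true(all(abs(rowSums(ct2$proportions) - 1) < 1e-12))
  # independent labels approach the marginals of the second factor
  set.seed(2)
  a3 <- sample(c("u", "v"), 20000, TRUE)
  b3 <- sample(c("p", "q"), 20000, TRUE, prob = c(0.7, 0.3))
  ct3 <- composition_table(a3, b3)
  expect_true(all(abs(ct3$proportions[, "p"] - 0.7) < 0.02))
  expect_error(composition_table(a, b[1:10]), "alignment")
})

test_that("motif enumeration counts distinct nonzero patterns", {
  b <- rbind(matrix(rep(c(1, 1, 0), 3), 3, byrow = TRUE),
             matrix(rep(c(1, 0, 0), 2), 2, byrow = TRUE),
             c(0, 0, 1), c(0, 0, 0))
  colnames(b) <- c("A-I", "B-I", "C-I")
  tab <- enumerate_motifs(b, top_n = 2)
  expect_equal(tab$signature, c("A-I+B-I", "A-I"))
  expect_equal(tab$count, c(3, 2))
  expect_equal(attr(tab, "n_zero"), 1)
  all_tab <- enumerate_motifs(b, top_n = 99)
  expect_equal(nrow(all_tab), 3)
  expect_equal(sum(all_tab$count), 6)  # conservation over projecting cells
  expect_warning(enumerate_motifs(matrix(0, 2, 2,
    dimnames = list(NULL, c("A-I", "B-I")))), "zero")
})

test_that("motif expected counts follow the independence product", {
  sim <- simulate_dataset(cfg_flat(2000, c(0.5, 0.4, 0.3)), seed = 16)
  b <- sim$truth$binary
  tab <- motif_enrichment(b, min_observed = 1)
  p_t <- attr(tab, "marginals")
  N <- attr(tab, "n")
  sigs <- attr(tab, "signatures")
  for (i in seq_len(nrow(tab))) {
    s <- sigs[i, ] > 0
    expect_equal(tab$expected[i], N * prod(p_t[s]) * prod(1 - p_t[!s]),
                 tolerance = 1e-9)
  }
  # probability conservation over all 2^T - 1 motifs
  pats <- as.matrix(expand.grid(rep(list(0:1), 3)))
  pats <- pats[rowSums(pats) > 0, ]
  total <- sum(apply(pats, 1, function(s)
    N * prod(ifelse(s == 1, p_t, 1 - p_t))))
  expect_equal(total, N * (1 - prod(1 - p_t)), tolerance = 1e-9)
  expect_true(all(tab$q_value >= tab$p_value - 1e-12, na.rm = TRUE))
})

test_that("motif p-values match an exact binomial oracle", {
  set.seed(17)
  b <- (matrix(runif(400 * 5), 400) < 0.35) * 1L
  colnames(b) <- paste0(LETTERS[1:5], "-I")
  tab <- motif_enrichment(b, min_observed = 3)
  tested <- which(!is.na(tab$p_value) & !tab$degenerate)
  N <- attr(tab, "n")
  for (i in tested[seq_len(min(10, length(tested)))]) {
    expect_equal(tab$p_value[i],
                 oracle_binom_p(tab$observed[i], N, tab$expected[i] / N),
                 tolerance = 1e-10)
  }
  # label consistency with q and the sign of observed - expected
  called <- which(tab$label != "not significant")
  expect_true(all(tab$q_value[called] <= 0.05))
  expect_true(all((tab$observed > tab$expected)[called] ==
                  (tab$label[called] == "overrepresented")))
})

test_that("degenerate marginals are flagged, not tested", {
  b <- cbind(`A-I` = rep(1L, 50), `B-I` = rbinom(50, 1, 0.5))
  tab <- motif_enrichment(b, min_observed = 1)
  expect_true(all(tab$degenerate))
  expect_true(all(tab$label == "not significant"))
  expect_true(all(tab$p_value[!is.na(tab$p_value)] == 1))
})

test_that("a planted enriched pair motif is called overrepresented", {
  mm <- simulate_motif_mixture(5000, 6, 0.3, 3, seed = 3)
  tab <- motif_enrichment(mm$binary)
  expect_equal(tab$label[tab$signature == mm$motif], "overrepresented")
  mm2 <- simulate_motif_mixture(5000, 6, 0.3, 0.3, seed = 3)
  tab2 <- motif_enrichment(mm2$binary)
  expect_equal(tab2$label[tab2$signature == mm2$motif], "underrepresented")
})
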