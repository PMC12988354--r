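coords_df <- function(n, ap = NULL, dv = NULL, ml = NULL) {
  data.frame(ap_mm = ap %||% runif(n, 0.5, 2.8),
             dv_mm = dv %||% runif(n, 0.5, 3),
             ml_mm = ml %||% runif(n, 0, 1))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("axis profiles are row-normalized with closed-form z-scores", {
  # 4 bins engineered to hold 10/20/30/40 percent of one target's cells
  n <- 100
  x <- c(0, rep(0.5, 9), rep(1.5, 20), rep(2.5, 30), rep(3.5, 39), 4)
  co <- coords_df(n, dv = x)
  b <- cbind(`A-I` = rep(1L, n))
  ax <- axis_binned_proportions(b, co, axis = "dv", n_bins = 4)
  pr <- c(0.1, 0.2, 0.3, 0.4)
  expect_equal(unname(ax$proportions[1, ]), pr)
  expect_equal(sum(ax$proportions[1, ]), 1, tolerance = 1e-12)
  expect_equal(unname(ax$z[1, ]),
               unname((ax$proportions[1, ] - mean(ax$proportions[1, ])) /
                      sd(ax$proportions[1, ])), tolerance = 1e-12)
})

test_that("axis profiles are invariant to affine coordinate rescaling", {
  set.seed(31)
  n <- 500
  co <- coords_df(n)
  b <- cbind(`A-I` = rbinom(n, 1, 0.5), `B-I` = rbinom(n, 1, 0.3))
  ax1 <- axis_binned_proportions(b, co, "dv", 8)
  co2 <- co; co2$dv_mm <- 3 * co$dv_mm + 10
  ax2 <- axis_binned_proportions(b, co2, "dv", 8)
  expect_equal(ax1$proportions, ax2$proportions, tolerance = 1e-12)
})

test_that("uniformly placed cells show no axis structure", {
  set.seed(32)
  n <- 4000
  co <- coords_df(n)
  b <- cbind(`A-I` = rbinom(n, 1, 0.5))
  ax <- axis_binned_proportions(b, co, "dv", 5)
  expect_true(all(abs(ax$proportions[1, ] - 0.2) < 3 * sqrt(0.2 * 0.8 / (0.5 * n))))
  # target with no projecting cells is dropped with a warning
  b2 <- cbind(b, `B-I` = 0L)
  expect_warning(ax2 <- axis_binned_proportions(b2, co, "dv", 5), "dropped")
  expect_equal(rownames(ax2$proportions), "A-I")
})

test_that("planted dorsoventral gradient is recovered in bin ordering", {
  tg <- tg8()
  pr <- default_class_profiles(tg, c("c1", "c2"), p_anchor = 0.6,
                               p_secondary = 0.6, p_out = 0.02)
  cfg <- sim_config(n_cells = 3000, targets = tg,
                    class_mix = c(c1 = 0.5, c2 = 0.5), class_profiles = pr,
                    coupling_rho = 0.3, n_genes = 10, n_modules = 0,
                    module_sizes = integer(0),
                    spatial_means = cbind(ap_mm = c(1.5, 1.5), dv_mm = c(1, 2)),
                    spatial_sd = 0.3)
  sim <- simulate_dataset(cfg, seed = 33)
  ax <- axis_binned_proportions(sim$truth$binary, sim$dataset$meta, "dv", 6)
  peak <- apply(ax$proportions, 1, which.max)
  # dorsal-class targets peak in lower-dv bins than ventral-class targets
  expect_true(mean(peak[tg$target_id[tg$class_id == "c1"]]) <
              mean(peak[tg$target_id[tg$class_id == "c2"]]))
})

test_that("group centroids are arithmetic means, order-invariant", {
  co <- coords_df(4, ap = c(1, 3, 5, 7), dv = c(2, 2, 4, 4), ml = c(0, 1, 0, 1))
  g <- c("a", "a", "b", "b")
  cent <- group_centroids(g, co)
  expect_equal(unname(cent["a", ]), c(2, 2, 0.5))
  expect_equal(unname(cent["b", ]), c(6, 4, 0.5))
  perm <- c(3, 1, 4, 2)
  expect_equal(group_centroids(g[perm], co[perm, ])[rownames(cent), ], cent)
  expect_equal(unname(group_centroids("solo", co[1, ])[1, ]),
               unname(as.numeric(co[1, ])))
})

test_that("motif distance correlations behave on constructed geometries", {
  sig <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(1, 1, 0))
  rownames(sig) <- paste0("m", 1:4)
  # centroids = affine embedding of signatures -> distances proportional
  cent <- cbind(ap_mm = 2 * sig[, 1] + 0.5, dv_mm = 2 * sig[, 2] + 0.5,
                ml_mm = 2 * sig[, 3])
  mdc <- motif_distance_correlation(sig, cent)
  expect_equal(mdc$spatial_r, 1, tolerance = 1e-9)
  # identical centroids -> degenerate spatial axis
  cent0 <- cent; cent0[, ] <- 1
  mdc0 <- motif_distance_correlation(sig, cent0)
  expect_true(is.na(mdc0$spatial_r))
  expect_true("spatial" %in% mdc0$degenerate)
  expect_error(motif_distance_correlation(sig[1:2, ], cent[1:2, ]),
               "insufficient")
  # transcriptome axis from mean-expression vectors
  expr <- 3 * sig + 1
  mdc2 <- motif_distance_correlation(sig, cent, expr)
  expect_equal(mdc2$transcriptome_r, 1, tolerance = 1e-9)
})

test_that("region enrichment flags concentrated groups only", {
  g <- rep("motifA", 10)
  r <- rep("ACC", 10)
  re <- region_enrichment(g, r)
  expect_equal(unname(re$proportions[1, 1]), 1)
  expect_true(re$highlight[1, 1])
  g2 <- rep("motifB", 50)
  r2 <- rep(c("ACC", "PL", "ILA", "MOs", "ORB"), 10)
  re2 <- region_enrichment(g2, r2)
  expect_true(all(abs(re2$proportions - 0.2) < 1e-12))
  expect_false(any(re2$highlight))
  expect_error(region_enrichment(g, r2), "alignment")
})
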