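test_that("correlation network thresholds edges and zeroes constants", {
  set.seed(41)
  g1 <- rnorm(300)
  expr <- cbind(a = g1, b = g1, c = rnorm(300), d = rep(1, 300))
  expect_warning(net <- correlation_network(expr, edge_threshold = 0.3),
                 "constant")
  expect_equal(net$adjacency["a", "b"], 1)
  expect_equal(net$adjacency["a", "c"], 0)   # independent noise below threshold
  expect_true(all(net$adjacency[, "d"] == 0))
  expect_equal(net$adjacency, t(net$adjacency), tolerance = 1e-12)
  expect_true(all(diag(net$adjacency) == 0))
})

test_that("separated correlation blocks are recovered exactly", {
  set.seed(42)
  s1 <- rnorm(400); s2 <- rnorm(400)
  expr <- cbind(sapply(1:5, function(i) s1 + rnorm(400, sd = 0.1)),
                sapply(1:5, function(i) s2 + rnorm(400, sd = 0.1)))
  colnames(expr) <- paste0("g", 1:10)
  net <- correlation_network(expr)
  gm <- detect_modules(net, k = 2)
  expect_equal(adjusted_rand(gm$modules, rep(1:2, each = 5)), 1)
  expect_true(all(lengths(gm$hubs) == 5))  # min(hub_n, module size)
  expect_error(detect_modules(net, k = 11), "panel size")
  # silhouette auto-k finds the planted two blocks
  expect_equal(detect_modules(net, k = "auto")$k, 2)
})

test_that("planted modules and eigengenes are recovered from simulation", {
  cfg <- sim_config(n_cells = 1500)
  sim <- simulate_dataset(cfg, seed = 43)
  panel <- names(sim$truth$gene_module)[sim$truth$gene_module != "M0"]
  net <- correlation_network(sim$dataset$expr$values[, panel])
  gm <- detect_modules(net, k = 4)
  expect_gte(adjusted_rand(gm$modules, sim$truth$gene_module[names(gm$modules)]), 0.9)
  me <- module_eigengenes(sim$dataset$expr$values[, panel], gm)
  cors <- abs(cor(me, sim$truth$module_scores))
  expect_true(all(apply(cors, 2, max) >= 0.9))
})

test_that("module eigengenes follow the first-PC contract", {
  set.seed(44)
  g <- rnorm(200)
  expr <- cbind(g1 = g, g2 = g + rnorm(200, sd = 1e-8), g3 = rnorm(200))
  # single-gene module equals the z-scored gene
  me1 <- module_eigengenes(expr, c(g3 = "M1"))
  expect_equal(unname(me1[, "M1"]), as.numeric(scale(expr[, "g3"])),
               tolerance = 1e-9)
  expect_equal(attr(me1, "single_gene"), "M1")
  # two perfectly correlated genes: ME correlates 1 with both
  me2 <- module_eigengenes(expr, c(g1 = "M1", g2 = "M1"))
  expect_equal(abs(cor(me2[, "M1"], expr[, "g1"])), 1, tolerance = 1e-6)
  expect_equal(sd(me2[, "M1"]), 1, tolerance = 1e-9)
  # sign is fixed toward the module mean
  expect_gte(cor(me2[, "M1"], rowMeans(scale(expr[, c("g1", "g2")]))), 0)
})

test_that("eigengenes are invariant to gene and cell order", {
  cfg <- sim_config(n_cells = 400)
  sim <- simulate_dataset(cfg, seed = 45)
  panel <- names(sim$truth$gene_module)[sim$truth$gene_module != "M0"]
  expr <- sim$dataset$expr$values[, panel]
  modules <- sim$truth$gene_module[panel]
  me <- module_eigengenes(expr, modules)
  gperm <- sample(ncol(expr)); cperm <- sample(nrow(expr))
  me_p <- module_eigengenes(expr[cperm, gperm], modules[gperm])
  expect_equal(me_p[rownames(me), colnames(me)], me, tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("module-projection correlation recovers planted coupling", {
  cfg <- sim_config(n_cells = 1500)
  sim <- simulate_dataset(cfg, seed = 46)
  panel <- names(sim$truth$gene_module)[sim$truth$gene_module != "M0"]
  me <- module_eigengenes(sim$dataset$expr$values[, panel],
                          sim$truth$gene_module[panel])
  prof <- filter_background(sim$dataset$barcode)
  mp <- module_projection_correlation(me, prof$intensity, method = "both")
  for (m in colnames(me)) {
    tgt <- sim$truth$module_target[[m]]
    row <- mp[mp$module == m & mp$target == tgt, ]
    sgn <- sign(cor(me[, m], sim$truth$module_scores[, m]))
    expect_gt(sgn * row$r, 0.3)
    expect_lt(row$q_value, 0.05)
    # discrete Fisher agrees in direction: odds ratio on the same side of 1
    expect_true((row$odds_ratio > 1) == (sgn * row$r > 0))
    expect_lt(row$fisher_q, 0.05)
  }
  # identity coupling gives r = 1
  mp_id <- module_projection_correlation(cbind(M1 = prof$intensity[, 1]),
                                         prof$intensity[, 1, drop = FALSE])
  expect_equal(mp_id$r[1], 1, tolerance = 1e-12)
})

test_that("uncoupled eigengenes show no projection correlation", {
  set.seed(47)
  me <- cbind(M1 = rnorm(2000))
  intensity <- cbind(`A-I` = rpois(2000, 3))
  mp <- module_projection_correlation(me, intensity)
  expect_lt(abs(mp$r[1]), 0.1)
})

test_that("differential expression is antisymmetric and powered", {
  set.seed(48)
  n <- 400
  expr <- matrix(rnorm(2 * n * 30, mean = 2, sd = 0.5), 2 * n, 30,
                 dimnames = list(sprintf("c%04d", seq_len(2 * n)),
                                 sprintf("g%02d", 1:30)))
  a <- rownames(expr)[1:n]; b <- rownames(expr)[(n + 1):(2 * n)]
  expr[a, "g01"] <- expr[a, "g01"] + 1   # planted shift
  de <- differential_expression(expr, a, b)
  de_sw <- differential_expression(expr, b, a)
  expect_equal(de$log2fc, -de_sw$log2fc, tolerance = 1e-12)
  expect_lt(de$q_value[de$gene == "g01"], 0.01)
  expect_gt(de$log2fc[de$gene == "g01"], 0)
  # null genes keep a calibrated false positive rate
  expect_lte(mean(de$q_value[de$gene != "g01"] < 0.05), 0.07)
  expect_error(differential_expression(expr, a, c(b, a[1])), "overlap")
  expect_error(differential_expression(expr, a[1:2], b), ">= 3")
})
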