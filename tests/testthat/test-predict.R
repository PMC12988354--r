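small_pred_sim <- function(n = 800, alpha = 0.6, seed = 51) {
  cfg <- sim_config(n_cells = n, module_alpha = alpha, n_genes = 60,
                    module_sizes = rep(12L, 4))
  simulate_dataset(cfg, seed = seed)
}

test_that("feature building standardizes and round-trips the PC model", {
  sim <- small_pred_sim()
  fm <- build_features(sim$dataset$expr, sim$dataset$meta, n_pcs = 10)
  expect_equal(ncol(fm$features), 13)  # 10 PCs + 3 coords
  expect_true(all(abs(colMeans(fm$features)) < 1e-10))
  expect_true(all(abs(apply(fm$features, 2, sd) - 1) < 1e-10))
  fm2 <- build_features(sim$dataset$expr, sim$dataset$meta, n_pcs = 10,
                        use_spatial = FALSE)
  expect_equal(ncol(fm2$features), 10)
  # replaying the stored transform on the training data reproduces features
  replay <- apply_feature_model(fm$pc_model, sim$dataset$expr,
                                sim$dataset$meta,
                                min_shared = ncol(sim$dataset$expr$values))
  expect_equal(unname(replay), unname(fm$features), tolerance = 1e-8)
  # constant genes are dropped with a warning
  vals <- sim$dataset$expr$values; vals[, 1] <- 1
  expect_warning(build_features(vals, sim$dataset$meta, n_pcs = 5), "constant")
})

test_that("a separable label is predicted perfectly, a shuffled one at chance", {
  sim <- small_pred_sim()
  fm <- build_features(sim$dataset$expr, sim$dataset$meta, n_pcs = 10)
  y_sep <- (fm$features[, "PC1"] > 0) * 1L
  labels <- cbind(`SEP-I` = y_sep)
  fit <- train_predictors(fm, labels, seed = 1)
  res <- evaluate_roc(fit, fm, labels, seed = 1)
  expect_gt(res$auc[1], 0.99)
  set.seed(2)
  labels_null <- cbind(`NULL-I` = sample(y_sep))
  fit_n <- train_predictors(fm, labels_null, seed = 2)
  res_n <- evaluate_roc(fit_n, fm, labels_null, n_shuffle = 10, seed = 2)
  expect_true(res_n$auc[1] > 0.4 && res_n$auc[1] < 0.6)
  expect_true(all(abs(attr(res_n, "shuffle_aucs")[["NULL-I"]] - 0.5) < 0.15))
})

test_that("training skips targets without enough cells of both classes", {
  sim <- small_pred_sim()
  fm <- build_features(sim$dataset$expr, sim$dataset$meta, n_pcs = 5)
  labels <- cbind(`RARE-I` = c(rep(1L, 5), rep(0L, nrow(fm$features) - 5)),
                  `OK-I` = rbinom(nrow(fm$features), 1, 0.4))
  fit <- train_predictors(fm, labels, seed = 3)
  expect_equal(fit$skipped, "RARE-I")
  expect_named(fit$models, "OK-I")
  expect_error(train_predictors(fm, labels[, "RARE-I", drop = FALSE], seed = 3),
               "precondition")
})

test_that("the full prediction pipeline is deterministic under a fixed seed", {
  sim <- small_pred_sim(n = 500)
  prof <- filter_background(sim$dataset$barcode)
  run <- function() {
    fm <- build_features(sim$dataset$expr, sim$dataset$meta, n_pcs = 10)
    fit <- train_predictors(fm, prof$binary[, c("LHA-I", "CP-I")], seed = 9)
    evaluate_roc(fit, fm, prof$binary[, c("LHA-I", "CP-I")], seed = 9)$auc
  }
  expect_equal(run(), run(), tolerance = 1e-10)
})

test_that("transfer to the training data reproduces in-sample predictions", {
  sim <- small_pred_sim(n = 600)
  prof <- filter_background(sim$dataset$barcode)
  fm <- build_features(sim$dataset$expr, sim$dataset$meta, n_pcs = 10)
  fit <- train_predictors(fm, prof$binary[, "LHA-I", drop = FALSE], seed = 4)
  tp <- transfer_predict(sim$dataset$expr, sim$dataset$meta, fm$pc_model, fit,
                         min_shared = 50)
  direct <- predict(fit$models[["LHA-I"]], xgboost::xgb.DMatrix(fm$features))
  expect_equal(unname(tp$probability[, "LHA-I"]), unname(direct),
               tolerance = 1e-7)
  # insufficient shared genes is a transfer error
  few <- sim$dataset$expr$values[, 1:10]
  expect_error(transfer_predict(few, sim$dataset$meta, fm$pc_model, fit),
               "transfer error")
})

test_that("projection map comparison is exact on self and bounded", {
  sim <- small_pred_sim(n = 600)
  prof <- filter_background(sim$dataset$barcode)
  cmp <- compare_projection_maps(prof$binary, sim$dataset$meta$region,
                                 prof$binary, sim$dataset$meta$region)
  expect_equal(cmp$r, 1)
  expect_identical(dim(cmp$predicted), dim(cmp$reference))
  expect_true(all(cmp$predicted >= 0 & cmp$predicted <= 100))
  # a region present on one side only is excluded with a warning
  reg2 <- sim$dataset$meta$region
  reg2[1:5] <- "GHOST"
  expect_warning(compare_projection_maps(prof$binary, reg2, prof$binary,
                                         sim$dataset$meta$region), "GHOST")
})

test_that("group proportion test detects a planted enrichment", {
  set.seed(52)
  n_rep <- 8; per <- 250
  n <- n_rep * per
  replicate_id <- rep(paste0("r", 1:n_rep), each = per)
  group <- rep(c("FR", "NF"), each = n / 2)
  pred <- cbind(`ACB-I` = rbinom(n, 1, 0.5), `CP-I` = rbinom(n, 1, 0.5))
  flagged <- rbinom(n, 1, 0.1) == 1
  # FR cells predicted to ACB-I (and not CP-I, keeping its pool clean) are
  # flagged 4x as often
  idx <- group == "FR" & pred[, "ACB-I"] == 1 & pred[, "CP-I"] == 0
  flagged[idx] <- rbinom(sum(idx), 1, 0.4) == 1
  gp <- group_proportion_test(pred, flagged, replicate_id, group)
  expect_lt(gp$tests$p_value[gp$tests$target == "ACB-I"], 0.05)
  expect_gt(gp$tests$p_value[gp$tests$target == "CP-I"], 0.05)
  expect_true(all(gp$proportions >= 0 & gp$proportions <= 1, na.rm = TRUE))
  # identical proportions across replicates give p = 1
  flat <- rep(c(TRUE, FALSE), n / 2)
  pred1 <- cbind(`X-I` = rep(1L, n))
  gp1 <- group_proportion_test(pred1, flat, replicate_id, group)
  expect_equal(gp1$tests$p_value[1], 1)
  expect_error(group_proportion_test(pred, flagged, replicate_id,
                                     rep("FR", n)), "2 levels")
})
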