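# Per-target projection prediction from transcriptome principal components
# plus spatial coordinates, with shuffle and spatial-ablation controls, and
# transfer to external spatial-transcriptomic datasets via shared-gene
# standardization into the stored PC space.

#' Build a standardized feature matrix (PCs + coordinates)
#'
#' Genes are standardized (constant genes dropped with a warning), the top
#' `n_pcs` principal components are extracted, and each feature column --
#' including the three spatial coordinates when `use_spatial` -- is
#' standardized to mean 0, sd 1 on this (training) set. All standardization
#' parameters and PC loadings are retained in `pc_model` so the identical
#' transform can be replayed on external data.
#'
#' @param expr an [expression_matrix()] (log_normalized) or plain matrix.
#' @param coords data frame with `ap_mm`, `dv_mm`, `ml_mm` aligned to cells.
#' @param n_pcs number of principal components.
#' @param use_spatial append standardized coordinates as features?
#' @return A `feature_matrix`: `features` (cells x features), `pc_model`.
#' @export
build_features <- function(expr, coords, n_pcs = 50L, use_spatial = TRUE) {
  vals <- if (inherits(expr, "expression_matrix")) expr$values else expr
  n_pcs <- min(n_pcs, nrow(vals) - 1L, ncol(vals))
  stopifnot(n_pcs >= 1)
  sds <- apply(vals, 2, sd)
  if (any(sds == 0))
    warning("constant gene(s) dropped before PCA: ",
            paste(colnames(vals)[sds == 0], collapse = ", "))
  keep <- sds > 0
  vals <- vals[, keep, drop = FALSE]
  gmean <- colMeans(vals)
  gsd <- sds[keep]
  Xs <- scale(vals, center = gmean, scale = gsd)
  pc <- prcomp(Xs, center = FALSE, scale. = FALSE, rank. = n_pcs)
  scores <- pc$x[, seq_len(n_pcs), drop = FALSE]
  pc_mean <- colMeans(scores)
  pc_sd <- apply(scores, 2, sd)
  pc_sd[pc_sd == 0] <- 1
  feats <- scale(scores, center = pc_mean, scale = pc_sd)
  colnames(feats) <- paste0("PC", seq_len(n_pcs))
  coord_mean <- coord_sd <- NULL
  if (use_spatial) {
    cm <- as.matrix(coords[, c("ap_mm", "dv_mm", "ml_mm")])
    coord_mean <- colMeans(cm)
    coord_sd <- apply(cm, 2, sd)
    coord_sd[coord_sd == 0] <- 1
    feats <- cbind(feats, scale(cm, center = coord_mean, scale = coord_sd))
  }
  rownames(feats) <- rownames(vals)
  pc_model <- list(gene_ids = colnames(vals), gene_mean = gmean, gene_sd = gsd,
                   rotation = pc$rotation[, seq_len(n_pcs), drop = FALSE],
                   pc_mean = pc_mean, pc_sd = pc_sd,
                   coord_mean = coord_mean, coord_sd = coord_sd,
                   use_spatial = use_spatial)
  structure(list(features = feats, pc_model = pc_model),
            class = "feature_matrix")
}

#' Replay a stored feature transform on (external) data
#'
#' Restricts to the genes shared with the training panel, standardizes them
#' with the stored training means/sds, imputes missing training genes at 0
#' (the training mean after standardization), projects into the stored PC
#' space and appends standardized coordinates.
#'
#' @param pc_model the `pc_model` component of a [build_features()] result.
#' @param expr expression matrix or [expression_matrix()] of the new data.
#' @param coords coordinate data frame of the new data.
#' @param min_shared minimum number of shared genes.
#' @return Feature matrix with the training feature layout.
#' @export
apply_feature_model <- function(pc_model, expr, coords, min_shared = 50L) {
  vals <- if (inherits(expr, "expression_matrix")) expr$values else expr
  shared <- intersect(pc_model$gene_ids, colnames(vals))
  if (length(shared) < min_shared)
    stop("transfer error: only ", length(shared), " shared genes (need >= ",
         min_shared, ")")
  Xs <- matrix(0, nrow(vals), length(pc_model$gene_ids),
               dimnames = list(rownames(vals), pc_model$gene_ids))
  Xs[, shared] <- scale(vals[, shared, drop = FALSE],
                        center = pc_model$gene_mean[shared],
                        scale = pc_model$gene_sd[shared])
  scores <- Xs %*% pc_model$rotation
  feats <- scale(scores, center = pc_model$pc_mean, scale = pc_model$pc_sd)
  colnames(feats) <- paste0("PC", seq_len(ncol(feats)))
  if (pc_model$use_spatial) {
    cm <- as.matrix(coords[, c("ap_mm", "dv_mm", "ml_mm")])
    feats <- cbind(feats, scale(cm, center = pc_model$coord_mean,
                                scale = pc_model$coord_sd))
  }
  feats
}

spatial_cols <- c("ap_mm", "dv_mm", "ml_mm")

fit_xgb <- function(X, y, seed, nrounds = 300L, max_depth = 3L, eta = 0.1) {
  # deterministic: single thread, no row/column subsampling
  n <- nrow(X)
  set.seed(seed)
  val <- sample(n, max(1L, round(0.2 * n)))
  dtrain <- xgboost::xgb.DMatrix(X[-val, , drop = FALSE], label = y[-val])
  dval <- xgboost::xgb.DMatrix(X[val, , drop = FALSE], label = y[val])
  xgboost::xgb.train(
    params = list(objective = "binary:logistic", max_depth = max_depth,
                  eta = eta, nthread = 1, eval_metric = "logloss"),
    data = dtrain, nrounds = nrounds,
    evals = list(val = dval),
    early_stopping_rounds = 25L, verbose = 0)
}

#' Train per-target gradient-boosted projection classifiers
#'
#' For every target with at least 10 positive and 10 negative training cells
#' after a stratified 70/30 split, fits an independent gradient-boosted
#' decision-tree binary classifier (shallow trees, logistic objective, early
#' stopping on an internal validation fold) on the feature matrix. Targets
#' failing the class-count precondition are skipped and reported.
#'
#' @param fm a [build_features()] result (or plain feature matrix).
#' @param labels 0/1 cells x targets matrix aligned to the features.
#' @param train_fraction fraction of cells in the training split.
#' @param seed RNG seed controlling the split and fitting.
#' @return A `projection_predictor`: per-target `models`, `train_idx` /
#'   `test_idx` per target, `skipped` targets, the split definition.
#' @export
train_predictors <- function(fm, labels, train_fraction = 0.7, seed = 1L) {
  feats <- if (inherits(fm, "feature_matrix")) fm$features else fm
  stopifnot(nrow(feats) == nrow(labels))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  models <- list(); train_idx <- list(); test_idx <- list()
  skipped <- character(0)
  for (t in colnames(labels)) {
    y <- labels[, t]
    set.seed(seed + match(t, colnames(labels)))
    pos <- which(y == 1); neg <- which(y == 0)
    tr <- c(sample(pos, round(train_fraction * length(pos))),
            sample(neg, round(train_fraction * length(neg))))
    tr <- sort(tr)
    if (sum(y[tr] == 1) < 10 || sum(y[tr] == 0) < 10) {
      skipped <- c(skipped, t)
      next
    }
    models[[t]] <- fit_xgb(feats[tr, , drop = FALSE], y[tr],
                           seed = seed + match(t, colnames(labels)))
    train_idx[[t]] <- tr
    test_idx[[t]] <- setdiff(seq_len(nrow(feats)), tr)
  }
  if (!length(models)) stop("no target satisfies the class-count precondition")
  structure(list(models = models, train_idx = train_idx, test_idx = test_idx,
                 skipped = skipped, train_fraction = train_fraction,
                 seed = seed),
            class = "projection_predictor")
}

auc_score <- function(scores, y) {
  if (length(unique(y)) < 2) return(NA_real_)
  as.numeric(pROC::auc(pROC::roc(y, scores, quiet = TRUE,
                                 direction = "<", levels = c(0, 1))))
}

#' Evaluate predictors: ROC, shuffle control and spatial ablation
#'
#' Per target: the test-set ROC curve and AUC; a shuffle control (AUC of the
#' same scores against permuted test labels, averaged over `n_shuffle`
#' permutations); and, when the features carry spatial columns, a
#' transcriptome-only AUC from a classifier retrained on the same split with
#' the spatial columns removed.
#'
#' @param fit a [train_predictors()] result.
#' @param fm the feature matrix used to train (features + pc_model).
#' @param labels the label matrix used to train.
#' @param n_shuffle number of label permutations for the shuffle control.
#' @param ablate_spatial retrain without coordinates for the
#'   transcriptome-only control?
#' @param seed RNG seed for the permutations.
#' @return A `prediction_result` data frame per target: `auc`,
#'   `shuffle_auc`, `transcriptome_auc`, plus `roc` curves (list of
#'   data frames) and per-target test scores in attributes.
#' @export
evaluate_roc <- function(fit, fm, labels, n_shuffle = 1L,
                         ablate_spatial = TRUE, seed = 1L) {
  feats <- if (inherits(fm, "feature_matrix")) fm$features else fm
  has_spatial <- all(spatial_cols %in% colnames(feats))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  targets <- names(fit$models)
  rocs <- list(); scores_list <- list(); shuffle_list <- list()
  res <- data.frame(target = targets, auc = NA_real_, shuffle_auc = NA_real_,
                    transcriptome_auc = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_along(targets)) {
    t <- targets[i]
    te <- fit$test_idx[[t]]
    y <- labels[te, t]
    sc <- predict(fit$models[[t]],
                  xgboost::xgb.DMatrix(feats[te, , drop = FALSE]))
    scores_list[[t]] <- sc
    if (length(unique(y)) < 2) {
      warning("target ", t, ": single class in test set, AUC undefined")
      next
    }
    ro <- pROC::roc(y, sc, quiet = TRUE, direction = "<", levels = c(0, 1))
    res$auc[i] <- as.numeric(pROC::auc(ro))
    rocs[[t]] <- data.frame(fpr = rev(1 - ro$specificities),
                            tpr = rev(ro$sensitivities))
    set.seed(seed + i)
    sh <- vapply(seq_len(n_shuffle), function(s) auc_score(sc, sample(y)),
                 numeric(1))
    res$shuffle_auc[i] <- mean(sh)
    shuffle_list[[t]] <- sh
    if (ablate_spatial && has_spatial) {
      tr <- fit$train_idx[[t]]
      Xa <- feats[, setdiff(colnames(feats), spatial_cols), drop = FALSE]
      ma <- fit_xgb(Xa[tr, , drop = FALSE], labels[tr, t],
                    seed = fit$seed + match(t, colnames(labels)))
      sca <- predict(ma, xgboost::xgb.DMatrix(Xa[te, , drop = FALSE]))
      res$transcriptome_auc[i] <- auc_score(sca, y)
    }
  }
  attr(res, "roc") <- rocs
  attr(res, "scores") <- scores_list
  attr(res, "shuffle_aucs") <- shuffle_list
  class(res) <- c("prediction_result", "data.frame")
  res
}

#' Transfer trained predictors to an external dataset
#'
#' Harmonizes the external expression matrix into the stored feature space
#' (shared-gene standardization with training parameters, missing genes
#' imputed at the training mean, stored PC projection, standardized
#' coordinates), applies every per-target model and calls a projection at
#' predicted probability >= 0.5.
#'
#' @param expr_ext,coords_ext external expression matrix and coordinates.
#' @param pc_model stored `pc_model` from [build_features()].
#' @param fit a [train_predictors()] result.
#' @param min_shared minimum shared genes (default 50).
#' @return List with `probability` and `binary` (cells x targets matrices).
#' @export
transfer_predict <- function(expr_ext, coords_ext, pc_model, fit,
                             min_shared = 50L) {
  feats <- apply_feature_model(pc_model, expr_ext, coords_ext,
                               min_shared = min_shared)
  targets <- names(fit$models)
  prob <- vapply(targets, function(t)
    predict(fit$models[[t]], xgboost::xgb.DMatrix(feats)),
    numeric(nrow(feats)))
  if (is.null(dim(prob))) prob <- matrix(prob, nrow = 1, dimnames = list(rownames(feats), targets))
  rownames(prob) <- rownames(feats)
  list(probability = prob, binary = (prob >= 0.5) * 1L)
}

#' Compare predicted and reference region-by-target projection maps
#'
#' Per anatomical region and target: the percentage of the region's neurons
#' predicted (resp. observed) to project there; regions present in only one
#' dataset are excluded with a warning. The Pearson correlation over all
#' region x target percentages quantifies map agreement.
#'
#' @param pred_labels,ref_labels 0/1 cells x targets matrices (shared target
#'   columns are used).
#' @param pred_regions,ref_regions per-cell region labels.
#' @return List with `predicted`, `reference` percentage matrices
#'   (regions x targets, 0-100) and `r`.
#' @export
compare_projection_maps <- function(pred_labels, pred_regions,
                                    ref_labels, ref_regions) {
  targets <- intersect(colnames(pred_labels), colnames(ref_labels))
  regions <- intersect(unique(pred_regions), unique(ref_regions))
  only <- setdiff(union(unique(pred_regions), unique(ref_regions)), regions)
  if (length(only))
    warning("region(s) present in one dataset only, excluded: ",
            paste(only, collapse = ", "))
  pct <- function(labels, reg) {
    t(vapply(regions, function(r)
      100 * colMeans(labels[reg == r, targets, drop = FALSE]),
      numeric(length(targets))))
  }
  P <- pct(pred_labels, pred_regions)
  R <- pct(ref_labels, ref_regions)
  rownames(P) <- rownames(R) <- regions
  list(predicted = P, reference = R, r = cor(as.numeric(P), as.numeric(R)))
}

#' Per-target group proportion test across replicates
#'
#' For each replicate and target: the fraction of flagged cells (e.g.
#' behavior-activated neurons) among cells predicted to project to the
#' target. Per target, a two-sided two-sample t-test compares the
#' replicate-level proportions between the two groups.
#'
#' @param pred_labels 0/1 cells x targets matrix of predicted projections.
#' @param flagged logical per-cell flag.
#' @param replicate per-cell replicate identifier.
#' @param group per-cell group label with exactly 2 levels.
#' @param bh also report Benjamini-Hochberg q-values across targets?
#' @return List with `proportions` (replicate x target) and `tests`
#'   (data frame per target: group means, `p_value`, optional `q_value`).
#' @export
group_proportion_test <- function(pred_labels, flagged, replicate, group,
                                  bh = TRUE) {
  stopifnot(length(flagged) == nrow(pred_labels),
            length(replicate) == nrow(pred_labels),
            length(group) == nrow(pred_labels))
  glv <- unique(as.character(group))
  if (length(glv) != 2) stop("group must have exactly 2 levels")
  reps <- unique(as.character(replicate))
  rep_group <- vapply(reps, function(r) unique(as.character(group[replicate == r]))[1],
                      character(1))
  if (any(table(rep_group) < 2)) stop("need >= 2 replicates per group")
  prop <- matrix(NA_real_, length(reps), ncol(pred_labels),
                 dimnames = list(reps, colnames(pred_labels)))
  for (r in reps) for (t in colnames(pred_labels)) {
    sel <- replicate == r & pred_labels[, t] == 1
    if (!any(sel)) {
      warning("replicate ", r, " has no predicted cells for ", t, "; excluded")
      next
    }
    prop[r, t] <- mean(flagged[sel])
  }
  tests <- data.frame(target = colnames(pred_labels),
                      mean_a = NA_real_, mean_b = NA_real_,
                      p_value = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(ncol(pred_labels))) {
    a <- prop[rep_group == glv[1], i]; b <- prop[rep_group == glv[2], i]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    tests$mean_a[i] <- mean(a); tests$mean_b[i] <- mean(b)
    if (length(a) >= 2 && length(b) >= 2) {
      tests$p_value[i] <- if (sd(c(a, b)) == 0) 1 else
        tryCatch(t.test(a, b)$p.value, error = function(e) 1)
    }
  }
  names(tests)[2:3] <- paste0("mean_", glv)
  if (bh) tests$q_value <- p.adjust(tests$p_value, method = "BH")
  list(proportions = prop, tests = tests, groups = glv)
}
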