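# Synthetic multi-modal datasets with planted projection classes, motifs,
# spatial gradients and gene modules. The generator is first-class: every
# downstream stage is validated by recovering its planted structure.

#' Default prefrontal-cortex-like target catalog
#'
#' 24 ipsi-/contralateral downstream targets in four projection classes
#' (`PTi`, `ITi-M1`, `ITi-M2`, `ITc-M3`), six targets each: subcortical
#' ipsilateral nuclei for the pyramidal-tract class, dorsal-cortical and
#' dorsal-striatal ipsilateral targets, ventral-cortical/ventral-striatal and
#' amygdalar ipsilateral targets, and their contralateral counterparts.
#'
#' @return A [target_catalog()].
#' @export
default_targets <- function() {
  target_catalog(
    target_id = c("LHA-I", "VTA-I", "DR-I", "MD-I", "PAG-I", "SC-I",
                  "CP-I", "RSP-I", "VIS-I", "AUD-I", "SSp-I", "MOs-I",
                  "ACB-I", "BLA-I", "AId-I", "ECT-I", "ENTl-I", "PL-I",
                  "CP-C", "ACB-C", "PL-C", "AId-C", "ECT-C", "ENTl-C"),
    class_id = rep(c("PTi", "ITi-M1", "ITi-M2", "ITc-M3"), each = 6L))
}

#' Per-class marginal projection probabilities
#'
#' Builds the targets x classes matrix of marginal firing probabilities
#' `p[t, c]`. Each class has `n_anchor` anchor targets fired with probability
#' `p_anchor` (the class-defining joint projections, e.g. the several
#' subcortical nuclei a pyramidal-tract neuron innervates together),
#' secondary in-class targets at `p_secondary`, and off-class targets at
#' `p_out`.
#'
#' @param targets a [target_catalog()] with class assignments.
#' @param classes class labels (columns).
#' @param p_anchor,p_secondary,p_out firing probabilities.
#' @param n_anchor anchors per class.
#' @return Numeric matrix targets x classes.
#' @export
default_class_profiles <- function(targets, classes, p_anchor = 0.85,
                                   p_secondary = 0.30, p_out = 0.01,
                                   n_anchor = 4L) {
  pr <- matrix(p_out, nrow = nrow(targets), ncol = length(classes),
               dimnames = list(targets$target_id, classes))
  for (cl in classes) {
    idx <- which(targets$class_id == cl)
    anchors <- idx[seq_len(min(n_anchor, length(idx)))]
    pr[idx, cl] <- p_secondary
    pr[anchors, cl] <- p_anchor
  }
  pr
}

#' Simulation configuration
#'
#' Defines the statistical structure of a synthetic projectome-transcriptome
#' dataset: projection classes with per-class per-target firing probabilities,
#' a Gaussian-copula coupling between same-class targets, negative-binomial
#' signal UMIs over a Poisson ambient background, class-specific
#' anterior-posterior/dorsoventral soma positions, and gene co-expression
#' modules whose per-cell scores are coupled to the projection intensity of a
#' designated target.
#'
#' Defaults model a prefrontal-cortex-like projectome: 24 ipsi/contralateral
#' targets in four projection classes (`PTi`, `ITi-M1`, `ITi-M2`, `ITc-M3`,
#' six targets each), anchor-structured class profiles (four anchor targets
#' per class fired at 0.85, two secondary at 0.30, off-class at 0.01 -- so
#' nearly all neurons are multi-target and classes are coherent), signal UMI
#' mean 200 with dispersion 2 over a 0.5 ambient Poisson rate, class
#' centroids spread over the 0.5-2.8 mm anterior-posterior and dorsoventral
#' extent of the region with 0.3 mm spread, and four 25-gene modules each
#' coupled (alpha = 0.6) to one target of a different class.
#'
#' @param n_cells number of cells.
#' @param targets a [target_catalog()] with class assignments.
#' @param class_mix named class probabilities, summing to 1.
#' @param class_profiles targets x classes matrix of marginal firing
#'   probabilities `p[t, c]` in `[0, 1]`.
#' @param coupling_rho latent Gaussian correlation between same-class targets,
#'   in `[0, 1)`.
#' @param umi_signal_mean,umi_signal_dispersion negative-binomial mean and
#'   size for UMI counts of true projections.
#' @param background_rate Poisson mean of ambient counts on non-projecting
#'   cell-target pairs.
#' @param n_genes,n_modules,module_sizes gene-panel geometry; genes beyond
#'   `sum(module_sizes)` are unassigned noise genes (module `M0`).
#' @param module_loading per-gene loading on the module score.
#' @param module_target_coupling named vector: for each module, the coupled
#'   target_id; names `M1..Mk`.
#' @param module_alpha coupling strength alpha in `[0, 1]` shared by all
#'   modules (score = alpha * standardized target intensity +
#'   sqrt(1 - alpha^2) * noise).
#' @param spatial_means classes x 2 matrix of (ap_mm, dv_mm) means.
#' @param spatial_sd spatial standard deviation (mm).
#' @param expr_noise_sd per-gene expression noise sd.
#' @param seed default RNG seed used when [simulate_dataset()] is not given one.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_cells = 3000,
                       targets = default_targets(),
                       class_mix = NULL,
                       class_profiles = NULL,
                       coupling_rho = 0.5,
                       umi_signal_mean = 200,
                       umi_signal_dispersion = 2,
                       background_rate = 0.5,
                       n_genes = 120,
                       n_modules = 4,
                       module_sizes = rep(25L, 4),
                       module_loading = 1.0,
                       module_target_coupling = NULL,
                       module_alpha = 0.6,
                       spatial_means = NULL,
                       spatial_sd = 0.3,
                       expr_noise_sd = 0.5,
                       seed = 1L) {
  classes <- unique(targets$class_id[!is.na(targets$class_id)])
  if (!length(classes)) classes <- "C1"
  if (is.null(class_mix))
    class_mix <- setNames(rep(1 / length(classes), length(classes)), classes)
  if (is.null(class_profiles))
    class_profiles <- default_class_profiles(targets, names(class_mix))
  if (is.null(spatial_means)) {
    ap <- seq(2.4, 0.9, length.out = length(class_mix))
    dv <- c(2.4, 1.0, 2.2, 1.5)[seq_along(class_mix)]
    dv[is.na(dv)] <- 1.6
    spatial_means <- cbind(ap_mm = ap, dv_mm = dv)
  }
  spatial_means <- as.matrix(spatial_means)
  if (is.null(rownames(spatial_means)))
    rownames(spatial_means) <- names(class_mix)
  if (is.null(module_target_coupling) && n_modules > 0) {
    picks <- c("LHA-I", "CP-I", "ACB-I", "CP-C")
    picks <- picks[picks %in% targets$target_id]
    if (length(picks) < n_modules)
      picks <- targets$target_id[seq_len(n_modules)]
    module_target_coupling <- setNames(picks[seq_len(n_modules)],
                                       paste0("M", seq_len(n_modules)))
  }
  cfg <- list(n_cells = n_cells, targets = targets, class_mix = class_mix,
              class_profiles = class_profiles, coupling_rho = coupling_rho,
              umi_signal_mean = umi_signal_mean,
              umi_signal_dispersion = umi_signal_dispersion,
              background_rate = background_rate, n_genes = n_genes,
              n_modules = n_modules, module_sizes = module_sizes,
              module_loading = module_loading,
              module_target_coupling = module_target_coupling,
              module_alpha = module_alpha, spatial_means = spatial_means,
              spatial_sd = spatial_sd, expr_noise_sd = expr_noise_sd,
              seed = as.integer(seed))
  problems <- validate_sim_config(cfg)
  if (length(problems))
    stop("invalid simulation config: ", paste(problems, collapse = "; "))
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  p <- character(0)
  if (cfg$n_cells < 1) p <- c(p, "n_cells must be >= 1")
  if (abs(sum(cfg$class_mix) - 1) > 1e-9) p <- c(p, "class_mix must sum to 1")
  if (any(cfg$class_profiles < 0 | cfg$class_profiles > 1))
    p <- c(p, "class_profiles entries must lie in [0,1]")
  if (cfg$coupling_rho < 0 || cfg$coupling_rho >= 1)
    p <- c(p, "coupling_rho must lie in [0,1)")
  if (cfg$module_alpha < 0 || cfg$module_alpha > 1)
    p <- c(p, "module_alpha must lie in [0,1]")
  if (cfg$n_modules > 0 && sum(cfg$module_sizes) > cfg$n_genes)
    p <- c(p, "module_sizes sum exceeds n_genes")
  if (cfg$n_modules > 0 && length(cfg$module_sizes) != cfg$n_modules)
    p <- c(p, "module_sizes length must equal n_modules")
  if (!setequal(colnames(cfg$class_profiles), names(cfg$class_mix)))
    p <- c(p, "class_profiles columns must match class_mix names")
  if (cfg$background_rate < 0) p <- c(p, "background_rate must be >= 0")
  p
}

# Region labels derived deterministically from soma position: dorsal somata
# fall in MOs/ACC (anterior/posterior split), mid-depth in PL, ventral in ILA.
assign_region <- function(ap, dv) {
  region <- ifelse(dv < 1.4, ifelse(ap >= 1.6, "ACC", "MOs"),
                   ifelse(dv < 2.0, "PL", "ILA"))
  region
}

subtype_for_class <- c(PTi = "L5PT", `ITi-M1` = "L2/3IT1",
                       `ITi-M2` = "L2/3IT2", `ITc-M3` = "L5IT")

#' Simulate a multi-modal dataset with known ground truth
#'
#' Generation contract, per cell: (1) a projection class is drawn from
#' `class_mix`; (2) the binary projection vector comes from a Gaussian copula
#' -- a latent normal vector with correlation `coupling_rho` between targets
#' of the same target class and 0 otherwise, thresholded so that target `t`
#' fires with its configured marginal `p[t, class]`; (3) the UMI count of a
#' fired cell-target pair is negative binomial
#' (`umi_signal_mean`, `umi_signal_dispersion`), of a silent pair Poisson
#' (`background_rate`); (4) ap/dv positions are class-specific normals, ml is
#' uniform on (0, 1) mm; (5) each gene module's per-cell score is
#' `alpha * z(intensity of coupled target) + sqrt(1 - alpha^2) * N(0,1)`, and
#' a module gene's log-normalized value is
#' `baseline + loading * score + N(0, expr_noise_sd)`, clipped at 0.
#'
#' One barcode per target (`bc_<target>`). The same `(config, seed)` pair
#' reproduces the dataset exactly.
#'
#' @param config a [sim_config()].
#' @param seed RNG seed; defaults to `config$seed`.
#' @return A list with elements `dataset` (a `multimodal_dataset`) and
#'   `truth` (per-cell class, true binary matrix, per-gene module labels,
#'   per-module coupled target, module score matrix, configured marginals).
#' @export
simulate_dataset <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(as.integer(seed))

  n <- config$n_cells
  tg <- config$targets
  Tn <- nrow(tg)
  classes <- names(config$class_mix)
  cell_ids <- sprintf("cell_%05d", seq_len(n))

  cell_class <- sample(classes, n, replace = TRUE, prob = config$class_mix)

  # Gaussian copula: per-cell latent z over targets, block correlation rho
  # within each *target* class. Marginals are exact by construction.
  tclass <- tg$class_id
  tclass[is.na(tclass)] <- "unassigned"
  ublocks <- unique(tclass)
  rho <- config$coupling_rho
  g <- matrix(rnorm(n * length(ublocks)), n, length(ublocks),
              dimnames = list(NULL, ublocks))
  e <- matrix(rnorm(n * Tn), n, Tn)
  z <- sqrt(rho) * g[, tclass, drop = FALSE] + sqrt(1 - rho) * e
  pmat <- t(config$class_profiles[, cell_class, drop = FALSE])  # n x T
  fired <- z < qnorm(pmat)
  fired[pmat == 0] <- FALSE
  fired[pmat == 1] <- TRUE
  storage.mode(fired) <- "integer"
  dimnames(fired) <- list(cell_ids, tg$target_id)

  counts <- matrix(rpois(n * Tn, config$background_rate), n, Tn)
  nf <- sum(fired)
  # a true projection always yields at least one UMI: shifted negative
  # binomial with the configured mean
  counts[fired == 1L] <- 1L + rnbinom(nf, size = config$umi_signal_dispersion,
                                      mu = config$umi_signal_mean - 1)
  dimnames(counts) <- list(cell_ids, paste0("bc_", tg$target_id))
  bc <- barcode_count_matrix(counts, setNames(tg$target_id, colnames(counts)))

  mu <- config$spatial_means[cell_class, , drop = FALSE]
  ap <- rnorm(n, mu[, 1], config$spatial_sd)
  dv <- rnorm(n, mu[, 2], config$spatial_sd)
  ml <- runif(n, 0, 1)
  subtype <- subtype_for_class[cell_class]
  subtype[is.na(subtype)] <- "IT-other"
  flip <- runif(n) < 0.15
  subtype[flip] <- sample(unique(c(subtype_for_class, "L6CT")), sum(flip),
                          replace = TRUE)
  meta <- data.frame(cell_id = cell_ids, ap_mm = ap, dv_mm = dv, ml_mm = ml,
                     slice_index = pmax(0L, pmin(5L, as.integer(floor((2.8 - ap) / 0.4)))),
                     subtype = subtype, region = assign_region(ap, dv),
                     stringsAsFactors = FALSE)

  # expression: module scores coupled to the intensity of a designated target
  k <- config$n_modules
  gene_ids <- sprintf("gene_%04d", seq_len(config$n_genes))
  gene_module <- rep("M0", config$n_genes)
  if (k > 0)
    gene_module[seq_len(sum(config$module_sizes))] <-
      rep(paste0("M", seq_len(k)), times = config$module_sizes)
  scores <- NULL
  expr_vals <- matrix(0, n, config$n_genes, dimnames = list(cell_ids, gene_ids))
  baseline <- 2
  if (k > 0) {
    alpha <- config$module_alpha
    scores <- matrix(0, n, k, dimnames = list(cell_ids, paste0("M", seq_len(k))))
    for (m in seq_len(k)) {
      tgt <- config$module_target_coupling[[paste0("M", m)]]
      x <- counts[, paste0("bc_", tgt)]
      zt <- if (sd(x) > 0) (x - mean(x)) / sd(x) else rep(0, n)
      scores[, m] <- alpha * zt + sqrt(1 - alpha^2) * rnorm(n)
    }
  }
  loadings <- ifelse(gene_module == "M0", 0, config$module_loading)
  signal <- matrix(0, n, config$n_genes)
  if (k > 0) {
    in_mod <- gene_module != "M0"
    signal[, in_mod] <- scores[, gene_module[in_mod], drop = FALSE]
  }
  expr_vals <- baseline + sweep(signal, 2, loadings, `*`) +
    matrix(rnorm(n * config$n_genes, sd = config$expr_noise_sd), n, config$n_genes)
  expr_vals <- pmax(expr_vals, 0)
  dimnames(expr_vals) <- list(cell_ids, gene_ids)
  expr <- expression_matrix(expr_vals, layer = "log_normalized")

  ds <- multimodal_dataset(bc, expr, meta, tg)
  truth <- structure(list(cell_id = cell_ids, class = cell_class,
                          binary = fired, gene_module = setNames(gene_module, gene_ids),
                          module_target = config$module_target_coupling,
                          module_scores = scores,
                          marginals = config$class_profiles),
                     class = "sim_truth")
  list(dataset = ds, truth = truth)
}

#' Simulate a dataset under the target-independence null
#'
#' Identical generative process to [simulate_dataset()] except that the
#' copula coupling is removed (`coupling_rho = 0`), module-projection coupling
#' is removed (`alpha = 0`), spatial means are shared across classes, and the
#' per-target marginals are collapsed to their class-mix-weighted average --
#' so targets are mutually independent Bernoulli draws.
#'
#' @inheritParams simulate_dataset
#' @return As [simulate_dataset()].
#' @export
simulate_null_dataset <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  p_bar <- as.numeric(config$class_profiles %*% config$class_mix[colnames(config$class_profiles)])
  prof <- matrix(p_bar, nrow = nrow(config$class_profiles),
                 ncol = ncol(config$class_profiles),
                 dimnames = dimnames(config$class_profiles))
  mean_xy <- colMeans(config$spatial_means)
  sm <- config$spatial_means
  sm[, 1] <- mean_xy[1]; sm[, 2] <- mean_xy[2]
  cfg <- config
  cfg$class_profiles <- prof
  cfg$coupling_rho <- 0
  cfg$module_alpha <- 0
  cfg$spatial_means <- sm
  simulate_dataset(cfg, seed = seed)
}

#' Simulate binary profiles with one planted enriched or depleted motif
#'
#' Generates cells x targets binary projection patterns that are independent
#' Bernoulli(`p_base`) draws except for one planted motif (the pattern firing
#' exactly the first two targets), whose probability is calibrated -- by
#' exact enumeration of the pattern distribution and root finding -- so that
#' it is observed at `target_ratio` times its expectation under independence
#' *of the realized marginals*. `target_ratio > 1` plants an overrepresented
#' motif (mixture with a point mass on the motif), `target_ratio < 1` an
#' underrepresented one (thinning of the motif pattern).
#'
#' @param n_cells number of cells.
#' @param n_targets number of targets (<= 16; patterns are enumerated).
#' @param p_base baseline per-target firing probability.
#' @param target_ratio desired ratio of motif probability to the
#'   independence product.
#' @param seed RNG seed.
#' @return List: `binary` (matrix), `motif` (signature string), `ratio`
#'   (achieved exact ratio), `motif_probability`.
#' @export
simulate_motif_mixture <- function(n_cells, n_targets = 8L, p_base = 0.3,
                                   target_ratio = 3, seed = 1L) {
  stopifnot(n_targets <= 16, p_base > 0, p_base < 1, target_ratio > 0)
  pats <- as.matrix(expand.grid(rep(list(0:1), n_targets)))[, n_targets:1, drop = FALSE]
  colnames(pats) <- paste0(sprintf("T%02d", seq_len(n_targets)),
                           rep("-I", n_targets))
  q <- apply(pats, 1, function(s) prod(ifelse(s == 1, p_base, 1 - p_base)))
  motif_row <- which(apply(pats, 1, function(s)
    all(s[1:2] == 1) && all(s[-(1:2)] == 0)))
  ratio_of <- function(prob) {
    marg <- as.numeric(t(pats) %*% prob)
    s <- pats[motif_row, ]
    prob[motif_row] / prod(ifelse(s == 1, marg, 1 - marg))
  }
  adjust <- function(par) {
    prob <- q
    if (target_ratio >= 1) {           # mixture with point mass `par` on motif
      prob <- (1 - par) * q
      prob[motif_row] <- prob[motif_row] + par
    } else {                           # thin the motif pattern by factor `par`
      prob[motif_row] <- par * q[motif_row]
      prob <- prob / sum(prob)
    }
    prob
  }
  f <- function(par) ratio_of(adjust(par)) - target_ratio
  # the ratio is not monotone in the mixture weight (marginals inflate with
  # it), so bracket the smallest sign change on a grid before root finding
  grid <- seq(if (target_ratio >= 1) 0 else 1e-6, if (target_ratio >= 1) 0.9 else 1,
              length.out = 200)
  fg <- vapply(grid, f, numeric(1))
  flip <- which(fg[-1] * fg[-length(fg)] <= 0)[1]
  if (is.na(flip)) stop("target_ratio ", target_ratio, " not attainable at p_base ", p_base)
  par <- if (abs(target_ratio - 1) < 1e-12) if (target_ratio >= 1) 0 else 1 else
    stats::uniroot(f, grid[c(flip, flip + 1)], tol = 1e-12)$root
  prob <- adjust(par)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(as.integer(seed))
  idx <- sample.int(nrow(pats), n_cells, replace = TRUE, prob = prob)
  binary <- pats[idx, , drop = FALSE]
  rownames(binary) <- sprintf("cell_%05d", seq_len(n_cells))
  list(binary = binary,
       motif = paste(colnames(pats)[1:2], collapse = "+"),
       ratio = ratio_of(prob), motif_probability = prob[motif_row])
}

#' Write simulation truth tables alongside a dataset directory
#' @param truth a `sim_truth` object.
#' @param dir directory.
#' @export
write_truth <- function(truth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cells <- data.frame(cell_id = truth$cell_id, class = truth$class,
                      truth$binary, check.names = FALSE)
  write.table(cells, file.path(dir, "truth_cells.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(data.frame(gene_id = names(truth$gene_module),
                         module = unname(truth$gene_module)),
              file.path(dir, "truth_genes.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(truth$module_scores))
    write_results(truth$module_scores, file.path(dir, "truth_module_scores.tsv"))
  invisible(dir)
}
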