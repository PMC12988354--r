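# Independent oracles used across the suite. Each implements the target
# quantity by brute force / closed form, deliberately independent of the
# package code paths it is used to check.

# exhaustive chord-distance knee: evaluates the perpendicular distance of
# every point to the first-last chord with explicit point-line geometry
oracle_knee <- function(counts) {
  n <- length(counts)
  y <- log10(counts + 1)
  p1 <- c(1, y[1]); p2 <- c(n, y[n])
  chord_len <- sqrt(sum((p2 - p1)^2))
  d <- vapply(seq_len(n), function(i) {
    p <- c(i, y[i])
    # twice the triangle area over the base length
    abs((p2[1] - p1[1]) * (p1[2] - p[2]) - (p1[1] - p[1]) * (p2[2] - p1[2])) / chord_len
  }, numeric(1))
  best <- which(d == max(d))[1]   # smallest rank on ties
  counts[best]
}

# two-sided exact binomial p-value, minimum-likelihood method: sum of
# P(X = k) over all k whose probability does not exceed P(X = observed)
oracle_binom_p <- function(observed, n, p) {
  pm <- dbinom(0:n, n, p)
  sum(pm[pm <= pm[observed + 1] * (1 + 1e-7)])
}

# phi coefficient of a 2x2 table (a = both, b = only first, c = only second,
# d = neither)
oracle_phi_2x2 <- function(a, b, c, d) {
  (a * d - b * c) / sqrt((a + b) * (c + d) * (a + c) * (b + d))
}

# descending positive integer count vector with a high head and low tail,
# emulating a ranked UMI curve
random_count_vector <- function(len) {
  head_n <- max(1, rbinom(1, len, 0.4))
  x <- c(rnbinom(head_n, size = 2, mu = 150) + 1, rpois(len - head_n, 1.5) + 1)
  sort(x, decreasing = TRUE)
}

adjusted_rand <- function(a, b) mclust::adjustedRandIndex(a, b)

# small 8-target two-class catalog used throughout
tg8 <- function() {
  target_catalog(paste0(LETTERS[1:8], "-I"), rep(c("c1", "c2"), each = 4L))
}

# cheap 8-target config: barcode structure only, minimal expression block
cfg8 <- function(n_cells = 2000, p_in = 0.4, p_out = 0.05, rho = 0.5, ...) {
  tg <- tg8()
  pr <- default_class_profiles(tg, c("c1", "c2"), p_anchor = p_in,
                               p_secondary = p_in, p_out = p_out)
  sim_config(n_cells = n_cells, targets = tg,
             class_mix = c(c1 = 0.5, c2 = 0.5), class_profiles = pr,
             coupling_rho = rho, n_genes = 10, n_modules = 0,
             module_sizes = integer(0), ...)
}

# single-class independent-target config with explicit marginals
cfg_flat <- function(n_cells, p_t, ...) {
  ids <- paste0(sprintf("T%02d", seq_along(p_t)), "-I")
  tg <- target_catalog(ids, "c1")
  sim_config(n_cells = n_cells, targets = tg, class_mix = c(c1 = 1),
             class_profiles = matrix(p_t, length(p_t), 1,
                                     dimnames = list(ids, "c1")),
             coupling_rho = 0, n_genes = 10, n_modules = 0,
             module_sizes = integer(0), ...)
}
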