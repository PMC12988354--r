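# Background filtering of barcode UMI counts and projection profile
# construction. The ambient pool of a barcode produces a low-count shoulder in
# the ranked count curve; the knee of that curve (on a log scale) separates
# true projections from background.

#' Knee point of a descending count curve
#'
#' Finds the elbow of a descending, positive count vector: ranks are plotted
#' against `log10(count + 1)` and the knee is the point with maximum
#' perpendicular distance to the chord joining the first and last points.
#' Ties on distance break toward the smaller rank, i.e. the stricter filter.
#'
#' A knee below the chord is the corner of an ambient background shoulder; a
#' knee above the chord is the bulge of a pure signal curve (no background
#' shoulder to cut). [filter_background()] uses the `below_chord` attribute
#' to distinguish the two regimes.
#'
#' @param sorted_counts positive integer (or numeric) counts, sorted
#'   descending, length >= 3.
#' @return The count value at the knee, with attributes `rank` (knee rank)
#'   and `below_chord` (does the knee lie below the chord?), or `NA` when
#'   all counts are equal (no knee: retain everything).
#' @export
elbow_threshold <- function(sorted_counts) {
  n <- length(sorted_counts)
  if (n < 3) stop("elbow analysis needs at least 3 points, got ", n)
  if (any(sorted_counts <= 0)) stop("counts must be positive")
  if (is.unsorted(rev(sorted_counts))) stop("counts must be sorted descending")
  if (sorted_counts[1] == sorted_counts[n]) return(NA_real_)  # flat: no knee
  x <- seq_len(n)
  y <- log10(sorted_counts + 1)
  dx <- n - 1
  dy <- y[n] - y[1]
  # signed distance of (x_i, y_i) to the chord (1,y1)-(n,yn); > 0 = below
  d <- (dy * (x - 1) - dx * (y - y[1])) / sqrt(dx^2 + dy^2)
  knee <- which.max(abs(d))  # first maximum = smaller rank on ties
  structure(sorted_counts[knee], rank = knee, below_chord = d[knee] > 0)
}

#' Filter ambient background from a barcode count matrix
#'
#' Barcodes mapping to the same target are summed, then each target's positive
#' counts across cells are ranked and thresholded at their
#' [elbow_threshold()]. When the knee lies below the chord it marks the top
#' of the ambient background shoulder, and counts at or below the knee count
#' are zeroed (retention is strictly above the cutoff -- the knee point
#' itself is the largest ambient count, not the smallest signal count). When
#' the knee lies above the chord the ranked curve has no background shoulder
#' and all positive counts are retained. Targets with fewer than 3 positive
#' cells, or with a flat count profile, cannot be elbow-filtered and retain
#' all their positive counts (with a warning / report flag).
#'
#' @param bc a [barcode_count_matrix()].
#' @return A `projection_profiles` object: `intensity` (retained raw UMI,
#'   cells x targets), `binary` (0/1), a per-target `report` data frame
#'   (cutoff, n_positive, n_retained, filtered flag) and the ids of
#'   non-projecting cells (`all-zero` rows after filtering).
#' @export
filter_background <- function(bc) {
  stopifnot(inherits(bc, "barcode_count_matrix"))
  targets <- unique(unname(bc$barcode_to_target))
  n <- nrow(bc$counts)
  intensity <- matrix(0, n, length(targets),
                      dimnames = list(rownames(bc$counts), targets))
  report <- data.frame(target_id = targets, cutoff = NA_real_,
                       n_positive = 0L, n_retained = 0L, filtered = FALSE,
                       stringsAsFactors = FALSE)
  for (j in seq_along(targets)) {
    cols <- names(bc$barcode_to_target)[bc$barcode_to_target == targets[j]]
    x <- rowSums(bc$counts[, cols, drop = FALSE])
    pos <- x > 0
    report$n_positive[j] <- sum(pos)
    if (sum(pos) < 3) {
      if (sum(pos) > 0)
        warning("target ", targets[j], " has < 3 positive cells; unfilterable, all retained")
      intensity[, j] <- x
      report$n_retained[j] <- sum(pos)
      next
    }
    xs <- sort(x[pos], decreasing = TRUE)
    cutoff <- elbow_threshold(xs)
    # a genuine ambient shoulder is a below-chord corner in the low-count
    # half of the log-scale range; a knee outside that regime means the
    # curve is pure signal and nothing is filtered
    low_half <- !is.na(cutoff) &&
      log10(as.numeric(cutoff) + 1) <
        (log10(xs[1] + 1) + log10(xs[length(xs)] + 1)) / 2
    if (is.na(cutoff) || !attr(cutoff, "below_chord") || !low_half) {
      if (is.na(cutoff))
        warning("target ", targets[j], " has a flat count profile; no knee, all retained")
      intensity[, j] <- x
      report$n_retained[j] <- sum(pos)
      next
    }
    x[x <= cutoff] <- 0
    intensity[, j] <- x
    report$cutoff[j] <- as.numeric(cutoff)
    report$n_retained[j] <- sum(x > 0)
    report$filtered[j] <- TRUE
  }
  binary <- (intensity > 0) * 1L
  structure(list(intensity = intensity, binary = binary, report = report,
                 non_projecting = rownames(intensity)[rowSums(binary) == 0]),
            class = "projection_profiles")
}

#' Construct projection profiles directly from an intensity matrix
#'
#' Convenience constructor for already-filtered data (or planted truth).
#'
#' @param intensity nonnegative cells x targets matrix with dimnames.
#' @return A `projection_profiles` object.
#' @export
projection_profiles <- function(intensity) {
  intensity <- as.matrix(intensity)
  stopifnot(all(intensity >= 0))
  binary <- (intensity > 0) * 1L
  structure(list(intensity = intensity, binary = binary, report = NULL,
                 non_projecting = rownames(intensity)[rowSums(binary) == 0]),
            class = "projection_profiles")
}

#' @export
print.projection_profiles <- function(x, ...) {
  cat("projection_profiles:", nrow(x$intensity), "cells x",
      ncol(x$intensity), "targets;",
      sum(rowSums(x$binary) > 0), "projecting cells\n")
  invisible(x)
}

#' Normalize a projection intensity matrix
#'
#' @param p a `projection_profiles` object.
#' @param mode `"relative"` (each row divided by its row sum; all-zero rows
#'   stay zero), `"log1p"` (elementwise `log(1 + x)`), or
#'   `"zscore_by_target"` (per column, `(x - mean) / sd` computed over
#'   projecting cells; non-projecting entries stay 0).
#' @return Numeric matrix of the same shape.
#' @export
normalize_intensity <- function(p, mode = c("relative", "log1p", "zscore_by_target")) {
  mode <- match.arg(mode)
  m <- p$intensity
  switch(mode,
    relative = {
      rs <- rowSums(m)
      rs[rs == 0] <- 1
      m / rs
    },
    log1p = log1p(m),
    zscore_by_target = {
      out <- m * 0
      for (j in seq_len(ncol(m))) {
        idx <- p$binary[, j] == 1
        if (sum(idx) >= 2 && sd(m[idx, j]) > 0)
          out[idx, j] <- (m[idx, j] - mean(m[idx, j])) / sd(m[idx, j])
      }
      out
    })
}

#' Targets-per-cell multiplicity summary
#'
#' Distribution of the number of targets each projecting cell innervates,
#' the fraction of multi-target cells (>= 2 targets) and the maximum
#' multiplicity.
#'
#' @param p a `projection_profiles` object.
#' @return List with `histogram` (named counts over multiplicities),
#'   `fraction_multi`, `max_multiplicity`, `n_projecting`.
#' @export
multiplicity_summary <- function(p) {
  k <- rowSums(p$binary)
  k <- k[k > 0]
  if (!length(k))
    return(structure(list(histogram = integer(0), fraction_multi = NA_real_,
                          max_multiplicity = 0L, n_projecting = 0L),
                     class = "multiplicity_summary"))
  structure(list(histogram = table(factor(k, levels = seq_len(max(k)))),
                 fraction_multi = mean(k >= 2),
                 max_multiplicity = max(k),
                 n_projecting = length(k)),
            class = "multiplicity_summary")
}
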