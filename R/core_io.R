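#' @importFrom stats cor cor.test cutree dist hclust prcomp qnorm quantile
#'   binom.test fisher.test wilcox.test t.test p.adjust rnorm rpois rnbinom
#'   runif sd setNames median aggregate complete.cases
#' @importFrom utils read.csv read.delim write.table head packageVersion
NULL

# ---- target catalog ---------------------------------------------------------

#' Build a target catalog
#'
#' A target catalog records the downstream projection targets traced by the
#' barcoded viruses: a short identifier carrying an ipsi-/contralateral
#' hemisphere suffix (`"-I"` / `"-C"`) and an optional projection-class label
#' (e.g. `"PTi"`, `"ITi-M1"`).
#'
#' @param target_id character vector of unique target identifiers ending in
#'   `-I` (ipsilateral) or `-C` (contralateral).
#' @param class_id optional character vector of projection-class labels,
#'   recycled `NA` when absent.
#' @return A `target_catalog` data frame with columns `target_id`,
#'   `hemisphere`, `class_id`.
#' @export
target_catalog <- function(target_id, class_id = NA_character_) {
  target_id <- as.character(target_id)
  if (anyDuplicated(target_id))
    stop("duplicate target_id: ", paste(unique(target_id[duplicated(target_id)]), collapse = ", "))
  suffix <- sub("^.*-(I|C)$", "\\1", target_id)
  bad <- !grepl("-(I|C)$", target_id)
  if (any(bad))
    stop("target_id without -I/-C hemisphere suffix: ", paste(target_id[bad], collapse = ", "))
  hemisphere <- ifelse(suffix == "I", "ipsilateral", "contralateral")
  out <- data.frame(target_id = target_id, hemisphere = hemisphere,
                    class_id = rep_len(as.character(class_id), length(target_id)),
                    stringsAsFactors = FALSE)
  class(out) <- c("target_catalog", "data.frame")
  out
}

# ---- barcode count matrix ---------------------------------------------------

#' Construct a cell x barcode UMI count matrix
#'
#' Entry point of the pipeline: raw UMI counts of target-specific viral
#' barcodes per cell, together with the barcode-to-target map. Counts must be
#' nonnegative integers; each barcode maps to exactly one target.
#'
#' @param counts nonnegative integer matrix, cells in rows, barcodes in
#'   columns; dimnames required.
#' @param barcode_to_target named character vector mapping every barcode
#'   (names) to a target_id.
#' @return A `barcode_count_matrix` object.
#' @export
barcode_count_matrix <- function(counts, barcode_to_target) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have cell_ids as rownames and barcode_ids as colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate cell_id: ", rownames(counts)[duplicated(rownames(counts))][1])
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers")
  missing_map <- setdiff(colnames(counts), names(barcode_to_target))
  if (length(missing_map))
    stop("barcode without target mapping: ", paste(missing_map, collapse = ", "))
  structure(list(counts = counts,
                 barcode_to_target = barcode_to_target[colnames(counts)]),
            class = "barcode_count_matrix")
}

#' @export
print.barcode_count_matrix <- function(x, ...) {
  cat("barcode_count_matrix:", nrow(x$counts), "cells x", ncol(x$counts),
      "barcodes ->", length(unique(x$barcode_to_target)), "targets\n")
  invisible(x)
}

# ---- expression matrix ------------------------------------------------------

#' Construct an expression matrix with a declared layer
#'
#' @param values nonnegative numeric matrix, cells in rows, genes in columns.
#' @param layer `"raw_counts"` (integral) or `"log_normalized"`.
#' @return An `expression_matrix` object.
#' @export
expression_matrix <- function(values, layer = c("log_normalized", "raw_counts")) {
  layer <- match.arg(layer)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must have cell_ids as rownames and gene_ids as colnames")
  if (anyDuplicated(colnames(values)))
    stop("duplicate gene_id")
  if (any(!is.finite(values)) || any(values < 0))
    stop("expression values must be finite and >= 0")
  if (layer == "raw_counts" && any(values != round(values)))
    stop("raw_counts layer must be integral")
  structure(list(values = values, layer = layer), class = "expression_matrix")
}

# ---- metadata ---------------------------------------------------------------

meta_columns <- c("cell_id", "ap_mm", "dv_mm", "ml_mm", "slice_index",
                  "subtype", "region")

check_metadata <- function(meta) {
  miss <- setdiff(meta_columns, names(meta))
  if (length(miss)) stop("metadata missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(meta$cell_id)) stop("duplicate cell_id in metadata")
  coords <- as.matrix(meta[, c("ap_mm", "dv_mm", "ml_mm")])
  if (any(!is.finite(coords))) stop("non-finite coordinate in metadata")
  if (any(meta$slice_index < 0)) stop("negative slice_index")
  invisible(meta)
}

# ---- multimodal dataset -----------------------------------------------------

#' Assemble an aligned multi-modal dataset
#'
#' Restricts the barcode matrix, expression matrix and per-cell metadata to
#' their common cells, preserving the barcode-matrix cell order, and records
#' how many cells were dropped from each component.
#'
#' @param barcode a [barcode_count_matrix()].
#' @param expr an [expression_matrix()].
#' @param meta metadata data frame with columns `cell_id`, `ap_mm`, `dv_mm`,
#'   `ml_mm`, `slice_index`, `subtype`, `region`.
#' @param targets a [target_catalog()].
#' @return A `multimodal_dataset` with components `barcode`, `expr`, `meta`,
#'   `targets` and a `dropped` report.
#' @export
multimodal_dataset <- function(barcode, expr, meta, targets) {
  stopifnot(inherits(barcode, "barcode_count_matrix"),
            inherits(expr, "expression_matrix"))
  check_metadata(meta)
  cells_b <- rownames(barcode$counts)
  cells_e <- rownames(expr$values)
  cells_m <- as.character(meta$cell_id)
  keep <- cells_b[cells_b %in% cells_e & cells_b %in% cells_m]
  if (!length(keep))
    stop("alignment error: no shared cell_ids across barcode, expression and metadata")
  dropped <- c(barcode = length(cells_b) - length(keep),
               expr = length(cells_e) - length(keep),
               meta = length(cells_m) - length(keep))
  barcode$counts <- barcode$counts[keep, , drop = FALSE]
  expr$values <- expr$values[keep, , drop = FALSE]
  meta <- meta[match(keep, cells_m), , drop = FALSE]
  rownames(meta) <- NULL
  structure(list(barcode = barcode, expr = expr, meta = meta,
                 targets = targets, dropped = dropped),
            class = "multimodal_dataset")
}

#' @export
print.multimodal_dataset <- function(x, ...) {
  cat("multimodal_dataset:", nrow(x$barcode$counts), "cells,",
      ncol(x$barcode$counts), "barcodes,", ncol(x$expr$values), "genes,",
      nrow(x$targets), "targets\n")
  cat("  dropped cells: barcode", x$dropped["barcode"], "| expr",
      x$dropped["expr"], "| meta", x$dropped["meta"], "\n")
  invisible(x)
}

# ---- loading ----------------------------------------------------------------

read_numeric_matrix <- function(path) {
  if (grepl("\\.mtx$", path)) {
    m <- as.matrix(Matrix::readMM(path))
    cells <- readLines(sub("\\.mtx$", "_cells.tsv", path))
    feats <- readLines(sub("\\.mtx$", "_features.tsv", path))
    if (nrow(m) != length(cells) || ncol(m) != length(feats))
      stop("format error in ", path, ": dimensions disagree with sidecar tsv files")
    dimnames(m) <- list(cells, feats)
    m
  } else {
    df <- read.csv(path, row.names = 1, check.names = FALSE)
    bad <- which(!vapply(df, is.numeric, logical(1)))
    if (length(bad))
      stop("format error in ", path, ": non-numeric column '", names(df)[bad[1]], "'")
    as.matrix(df)
  }
}

#' Load a multi-modal dataset from disk
#'
#' Reads the barcode UMI matrix (dense CSV or MatrixMarket `.mtx` with
#' `*_cells.tsv` / `*_features.tsv` sidecars), the expression matrix (same
#' formats; layer declared in a YAML sidecar `<expr>_layer.yaml`, defaulting
#' to `log_normalized`), the metadata TSV and the targets TSV, then aligns
#' them with [multimodal_dataset()].
#'
#' @param barcode_path barcode count matrix file.
#' @param expr_path expression matrix file.
#' @param meta_path metadata TSV.
#' @param target_path targets TSV with columns `target_id`, `class_id`.
#' @param barcode_map_path TSV with columns `barcode_id`, `target_id`; if
#'   `NULL`, barcode column names are assumed to be target ids already.
#' @return A `multimodal_dataset`.
#' @export
load_dataset <- function(barcode_path, expr_path, meta_path, target_path,
                         barcode_map_path = NULL) {
  for (p in c(barcode_path, expr_path, meta_path, target_path))
    if (!file.exists(p)) stop("file not found: ", p)
  bc_counts <- read_numeric_matrix(barcode_path)
  if (any(bc_counts < 0)) {
    bad <- which(rowSums(bc_counts < 0) > 0)[1]
    stop("format error in ", barcode_path, ": negative count at row '",
         rownames(bc_counts)[bad], "'")
  }
  if (!is.null(barcode_map_path)) {
    map_df <- read.delim(barcode_map_path, stringsAsFactors = FALSE)
    if (!all(c("barcode_id", "target_id") %in% names(map_df)))
      stop("format error in ", barcode_map_path,
           ": need columns barcode_id, target_id")
    map <- setNames(map_df$target_id, map_df$barcode_id)
  } else {
    map <- setNames(colnames(bc_counts), colnames(bc_counts))
  }
  bc <- barcode_count_matrix(bc_counts, map)

  layer_file <- sub("\\.(csv|mtx)$", "_layer.yaml", expr_path)
  layer <- if (file.exists(layer_file))
    yaml::read_yaml(layer_file)$layer else "log_normalized"
  expr <- expression_matrix(read_numeric_matrix(expr_path), layer = layer)

  meta <- read.delim(meta_path, stringsAsFactors = FALSE)
  tg <- read.delim(target_path, stringsAsFactors = FALSE)
  if (!"target_id" %in% names(tg))
    stop("format error in ", target_path, ": need column target_id")
  if (!"class_id" %in% names(tg)) tg$class_id <- NA_character_
  targets <- target_catalog(tg$target_id, tg$class_id)
  multimodal_dataset(bc, expr, meta, targets)
}

# ---- validation -------------------------------------------------------------

#' Validate a multi-modal dataset
#'
#' Checks every structural invariant (count integrality, unique ids, complete
#' barcode-target mapping, coordinate finiteness, cell alignment) and returns
#' the violations as data, never as exceptions.
#'
#' @param ds a `multimodal_dataset`.
#' @return Character vector of violations; `character(0)` means valid.
#' @export
validate_dataset <- function(ds) {
  v <- character(0)
  cts <- ds$barcode$counts
  if (any(cts < 0)) v <- c(v, "negative barcode counts")
  if (any(cts != round(cts))) v <- c(v, "non-integral barcode counts")
  dup <- rownames(cts)[duplicated(rownames(cts))]
  for (d in unique(dup)) v <- c(v, paste0("duplicate cell_id: ", d))
  unmapped <- setdiff(colnames(cts), names(ds$barcode$barcode_to_target))
  for (b in unmapped) v <- c(v, paste0("barcode without target mapping: ", b))
  known <- ds$targets$target_id
  stray <- setdiff(ds$barcode$barcode_to_target, known)
  for (t in stray) v <- c(v, paste0("barcode target not in catalog: ", t))
  if (!identical(rownames(cts), rownames(ds$expr$values)))
    v <- c(v, "cell order mismatch between barcode and expression")
  if (!identical(rownames(cts), as.character(ds$meta$cell_id)))
    v <- c(v, "cell order mismatch between barcode and metadata")
  coords <- as.matrix(ds$meta[, c("ap_mm", "dv_mm", "ml_mm")])
  if (any(!is.finite(coords))) v <- c(v, "non-finite spatial coordinate")
  if (any(ds$meta$slice_index < 0)) v <- c(v, "negative slice_index")
  if (ds$expr$layer == "raw_counts" && any(ds$expr$values != round(ds$expr$values)))
    v <- c(v, "raw_counts layer not integral")
  v
}

# ---- writing ----------------------------------------------------------------

#' Write a result table to TSV or JSON
#'
#' TSV output uses a fixed column order, `.` decimal separator and 15
#' significant digits so that a write-read round trip reproduces values to at
#' least 12 significant digits.
#'
#' @param x a data frame or matrix produced by the pipeline.
#' @param path output file.
#' @param format `"tsv"` or `"json"`.
#' @export
write_results <- function(x, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(path))
  }
  if (is.matrix(x)) {
    df <- data.frame(id = rownames(x), as.data.frame(x, check.names = FALSE),
                     check.names = FALSE)
  } else df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(col) {
    ifelse(is.na(col), NA, format(col, digits = 15, trim = TRUE, scientific = FALSE))
  })
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, dec = ".")
  invisible(path)
}

#' Read back a matrix written by [write_results()]
#' @param path TSV path with an `id` first column.
#' @return Numeric matrix with ids as rownames.
#' @export
read_results_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write a simulated or loaded dataset to a directory
#'
#' Emits `barcode_counts.csv`, `barcode_map.tsv`, `expression.mtx` with
#' `expression_cells.tsv` / `expression_features.tsv` / `expression_layer.yaml`
#' sidecars, `metadata.tsv` and `targets.tsv`.
#'
#' @param ds a `multimodal_dataset`.
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  bc <- data.frame(cell_id = rownames(ds$barcode$counts),
                   as.data.frame(ds$barcode$counts, check.names = FALSE),
                   check.names = FALSE)
  write.table(bc, file.path(dir, "barcode_counts.csv"), sep = ",",
              quote = FALSE, row.names = FALSE)
  write.table(data.frame(barcode_id = names(ds$barcode$barcode_to_target),
                         target_id = unname(ds$barcode$barcode_to_target)),
              file.path(dir, "barcode_map.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  Matrix::writeMM(Matrix::Matrix(ds$expr$values, sparse = TRUE),
                  file.path(dir, "expression.mtx"))
  writeLines(rownames(ds$expr$values), file.path(dir, "expression_cells.tsv"))
  writeLines(colnames(ds$expr$values), file.path(dir, "expression_features.tsv"))
  yaml::write_yaml(list(layer = ds$expr$layer),
                   file.path(dir, "expression_layer.yaml"))
  write.table(ds$meta, file.path(dir, "metadata.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(as.data.frame(ds$targets)[, c("target_id", "class_id")],
              file.path(dir, "targets.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(dir)
}

#' Load a dataset directory written by [write_dataset()]
#' @param dir directory path.
#' @return A `multimodal_dataset`.
#' @export
load_dataset_dir <- function(dir) {
  load_dataset(file.path(dir, "barcode_counts.csv"),
               file.path(dir, "expression.mtx"),
               file.path(dir, "metadata.tsv"),
               file.path(dir, "targets.tsv"),
               barcode_map_path = file.path(dir, "barcode_map.tsv"))
}
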