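#' Single-cell count matrix container
#'
#' Bundles a cells x features matrix with its cell and feature identifiers,
#' optional per-cell labels (cell types or states), the assay modality and
#' optional per-cell QC covariates (mitochondrial read count, TSS enrichment
#' score, nucleosome signal). All pipeline stages consume and produce this
#' object.
#'
#' @param counts numeric cells x features matrix, non-negative; integer counts
#'   before normalisation.
#' @param cell_ids,feature_ids unique character identifiers; default to the
#'   dimnames of `counts` or generated `cell_<i>` / `feat_<j>` names.
#' @param labels optional per-cell category (character or factor).
#' @param modality one of `"GEX"` (gene expression), `"PEAKS"`, `"WINDOWS"`.
#' @param qc optional data.frame of per-cell QC columns; recognised names are
#'   `mito_count`, `tss_enrichment`, `nucleosome_signal`.
#' @param is_normalised,is_log processing-state flags; `is_log` requires
#'   `is_normalised`.
#' @return an object of class `count_matrix`.
#' @export
count_matrix <- function(counts, cell_ids = NULL, feature_ids = NULL,
                         labels = NULL, modality = c("GEX", "PEAKS", "WINDOWS"),
                         qc = NULL, is_normalised = FALSE, is_log = FALSE) {
  modality <- match.arg(modality)
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  .assert(all(is.finite(counts)), "counts must be finite")
  .assert(min(counts) >= 0, "counts must be non-negative")
  n <- nrow(counts); f <- ncol(counts)
  cell_ids <- cell_ids %||% rownames(counts) %||% sprintf("cell_%d", seq_len(n))
  feature_ids <- feature_ids %||% colnames(counts) %||% sprintf("feat_%d", seq_len(f))
  .assert(length(cell_ids) == n, "cell_ids length (%d) != rows (%d)", length(cell_ids), n)
  .assert(length(feature_ids) == f, "feature_ids length (%d) != cols (%d)", length(feature_ids), f)
  .assert(!anyDuplicated(cell_ids), "cell_ids must be unique")
  .assert(!anyDuplicated(feature_ids), "feature_ids must be unique")
  if (!is.null(labels)) {
    .assert(length(labels) == n, "labels length != number of cells")
    labels <- factor(labels)
  }
  if (!is.null(qc)) {
    .assert(is.data.frame(qc) && nrow(qc) == n, "qc must be a data.frame with one row per cell")
  }
  .assert(!(is_log && !is_normalised), "is_log implies is_normalised")
  dimnames(counts) <- list(cell_ids, feature_ids)
  structure(
    list(counts = counts, cell_ids = as.character(cell_ids),
         feature_ids = as.character(feature_ids), labels = labels,
         modality = modality, qc = qc,
         is_normalised = is_normalised, is_log = is_log),
    class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d cells x %d features [%s]%s%s\n",
              nrow(x$counts), ncol(x$counts), x$modality,
              if (x$is_normalised) ", normalised" else "",
              if (x$is_log) ", log1p" else ""))
  if (!is.null(x$labels))
    cat("  labels:", paste(levels(x$labels), collapse = ", "), "\n")
  if (!is.null(x$qc))
    cat("  qc:", paste(names(x$qc), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Number of cells / features
#' @param m a [count_matrix()].
#' @return integer scalar.
#' @export
n_cells <- function(m) nrow(m$counts)

#' @rdname n_cells
#' @export
n_features <- function(m) ncol(m$counts)

# keep a subset of cells/features, propagating ids, labels and qc
.subset_cm <- function(m, cells = NULL, features = NULL) {
  cells <- cells %||% seq_len(nrow(m$counts))
  features <- features %||% seq_len(ncol(m$counts))
  count_matrix(m$counts[cells, features, drop = FALSE],
               cell_ids = m$cell_ids[cells],
               feature_ids = m$feature_ids[features],
               labels = if (!is.null(m$labels)) m$labels[cells] else NULL,
               modality = m$modality,
               qc = if (!is.null(m$qc)) m$qc[cells, , drop = FALSE] else NULL,
               is_normalised = m$is_normalised, is_log = m$is_log)
}

# interpret matrices, count_matrix, embeddings or trained models as a plain
# numeric matrix of per-cell features
.as_feature_matrix <- function(x) {
  if (inherits(x, "count_matrix")) return(x$counts)
  if (inherits(x, "geometry_embedding")) return(x$coords)
  if (inherits(x, "trained_autoencoder")) return(x$latent)
  as.matrix(x)
}

#' Compute the mitochondrial read count QC column
#'
#' Sums counts over features whose identifier matches a prefix (default
#' `"MT-"`) and stores the per-cell total as the `mito_count` QC column.
#'
#' @param m a raw [count_matrix()].
#' @param prefix feature-id prefix identifying mitochondrial genes.
#' @return `m` with `qc$mito_count` filled in.
#' @export
add_mito_counts <- function(m, prefix = "MT-") {
  hit <- startsWith(m$feature_ids, prefix)
  mito <- rowSums(m$counts[, hit, drop = FALSE])
  if (is.null(m$qc)) m$qc <- data.frame(row.names = m$cell_ids)
  m$qc$mito_count <- mito
  m
}

#' Read / write a count matrix in MatrixMarket format
#'
#' `read_mtx_dir()` expects `matrix.mtx` (features in MTX rows or cells in
#' rows, controlled by `cells_in_rows`), `barcodes.tsv` and `features.tsv` in
#' `dir`; an optional `labels.tsv` (cell_id, label) is attached when present.
#' `write_mtx_dir()` mirrors the layout. MTX 1-based coordinates are handled
#' by the Matrix package.
#'
#' @param dir directory containing / receiving the files.
#' @param modality assay modality, see [count_matrix()].
#' @param cells_in_rows whether the MTX stores cells as rows (default FALSE:
#'   features x cells, the common convention).
#' @return a [count_matrix()] (read) or `dir`, invisibly (write).
#' @export
read_mtx_dir <- function(dir, modality = "GEX", cells_in_rows = FALSE) {
  mm <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  cells <- readLines(file.path(dir, "barcodes.tsv"))
  feats <- readLines(file.path(dir, "features.tsv"))
  counts <- as.matrix(mm)
  if (!cells_in_rows) counts <- t(counts)
  labels <- NULL
  lab_path <- file.path(dir, "labels.tsv")
  if (file.exists(lab_path)) {
    lab <- utils::read.table(lab_path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
    labels <- lab$label[match(cells, lab$cell_id)]
  }
  count_matrix(counts, cell_ids = cells, feature_ids = feats,
               labels = labels, modality = modality)
}

#' @rdname read_mtx_dir
#' @param m a [count_matrix()] to write.
#' @export
write_mtx_dir <- function(m, dir, cells_in_rows = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mm <- Matrix::Matrix(if (cells_in_rows) m$counts else t(m$counts), sparse = TRUE)
  Matrix::writeMM(mm, file.path(dir, "matrix.mtx"))
  writeLines(m$cell_ids, file.path(dir, "barcodes.tsv"))
  writeLines(m$feature_ids, file.path(dir, "features.tsv"))
  if (!is.null(m$labels)) {
    utils::write.table(
      data.frame(cell_id = m$cell_ids, label = as.character(m$labels)),
      file.path(dir, "labels.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' Read / write a dense delimited count matrix
#'
#' Dense text layout: header row of feature ids, first column of cell ids.
#'
#' @param path file path.
#' @param sep field separator (default tab).
#' @inheritParams read_mtx_dir
#' @return a [count_matrix()] (read) or `path`, invisibly (write).
#' @export
read_dense_matrix <- function(path, sep = "\t", modality = "GEX") {
  df <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                          row.names = 1, stringsAsFactors = FALSE)
  count_matrix(as.matrix(df), cell_ids = rownames(df),
               feature_ids = colnames(df), modality = modality)
}

#' @rdname read_dense_matrix
#' @param m a [count_matrix()] to write.
#' @export
write_dense_matrix <- function(m, path, sep = "\t") {
  df <- data.frame(cell_id = m$cell_ids, m$counts, check.names = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
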