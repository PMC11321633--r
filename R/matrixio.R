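#' Construct a cells-by-genes count matrix object
#'
#' The central expression container: a sparse cells x genes matrix of
#' non-negative integer counts plus a per-cell metadata tibble. Cells are
#' rows throughout the package; "positive" for a marker always means
#' `count > 0` on this raw scale.
#'
#' @param counts Matrix (dense or sparse) of non-negative integer counts,
#'   cells in rows. Dimnames, when present, seed `cell_ids` / `gene_ids`.
#' @param cell_ids,gene_ids Unique identifier vectors; defaults are taken
#'   from dimnames or generated (`cell_1`, ..., `gene_1`, ...).
#' @param cell_meta Tibble with one row per cell; typical columns are
#'   `timepoint`, `cluster` and the simulator's ground truth `truth_mic`.
#' @return An object of class `count_matrix`.
#' @export
count_matrix <- function(counts, cell_ids = NULL, gene_ids = NULL,
                         cell_meta = NULL) {
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "generalMatrix"), "CsparseMatrix")
  if (any(counts@x < 0)) abort("count matrix has negative entries",
                               class = "mictrack_format_error")
  if (any(counts@x != round(counts@x))) {
    abort("count matrix has non-integer entries", class = "mictrack_format_error")
  }
  cell_ids <- cell_ids %||% rownames(counts) %||% paste0("cell_", seq_len(nrow(counts)))
  gene_ids <- gene_ids %||% colnames(counts) %||% paste0("gene_", seq_len(ncol(counts)))
  if (length(cell_ids) != nrow(counts) || anyDuplicated(cell_ids)) {
    abort("cell_ids must be unique and match the number of rows",
          class = "mictrack_format_error")
  }
  if (length(gene_ids) != ncol(counts) || anyDuplicated(gene_ids)) {
    abort("gene_ids must be unique and match the number of columns",
          class = "mictrack_format_error")
  }
  cell_meta <- cell_meta %||% tibble::tibble(cell_id = cell_ids)
  cell_meta <- tibble::as_tibble(cell_meta)
  if (!"cell_id" %in% names(cell_meta)) {
    cell_meta <- dplyr::mutate(cell_meta, cell_id = cell_ids, .before = 1)
  }
  if (nrow(cell_meta) != nrow(counts)) {
    abort("cell_meta must have one row per cell", class = "mictrack_format_error")
  }
  dimnames(counts) <- list(cell_ids, gene_ids)
  structure(list(counts = counts, cell_ids = cell_ids, gene_ids = gene_ids,
                 cell_meta = cell_meta),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d cells x %d genes (%.1f%% non-zero)\n",
              nrow(x$counts), ncol(x$counts),
              100 * Matrix::nnzero(x$counts) / max(1, length(x$counts))))
  meta_cols <- setdiff(names(x$cell_meta), "cell_id")
  if (length(meta_cols)) cat("cell_meta:", paste(meta_cols, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Read a Matrix-Market count triple
#'
#' Reads the 10x-style triple written by [write_count_matrix()]: a
#' Matrix-Market coordinate file plus header-less TSV cell (barcode) and
#' gene (feature) tables. The on-disk orientation is cells x genes; if the
#' first matrix dimension instead matches the gene table the matrix is
#' transposed with a warning.
#'
#' @param matrix_path Path to the `.mtx` file.
#' @param cells_path,genes_path Paths to the TSV tables. The cell table's
#'   first column is the cell id; additional columns become `cell_meta`.
#' @return A [count_matrix()].
#' @export
read_count_matrix <- function(matrix_path, cells_path, genes_path) {
  for (p in c(matrix_path, cells_path, genes_path)) {
    if (!file.exists(p)) abort(paste0("file not found: ", p),
                               class = "mictrack_io_error")
  }
  m <- Matrix::readMM(matrix_path)
  cells <- readr::read_tsv(cells_path, col_names = FALSE, show_col_types = FALSE,
                           progress = FALSE)
  genes <- readr::read_tsv(genes_path, col_names = FALSE, show_col_types = FALSE,
                           progress = FALSE)
  if (nrow(m) != nrow(cells) && nrow(m) == nrow(genes) && ncol(m) == nrow(cells)) {
    warn("matrix stored genes x cells; transposing to cells x genes")
    m <- Matrix::t(m)
  }
  if (nrow(m) != nrow(cells) || ncol(m) != nrow(genes)) {
    abort(sprintf(
      "dimension mismatch: matrix is %d x %d but tables have %d cells / %d genes",
      nrow(m), ncol(m), nrow(cells), nrow(genes)), class = "mictrack_format_error")
  }
  meta <- cells
  names(meta) <- c("cell_id", setdiff(meta_col_names(ncol(cells)), "cell_id"))[
    seq_len(ncol(cells))]
  # restore types lost by header-less TSV round-trip
  if ("truth_mic" %in% names(meta)) meta$truth_mic <- as.logical(meta$truth_mic)
  count_matrix(m, cell_ids = as.character(meta$cell_id),
               gene_ids = as.character(genes[[1]]), cell_meta = meta)
}

meta_col_names <- function(n) {
  c("cell_id", "timepoint", "cluster", "truth_mic",
    paste0("meta_", seq_len(max(0, n - 4))))
}

#' Write a count matrix as a Matrix-Market triple
#'
#' Emits `matrix.mtx` (coordinate integer general, 1-based indices,
#' cells x genes), `barcodes.tsv` (cell id plus metadata columns, no
#' header) and `features.tsv` (gene ids, no header). Exact inverse of
#' [read_count_matrix()].
#'
#' @param matrix A [count_matrix()].
#' @param out_dir Output directory, created if absent.
#' @return Invisibly, the three file paths.
#' @export
write_count_matrix <- function(matrix, out_dir) {
  stopifnot(inherits(matrix, "count_matrix"))
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok) abort(paste0("cannot create directory: ", out_dir),
                 class = "mictrack_io_error")
  paths <- file.path(out_dir, c("matrix.mtx", "barcodes.tsv", "features.tsv"))
  m <- matrix$counts
  idx <- Matrix::which(m != 0, arr.ind = TRUE)
  ord <- order(idx[, 2], idx[, 1])  # column-major, the MM convention
  idx <- idx[ord, , drop = FALSE]
  vals <- m[idx]
  con <- file(paths[1], "w")
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               sprintf("%d %d %d", nrow(m), ncol(m), nrow(idx))), con)
  if (nrow(idx)) {
    writeLines(sprintf("%d %d %d", idx[, 1], idx[, 2], as.integer(vals)), con)
  }
  close(con)
  meta <- matrix$cell_meta
  front <- intersect(c("cell_id", "timepoint", "cluster", "truth_mic"), names(meta))
  meta <- meta[, c(front, setdiff(names(meta), front))]
  readr::write_tsv(meta, paths[2], col_names = FALSE, progress = FALSE)
  readr::write_tsv(tibble::tibble(gene = matrix$gene_ids), paths[3],
                   col_names = FALSE, progress = FALSE)
  invisible(paths)
}

#' Filter cells by detected genes and library size
#'
#' Quality control in the usual single-cell sense: a cell is retained when
#' it has at least `min_genes_per_cell` genes with non-zero count and a
#' total count of at least `min_total_counts`. Genes are never removed and
#' cell order is preserved.
#'
#' @param matrix A [count_matrix()].
#' @param min_genes_per_cell,min_total_counts Non-negative integer thresholds.
#' @return A filtered [count_matrix()]; possibly with zero cells.
#' @export
qc_filter_cells <- function(matrix, min_genes_per_cell = 0, min_total_counts = 0) {
  stopifnot(inherits(matrix, "count_matrix"))
  if (min_genes_per_cell < 0 || min_total_counts < 0) {
    stop_config("qc thresholds", "must be non-negative")
  }
  detected <- Matrix::rowSums(matrix$counts > 0)
  totals <- Matrix::rowSums(matrix$counts)
  keep <- detected >= min_genes_per_cell & totals >= min_total_counts
  count_matrix(matrix$counts[keep, , drop = FALSE],
               cell_ids = matrix$cell_ids[keep],
               gene_ids = matrix$gene_ids,
               cell_meta = matrix$cell_meta[keep, , drop = FALSE])
}

#' Log-normalize counts
#'
#' Standard library-size normalization: each cell's counts are scaled to
#' `scale_factor` total and log1p-transformed, i.e.
#' `log(1 + scale_factor * count / cell_total)`. Cells with zero total map
#' to all-zero rows. The result is for differential expression and
#' plotting only; the 1+1 classifier refuses normalized input because its
#' `count >= 1` threshold is defined on raw counts.
#'
#' @param matrix A [count_matrix()].
#' @param scale_factor Positive scale (default 1e4).
#' @return An object of class `normalized_matrix`.
#' @export
normalize_counts <- function(matrix, scale_factor = 1e4) {
  stopifnot(inherits(matrix, "count_matrix"))
  check_positive(scale_factor, "scale_factor")
  totals <- Matrix::rowSums(matrix$counts)
  inv <- ifelse(totals > 0, scale_factor / totals, 0)
  vals <- log1p(Matrix::Diagonal(x = inv) %*% matrix$counts)
  structure(list(values = methods::as(vals, "CsparseMatrix"),
                 scale_factor = scale_factor,
                 cell_ids = matrix$cell_ids, gene_ids = matrix$gene_ids,
                 cell_meta = matrix$cell_meta),
            class = "normalized_matrix")
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat(sprintf("<normalized_matrix> %d cells x %d genes (scale %g)\n",
              nrow(x$values), ncol(x$values), x$scale_factor))
  invisible(x)
}

#' @export
dim.normalized_matrix <- function(x) dim(x$values)
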