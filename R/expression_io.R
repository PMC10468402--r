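#' Construct an expression dataset
#'
#' Container for a cells x genes count matrix together with its
#' log-normalized transform and per-cell annotations. All inference in
#' this package operates on this object. Cells are rows; genes are columns.
#'
#' @param counts cells x genes matrix of non-negative integer counts
#'   (base matrix or any [Matrix::Matrix] subclass). Row names are cell
#'   ids, column names gene ids; both are required.
#' @param cells data.frame of per-cell annotations with at least
#'   `cell_id`, `cell_type`, `condition`; optional `subcluster`,
#'   `sample_id`. Rows are matched to `counts` by `cell_id`.
#' @param scale library-size scale factor for log-normalization
#'   (counts-per-`scale` then `log1p`). Default 1e4.
#' @param lognorm optional precomputed log-normalized matrix; when `NULL`
#'   it is computed with [log_normalize()].
#'
#' @return An object of class `ExpressionDataset`: a list with elements
#'   `counts`, `lognorm` (sparse cells x genes), `cells` (annotations,
#'   including the computed `cdr` column) and `genes`.
#' @export
ExpressionDataset <- function(counts, cells, scale = 1e4, lognorm = NULL) {
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "generalMatrix"), "CsparseMatrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry cell ids as rownames and gene ids as colnames")
  if (any(counts@x < 0)) stop("counts must be non-negative")
  required <- c("cell_id", "cell_type", "condition")
  missing_cols <- setdiff(required, names(cells))
  if (length(missing_cols))
    stop("cell annotations missing column(s): ",
         paste(missing_cols, collapse = ", "))
  cells <- as.data.frame(cells, stringsAsFactors = FALSE)
  keep <- rownames(counts) %in% cells$cell_id
  if (!all(keep)) {
    message(sum(!keep), " cell(s) lacked annotations and were dropped")
    counts <- counts[keep, , drop = FALSE]
  }
  cells <- cells[match(rownames(counts), cells$cell_id), , drop = FALSE]
  rownames(cells) <- NULL
  if (!"subcluster" %in% names(cells)) cells$subcluster <- NA_character_
  if (!"sample_id" %in% names(cells)) cells$sample_id <- NA_character_
  cells$condition <- as.character(cells$condition)
  cells$cdr <- compute_cdr(counts)
  if (is.null(lognorm)) lognorm <- log_normalize(counts, scale = scale)
  structure(
    list(counts = counts, lognorm = lognorm, cells = cells,
         genes = colnames(counts), scale = scale),
    class = "ExpressionDataset")
}

#' @export
print.ExpressionDataset <- function(x, ...) {
  cat(sprintf("ExpressionDataset: %d cells x %d genes\n",
              nrow(x$counts), ncol(x$counts)))
  cat("  cell types:", paste(sort(unique(x$cells$cell_type)), collapse = ", "),
      "\n  conditions:", paste(sort(unique(x$cells$condition)), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
dim.ExpressionDataset <- function(x) dim(x$counts)

#' Log-normalize a count matrix
#'
#' Counts-per-`scale` normalization followed by `log1p`:
#' `log1p(count / library_size * scale)`. Zero counts map to zero, so
#' sparsity is preserved.
#'
#' @param counts cells x genes non-negative matrix.
#' @param scale positive scale factor (default 1e4, i.e. counts per 10k).
#' @return sparse matrix of the same shape.
#' @export
log_normalize <- function(counts, scale = 1e4) {
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "generalMatrix"), "CsparseMatrix")
  stopifnot(scale > 0)
  libsize <- Matrix::rowSums(counts)
  if (any(libsize == 0)) {
    bad <- rownames(counts)[libsize == 0]
    stop("cell(s) with zero library size: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  out <- counts
  # dgCMatrix stores column-major; recover row index per nonzero entry
  i <- out@i + 1L
  out@x <- log1p(out@x / libsize[i] * scale)
  out
}

#' Per-cell detection rate
#'
#' The cellular detection rate (CDR) is the fraction of genes with at
#' least one count in a cell. It is a standard nuisance covariate in
#' single-cell regression models and enters every hurdle fit here.
#'
#' @param counts cells x genes matrix.
#' @return numeric vector in \[0, 1\], one value per cell.
#' @export
compute_cdr <- function(counts) {
  counts <- Matrix::Matrix(counts, sparse = TRUE)
  if (ncol(counts) < 1) stop("need at least one gene")
  as.numeric(Matrix::rowSums(counts > 0)) / ncol(counts)
}

#' Read an expression dataset from disk
#'
#' Accepts either Matrix Market sparse format with companion gene/cell
#' lists (10x convention) or a dense CSV with cell ids in the first
#' column and gene ids in the header. Matrix Market orientation
#' (genes x cells vs cells x genes) is auto-detected from the list
#' lengths and transposed to cells x genes.
#'
#' @param matrix_path `.mtx` file or dense `.csv`.
#' @param genes_path one-gene-per-line file (TSV; first column used);
#'   ignored for dense CSV.
#' @param cells_path one-cell-per-line file; ignored for dense CSV.
#' @param annotations_path TSV with columns `cell_id`, `cell_type`,
#'   `condition` and optional `subcluster`, `sample_id`.
#' @param scale log-normalization scale factor.
#' @return [ExpressionDataset()].
#' @export
read_expression <- function(matrix_path, genes_path = NULL, cells_path = NULL,
                            annotations_path, scale = 1e4) {
  if (grepl("\\.mtx$", matrix_path)) {
    m <- Matrix::readMM(matrix_path)
    genes <- utils::read.delim(genes_path, header = FALSE,
                               stringsAsFactors = FALSE)[[1]]
    cellids <- utils::read.delim(cells_path, header = FALSE,
                                 stringsAsFactors = FALSE)[[1]]
    if (nrow(m) == length(genes) && ncol(m) == length(cellids)) {
      m <- Matrix::t(m)
    } else if (!(nrow(m) == length(cellids) && ncol(m) == length(genes))) {
      stop(sprintf(
        "matrix is %d x %d but %d genes and %d cells were listed",
        nrow(m), ncol(m), length(genes), length(cellids)))
    }
    dimnames(m) <- list(cellids, genes)
  } else {
    df <- utils::read.csv(matrix_path, row.names = 1, check.names = FALSE)
    m <- Matrix::Matrix(as.matrix(df), sparse = TRUE)
  }
  ann <- utils::read.delim(annotations_path, stringsAsFactors = FALSE)
  ExpressionDataset(m, ann, scale = scale)
}

#' Write an expression dataset to disk
#'
#' Writes counts as Matrix Market plus gene/cell lists and the
#' annotations as TSV, the layout [read_expression()] reads back.
#'
#' @param ds [ExpressionDataset()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_expression <- function(ds, dir) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(ds$counts, file.path(dir, "matrix.mtx"))
  writeLines(ds$genes, file.path(dir, "features.tsv"))
  writeLines(rownames(ds$counts), file.path(dir, "barcodes.tsv"))
  ann <- ds$cells[, setdiff(names(ds$cells), "cdr"), drop = FALSE]
  utils::write.table(ann, file.path(dir, "annotations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Subset an expression dataset by cells
#'
#' @param ds [ExpressionDataset()].
#' @param idx logical or integer index over cells.
#' @return [ExpressionDataset()] restricted to the selected cells; the
#'   lognorm matrix and CDR are carried over, not recomputed.
#' @export
subset_cells <- function(ds, idx) {
  out <- ds
  out$counts <- ds$counts[idx, , drop = FALSE]
  out$lognorm <- ds$lognorm[idx, , drop = FALSE]
  out$cells <- ds$cells[idx, , drop = FALSE]
  rownames(out$cells) <- NULL
  out
}
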