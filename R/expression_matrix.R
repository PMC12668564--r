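#' Construct an ExpressionMatrix
#'
#' The central data container of the package: a dense non-negative matrix with
#' rows = cells (or bulk samples) and columns = genes, plus identifier vectors
#' and optional per-cell annotations. Absent measurements are stored as 0;
#' missing values are not allowed.
#'
#' @param values numeric matrix, rows = cells/samples, columns = genes,
#'   all entries finite and >= 0.
#' @param cell_ids character vector of unique row identifiers. Defaults to
#'   rownames(values) or `cell_1..cell_n`.
#' @param gene_ids character vector of unique column identifiers. Defaults to
#'   colnames(values) or `gene_1..gene_m`.
#' @param labels optional per-cell categorical annotation (cell type, group),
#'   length nrow(values).
#' @param mito_pct optional per-cell mitochondrial percentage in \[0, 100\].
#'
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values`, `cell_ids`, `gene_ids`, `labels`, `mito_pct`.
#' @export
#' @examples
#' x <- expression_matrix(matrix(0:5, nrow = 2))
#' dim(x)
expression_matrix <- function(values, cell_ids = NULL, gene_ids = NULL,
                              labels = NULL, mito_pct = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  attributes(values) <- attributes(values)[c("dim", "dimnames")]
  if (anyNA(values) || any(!is.finite(values))) {
    stop("expression values must be finite and non-missing (store absent measurements as 0)")
  }
  if (any(values < 0)) stop("expression values must be non-negative")
  if (is.null(cell_ids)) {
    cell_ids <- rownames(values)
    if (is.null(cell_ids)) cell_ids <- paste0("cell_", seq_len(nrow(values)))
  }
  if (is.null(gene_ids)) {
    gene_ids <- colnames(values)
    if (is.null(gene_ids)) gene_ids <- paste0("gene_", seq_len(ncol(values)))
  }
  cell_ids <- as.character(cell_ids)
  gene_ids <- as.character(gene_ids)
  if (length(cell_ids) != nrow(values)) stop("cell_ids length does not match nrow(values)")
  if (length(gene_ids) != ncol(values)) stop("gene_ids length does not match ncol(values)")
  if (anyDuplicated(cell_ids)) stop("cell_ids contain duplicates")
  if (anyDuplicated(gene_ids)) stop("gene_ids contain duplicates")
  if (!is.null(labels)) {
    if (length(labels) != nrow(values)) stop("labels length does not match number of cells")
    labels <- as.character(labels)
  }
  if (!is.null(mito_pct)) {
    if (length(mito_pct) != nrow(values)) stop("mito_pct length does not match number of cells")
    mito_pct <- as.numeric(mito_pct)
    if (any(!is.finite(mito_pct)) || any(mito_pct < 0) || any(mito_pct > 100)) {
      stop("mito_pct must lie in [0, 100]")
    }
  }
  dimnames(values) <- list(cell_ids, gene_ids)
  structure(
    list(values = values, cell_ids = cell_ids, gene_ids = gene_ids,
         labels = labels, mito_pct = mito_pct),
    class = "ExpressionMatrix"
  )
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d cells x %d genes\n", nrow(x$values), ncol(x$values)))
  nz <- mean(x$values != 0)
  cat(sprintf("  non-zero fraction: %.4f\n", nz))
  if (!is.null(x$labels)) {
    cat("  labels:", paste(utils::head(sort(unique(x$labels)), 8), collapse = ", "),
        if (length(unique(x$labels)) > 8) "..." else "", "\n")
  }
  if (!is.null(x$mito_pct)) cat("  mito_pct: present\n")
  invisible(x)
}

#' Subset an ExpressionMatrix by row/column index
#'
#' Keeps identifiers and per-cell annotations aligned with the matrix.
#'
#' @param x ExpressionMatrix.
#' @param cells integer/logical/character index of rows to keep (default all).
#' @param genes integer/logical/character index of columns to keep (default all).
#' @return ExpressionMatrix restricted to the selected cells and genes.
#' @export
subset_matrix <- function(x, cells = NULL, genes = NULL) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (is.null(cells)) cells <- seq_len(nrow(x$values))
  if (is.null(genes)) genes <- seq_len(ncol(x$values))
  if (is.character(cells)) cells <- match(cells, x$cell_ids)
  if (is.character(genes)) genes <- match(genes, x$gene_ids)
  expression_matrix(
    x$values[cells, genes, drop = FALSE],
    cell_ids = x$cell_ids[cells],
    gene_ids = x$gene_ids[genes],
    labels = if (!is.null(x$labels)) x$labels[cells] else NULL,
    mito_pct = if (!is.null(x$mito_pct)) x$mito_pct[cells] else NULL
  )
}
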