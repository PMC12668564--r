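#' Read an expression matrix from disk
#'
#' Supports MatrixMarket coordinate files (1-based indices) with plain-text
#' identifier sidecars, and dense delimited tables (TSV/CSV) whose header row
#' holds gene IDs and whose first column holds cell IDs. Rows are cells
#' throughout the package.
#'
#' For MTX input the identifier sidecars default to `<path>_cells.txt` and
#' `<path>_genes.txt` (one ID per line, no header), written by
#' [write_matrix()].
#'
#' @param path file path.
#' @param format one of `"mtx"`, `"tsv"`, `"csv"`; default guessed from the
#'   file extension.
#' @param cells_file,genes_file optional explicit sidecar paths (MTX only).
#' @return An [expression_matrix()].
#' @export
read_matrix <- function(path, format = c("auto", "mtx", "tsv", "csv"),
                        cells_file = NULL, genes_file = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, mtx = "mtx", csv = "csv", tsv = "tsv", txt = "tsv",
                     stop("cannot guess format from extension '", ext,
                          "'; pass format= explicitly"))
  }
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "mtx") {
    m <- tryCatch(Matrix::readMM(path),
                  error = function(e) stop("malformed MatrixMarket file '", path,
                                           "': ", conditionMessage(e)))
    m <- as.matrix(m)
    if (is.null(cells_file)) cells_file <- paste0(path, "_cells.txt")
    if (is.null(genes_file)) genes_file <- paste0(path, "_genes.txt")
    cell_ids <- if (file.exists(cells_file)) readLines(cells_file) else NULL
    gene_ids <- if (file.exists(genes_file)) readLines(genes_file) else NULL
    if (!is.null(cell_ids) && length(cell_ids) != nrow(m)) {
      stop("cell ID sidecar '", cells_file, "' has ", length(cell_ids),
           " entries but matrix has ", nrow(m), " rows")
    }
    if (!is.null(gene_ids) && length(gene_ids) != ncol(m)) {
      stop("gene ID sidecar '", genes_file, "' has ", length(gene_ids),
           " entries but matrix has ", ncol(m), " columns")
    }
    return(expression_matrix(m, cell_ids = cell_ids, gene_ids = gene_ids))
  }
  sep <- if (format == "csv") "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                           check.names = FALSE, stringsAsFactors = FALSE)
  expression_matrix(as.matrix(tab), cell_ids = rownames(tab), gene_ids = colnames(tab))
}

#' Write an expression matrix to disk
#'
#' Round-trips bit-exactly with [read_matrix()] for integer counts. MTX output
#' writes `<path>_cells.txt` / `<path>_genes.txt` identifier sidecars.
#'
#' @param x ExpressionMatrix (or plain matrix).
#' @param path destination path.
#' @param format `"mtx"`, `"tsv"` or `"csv"` (default guessed from extension).
#' @return `path`, invisibly.
#' @export
write_matrix <- function(x, path, format = c("auto", "mtx", "tsv", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, mtx = "mtx", csv = "csv", tsv = "tsv", txt = "tsv",
                     stop("cannot guess format from extension '", ext, "'"))
  }
  if (!inherits(x, "ExpressionMatrix")) x <- expression_matrix(x)
  if (format == "mtx") {
    Matrix::writeMM(methods::as(Matrix::Matrix(x$values, sparse = TRUE), "generalMatrix"), path)
    writeLines(x$cell_ids, paste0(path, "_cells.txt"))
    writeLines(x$gene_ids, paste0(path, "_genes.txt"))
  } else {
    sep <- if (format == "csv") "," else "\t"
    tab <- as.data.frame(x$values)
    utils::write.table(cbind(cell_id = x$cell_ids, tab), path, sep = sep,
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
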