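#' Quality-control parameters
#'
#' Thresholds for cellular and genomic quality control. Defaults follow common
#' practice for droplet scRNA-seq: at least 200 detected genes per cell, genes
#' kept when detected in at least 3 cells, top 2000 highly variable genes.
#' The upper detected-gene bound and the mitochondrial cutoff are
#' dataset-specific and have permissive defaults.
#'
#' @param min_genes_per_cell minimum number of detected (non-zero) genes a cell
#'   must have. Default 200.
#' @param max_features_per_cell maximum number of detected genes (doublet /
#'   saturation guard). Default `Inf` (disabled).
#' @param max_mito_pct maximum mitochondrial percentage per cell. Default `Inf`
#'   (disabled); requires `mito_pct` on the matrix when finite.
#' @param min_cells_per_gene a gene is kept when detected in at least this many
#'   cells. Default 3.
#' @param n_hvgs number of highly variable genes to keep. Default 2000.
#' @return A list of class `qc_params`.
#' @export
qc_params <- function(min_genes_per_cell = 200, max_features_per_cell = Inf,
                      max_mito_pct = Inf, min_cells_per_gene = 3, n_hvgs = 2000) {
  stopifnot(min_genes_per_cell > 0, max_features_per_cell > 0,
            max_mito_pct > 0, min_cells_per_gene > 0, n_hvgs > 0)
  if (min_genes_per_cell > max_features_per_cell) {
    stop("min_genes_per_cell must be <= max_features_per_cell")
  }
  structure(list(min_genes_per_cell = min_genes_per_cell,
                 max_features_per_cell = max_features_per_cell,
                 max_mito_pct = max_mito_pct,
                 min_cells_per_gene = min_cells_per_gene,
                 n_hvgs = n_hvgs),
            class = "qc_params")
}

#' Filter cells by detected-gene count and mitochondrial content
#'
#' Retains exactly the cells whose detected-gene count (number of non-zero
#' entries) lies in `[min_genes_per_cell, max_features_per_cell]` and whose
#' mitochondrial percentage does not exceed `max_mito_pct`. Cell order is
#' preserved.
#'
#' @param x ExpressionMatrix of raw counts.
#' @param qc [qc_params()].
#' @return The row-subset ExpressionMatrix, with attribute `qc_removed` giving
#'   the number of cells removed per criterion.
#' @export
filter_cells <- function(x, qc = qc_params()) {
  stopifnot(inherits(x, "ExpressionMatrix"), inherits(qc, "qc_params"))
  detected <- rowSums(x$values > 0)
  low  <- detected < qc$min_genes_per_cell
  high <- detected > qc$max_features_per_cell
  if (is.finite(qc$max_mito_pct)) {
    if (is.null(x$mito_pct)) {
      stop("max_mito_pct is set but the matrix carries no mito_pct annotation")
    }
    mito <- x$mito_pct > qc$max_mito_pct
  } else {
    mito <- rep(FALSE, nrow(x$values))
  }
  keep <- !(low | high | mito)
  if (!any(keep)) stop("no cells survive QC")
  out <- subset_matrix(x, cells = which(keep))
  attr(out, "qc_removed") <- c(low_genes = sum(low), high_features = sum(high),
                               high_mito = sum(mito))
  out
}

#' Filter genes by detection ubiquity
#'
#' Removes genes detected (value > 0) in fewer than `min_cells_per_gene` cells;
#' a gene detected in exactly the threshold number of cells is retained.
#' Column order is preserved.
#'
#' @inheritParams filter_cells
#' @return Column-subset ExpressionMatrix.
#' @export
filter_genes <- function(x, qc = qc_params()) {
  stopifnot(inherits(x, "ExpressionMatrix"), inherits(qc, "qc_params"))
  ncells <- colSums(x$values > 0)
  keep <- ncells >= qc$min_cells_per_gene
  if (!any(keep)) stop("no genes survive QC")
  subset_matrix(x, genes = which(keep))
}

#' Variance-stabilized HVG scores
#'
#' Standardized variance per gene under a mean-variance trend: a loess fit of
#' log10(variance) on log10(mean) over genes with positive variance predicts
#' the expected standard deviation per gene; values are standardized by it,
#' clipped at sqrt(n_cells), and the variance of the clipped standardized
#' values is the score. Genes with zero variance or a non-finite score rank
#' last (score 0 with a warning for non-finite estimates).
#'
#' @param x ExpressionMatrix (counts, after gene filtering).
#' @return numeric vector of scores, one per gene.
#' @keywords internal
hvg_scores <- function(x) {
  v <- x$values
  n <- nrow(v)
  mu <- colMeans(v)
  s2 <- apply(v, 2, stats::var)
  score <- numeric(ncol(v))
  ok <- is.finite(s2) & s2 > 0 & mu > 0
  if (any(!is.finite(s2))) {
    warning("non-finite variance estimates for ", sum(!is.finite(s2)),
            " genes; ranked last")
  }
  if (sum(ok) >= 2) {
    fit <- stats::loess(log10(s2[ok]) ~ log10(mu[ok]), span = 0.3,
                        degree = 2, family = "gaussian",
                        control = stats::loess.control(surface = "direct"))
    sd_exp <- sqrt(10^stats::predict(fit, data.frame(`log10(mu[ok])` = log10(mu[ok]),
                                                     check.names = FALSE)))
    sd_exp <- pmax(sd_exp, .Machine$double.eps)
    clipmax <- sqrt(n)
    idx <- which(ok)
    for (j in seq_along(idx)) {
      z <- (v[, idx[j]] - mu[idx[j]]) / sd_exp[j]
      z <- pmin(pmax(z, -clipmax), clipmax)
      score[idx[j]] <- stats::var(z)
    }
  } else if (sum(ok) == 1) {
    score[ok] <- 1
  }
  score[!is.finite(score)] <- 0
  score
}

#' Select highly variable genes
#'
#' Keeps the `n_hvgs` genes with the highest standardized variance under the
#' mean-variance trend fit of [hvg_scores()]. Deterministic; ties broken by
#' input gene order. If fewer than `n_hvgs` genes are present, all are
#' returned (with a message) in score order.
#'
#' @param x ExpressionMatrix after gene filtering.
#' @param n_hvgs number of genes to keep.
#' @return ExpressionMatrix restricted to the selected genes, ordered by
#'   decreasing score.
#' @export
select_hvgs <- function(x, n_hvgs = 2000) {
  stopifnot(inherits(x, "ExpressionMatrix"), n_hvgs > 0)
  score <- hvg_scores(x)
  if (ncol(x$values) <= n_hvgs) {
    message("only ", ncol(x$values), " genes available for ", n_hvgs,
            " requested HVGs; returning all")
    n_hvgs <- ncol(x$values)
  }
  ord <- order(-score, seq_along(score))  # ties by input order
  top <- ord[seq_len(n_hvgs)]
  out <- subset_matrix(x, genes = top)
  attr(out, "hvg_scores") <- score[top]
  out
}

#' Restrict single-cell and bulk matrices to their common genes
#'
#' Both outputs are restricted to the ordered intersection of gene IDs, in the
#' single-cell matrix's gene order.
#'
#' @param sc single-cell ExpressionMatrix.
#' @param bulk bulk ExpressionMatrix (samples x genes).
#' @return list with elements `sc`, `bulk`, `n_common`.
#' @export
intersect_with_bulk <- function(sc, bulk) {
  stopifnot(inherits(sc, "ExpressionMatrix"), inherits(bulk, "ExpressionMatrix"))
  common <- sc$gene_ids[sc$gene_ids %in% bulk$gene_ids]
  if (length(common) == 0) {
    stop("no genes shared between single-cell namespace (e.g. ",
         paste(utils::head(sc$gene_ids, 3), collapse = ","),
         ") and bulk namespace (e.g. ",
         paste(utils::head(bulk$gene_ids, 3), collapse = ","), ")")
  }
  list(sc = subset_matrix(sc, genes = common),
       bulk = subset_matrix(bulk, genes = common),
       n_common = length(common))
}

#' Build a pseudo-bulk reference from single-cell data
#'
#' Aggregates cells gene-wise by mean or sum. With per-cell labels (either on
#' the matrix or passed explicitly) one pseudo-bulk sample is produced per
#' label; otherwise a single row.
#'
#' @param sc single-cell ExpressionMatrix.
#' @param mode `"mean"` or `"sum"`.
#' @param labels optional per-cell grouping overriding `sc$labels`.
#' @param per_label aggregate per label when labels are available. Default TRUE.
#' @return ExpressionMatrix with one row per pseudo-bulk sample.
#' @export
make_pseudobulk <- function(sc, mode = c("mean", "sum"), labels = NULL,
                            per_label = TRUE) {
  stopifnot(inherits(sc, "ExpressionMatrix"), nrow(sc$values) > 0)
  mode <- match.arg(mode)
  if (is.null(labels)) labels <- sc$labels
  agg <- function(v) if (mode == "mean") colMeans(v) else colSums(v)
  if (per_label && !is.null(labels)) {
    groups <- sort(unique(labels))
    out <- t(vapply(groups, function(g) agg(sc$values[labels == g, , drop = FALSE]),
                    numeric(ncol(sc$values))))
    rownames(out) <- paste0("pseudobulk_", groups)
  } else {
    out <- matrix(agg(sc$values), nrow = 1,
                  dimnames = list("pseudobulk", sc$gene_ids))
  }
  expression_matrix(out, gene_ids = sc$gene_ids)
}
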