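#' SNN-refined cell neighborhoods
#'
#' For each cell, its k nearest neighbors under Euclidean distance on the
#' transformed matrix (ties by lower index); for each neighbor `c_j` of
#' `c_i` the shared-nearest-neighbor count `|N_k(c_i) ∩ N_k(c_j)|`; and the
#' refined set `E(c_i)`: the neighbors of `c_i` reordered by descending SNN
#' count (ties by original kNN rank). A cell is never its own neighbor.
#'
#' @param x ExpressionMatrix (transformed) or plain matrix, rows = cells.
#' @param k neighborhood size, `1 <= k < n`.
#' @return list of class `neighborhood_plan`: `knn` (n x k index matrix,
#'   nearest first), `snn_counts` (n x k integer matrix aligned with `knn`),
#'   `refined` (n x k index matrix, `E` per cell), `k`.
#' @export
build_neighborhoods <- function(x, k) {
  v <- if (inherits(x, "ExpressionMatrix")) x$values else as.matrix(x)
  n <- nrow(v)
  if (k < 1 || k >= n) stop("k must satisfy 1 <= k < n, got k=", k, ", n=", n)
  d <- as.matrix(stats::dist(v))
  knn <- matrix(0L, n, k)
  for (i in seq_len(n)) {
    dd <- d[i, ]
    dd[i] <- Inf
    ord <- order(dd, seq_len(n))  # nearest first, ties by lower index
    knn[i, ] <- ord[seq_len(k)]
  }
  member <- matrix(FALSE, n, n)
  for (i in seq_len(n)) member[i, knn[i, ]] <- TRUE
  snn <- matrix(0L, n, k)
  refined <- matrix(0L, n, k)
  for (i in seq_len(n)) {
    for (jj in seq_len(k)) {
      j <- knn[i, jj]
      snn[i, jj] <- sum(member[i, ] & member[j, ])
    }
    # descending SNN overlap, ties by original kNN rank
    ord <- order(-snn[i, ], seq_len(k))
    refined[i, ] <- knn[i, ord]
  }
  structure(list(knn = knn, snn_counts = snn, refined = refined, k = k),
            class = "neighborhood_plan")
}

#' Density-guided projection of one cell
#'
#' The mapping centroid `F` is the mean of the refined-neighborhood expression
#' vectors; candidate positions `c_t = c_i + t (F - c_i)` are scored by the
#' local density `rho(c_t) = 1 / (sum_j ||c_t - c_j||^2 + eps)` over the
#' neighborhood, and the candidate with maximal density (equivalently minimal
#' summed squared distance) is returned, ties to the smaller t.
#'
#' @param ci numeric expression vector of the target cell.
#' @param E numeric matrix of refined-neighbor expression vectors (rows).
#' @param t_grid candidate projection weights. Default `seq(0, 1, by = 0.1)`.
#' @param eps density guard against division by zero. Default 1e-12.
#' @return list of class `projection_result`: `centroid`, `t_grid`,
#'   `densities`, `chosen_t`, `c_t_star`.
#' @export
project_cell <- function(ci, E, t_grid = seq(0, 1, by = 0.1), eps = 1e-12) {
  E <- as.matrix(E)
  if (nrow(E) == 0) stop("empty neighborhood E")
  if (length(t_grid) == 0) stop("empty t_grid")
  stopifnot(ncol(E) == length(ci))
  Fc <- colMeans(E)
  dir <- Fc - ci
  dens <- vapply(t_grid, function(t) {
    ct <- ci + t * dir
    ss <- sum((matrix(ct, nrow(E), length(ct), byrow = TRUE) - E)^2)
    1 / (ss + eps)
  }, numeric(1))
  stopifnot(all(is.finite(dens)))
  best <- which.max(dens)  # which.max takes the first: ties to smaller t given ordered grid
  structure(list(centroid = Fc, t_grid = t_grid, densities = dens,
                 chosen_t = t_grid[best], c_t_star = ci + t_grid[best] * dir),
            class = "projection_result")
}

#' Impute flagged dropout positions
#'
#' Each cell carrying at least one flagged position is projected along the
#' direction to its SNN-refined neighborhood centroid ([project_cell()]); the
#' projected row supplies values only at that cell's flagged positions. All
#' projections in a pass are computed against the frozen input matrix, so the
#' result does not depend on cell order; `passes > 1` repeats the whole cycle
#' on the updated matrix. The final matrix is
#' `Y_imputed = Y1 * I1 + X` (element-wise), which leaves observed entries
#' bit-identical and biological zeros exactly 0.
#'
#' @param x ExpressionMatrix (transformed single-cell matrix).
#' @param I1 binary imputation index from [call_dropouts()]; must satisfy
#'   `I1 * I0 = 0`.
#' @param k neighborhood size. Default 21.
#' @param t_grid candidate projection weights. Default `seq(0, 1, by = 0.1)`.
#' @param passes number of whole imputation passes. Default 1.
#' @return list of class `imputed_matrix`: `Y_imputed` (ExpressionMatrix),
#'   `Y1` (projected matrix), `provenance` (0 observed, 1 imputed,
#'   2 biological zero), `chosen_t` (per-cell, NA where no projection ran).
#' @export
impute_all <- function(x, I1, k = 21, t_grid = seq(0, 1, by = 0.1), passes = 1) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  I1 <- as.matrix(I1)
  attributes(I1) <- attributes(I1)["dim"]  # drop caller attrs (tau, counts)
  v <- x$values
  if (!all(dim(I1) == dim(v))) stop("shape mismatch between X and I1")
  I0 <- (v != 0) * 1
  if (any(I1 * I0 != 0)) stop("I1 flags observed positions (I1 * I0 != 0)")
  stopifnot(passes >= 1)
  n <- nrow(v)
  chosen_t <- rep(NA_real_, n)
  cur <- v
  for (pass in seq_len(passes)) {
    plan <- build_neighborhoods(cur, k = k)
    Y1 <- cur
    todo <- which(rowSums(I1) > 0)
    for (i in todo) {
      E <- cur[plan$refined[i, ], , drop = FALSE]
      pr <- project_cell(cur[i, ], E, t_grid = t_grid)
      chosen_t[i] <- pr$chosen_t
      Y1[i, ] <- pr$c_t_star
    }
    cur <- Y1 * I1 + cur * (1 - I1)
  }
  Y1_final <- Y1
  Y_imputed <- Y1_final * I1 + v * (1 - I1)
  # identical to Y1 * I1 + X when X is 0 at flagged positions (I1 * I0 = 0)
  provenance <- matrix(2L, n, ncol(v), dimnames = dimnames(v))
  provenance[I0 == 1] <- 0L
  provenance[I1 == 1] <- 1L
  structure(list(
    Y_imputed = expression_matrix(Y_imputed, cell_ids = x$cell_ids,
                                  gene_ids = x$gene_ids, labels = x$labels,
                                  mito_pct = x$mito_pct),
    Y1 = Y1_final,
    provenance = provenance,
    chosen_t = chosen_t
  ), class = "imputed_matrix")
}
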