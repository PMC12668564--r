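#' Build the binary observed-entry indicator matrix
#'
#' `I0[i, j] = 1` exactly when the transformed expression value is non-zero.
#' This matrix is the reconstruction target of [factorize()].
#'
#' @param x ExpressionMatrix (the transformed single-cell matrix).
#' @return binary matrix, same dimensions and dimnames as `x$values`.
#' @export
build_indicator <- function(x) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  i0 <- (x$values != 0) * 1
  dimnames(i0) <- dimnames(x$values)
  i0
}

#' Pairwise Pearson similarity matrix
#'
#' Correlation of all row pairs (`axis = "rows"`, e.g. cell-cell similarity of
#' a cell x gene matrix) or column pairs (`axis = "columns"`, e.g. gene-gene
#' co-expression of a sample x gene bulk matrix). Constant (zero-variance)
#' vectors have undefined correlation; their off-diagonal entries are set to 0
#' with a warning. The diagonal is 1.
#'
#' @param m numeric matrix with at least 2 vectors along the chosen axis.
#' @param axis `"rows"` or `"columns"`.
#' @return symmetric similarity matrix.
#' @export
pearson_similarity <- function(m, axis = c("rows", "columns")) {
  axis <- match.arg(axis)
  m <- as.matrix(m)
  v <- if (axis == "rows") t(m) else m
  if (ncol(v) < 2) stop("need at least 2 vectors along the chosen axis")
  sds <- apply(v, 2, stats::sd)
  const <- sds == 0
  r <- suppressWarnings(stats::cor(v))
  if (any(const)) {
    warning(sum(const), " zero-variance vectors: correlations set to 0")
    r[const, ] <- 0
    r[, const] <- 0
  }
  r[!is.finite(r)] <- 0
  diag(r) <- 1
  r <- (r + t(r)) / 2  # enforce exact symmetry against fp jitter
  r
}

#' k-nearest-neighbor sparsification of a similarity matrix
#'
#' For each node i, its k nearest neighbors are the k indices `j != i` with
#' the largest similarity (ties broken by lower index). The sparsification
#' weight is 1 for mutual neighbor pairs, 0.5 for one-sided pairs, 0
#' otherwise; the diagonal is 0 (no self-neighbors). The sparsified network is
#' `S * pmax(R, 0)` (negative correlations are clamped so the graph Laplacian
#' stays positive semi-definite), from which the degree matrix and the
#' Laplacian `L = D - R_sparse` are formed.
#'
#' @param R symmetric similarity matrix.
#' @param k neighborhood size, `1 <= k < nrow(R)`.
#' @return list of class `neighbor_graphs` with elements `S`, `R_sparse`,
#'   `D` (degree vector), `L`, `knn` (n x k neighbor index matrix), `k`.
#' @export
knn_sparsify <- function(R, k) {
  R <- as.matrix(R)
  n <- nrow(R)
  stopifnot(nrow(R) == ncol(R))
  if (k < 1 || k >= n) stop("k must satisfy 1 <= k < nrow(R), got k=", k, ", n=", n)
  knn <- matrix(0L, n, k)
  for (i in seq_len(n)) {
    cand <- R[i, ]
    cand[i] <- -Inf
    # largest similarity first, ties by lower index
    ord <- order(-cand, seq_len(n))
    knn[i, ] <- ord[seq_len(k)]
  }
  member <- matrix(FALSE, n, n)
  for (i in seq_len(n)) member[i, knn[i, ]] <- TRUE
  S <- (member + t(member)) / 2  # 1 mutual, 0.5 one-sided, 0 neither
  diag(S) <- 0
  R_sparse <- S * pmax(R, 0)
  D <- rowSums(R_sparse)
  L <- diag(D, n) - R_sparse
  structure(list(S = S, R_sparse = R_sparse, D = D, L = L, knn = knn, k = k),
            class = "neighbor_graphs")
}

#' Dual graph-regularized non-negative factorization of the indicator matrix
#'
#' Minimizes
#' `||I0 - t(U) V||_F^2 + beta (||U||_F^2 + ||V||_F^2)
#'  + lambda_c Tr(U L_c t(U)) + lambda_g Tr(V L_g t(V))`
#' over non-negative `U` (p x n, cell embedding) and `V` (p x m, gene
#' embedding) by multiplicative updates:
#' \preformatted{
#' U <- U * (V I0' + lambda_c U Rc*) / (V V' U + beta U + lambda_c U Dc)
#' V <- V * (U I0  + lambda_g V Rg*) / (U U' V + beta V + lambda_g V Dg)
#' }
#' Every denominator is guarded with a small epsilon. Iteration stops at
#' `max_iter` or when the relative objective change drops below `tol`; the
#' per-iteration objective (and its reconstruction / Tikhonov / graph parts)
#' is recorded. Initialization is Uniform(0,1) scaled by
#' `sqrt(mean(I0) / p)`, seeded, so runs are reproducible.
#'
#' @param I0 binary n x m indicator matrix.
#' @param graphs_c cell-side [knn_sparsify()] output (n x n), or NULL when
#'   `lambda_c = 0`.
#' @param graphs_g gene-side [knn_sparsify()] output (m x m), or NULL when
#'   `lambda_g = 0`.
#' @param p latent dimension (`p << min(n, m)`).
#' @param beta Tikhonov (Frobenius-norm) weight, >= 0.
#' @param lambda_c,lambda_g graph regularization weights, >= 0.
#' @param max_iter iteration cap. Default 500.
#' @param tol relative objective-change convergence tolerance. Default 1e-6.
#' @param seed RNG seed for initialization.
#' @param init optional list(U=, V=) overriding the random initialization.
#' @return list of class `factor_pair`: `U`, `V`, `p`, hyperparameters,
#'   `objective_trace` (data.frame iter/objective/recon/tikhonov/graph),
#'   `iterations`, `converged`.
#' @export
factorize <- function(I0, graphs_c = NULL, graphs_g = NULL, p = 10,
                      beta = 0.01, lambda_c = 0.01, lambda_g = 0.01,
                      max_iter = 500, tol = 1e-6, seed = 1L, init = NULL) {
  I0 <- as.matrix(I0)
  n <- nrow(I0); m <- ncol(I0)
  if (beta < 0 || lambda_c < 0 || lambda_g < 0) stop("hyperparameters must be >= 0")
  stopifnot(p >= 1)
  eps <- 1e-10
  if (lambda_c > 0 && is.null(graphs_c)) stop("lambda_c > 0 requires graphs_c")
  if (lambda_g > 0 && is.null(graphs_g)) stop("lambda_g > 0 requires graphs_g")
  Rc <- if (!is.null(graphs_c)) graphs_c$R_sparse else matrix(0, n, n)
  Dc <- if (!is.null(graphs_c)) graphs_c$D else numeric(n)
  Rg <- if (!is.null(graphs_g)) graphs_g$R_sparse else matrix(0, m, m)
  Dg <- if (!is.null(graphs_g)) graphs_g$D else numeric(m)
  if (!is.null(graphs_c)) stopifnot(nrow(Rc) == n)
  if (!is.null(graphs_g)) stopifnot(nrow(Rg) == m)

  if (is.null(init)) {
    old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
    set.seed(seed)
    scale0 <- sqrt(max(mean(I0), eps) / p)
    U <- matrix(stats::runif(p * n), p, n) * scale0
    V <- matrix(stats::runif(p * m), p, m) * scale0
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  } else {
    U <- as.matrix(init$U); V <- as.matrix(init$V)
    stopifnot(dim(U) == c(p, n), dim(V) == c(p, m), all(U >= 0), all(V >= 0))
  }

  objective_parts <- function(U, V) {
    recon <- sum((I0 - crossprod(U, V))^2)
    tik <- beta * (sum(U^2) + sum(V^2))
    graph <- 0
    if (lambda_c > 0) graph <- graph + lambda_c * (sum(t(U^2) * Dc) - sum((U %*% Rc) * U))
    if (lambda_g > 0) graph <- graph + lambda_g * (sum(t(V^2) * Dg) - sum((V %*% Rg) * V))
    c(recon = recon, tikhonov = tik, graph = graph)
  }

  parts <- objective_parts(U, V)
  trace <- matrix(NA_real_, max_iter + 1, 4,
                  dimnames = list(NULL, c("objective", "recon", "tikhonov", "graph")))
  trace[1, ] <- c(sum(parts), parts)
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    num_u <- V %*% t(I0)
    den_u <- (V %*% t(V)) %*% U + beta * U
    if (lambda_c > 0) {
      num_u <- num_u + lambda_c * (U %*% Rc)
      den_u <- den_u + lambda_c * sweep(U, 2, Dc, `*`)
    }
    U <- U * num_u / (den_u + eps)

    num_v <- U %*% I0
    den_v <- (U %*% t(U)) %*% V + beta * V
    if (lambda_g > 0) {
      num_v <- num_v + lambda_g * (V %*% Rg)
      den_v <- den_v + lambda_g * sweep(V, 2, Dg, `*`)
    }
    V <- V * num_v / (den_v + eps)

    parts <- objective_parts(U, V)
    obj <- sum(parts)
    if (!is.finite(obj)) stop("non-finite objective at iteration ", it)
    trace[it + 1, ] <- c(obj, parts)
    prev <- trace[it, "objective"]
    if (prev > 0 && abs(prev - obj) / prev < tol) { converged <- TRUE; break }
  }
  trace <- trace[seq_len(it + 1), , drop = FALSE]
  structure(list(U = U, V = V, p = p, beta = beta,
                 lambda_c = lambda_c, lambda_g = lambda_g,
                 objective_trace = data.frame(iter = seq_len(nrow(trace)) - 1L, trace),
                 iterations = it, converged = converged),
            class = "factor_pair")
}

#' Reconstruct the indicator matrix from the factor pair
#'
#' `I* = t(U) V`, an n x m non-negative matrix whose entries estimate the
#' propensity of each position to be an observed (expressed) value.
#'
#' @param fp [factorize()] output.
#' @return non-negative n x m matrix.
#' @export
reconstruct <- function(fp) {
  stopifnot(inherits(fp, "factor_pair"))
  crossprod(fp$U, fp$V)
}

#' Classify zeros as biological or non-biological
#'
#' The imputation index matrix: `I1[i, j] = 1` exactly when the position is a
#' zero in the data (`I0[i, j] = 0`) and its reconstruction exceeds the
#' threshold (`I_star[i, j] > tau`). Observed entries are never flagged.
#'
#' The regularized reconstruction has no anchored scale (Tikhonov and graph
#' penalties shrink it below the 0/1 range of the target), so the default
#' threshold is adaptive: half the mean reconstruction over observed
#' (`I0 = 1`) positions, i.e. a zero is called non-biological when the model
#' reconstructs it at least half as strongly as a typical observed entry.
#' Pass a numeric `tau` for a fixed absolute threshold instead.
#'
#' @param I0 binary indicator matrix.
#' @param I_star reconstruction from [reconstruct()], same shape.
#' @param tau non-negative threshold on the reconstruction scale, or NULL
#'   (default) for the adaptive threshold described above.
#' @return binary matrix `I1` with attribute `tau` (the threshold used) and
#'   attribute `zero_type_counts` (the four-way cross-tabulation of `I0` by
#'   `I_star > tau`: n00, n01, n10, n11).
#' @export
call_dropouts <- function(I0, I_star, tau = NULL) {
  I0 <- as.matrix(I0); I_star <- as.matrix(I_star)
  stopifnot(dim(I0) == dim(I_star))
  if (is.null(tau)) {
    if (!any(I0 == 1)) stop("adaptive threshold needs at least one observed entry")
    tau <- mean(I_star[I0 == 1]) * 0.5
  }
  if (tau < 0) stop("tau must be >= 0")
  pred <- (I_star > tau) * 1
  I1 <- (I0 == 0) * pred
  dimnames(I1) <- dimnames(I0)
  counts <- c(n00 = sum(I0 == 0 & pred == 0), n01 = sum(I0 == 0 & pred == 1),
              n10 = sum(I0 == 1 & pred == 0), n11 = sum(I0 == 1 & pred == 1))
  attr(I1, "tau") <- tau
  attr(I1, "zero_type_counts") <- counts
  I1
}
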