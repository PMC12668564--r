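#' The candidate transformation library
#'
#' Seven candidate transformations evaluated by [select_transformation()]:
#' `value-to-rank`, `unit-vector`, `log-normalization`, `log2`, `log10`,
#' `loge`, `box-cox`.
#'
#' @return character vector of the seven method names.
#' @export
transform_library <- function() {
  c("value-to-rank", "unit-vector", "log-normalization",
    "log2", "log10", "loge", "box-cox")
}

#' Specify a transformation
#'
#' @param method one of [transform_library()].
#' @param pseudocount pseudocount added before log-family and Box-Cox
#'   transforms. Default 1.
#' @param scale_factor per-cell library-size target for `log-normalization`.
#'   Default 10000.
#' @return list of class `transform_spec`.
#' @export
transform_spec <- function(method, pseudocount = 1, scale_factor = 1e4) {
  method <- match.arg(method, transform_library())
  structure(list(method = method, pseudocount = pseudocount,
                 scale_factor = scale_factor),
            class = "transform_spec")
}

# Profile log-likelihood Box-Cox lambda for a positive sample.
boxcox_lambda <- function(x, interval = c(-2, 2)) {
  n <- length(x)
  lx <- log(x)
  slx <- sum(lx)
  ll <- function(lambda) {
    z <- if (abs(lambda) < 1e-8) lx else (x^lambda - 1) / lambda
    s2 <- stats::var(z) * (n - 1) / n
    if (!is.finite(s2) || s2 <= 0) return(-Inf)
    -n / 2 * log(s2) + (lambda - 1) * slx
  }
  stats::optimize(ll, interval = interval, maximum = TRUE)$maximum
}

#' Apply a transformation to an expression matrix
#'
#' Transformation definitions:
#' \describe{
#'   \item{value-to-rank}{per-gene average ranks of the non-zero entries
#'     (ties.method "average"); zeros stay 0, preserving sparsity.}
#'   \item{unit-vector}{per-cell L2 normalization; all-zero cells stay zero.}
#'   \item{log-normalization}{per-cell scaling to `scale_factor` total counts,
#'     then natural log1p; all-zero cells stay zero.}
#'   \item{log2 / log10 / loge}{`log_base(x + pseudocount)`.}
#'   \item{box-cox}{per-gene Box-Cox of `x + pseudocount` with
#'     maximum-likelihood lambda (profile likelihood, lambda in \[-2, 2\]);
#'     constant genes pass through unchanged with a warning.}
#' }
#' The output never contains non-finite values, and the log-family and rank
#' transforms map 0 to 0.
#'
#' @param x ExpressionMatrix (non-negative).
#' @param spec a [transform_spec()] or a method name.
#' @return Transformed ExpressionMatrix; for `box-cox` the fitted per-gene
#'   lambdas are attached as attribute `boxcox_lambda`.
#' @export
apply_transform <- function(x, spec) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (is.character(spec)) spec <- transform_spec(spec)
  stopifnot(inherits(spec, "transform_spec"))
  v <- x$values
  pc <- spec$pseudocount
  out <- switch(
    spec$method,
    "value-to-rank" = {
      apply(v, 2, function(col) {
        nz <- col != 0
        r <- numeric(length(col))
        if (any(nz)) r[nz] <- rank(col[nz], ties.method = "average")
        r
      })
    },
    "unit-vector" = {
      nrm <- sqrt(rowSums(v^2))
      nrm[nrm == 0] <- 1
      v / nrm
    },
    "log-normalization" = {
      tot <- rowSums(v)
      tot[tot == 0] <- 1
      log1p(v / tot * spec$scale_factor)
    },
    "log2"  = log2(v + pc),
    "log10" = log10(v + pc),
    "loge"  = log(v + pc),
    "box-cox" = {
      lambdas <- rep(NA_real_, ncol(v))
      w <- v
      const <- 0L
      for (j in seq_len(ncol(v))) {
        col <- v[, j] + pc
        if (stats::var(col) == 0) { const <- const + 1L; next }
        lam <- boxcox_lambda(col)
        lambdas[j] <- lam
        w[, j] <- if (abs(lam) < 1e-8) log(col) else (col^lam - 1) / lam
      }
      if (const > 0) warning(const, " constant genes passed through Box-Cox unchanged")
      attr(w, "boxcox_lambda") <- lambdas
      w
    }
  )
  lam <- attr(out, "boxcox_lambda")
  dimnames(out) <- dimnames(v)
  stopifnot(all(is.finite(out)))
  # every candidate maps [0, Inf) into [0, Inf): monotone through the origin
  res <- expression_matrix(out, cell_ids = x$cell_ids, gene_ids = x$gene_ids,
                           labels = x$labels, mito_pct = x$mito_pct)
  if (!is.null(lam)) attr(res, "boxcox_lambda") <- lam
  res
}

#' Select the transformation maximizing cluster separation
#'
#' Applies each candidate transformation and scores the transformed matrix by
#' the silhouette coefficient ([silhouette_coef()]) under the supplied per-cell
#' labels; returns the argmax candidate (ties broken by candidate order) and
#' the full score table. When no labels are given, a deterministic fallback
#' labels cells by k-means on the top principal components
#' ([cluster_cells()]).
#'
#' @param x ExpressionMatrix (QC'd counts).
#' @param candidates character vector of method names or list of
#'   [transform_spec()]s. Default: the full seven-method library.
#' @param labels per-cell categories; default `x$labels`.
#' @param k number of clusters for the k-means fallback when labels are absent.
#' @param seed seed for the fallback clustering.
#' @return list with `spec` (winning transform_spec), `method`, `scores`
#'   (data.frame method/sc), and `labels` used.
#' @export
select_transformation <- function(x, candidates = transform_library(),
                                  labels = NULL, k = NULL, seed = 1L) {
  stopifnot(inherits(x, "ExpressionMatrix"), length(candidates) >= 1)
  specs <- lapply(candidates, function(s) if (is.character(s)) transform_spec(s) else s)
  if (is.null(labels)) labels <- x$labels
  if (is.null(labels)) {
    if (is.null(k)) stop("no labels available: supply labels= or k= for the clustering fallback")
    labels <- cluster_cells(log1p(x$values), k = k, seed = seed)
  }
  labels <- as.character(labels)
  sc <- vapply(specs, function(sp) {
    xt <- apply_transform(x, sp)
    if (length(unique(labels)) < 2) {
      warning("single label: silhouette undefined, candidate '", sp$method,
              "' scored -1")
      return(-1)
    }
    silhouette_coef(xt$values, labels)
  }, numeric(1))
  best <- which.max(sc)  # first maximum: ties broken by candidate order
  list(spec = specs[[best]],
       method = specs[[best]]$method,
       scores = data.frame(method = vapply(specs, `[[`, "", "method"), sc = sc),
       labels = labels)
}

#' Deterministic k-means cell labels on top principal components
#'
#' Fallback labelling used when no annotation is available: PCA of the
#' (centered) matrix to at most `n_pcs` components, then seeded k-means with
#' multiple restarts.
#'
#' @param values numeric matrix, rows = cells.
#' @param k number of clusters.
#' @param n_pcs number of principal components (default 50, capped by the
#'   matrix rank).
#' @param seed RNG seed.
#' @param nstart k-means restarts. Default 10.
#' @return character vector of cluster labels.
#' @export
cluster_cells <- function(values, k, n_pcs = 50, seed = 1L, nstart = 10) {
  stopifnot(k >= 2, k <= nrow(values))
  n_pcs <- min(n_pcs, nrow(values) - 1L, ncol(values))
  pcs <- stats::prcomp(values, center = TRUE, scale. = FALSE, rank. = n_pcs)$x
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  km <- stats::kmeans(pcs, centers = k, nstart = nstart, iter.max = 100)
  as.character(km$cluster)
}
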