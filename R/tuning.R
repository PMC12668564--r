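#' Hyperparameter search specification
#'
#' Grids for the three-stage search of [grid_search()]. The full printed
#' ranges are beta/lambda 0.0001 to 0.1 in steps of 0.0005, k from
#' `ceiling(log2(n))` to `n - 1` in steps of 2, and p from 10 to 100 in steps
#' of 5; because the joint beta x lambda stage is quadratic in grid length,
#' the default is a logarithmic coarsening of those ranges (`full = TRUE`
#' restores them).
#'
#' @param n_cells number of cells (bounds the k grid).
#' @param beta_grid,lambda_grid,k_grid,p_grid explicit grids overriding the
#'   defaults.
#' @param full use the full printed grids instead of the coarse defaults.
#' @param n_restarts seeded factorization/clustering restarts per grid point.
#'   Default 2.
#' @param seed base RNG seed.
#' @return list of class `search_spec`.
#' @export
search_spec <- function(n_cells, beta_grid = NULL, lambda_grid = NULL,
                        k_grid = NULL, p_grid = NULL, full = FALSE,
                        n_restarts = 2, seed = 1L) {
  stopifnot(n_cells >= 3, n_restarts >= 1)
  if (is.null(beta_grid)) {
    beta_grid <- if (full) seq(0.0001, 0.1, by = 0.0005) else c(0.0001, 0.001, 0.01, 0.1)
  }
  if (is.null(lambda_grid)) lambda_grid <- beta_grid
  if (is.null(k_grid)) {
    lo <- max(2L, ceiling(log2(n_cells)))
    hi <- n_cells - 1L
    k_grid <- if (full) seq(lo, hi, by = 2) else {
      unique(pmin(hi, pmax(lo, round(exp(seq(log(lo), log(hi), length.out = 5))))))
    }
  }
  if (is.null(p_grid)) {
    p_grid <- if (full) seq(10, 100, by = 5) else c(10, 25, 50, 100)
  }
  if (length(beta_grid) == 0 || length(lambda_grid) == 0 ||
      length(k_grid) == 0 || length(p_grid) == 0) stop("empty grid")
  structure(list(beta_grid = beta_grid, lambda_grid = lambda_grid,
                 k_grid = k_grid, p_grid = p_grid,
                 n_restarts = n_restarts, seed = seed),
            class = "search_spec")
}

#' Three-stage hyperparameter grid search
#'
#' Stage I jointly searches beta and lambda (with `lambda_c = lambda_g =
#' lambda`) at the middle k of the k grid and the first p of the p grid;
#' Stage II searches k with (beta, lambda) fixed; Stage III searches p with
#' all three fixed. Each grid point runs the full discriminate-impute-cluster
#' cycle over `n_restarts` seeded restarts and is scored by mean ARI against
#' the supplied labels, with mean silhouette (on the imputed matrix under the
#' predicted clustering) breaking ties. Later stages never alter
#' earlier-stage selections; a failed evaluation is scored -Inf and noted in
#' the table.
#'
#' @param x transformed ExpressionMatrix (cells x genes).
#' @param labels per-cell ground-truth labels for ARI.
#' @param spec [search_spec()].
#' @param bulk optional transformed bulk ExpressionMatrix for the gene graph;
#'   default: per-label pseudo-bulk of `x`.
#' @param tau dropout-call threshold passed to [call_dropouts()] (NULL =
#'   adaptive).
#' @param max_iter,tol factorization controls (defaults reduced for search
#'   loops).
#' @param t_grid,passes imputation controls.
#' @return list: `best` (beta, lambda, k, p), `table` (one row per evaluated
#'   grid point with stage, parameters, ari_mean, ari_sd, sc_mean).
#' @export
grid_search <- function(x, labels, spec, bulk = NULL, tau = NULL,
                        max_iter = 100, tol = 1e-5,
                        t_grid = seq(0, 1, by = 0.1), passes = 1) {
  stopifnot(inherits(x, "ExpressionMatrix"), inherits(spec, "search_spec"))
  labels <- as.character(labels)
  stopifnot(length(labels) == nrow(x$values))
  K <- length(unique(labels))
  if (K < 2) stop("grid_search needs at least 2 label classes for ARI")
  n <- nrow(x$values)
  gene_source <- if (!is.null(bulk)) bulk$values else {
    make_pseudobulk(x, mode = "mean", labels = labels)$values
  }
  if (nrow(gene_source) < 2) stop("gene-graph source needs >= 2 rows")
  Rc <- pearson_similarity(x$values, axis = "rows")
  Rg <- pearson_similarity(gene_source, axis = "columns")
  I0 <- build_indicator(x)
  graph_cache <- new.env(parent = emptyenv())
  get_graphs <- function(k) {
    key <- as.character(k)
    if (is.null(graph_cache[[key]])) {
      graph_cache[[key]] <- list(
        c = knn_sparsify(Rc, k = min(k, n - 1L)),
        g = knn_sparsify(Rg, k = min(k, ncol(x$values) - 1L))
      )
    }
    graph_cache[[key]]
  }
  eval_point <- function(beta, lambda, k, p) {
    aris <- numeric(spec$n_restarts); scs <- numeric(spec$n_restarts)
    for (r in seq_len(spec$n_restarts)) {
      run_seed <- spec$seed + 1000L * r
      g <- get_graphs(k)
      fp <- factorize(I0, g$c, g$g, p = p, beta = beta,
                      lambda_c = lambda, lambda_g = lambda,
                      max_iter = max_iter, tol = tol, seed = run_seed)
      I1 <- call_dropouts(I0, reconstruct(fp), tau = tau)
      imp <- impute_all(x, I1, k = min(k, n - 1L), t_grid = t_grid, passes = passes)
      pred <- cluster_cells(imp$Y_imputed$values, k = K, seed = run_seed)
      aris[r] <- ari(labels, pred)
      scs[r] <- if (length(unique(pred)) >= 2) {
        silhouette_coef(imp$Y_imputed$values, pred)
      } else 0
    }
    c(ari_mean = mean(aris), ari_sd = stats::sd(aris), sc_mean = mean(scs))
  }
  rows <- list()
  score_stage <- function(stage, grid_df) {
    res <- matrix(NA_real_, nrow(grid_df), 3,
                  dimnames = list(NULL, c("ari_mean", "ari_sd", "sc_mean")))
    for (i in seq_len(nrow(grid_df))) {
      g <- grid_df[i, ]
      res[i, ] <- tryCatch(
        eval_point(g$beta, g$lambda, g$k, g$p),
        error = function(e) {
          warning("grid point failed (", conditionMessage(e), "); scored -Inf")
          c(ari_mean = -Inf, ari_sd = NA_real_, sc_mean = -Inf)
        })
    }
    out <- cbind(stage = stage, grid_df, as.data.frame(res))
    rows[[length(rows) + 1]] <<- out
    # argmax ARI, SC tiebreak, then input order
    best <- order(-res[, "ari_mean"], -res[, "sc_mean"], seq_len(nrow(res)))[1]
    grid_df[best, ]
  }
  k0 <- spec$k_grid[ceiling(length(spec$k_grid) / 2)]
  p0 <- spec$p_grid[1]
  stage1 <- expand.grid(beta = spec$beta_grid, lambda = spec$lambda_grid,
                        k = k0, p = p0)
  pick1 <- score_stage("I", stage1)
  stage2 <- data.frame(beta = pick1$beta, lambda = pick1$lambda,
                       k = spec$k_grid, p = p0)
  pick2 <- score_stage("II", stage2)
  stage3 <- data.frame(beta = pick1$beta, lambda = pick1$lambda,
                       k = pick2$k, p = spec$p_grid)
  pick3 <- score_stage("III", stage3)
  list(best = list(beta = pick1$beta, lambda = pick1$lambda,
                   k = pick2$k, p = pick3$p),
       table = do.call(rbind, rows))
}
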