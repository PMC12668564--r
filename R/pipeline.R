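#' Default pipeline configuration
#'
#' Nested configuration for [run_pipeline()]. Sections and keys:
#' \describe{
#'   \item{io}{`sc`, `bulk` (paths or ExpressionMatrix objects; bulk optional),
#'     `outdir` (optional output directory).}
#'   \item{qc}{`min_genes`, `max_features`, `max_mito_pct`,
#'     `min_cells_per_gene`, `n_hvgs`.}
#'   \item{transform}{`candidates` (method names), `labels_source`
#'     (`"annotations"` or `"kmeans"`), `k` (cluster count for the k-means
#'     fallback).}
#'   \item{disc}{`p`, `beta`, `lambda_c`, `lambda_g`, `k_cells`, `k_genes`
#'     (NULL = same as `k_cells`), `tau` (NULL = adaptive threshold of
#'     [call_dropouts()]), `max_iter`, `tol`, `pseudobulk_mode`.}
#'   \item{impute}{`k` (NULL = `disc$k_cells`), `t_grid`, `passes`.}
#'   \item{evaluate}{`enabled` (cluster the matrix before/after imputation and
#'     report ARI/NMI/SC when labels exist).}
#' }
#' plus top-level `seed` and `verbose`. Unknown keys are rejected by
#' [run_pipeline()].
#'
#' @param ... replacement values, e.g. `disc = list(p = 5)`; unnamed sections
#'   merge over the defaults.
#' @return nested configuration list.
#' @export
default_config <- function(...) {
  cfg <- list(
    io = list(sc = NULL, bulk = NULL, outdir = NULL),
    qc = list(min_genes = 200, max_features = Inf, max_mito_pct = Inf,
              min_cells_per_gene = 3, n_hvgs = 2000),
    transform = list(candidates = transform_library(),
                     labels_source = "annotations", k = NULL),
    disc = list(p = 10, beta = 0.01, lambda_c = 0.01, lambda_g = 0.01,
                k_cells = 21, k_genes = NULL, tau = NULL,
                max_iter = 500, tol = 1e-6, pseudobulk_mode = "mean"),
    impute = list(k = NULL, t_grid = seq(0, 1, by = 0.1), passes = 1),
    evaluate = list(enabled = TRUE),
    seed = 1L,
    verbose = TRUE
  )
  mods <- list(...)
  for (nm in names(mods)) {
    if (!nm %in% names(cfg)) stop("unknown config section: ", nm)
    if (is.list(cfg[[nm]]) && is.list(mods[[nm]])) {
      bad <- setdiff(names(mods[[nm]]), names(cfg[[nm]]))
      if (length(bad)) stop("unknown config keys in '", nm, "': ",
                            paste(bad, collapse = ", "))
      cfg[[nm]][names(mods[[nm]])] <- mods[[nm]]
    } else {
      cfg[[nm]] <- mods[[nm]]
    }
  }
  cfg
}

pipeline_log <- function(lines, msg, verbose) {
  stamp <- format(Sys.time(), "%H:%M:%S")
  line <- paste0("[", stamp, "] ", msg)
  if (verbose) message(line)
  c(lines, line)
}

#' Run the full imputation pipeline
#'
#' Executes quality control, transformation selection, the dropout
#' discriminator, and density-guided imputation, with optional clustering
#' evaluation, in one deterministic run:
#' \enumerate{
#'   \item cell QC, gene QC, HVG selection ([filter_cells()],
#'     [filter_genes()], [select_hvgs()]); gene-space intersection with bulk
#'     when a bulk matrix is supplied;
#'   \item transformation selection by silhouette
#'     ([select_transformation()]); the winning transform is applied to the
#'     single-cell matrix and (with per-gene parameters re-estimated) to the
#'     bulk/pseudo-bulk reference;
#'   \item indicator-matrix factorization over the sparsified cell and gene
#'     networks ([factorize()]) and dropout calling ([call_dropouts()]);
#'   \item imputation of flagged positions ([impute_all()]).
#' }
#' With `io$outdir` set, all artifacts (imputed matrix, indicator matrices,
#' provenance, silhouette table, objective trace, metrics, resolved config,
#' log) are written as plain-text files.
#'
#' @param config nested list from [default_config()]; `config$io$sc` must hold
#'   an ExpressionMatrix or a readable path.
#' @return list: `x_qc`, `transform` (selection result), `x_transformed`,
#'   `I0`, `I_star`, `I1`, `factor_pair`, `imputed` (the [impute_all()]
#'   result), `metrics` (data.frame or NULL), `config`, `log`.
#' @export
run_pipeline <- function(config = default_config()) {
  lg <- character(0)
  vb <- isTRUE(config$verbose)
  stage <- "load"
  result <- tryCatch({
    sc <- config$io$sc
    if (is.character(sc)) sc <- read_matrix(sc)
    if (!inherits(sc, "ExpressionMatrix")) stop("config$io$sc must be a path or ExpressionMatrix")
    bulk <- config$io$bulk
    if (is.character(bulk)) bulk <- read_matrix(bulk)
    lg <- pipeline_log(lg, sprintf("loaded %d cells x %d genes", nrow(sc$values), ncol(sc$values)), vb)

    stage <- "qc"
    qc <- qc_params(min_genes_per_cell = config$qc$min_genes,
                    max_features_per_cell = config$qc$max_features,
                    max_mito_pct = config$qc$max_mito_pct,
                    min_cells_per_gene = config$qc$min_cells_per_gene,
                    n_hvgs = config$qc$n_hvgs)
    x <- filter_cells(sc, qc)
    x <- filter_genes(x, qc)
    x <- suppressMessages(select_hvgs(x, n_hvgs = qc$n_hvgs))
    if (!is.null(bulk)) {
      both <- intersect_with_bulk(x, bulk)
      x <- both$sc; bulk <- both$bulk
      lg <- pipeline_log(lg, sprintf("gene intersection with bulk: %d genes", both$n_common), vb)
    }
    lg <- pipeline_log(lg, sprintf("after QC: %d cells x %d genes", nrow(x$values), ncol(x$values)), vb)

    stage <- "transform"
    labels <- x$labels
    if (identical(config$transform$labels_source, "kmeans") || is.null(labels)) {
      if (is.null(config$transform$k)) {
        if (is.null(labels)) stop("no labels and no transform$k for the k-means fallback")
      } else {
        labels <- cluster_cells(log1p(x$values), k = config$transform$k,
                                seed = config$seed)
      }
    }
    sel <- select_transformation(x, candidates = config$transform$candidates,
                                 labels = labels, seed = config$seed)
    xt <- apply_transform(x, sel$spec)
    lg <- pipeline_log(lg, paste0("selected transformation: ", sel$method), vb)

    stage <- "discriminate"
    n <- nrow(xt$values); m <- ncol(xt$values)
    k_cells <- min(config$disc$k_cells, n - 1L)
    k_genes <- min(if (is.null(config$disc$k_genes)) config$disc$k_cells else config$disc$k_genes,
                   m - 1L)
    I0 <- build_indicator(xt)
    Rc <- pearson_similarity(xt$values, axis = "rows")
    if (!is.null(bulk)) {
      bulk_t <- apply_transform(bulk, sel$spec)
      gene_src <- bulk_t$values
    } else {
      pb <- make_pseudobulk(x, mode = config$disc$pseudobulk_mode, labels = labels)
      if (nrow(pb$values) < 2) stop("pseudo-bulk fallback needs >= 2 groups; supply labels, transform$k, or a bulk matrix")
      gene_src <- apply_transform(pb, sel$spec)$values
      lg <- pipeline_log(lg, sprintf("gene network from %d-sample pseudo-bulk", nrow(pb$values)), vb)
    }
    Rg <- suppressWarnings(pearson_similarity(gene_src, axis = "columns"))
    gc_ <- knn_sparsify(Rc, k = k_cells)
    gg_ <- knn_sparsify(Rg, k = k_genes)
    fp <- factorize(I0, gc_, gg_, p = config$disc$p, beta = config$disc$beta,
                    lambda_c = config$disc$lambda_c, lambda_g = config$disc$lambda_g,
                    max_iter = config$disc$max_iter, tol = config$disc$tol,
                    seed = config$seed)
    I_star <- reconstruct(fp)
    I1 <- call_dropouts(I0, I_star, tau = config$disc$tau)
    lg <- pipeline_log(lg, sprintf("factorization: %d iterations, %d positions flagged",
                                   fp$iterations, sum(I1)), vb)

    stage <- "impute"
    k_imp <- min(if (is.null(config$impute$k)) k_cells else config$impute$k, n - 1L)
    imp <- impute_all(xt, I1, k = k_imp, t_grid = config$impute$t_grid,
                      passes = config$impute$passes)
    lg <- pipeline_log(lg, "imputation complete", vb)

    stage <- "evaluate"
    metrics <- NULL
    if (isTRUE(config$evaluate$enabled) && !is.null(labels) &&
        length(unique(labels)) >= 2) {
      K <- length(unique(labels))
      pred_before <- cluster_cells(xt$values, k = K, seed = config$seed)
      pred_after <- cluster_cells(imp$Y_imputed$values, k = K, seed = config$seed)
      metrics <- data.frame(
        metric = c("ari_before", "ari_after", "nmi_before", "nmi_after",
                   "sc_before", "sc_after"),
        value = c(ari(labels, pred_before), ari(labels, pred_after),
                  nmi(labels, pred_before), nmi(labels, pred_after),
                  silhouette_coef(xt$values, labels),
                  silhouette_coef(imp$Y_imputed$values, labels)))
      lg <- pipeline_log(lg, sprintf("ARI before/after imputation: %.4f / %.4f",
                                     metrics$value[1], metrics$value[2]), vb)
    }

    list(x_qc = x, transform = sel, x_transformed = xt, I0 = I0,
         I_star = I_star, I1 = I1, factor_pair = fp, imputed = imp,
         metrics = metrics, config = config, log = lg)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })

  outdir <- config$io$outdir
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_matrix(result$imputed$Y_imputed, file.path(outdir, "Y_imputed.mtx"))
    write_matrix(expression_matrix(result$I0), file.path(outdir, "I0.mtx"))
    write_matrix(expression_matrix(result$I1), file.path(outdir, "I1.mtx"))
    write_matrix(expression_matrix(result$imputed$provenance * 1),
                 file.path(outdir, "provenance.mtx"))
    utils::write.table(result$transform$scores, file.path(outdir, "sc_table.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(result$factor_pair$objective_trace,
                       file.path(outdir, "objective_trace.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(result$metrics)) {
      utils::write.table(result$metrics, file.path(outdir, "metrics.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    cfg_out <- config
    cfg_out$io$sc <- if (is.character(config$io$sc)) config$io$sc else "<in-memory>"
    cfg_out$io$bulk <- if (is.character(config$io$bulk)) config$io$bulk
                       else if (is.null(config$io$bulk)) NULL else "<in-memory>"
    jsonlite::write_json(cfg_out, file.path(outdir, "config.json"),
                         auto_unbox = TRUE, null = "null", digits = NA)
    writeLines(result$log, file.path(outdir, "run.log"))
  }
  result
}
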