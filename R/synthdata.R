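#' Simulation parameters for group-structured counts
#'
#' Parameters of the splat-style negative-binomial generator in
#' [simulate_counts()]. Defaults reproduce the scale of the package's
#' reference masking scenario: 500 cells x 2000 genes in 3 groups with a
#' baseline zero rate in the mid-20s percent.
#'
#' @param n_cells,n_genes,n_groups matrix size and number of cell groups.
#' @param de_prob fraction of genes differential in each group. Default 0.1.
#' @param de_facLoc location (log scale) of the differential-expression factor
#'   distribution. Default 1 (about e-fold shifts).
#' @param base_mean mean of the gamma-distributed gene means. Default 10.
#' @param mean_shape gamma shape of the gene-mean distribution (small values =
#'   heavy tail). Default 0.5.
#' @param dispersion negative-binomial dispersion (NB size = 1/dispersion).
#'   Default 0.4.
#' @param lib_sd standard deviation of log-normal per-cell library-size
#'   factors. Default 0.2.
#' @param seed RNG seed.
#' @return list of class `sim_params`.
#' @export
sim_params <- function(n_cells = 500, n_genes = 2000, n_groups = 3,
                       de_prob = 0.1, de_facLoc = 1, base_mean = 10,
                       mean_shape = 0.5, dispersion = 0.4, lib_sd = 0.2,
                       seed = 1L) {
  stopifnot(n_cells >= 1, n_genes >= 1, n_groups >= 1,
            de_prob >= 0, de_prob <= 1, dispersion > 0,
            base_mean > 0, mean_shape > 0, lib_sd >= 0)
  structure(list(n_cells = n_cells, n_genes = n_genes, n_groups = n_groups,
                 de_prob = de_prob, de_facLoc = de_facLoc,
                 base_mean = base_mean, mean_shape = mean_shape,
                 dispersion = dispersion, lib_sd = lib_sd, seed = seed),
            class = "sim_params")
}

#' Simulate group-structured single-cell counts
#'
#' A splat-style generative model: gene means are gamma distributed (heavy
#' right tail); each group receives multiplicative differential-expression
#' factors (log-normal, randomly inverted) on a `de_prob` fraction of genes;
#' per-cell library-size factors are log-normal; counts are drawn
#' negative-binomial with the stated dispersion. Fully reproducible given the
#' seed.
#'
#' @param sp [sim_params()].
#' @return list with `counts` (ExpressionMatrix with group labels attached),
#'   `group_labels`, `zero_rate` (realized baseline zero fraction),
#'   `de_genes` (per-group logical matrix of differential genes).
#' @export
simulate_counts <- function(sp = sim_params()) {
  stopifnot(inherits(sp, "sim_params"))
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(sp$seed)
  n <- sp$n_cells; m <- sp$n_genes; G <- sp$n_groups
  gene_mean <- stats::rgamma(m, shape = sp$mean_shape,
                             rate = sp$mean_shape / sp$base_mean)
  de <- matrix(FALSE, G, m)
  fac <- matrix(1, G, m)
  if (G > 1 && sp$de_prob > 0) {
    for (g in seq_len(G)) {
      de[g, ] <- stats::runif(m) < sp$de_prob
      nde <- sum(de[g, ])
      if (nde > 0) {
        f <- exp(stats::rnorm(nde, mean = sp$de_facLoc, sd = 0.4))
        flip <- stats::runif(nde) < 0.5
        f[flip] <- 1 / f[flip]
        fac[g, de[g, ]] <- f
      }
    }
  }
  groups <- sort(rep_len(seq_len(G), n))
  lib <- exp(stats::rnorm(n, 0, sp$lib_sd))
  counts <- matrix(0, n, m)
  size <- 1 / sp$dispersion
  for (i in seq_len(n)) {
    mu <- lib[i] * gene_mean * fac[groups[i], ]
    counts[i, ] <- stats::rnbinom(m, size = size, mu = mu)
  }
  if (all(counts == 0)) stop("simulation produced an all-zero matrix; increase base_mean")
  labels <- paste0("group", groups)
  x <- expression_matrix(counts, labels = labels)
  list(counts = x, group_labels = labels,
       zero_rate = mean(counts == 0), de_genes = de)
}

#' Mask non-zero entries at a stated rate
#'
#' Samples `floor(rate * nnz)` of the non-zero positions uniformly without
#' replacement and sets them to zero, emulating dropout with known ground
#' truth. Zero entries of the truth are never touched; unmasked entries are
#' bit-identical between truth and masked matrix.
#'
#' @param x ExpressionMatrix of true counts.
#' @param rate fraction of non-zero entries to mask, in (0, 1).
#' @param seed RNG seed for the position sample.
#' @return list of class `masked_simulation`: `truth`, `masked`
#'   (ExpressionMatrices), `mask_positions` (two-column matrix of 1-based
#'   cell/gene indices), `requested_rate`, `realized_zero_rate` (overall zero
#'   fraction of the masked matrix).
#' @export
apply_dropout_mask <- function(x, rate, seed = 1L) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (rate <= 0 || rate >= 1) stop("rate must lie strictly between 0 and 1")
  nz <- which(x$values != 0)
  if (length(nz) == 0) stop("matrix has no non-zero entries to mask")
  n_mask <- floor(rate * length(nz))
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  picked <- if (n_mask > 0) sort(sample(nz, n_mask)) else integer(0)
  masked <- x$values
  masked[picked] <- 0
  pos <- cbind(cell = ((picked - 1) %% nrow(masked)) + 1,
               gene = ((picked - 1) %/% nrow(masked)) + 1)
  structure(list(
    truth = x,
    masked = expression_matrix(masked, cell_ids = x$cell_ids,
                               gene_ids = x$gene_ids, labels = x$labels,
                               mito_pct = x$mito_pct),
    mask_positions = pos,
    mask_linear = picked,
    requested_rate = rate,
    realized_zero_rate = mean(masked == 0)
  ), class = "masked_simulation")
}

#' Score an imputation run against masked ground truth
#'
#' Computes, at the masked positions: PCC and RMSE between the imputed matrix
#' and the truth (pass `truth` on the same scale as the imputed matrix, e.g.
#' the transformed true counts); the recall of masked positions within `I1`
#' (correctly recovered non-biological zeros); the fraction of true-zero
#' positions flagged in `I1` (falsely imputed biological zeros); and the
#' four-way zero-type counts. The zero-filled baseline vector at masked
#' positions is constant, so its PCC is reported as 0 (no linear association).
#'
#' When the imputed matrix covers only a subset of the simulated grid (cells
#' or genes removed by QC), it is aligned back onto the truth by its cell and
#' gene identifiers and scoring is restricted to the retained grid.
#'
#' The four-way counts cross-tabulate the observed indicator `I0` of the
#' masked matrix against predicted presence: `I_star > tau` when `I_star` is
#' supplied, else `pmax(I1, I0)` (in which case n10 is 0 by construction).
#'
#' @param sim [apply_dropout_mask()] output.
#' @param imputed [impute_all()] output (or a plain matrix of imputed values
#'   on the full simulated grid).
#' @param I1 binary imputation index used for the run (same grid as the
#'   imputed matrix).
#' @param truth optional truth matrix on the imputed scale, full simulated
#'   grid; default `sim$truth$values`.
#' @param I_star optional reconstruction matrix for the four-way counts.
#' @param tau threshold used with `I_star`. Default 0.5.
#' @return list: `pcc_masked`, `rmse_masked`, `pcc_zero_baseline`,
#'   `rmse_zero_baseline`, `dropout_recall`, `false_flag_rate`,
#'   `zero_type_counts`, `n_masked_scored`.
#' @export
score_masking_run <- function(sim, imputed, I1, truth = NULL,
                              I_star = NULL, tau = 0.5) {
  stopifnot(inherits(sim, "masked_simulation"))
  if (inherits(imputed, "imputed_matrix")) {
    Y <- imputed$Y_imputed$values
    ci <- match(imputed$Y_imputed$cell_ids, sim$truth$cell_ids)
    gi <- match(imputed$Y_imputed$gene_ids, sim$truth$gene_ids)
    if (anyNA(ci) || anyNA(gi)) stop("imputed identifiers not found in the simulation grid")
  } else {
    Y <- as.matrix(imputed)
    if (!all(dim(Y) == dim(sim$truth$values))) {
      stop("plain-matrix imputed input must cover the full simulated grid")
    }
    ci <- seq_len(nrow(Y)); gi <- seq_len(ncol(Y))
  }
  I1 <- as.matrix(I1)
  if (is.null(truth)) truth <- sim$truth$values
  truth <- as.matrix(truth)
  stopifnot(all(dim(truth) == dim(sim$truth$values)), all(dim(I1) == dim(Y)))
  truth <- truth[ci, gi, drop = FALSE]
  # map retained mask positions onto the (possibly subset) scoring grid
  keep <- sim$mask_positions[, "cell"] %in% ci & sim$mask_positions[, "gene"] %in% gi
  mrow <- match(sim$mask_positions[keep, "cell"], ci)
  mcol <- match(sim$mask_positions[keep, "gene"], gi)
  idx <- (mcol - 1L) * nrow(Y) + mrow
  if (length(idx) == 0) stop("no masked positions survive on the scoring grid")
  tv <- truth[idx]; yv <- Y[idx]
  pcc_m <- if (stats::sd(tv) == 0 || stats::sd(yv) == 0) 0 else pcc(yv, tv)
  res_pcc0 <- 0  # zero-filled baseline is constant at masked positions
  rmse_m <- rmse(yv, tv)
  rmse0 <- rmse(numeric(length(tv)), tv)
  recall <- sum(I1[idx] == 1) / length(idx)
  true_zero <- sim$truth$values[ci, gi, drop = FALSE] == 0
  false_flag <- if (any(true_zero)) mean(I1[true_zero] == 1) else NA_real_
  I0 <- (sim$masked$values[ci, gi, drop = FALSE] != 0) * 1
  pred <- if (!is.null(I_star)) (as.matrix(I_star) > tau) * 1 else pmax(I1, I0)
  stopifnot(all(dim(pred) == dim(I0)))
  counts <- c(n00 = sum(I0 == 0 & pred == 0), n01 = sum(I0 == 0 & pred == 1),
              n10 = sum(I0 == 1 & pred == 0), n11 = sum(I0 == 1 & pred == 1))
  list(pcc_masked = pcc_m, rmse_masked = rmse_m,
       pcc_zero_baseline = res_pcc0, rmse_zero_baseline = rmse0,
       dropout_recall = recall, false_flag_rate = false_flag,
       zero_type_counts = counts, n_masked_scored = length(idx))
}
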