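test_that("filter_cells applies the detected-gene and mitochondrial bounds", {
  # 3 cells with detected-gene counts 150 / 500 / 9000, bounds [200, 8000]
  v <- matrix(0, 3, 9000)
  v[1, seq_len(150)] <- 1
  v[2, seq_len(500)] <- 1
  v[3, seq_len(9000)] <- 1
  x <- expression_matrix(v)
  out <- filter_cells(x, qc_params(min_genes_per_cell = 200,
                                   max_features_per_cell = 8000))
  expect_identical(out$cell_ids, "cell_2")
  expect_identical(attr(out, "qc_removed"),
                   c(low_genes = 1L, high_features = 1L, high_mito = 0L))
  # bounds wider than all observed values: identity
  all_kept <- filter_cells(x, qc_params(min_genes_per_cell = 1,
                                        max_features_per_cell = 10000))
  expect_identical(all_kept$values, x$values)
})

test_that("cell filtering matches a per-cell predicate oracle on random data", {
  withr::local_seed(5)
  n <- 100; m <- 400
  v <- matrix(rpois(n * m, 0.8), n, m)
  mito <- runif(n, 0, 20)
  x <- expression_matrix(v, mito_pct = mito)
  qc <- qc_params(min_genes_per_cell = 210, max_features_per_cell = 230,
                  max_mito_pct = 12)
  out <- filter_cells(x, qc)
  keep_oracle <- vapply(seq_len(n), function(i) {
    det <- sum(v[i, ] > 0)
    det >= 210 && det <= 230 && mito[i] <= 12
  }, logical(1))
  expect_identical(out$cell_ids, x$cell_ids[keep_oracle])
})

test_that("cell QC fails loudly on empty results and missing annotations", {
  x <- expression_matrix(matrix(1, 2, 5))
  expect_error(filter_cells(x, qc_params(min_genes_per_cell = 100)),
               "no cells survive QC")
  expect_error(filter_cells(x, qc_params(min_genes_per_cell = 1,
                                         max_mito_pct = 5)),
               "no mito_pct annotation")
})

test_that("gene filtering is a strict detection-count threshold", {
  v <- matrix(0, 5, 3)
  v[1:2, 1] <- 1  # detected in 2 cells: removed at threshold 3
  v[1:3, 2] <- 1  # detected in exactly 3 cells: retained
  v[, 3] <- 1
  out <- filter_genes(expression_matrix(v), qc_params(min_cells_per_gene = 3))
  expect_identical(out$gene_ids, c("gene_2", "gene_3"))
  expect_error(filter_genes(expression_matrix(matrix(c(1, 0, 0, 0), 4, 1)),
                            qc_params(min_cells_per_gene = 2)),
               "no genes survive")
})

test_that("gene filtering equals column-sum thresholding on a random pattern", {
  withr::local_seed(9)
  v <- matrix(rbinom(50 * 200, 1, 0.05), 50, 200)
  x <- expression_matrix(v)
  out <- filter_genes(x, qc_params(min_cells_per_gene = 3))
  expect_identical(out$gene_ids, x$gene_ids[colSums(v > 0) >= 3])
})

test_that("QC is order-stable under cell permutation", {
  withr::local_seed(13)
  x <- make_count_matrix(n = 40, m = 60, density = 0.4, seed = 2)
  qc <- qc_params(min_genes_per_cell = 15, min_cells_per_gene = 3)
  perm <- sample(nrow(x$values))
  xp <- subset_matrix(x, cells = perm)
  a <- filter_genes(filter_cells(x, qc), qc)
  b <- filter_genes(filter_cells(xp, qc), qc)
  expect_setequal(a$cell_ids, b$cell_ids)
  expect_identical(a$gene_ids, b$gene_ids)
  # permuting input cells permutes output rows identically
  common <- intersect(b$cell_ids, a$cell_ids)
  expect_identical(b$values[common, ], a$values[common, ])
})

test_that("HVG selection returns everything when genes are scarce and ranks
           constant genes last", {
  x <- make_count_matrix(n = 30, m = 10, density = 0.8, seed = 4)
  expect_message(out <- select_hvgs(x, n_hvgs = 10), "returning all")
  expect_setequal(out$gene_ids, x$gene_ids)
  # a constant gene never outranks a variable one
  v <- x$values
  v[, 1] <- 5  # constant
  scored <- suppressMessages(select_hvgs(expression_matrix(v), n_hvgs = 10))
  expect_identical(scored$gene_ids[10], "gene_1")
})

test_that("HVG selection recovers genes with inflated dispersion", {
  withr::local_seed(21)
  n <- 200; m <- 500
  mu <- rgamma(m, shape = 2, rate = 0.5)
  hot <- sample(m, 20)
  size <- rep(10, m)     # low dispersion baseline
  size[hot] <- 0.5       # 20 genes with strongly inflated dispersion
  v <- matrix(0, n, m)
  for (j in seq_len(m)) v[, j] <- rnbinom(n, size = size[j], mu = mu[j])
  out <- suppressMessages(select_hvgs(expression_matrix(v), n_hvgs = 20))
  hits <- sum(out$gene_ids %in% paste0("gene_", hot))
  expect_gte(hits, 18)
})

test_that("gene-space intersection keeps single-cell order in both outputs", {
  sc <- expression_matrix(matrix(1, 2, 3), gene_ids = c("A", "B", "C"))
  bulk <- expression_matrix(matrix(1, 2, 3), gene_ids = c("B", "C", "D"))
  both <- intersect_with_bulk(sc, bulk)
  expect_identical(both$sc$gene_ids, c("B", "C"))
  expect_identical(both$bulk$gene_ids, c("B", "C"))
  expect_identical(both$n_common, 2L)
  # bulk superset: sc unchanged
  bulk2 <- expression_matrix(matrix(1, 2, 4), gene_ids = c("D", "C", "B", "A"))
  both2 <- intersect_with_bulk(sc, bulk2)
  expect_identical(both2$sc$values, sc$values)
  expect_identical(both2$bulk$gene_ids, c("A", "B", "C"))
  expect_error(intersect_with_bulk(
    sc, expression_matrix(matrix(1, 1, 1), gene_ids = "Z")), "no genes shared")
})

test_that("random overlapping namespaces reduce to the set-intersection oracle", {
  withr::local_seed(31)
  g1 <- sample(paste0("g", 1:60), 40)
  g2 <- sample(paste0("g", 1:60), 40)
  sc <- expression_matrix(matrix(runif(5 * 40), 5, 40), gene_ids = g1)
  bulk <- expression_matrix(matrix(runif(3 * 40), 3, 40), gene_ids = g2)
  both <- intersect_with_bulk(sc, bulk)
  expect_identical(both$sc$gene_ids, g1[g1 %in% g2])
})

test_that("pseudo-bulk aggregates by mean, sum, and group", {
  x <- expression_matrix(matrix(c(2, 4, 1, 3), 2, 2),
                         labels = c("a", "b"))
  expect_equal(unname(make_pseudobulk(x, "mean", per_label = FALSE)$values[1, 1]), 3)
  expect_equal(unname(make_pseudobulk(x, "sum", per_label = FALSE)$values[1, 1]), 6)
  withr::local_seed(17)
  y <- make_count_matrix(n = 12, m = 5, seed = 8,
                         labels = rep(c("t1", "t2", "t3"), 4))
  pb <- make_pseudobulk(y, "mean")
  oracle <- t(vapply(c("t1", "t2", "t3"), function(g)
    colMeans(y$values[y$labels == g, ]), numeric(5)))
  expect_equal(unname(pb$values), unname(oracle))
})
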