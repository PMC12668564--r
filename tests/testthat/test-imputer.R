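test_that("SNN counts match hand enumeration on collinear points", {
  # 4 equidistant collinear cells at x = 1, 2, 3, 4; k = 2
  # N2(1)={2,3}, N2(2)={1,3}, N2(3)={2,4}, N2(4)={3,2}
  # (ties at distance 2 broken by lower index)
  x <- matrix(c(1, 2, 3, 4), 4, 1)
  plan <- build_neighborhoods(x, k = 2)
  expect_identical(plan$knn, rbind(c(2L, 3L), c(1L, 3L), c(2L, 4L), c(3L, 2L)))
  # |N(1) ∩ N(2)| = |{2,3} ∩ {1,3}| = 1 ; |N(1) ∩ N(3)| = |{2,3} ∩ {2,4}| = 1
  expect_identical(plan$snn_counts[1, ], c(1L, 1L))
  # |N(3) ∩ N(2)| = |{2,4} ∩ {1,3}| = 0 ; |N(3) ∩ N(4)| = |{2,4} ∩ {3,2}| = 1
  expect_identical(plan$snn_counts[3, ], c(0L, 1L))
  # refined set of 3 puts neighbor 4 (overlap 1) ahead of neighbor 2 (overlap 0)
  expect_identical(plan$refined[3, ], c(4L, 2L))
})

test_that("two isolated tight pairs are each other's refined neighborhoods", {
  x <- rbind(c(0, 0), c(0.1, 0), c(100, 100), c(100.1, 100))
  plan <- build_neighborhoods(x, k = 1)
  expect_identical(plan$refined[, 1], c(2L, 1L, 4L, 3L))
  expect_error(build_neighborhoods(x, k = 4), "1 <= k < n")
})

test_that("neighborhood plans equal the exhaustive set oracle on random cells", {
  withr::local_seed(5)
  x <- matrix(rnorm(30 * 4), 30, 4)
  plan <- build_neighborhoods(x, k = 5)
  oracle <- oracle_snn_plan(x, 5)
  expect_identical(plan$knn, oracle$knn)
  expect_identical(plan$snn_counts, oracle$snn)
  expect_identical(plan$refined, oracle$refined)
  expect_true(all(plan$snn_counts >= 0 & plan$snn_counts <= 5))
  for (i in 1:30) expect_false(i %in% plan$refined[i, ])
})

test_that("the centroid and the degenerate projection behave as defined", {
  pr <- project_cell(c(1, 1), rbind(c(0, 0), c(2, 2)), t_grid = c(0, 0.5, 1))
  expect_equal(pr$centroid, c(1, 1))
  expect_equal(pr$chosen_t, 0)  # all candidates coincide: ties to smallest t
  expect_equal(pr$c_t_star, c(1, 1))
  expect_error(project_cell(c(1, 1), matrix(0, 0, 2)), "empty neighborhood")
})

test_that("the chosen projection maximizes density over the grid", {
  E <- rbind(c(2, 0), c(2, 2), c(2, -2))
  ci <- c(0, 0)
  grid <- c(0, 0.5, 1)
  pr <- project_cell(ci, E, t_grid = grid)
  sums <- vapply(grid, function(t) {
    ct <- ci + t * (colMeans(E) - ci)
    sum(apply(E, 1, function(e) sum((ct - e)^2)))
  }, numeric(1))
  expect_equal(pr$chosen_t, grid[which.min(sums)])
  expect_equal(pr$densities, 1 / (sums + 1e-12))
  expect_equal(max(pr$densities), pr$densities[which.min(sums)])
  # density maximization <=> distance-sum minimization on random instances
  withr::local_seed(31)
  for (rep in 1:10) {
    E2 <- matrix(rnorm(12), 4, 3)
    c2 <- rnorm(3)
    g2 <- seq(0, 1, by = 0.25)
    pr2 <- project_cell(c2, E2, t_grid = g2)
    s2 <- vapply(g2, function(t) {
      ct <- c2 + t * (colMeans(E2) - c2)
      sum(apply(E2, 1, function(e) sum((ct - e)^2)))
    }, numeric(1))
    expect_equal(pr2$chosen_t, g2[which.min(s2)])
  }
})

test_that("imputation preserves observed values and biological zeros exactly", {
  x <- make_count_matrix(n = 25, m = 15, density = 0.5, seed = 9)
  xt <- apply_transform(x, "log10")
  I0 <- build_indicator(xt)
  withr::local_seed(41)
  I1 <- (I0 == 0) * matrix(rbinom(25 * 15, 1, 0.4), 25, 15)
  imp <- impute_all(xt, I1, k = 6)
  Y <- imp$Y_imputed$values
  expect_identical(Y[I0 == 1], xt$values[I0 == 1])           # observed: bit-identical
  expect_true(all(Y[I0 == 0 & I1 == 0] == 0))                # biological zeros
  expect_identical(unname(Y), unname(imp$Y1 * I1 + xt$values))  # assembly identity
  expect_identical(unname(imp$provenance[I0 == 1]), rep(0L, sum(I0 == 1)))
  expect_identical(unname(imp$provenance[I1 == 1]), rep(1L, sum(I1)))
  expect_identical(unname(imp$provenance[I0 == 0 & I1 == 0]),
                   rep(2L, sum(I0 == 0 & I1 == 0)))
})

test_that("an empty imputation index returns the input unchanged", {
  x <- make_count_matrix(n = 10, m = 8, seed = 2)
  xt <- apply_transform(x, "log10")
  imp <- impute_all(xt, matrix(0, 10, 8), k = 3)
  expect_identical(imp$Y_imputed$values, xt$values)
})

test_that("a single flagged position changes exactly one entry", {
  x <- make_count_matrix(n = 12, m = 10, density = 0.6, seed = 13)
  xt <- apply_transform(x, "log10")
  I0 <- build_indicator(xt)
  zero_pos <- which(I0 == 0)[5]
  I1 <- matrix(0, 12, 10); I1[zero_pos] <- 1
  imp <- impute_all(xt, I1, k = 4)
  delta <- imp$Y_imputed$values != xt$values
  expect_identical(which(delta), zero_pos)
  expect_equal(imp$Y_imputed$values[zero_pos], imp$Y1[zero_pos])
})

test_that("imputation flags mismatched shapes and observed-position flags", {
  x <- make_count_matrix(n = 6, m = 5, seed = 1)
  xt <- apply_transform(x, "log10")
  expect_error(impute_all(xt, matrix(0, 3, 5), k = 2), "shape mismatch")
  I1_bad <- (xt$values != 0) * 1
  expect_error(impute_all(xt, I1_bad, k = 2), "I1 flags observed")
})

test_that("imputation is equivariant under cell permutation", {
  # continuous values so that Euclidean distances are almost surely tie-free
  withr::local_seed(17)
  v <- matrix(runif(20 * 12, 0.5, 5) * rbinom(20 * 12, 1, 0.5), 20, 12)
  xt <- expression_matrix(v)
  I0 <- build_indicator(xt)
  withr::local_seed(43)
  I1 <- (I0 == 0) * matrix(rbinom(20 * 12, 1, 0.5), 20, 12)
  imp <- impute_all(xt, I1, k = 5)
  perm <- sample(20)
  xp <- subset_matrix(xt, cells = perm)
  impp <- impute_all(xp, I1[perm, ], k = 5)
  expect_equal(unname(impp$Y_imputed$values), unname(imp$Y_imputed$values[perm, ]))
})
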