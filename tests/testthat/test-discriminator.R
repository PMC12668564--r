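test_that("the indicator matrix marks exactly the non-zero entries", {
  x <- expression_matrix(matrix(c(0, 3, 2, 0), 2, 2))
  expect_identical(unname(build_indicator(x)), matrix(c(0, 1, 1, 0), 2, 2))
  z <- expression_matrix(rbind(rep(0, 4), c(1, 0, 2, 0)))
  expect_identical(unname(build_indicator(z)[1, ]), rep(0, 4))
  withr::local_seed(3)
  r <- make_count_matrix(n = 20, m = 30, density = 0.3, seed = 3)
  expect_identical(build_indicator(r), (r$values != 0) * 1)
})

test_that("Pearson similarity matches the textbook formula pairwise", {
  m <- rbind(c(1, 2, 3), c(2, 4, 6), c(3, 2, 1))
  r <- pearson_similarity(m, "rows")
  expect_equal(r[1, 2], 1)
  expect_equal(r[1, 3], -1)
  expect_equal(diag(r), rep(1, 3), ignore_attr = TRUE)
  withr::local_seed(7)
  a <- matrix(rnorm(40), 8, 5)
  rr <- pearson_similarity(a, "rows")
  for (i in 1:7) for (j in (i + 1):8) {
    x <- a[i, ]; y <- a[j, ]
    byhand <- sum((x - mean(x)) * (y - mean(y))) /
      (sqrt(sum((x - mean(x))^2)) * sqrt(sum((y - mean(y))^2)))
    expect_equal(rr[i, j], byhand, tolerance = 1e-12)
  }
  rc <- pearson_similarity(a, "columns")
  expect_equal(rc[1, 2], cor(a[, 1], a[, 2]))
})

test_that("zero-variance vectors get similarity 0 with a warning", {
  m <- rbind(c(1, 1, 1), c(1, 2, 3), c(5, 1, 2))
  expect_warning(r <- pearson_similarity(m, "rows"), "zero-variance")
  expect_equal(r[1, 2], 0)
  expect_equal(r[1, 1], 1)
})

test_that("kNN sparsification classifies mutual and one-sided edges", {
  # nodes 1,2 mutual top neighbors; node 3's top neighbor is 1 but not vice versa
  R <- rbind(c(1, 0.9, 0.2),
             c(0.9, 1, 0.1),
             c(0.2, 0.1, 1))
  g <- knn_sparsify(R, k = 1)
  expect_equal(g$S[1, 2], 1); expect_equal(g$S[2, 1], 1)
  expect_equal(g$S[1, 3], 0.5); expect_equal(g$S[3, 1], 0.5)
  expect_equal(g$S[2, 3], 0); expect_equal(g$S[3, 2], 0)
  expect_equal(diag(g$S), rep(0, 3))
  expect_error(knn_sparsify(R, k = 3), "1 <= k < nrow")
})

test_that("Laplacians from sparsified graphs are symmetric PSD with zero row sums", {
  withr::local_seed(11)
  for (rep in 1:5) {
    A <- matrix(rnorm(225), 15, 15); R <- (A + t(A)) / 2; diag(R) <- 1
    g <- knn_sparsify(R, k = 3)
    expect_lt(max(abs(rowSums(g$L))), 1e-10)
    expect_identical(g$L, t(g$L))
    ev <- eigen(g$L, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-10)
    expect_equal(g$S, oracle_knn_classes(R, 3), ignore_attr = TRUE)
    expect_true(all(g$R_sparse >= 0))
  }
})

test_that("factorization recovers an exact rank-1 indicator", {
  u <- c(1, 2, 3, 0.5, 1.5)
  v <- c(2, 1, 0.5, 1, 3, 0.2)
  I0 <- outer(u, v)
  fp <- factorize(I0, p = 1, beta = 0, lambda_c = 0, lambda_g = 0,
                  max_iter = 2000, tol = 1e-14, seed = 4)
  rel_err <- norm(I0 - reconstruct(fp), "F") / norm(I0, "F")
  expect_lt(rel_err, 1e-3)
})

test_that("the objective decreases monotonically with graphs active", {
  withr::local_seed(13)
  I0 <- matrix(rbinom(30 * 40, 1, 0.3), 30, 40)
  gc_ <- knn_sparsify(pearson_similarity(I0 + matrix(rnorm(1200, 0, 0.01), 30), "rows"), k = 5)
  gg_ <- knn_sparsify(pearson_similarity(I0 + matrix(rnorm(1200, 0, 0.01), 30), "columns"), k = 5)
  fp <- factorize(I0, gc_, gg_, p = 4, beta = 0.05, lambda_c = 0.1,
                  lambda_g = 0.1, max_iter = 120, tol = 0, seed = 2)
  obj <- fp$objective_trace$objective
  expect_true(all(diff(obj) <= obj[-length(obj)] * 1e-8 + 1e-12))
  expect_true(all(fp$U >= 0) && all(fp$V >= 0))
  # graph quadratic forms are non-negative for the final iterate
  expect_gte(sum((fp$U %*% gc_$L) * fp$U), -1e-10)
  expect_gte(sum((fp$V %*% gg_$L) * fp$V), -1e-10)
})

test_that("with all regularizers off the updates coincide with plain NMF", {
  withr::local_seed(17)
  I0 <- matrix(rbinom(10 * 12, 1, 0.4), 10, 12)
  p <- 3
  U0 <- matrix(runif(p * 10), p, 10)
  V0 <- matrix(runif(p * 12), p, 12)
  n_iter <- 40
  fp <- factorize(I0, p = p, beta = 0, lambda_c = 0, lambda_g = 0,
                  max_iter = n_iter, tol = 0, init = list(U = U0, V = V0))
  oracle <- oracle_plain_nmf(I0, t(U0), V0, n_iter)
  expect_equal(fp$objective_trace$recon, oracle$objective, tolerance = 1e-6)
  expect_equal(unname(t(fp$U)), unname(oracle$W), tolerance = 1e-6)
})

test_that("stronger Tikhonov regularization shrinks the factor norms", {
  withr::local_seed(19)
  I0 <- matrix(rbinom(20 * 25, 1, 0.35), 20, 25)
  f0 <- factorize(I0, p = 3, beta = 0, lambda_c = 0, lambda_g = 0,
                  max_iter = 50, tol = 0, seed = 5)
  f1 <- factorize(I0, p = 3, beta = 50, lambda_c = 0, lambda_g = 0,
                  max_iter = 50, tol = 0, seed = 5)
  expect_lt(norm(f1$U, "F"), norm(f0$U, "F"))
  expect_lt(norm(f1$V, "F"), norm(f0$V, "F"))
  expect_error(factorize(I0, p = 3, beta = -1), ">= 0")
})

test_that("reconstruction is the exact crossproduct of the factors", {
  fp <- structure(list(U = matrix(c(1, 2), 1, 2), V = matrix(c(3, 4), 1, 2)),
                  class = "factor_pair")
  expect_equal(unname(reconstruct(fp)), rbind(c(3, 4), c(6, 8)))
  withr::local_seed(23)
  U <- matrix(runif(12), 3, 4); V <- matrix(runif(15), 3, 5)
  fp2 <- structure(list(U = U, V = V), class = "factor_pair")
  naive <- matrix(0, 4, 5)
  for (i in 1:4) for (j in 1:5) for (l in 1:3) {
    naive[i, j] <- naive[i, j] + U[l, i] * V[l, j]
  }
  expect_equal(unname(reconstruct(fp2)), naive, tolerance = 1e-12)
})

test_that("dropout calls never flag observed entries and conserve counts", {
  withr::local_seed(29)
  I0 <- matrix(rbinom(15 * 20, 1, 0.5), 15, 20)
  I_star <- matrix(runif(15 * 20), 15, 20)
  I1 <- call_dropouts(I0, I_star, tau = 0.5)
  expect_true(all(I1 * I0 == 0))
  oracle <- matrix(0, 15, 20)
  for (i in 1:15) for (j in 1:20) {
    oracle[i, j] <- as.numeric(I0[i, j] == 0 && I_star[i, j] > 0.5)
  }
  expect_equal(unname(I1), oracle, ignore_attr = TRUE)
  expect_identical(sum(attr(I1, "zero_type_counts")), 300L)
  # all-zero indicator with reconstruction above threshold: everything flagged
  allz <- call_dropouts(matrix(0, 3, 3), matrix(1, 3, 3), tau = 0.5)
  expect_true(all(allz == 1))
  expect_error(call_dropouts(I0, I_star, tau = -0.1), ">= 0")
})

test_that("the adaptive threshold is half the observed-position mean", {
  withr::local_seed(31)
  I0 <- matrix(rbinom(100, 1, 0.5), 10, 10)
  I_star <- matrix(runif(100), 10, 10)
  I1 <- call_dropouts(I0, I_star)
  expect_equal(attr(I1, "tau"), mean(I_star[I0 == 1]) / 2)
})
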