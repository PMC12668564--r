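# Fixture builders shared across test files.  All fixtures are generated in
# code under fixed seeds; nothing is read from disk.

# Two well-separated Gaussian clusters in gene space, returned as a
# non-negative ExpressionMatrix with labels.
make_two_cluster_matrix <- function(n_per = 10, m = 6, sep = 10, sd = 0.3,
                                    seed = 42) {
  withr::with_seed(seed, {
    a <- matrix(abs(rnorm(n_per * m, mean = 1, sd = sd)), n_per, m)
    b <- matrix(abs(rnorm(n_per * m, mean = 1 + sep, sd = sd)), n_per, m)
    expression_matrix(rbind(a, b),
                      labels = rep(c("A", "B"), each = n_per))
  })
}

# Small sparse count matrix with a controlled detection pattern.
make_count_matrix <- function(n = 20, m = 30, density = 0.5, seed = 7,
                              labels = NULL) {
  withr::with_seed(seed, {
    v <- matrix(rpois(n * m, lambda = 3) * (runif(n * m) < density), n, m)
    expression_matrix(v, labels = labels)
  })
}

random_labels <- function(n, k, seed) {
  withr::with_seed(seed, sample(seq_len(k), n, replace = TRUE))
}
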