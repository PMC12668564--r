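# Independent brute-force oracles used to validate the package implementations.
# Each oracle is a direct, unoptimized transcription of the defining formula.

# ARI by exhaustive enumeration of all n(n-1)/2 sample pairs.
oracle_ari_pairs <- function(truth, pred) {
  n <- length(truth)
  a <- b <- cc <- d <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    st <- truth[i] == truth[j]
    sp <- pred[i] == pred[j]
    if (st && sp) a <- a + 1
    else if (!st && sp) b <- b + 1
    else if (st && !sp) cc <- cc + 1
    else d <- d + 1
  }
  if (b == 0 && cc == 0) return(1)
  2 * (a * d - b * cc) / ((a + b) * (b + d) + (a + cc) * (cc + d))
}

# NMI from first principles: joint/marginal frequencies, entropies in nats.
oracle_nmi <- function(truth, pred) {
  n <- length(truth)
  tu <- unique(truth); pu <- unique(pred)
  joint <- outer(tu, pu, Vectorize(function(a, b) sum(truth == a & pred == b))) / n
  px <- rowSums(joint); py <- colSums(joint)
  h <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  if (h(px) + h(py) == 0) return(1)
  mi <- 0
  for (i in seq_along(px)) for (j in seq_along(py)) {
    if (joint[i, j] > 0) mi <- mi + joint[i, j] * log(joint[i, j] / (px[i] * py[j]))
  }
  2 * mi / (h(px) + h(py))
}

# Silhouette by explicit per-sample distance table arithmetic.
oracle_silhouette <- function(values, labels) {
  n <- nrow(values)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    d[i, j] <- sqrt(sum((values[i, ] - values[j, ])^2))
  }
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i] & seq_len(n) != i)
    if (length(own) == 0) { s[i] <- 0; next }
    A <- mean(d[i, own])
    B <- Inf
    for (g in setdiff(unique(labels), labels[i])) {
      B <- min(B, mean(d[i, labels == g]))
    }
    s[i] <- if (max(A, B) == 0) 0 else (B - A) / max(A, B)
  }
  mean(s)
}

# Ordering scores by explicit pair loops.
oracle_pos <- function(order_index, stages) {
  n <- length(order_index)
  r <- rank(order_index, ties.method = "first")
  s <- 0; m <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (stages[i] == stages[j]) next
    m <- m + 1
    agree <- (r[i] < r[j]) == (stages[i] < stages[j])
    s <- s + if (agree) 1 else -1
  }
  s / m
}

oracle_kendall <- function(order_index, stages) {
  n <- length(order_index)
  r <- rank(order_index, ties.method = "first")
  J <- 0; W <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    p <- (r[i] - r[j]) * (stages[i] - stages[j])
    if (p > 0) J <- J + 1 else if (p < 0) W <- W + 1
  }
  2 * (J - W) / (n * (n - 1))
}

# AUC as the Mann-Whitney pair statistic: P(score_pos > score_neg) + 0.5 ties.
oracle_auc_mw <- function(scores, positive) {
  pos <- scores[positive]; neg <- scores[!positive]
  tot <- 0
  for (a in pos) for (b in neg) {
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# Plain multiplicative-update NMF: X ~ W H, W n x p, H p x m.  Independent of
# factorize() (different parametrization); same epsilon guard and update order
# (W first, then H) so per-iteration objectives are comparable.
oracle_plain_nmf <- function(X, W, H, n_iter, eps = 1e-10) {
  obj <- numeric(n_iter + 1)
  obj[1] <- sum((X - W %*% H)^2)
  for (it in seq_len(n_iter)) {
    W <- W * (X %*% t(H)) / (W %*% H %*% t(H) + eps)
    H <- H * (t(W) %*% X) / (t(W) %*% W %*% H + eps)
    obj[it + 1] <- sum((X - W %*% H)^2)
  }
  list(W = W, H = H, objective = obj)
}

# kNN-set classification oracle for knn_sparsify: mutual / one-sided / neither.
oracle_knn_classes <- function(R, k) {
  n <- nrow(R)
  nbrs <- lapply(seq_len(n), function(i) {
    cand <- R[i, ]; cand[i] <- -Inf
    order(-cand, seq_len(n))[seq_len(k)]
  })
  S <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    ij <- j %in% nbrs[[i]]
    ji <- i %in% nbrs[[j]]
    S[i, j] <- if (ij && ji) 1 else if (!ij && !ji) 0 else 0.5
  }
  S
}

# SNN neighborhood oracle for build_neighborhoods.
oracle_snn_plan <- function(values, k) {
  n <- nrow(values)
  d <- as.matrix(stats::dist(values))
  nbrs <- lapply(seq_len(n), function(i) {
    dd <- d[i, ]; dd[i] <- Inf
    order(dd, seq_len(n))[seq_len(k)]
  })
  snn <- matrix(0L, n, k)
  refined <- matrix(0L, n, k)
  for (i in seq_len(n)) {
    for (jj in seq_len(k)) {
      snn[i, jj] <- length(intersect(nbrs[[i]], nbrs[[nbrs[[i]][jj]]]))
    }
    refined[i, ] <- nbrs[[i]][order(-snn[i, ], seq_len(k))]
  }
  list(knn = do.call(rbind, nbrs), snn = snn, refined = refined)
}

# Skewness directly from the defining sum.
oracle_skewness <- function(x) {
  n <- length(x)
  s <- sd(x)
  n / ((n - 1) * (n - 2)) * sum(((x - mean(x)) / s)^3)
}
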