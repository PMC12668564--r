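#' Skewness coefficient
#'
#' Adjusted Fisher-Pearson sample skewness,
#' `n/((n-1)(n-2)) * sum(((x - mean)/sd)^3)` with the (n-1) sample standard
#' deviation. Positive values indicate a right-skewed distribution.
#'
#' @param values numeric sample, length >= 3, positive standard deviation.
#' @return scalar skewness.
#' @export
skewness <- function(values) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 3) stop("skewness requires at least 3 values")
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0) stop("skewness undefined: zero standard deviation")
  n / ((n - 1) * (n - 2)) * sum(((values - mean(values)) / s)^3)
}

#' Silhouette coefficient
#'
#' Mean per-sample silhouette under Euclidean distance: for sample i,
#' `s_i = (B - A) / max(A, B)` where A is the mean distance to other members of
#' its own cluster and B the minimum over other clusters of the mean distance
#' to that cluster's members. Singleton-cluster samples and degenerate
#' `A = B = 0` samples score 0.
#'
#' @param values numeric matrix, rows = samples.
#' @param labels per-row cluster labels (>= 2 distinct).
#' @return scalar in \[-1, 1\].
#' @export
silhouette_coef <- function(values, labels) {
  values <- as.matrix(values)
  labels <- as.character(labels)
  stopifnot(nrow(values) == length(labels))
  ulab <- unique(labels)
  if (length(ulab) < 2) stop("silhouette requires at least 2 clusters")
  d <- as.matrix(stats::dist(values))
  idx <- split(seq_along(labels), labels)
  sizes <- lengths(idx)
  s <- numeric(length(labels))
  for (i in seq_along(labels)) {
    own <- labels[i]
    if (sizes[[own]] == 1) { s[i] <- 0; next }
    A <- sum(d[i, idx[[own]]]) / (sizes[[own]] - 1)
    B <- min(vapply(setdiff(names(idx), own),
                    function(g) mean(d[i, idx[[g]]]), numeric(1)))
    s[i] <- if (max(A, B) == 0) 0 else (B - A) / max(A, B)
  }
  out <- mean(s)
  stopifnot(out >= -1 - 1e-12, out <= 1 + 1e-12)
  out
}

entropy_nats <- function(p) {
  p <- p[p > 0]
  # summation in sorted order so the result is exactly invariant to relabeling
  -sum(sort(p * log(p)))
}

#' Normalized mutual information
#'
#' `2 I(X; Y) / (H(X) + H(Y))` with entropies in nats from empirical label
#' frequencies; the base cancels in the ratio. Returns 1 when both labelings
#' are constant (`H(X) + H(Y) = 0`).
#'
#' @param truth,pred equal-length category vectors.
#' @return scalar in \[0, 1\].
#' @export
nmi <- function(truth, pred) {
  truth <- as.character(truth); pred <- as.character(pred)
  stopifnot(length(truth) == length(pred), length(truth) >= 2)
  n <- length(truth)
  tab <- table(truth, pred)
  pxy <- tab / n
  px <- rowSums(pxy); py <- colSums(pxy)
  hx <- entropy_nats(px); hy <- entropy_nats(py)
  if (hx + hy == 0) return(1)
  terms <- numeric(0)
  for (i in seq_along(px)) for (j in seq_along(py)) {
    if (pxy[i, j] > 0) terms <- c(terms, pxy[i, j] * log(pxy[i, j] / (px[i] * py[j])))
  }
  mi <- sum(sort(terms))  # sorted summation: exact relabeling invariance
  out <- 2 * mi / (hx + hy)
  out <- min(max(out, 0), 1)  # clamp fp jitter at the boundaries
  out
}

#' Adjusted Rand index (pair-count form)
#'
#' Over all n(n-1)/2 sample pairs, counts a = pairs together in both truth and
#' prediction, b = together only in prediction, c = together only in truth,
#' d = separated in both, and returns
#' `2(ad - bc) / ((a+b)(b+d) + (a+c)(c+d))`. When every pair agrees
#' (b = c = 0) the index is 1 by convention (covers the degenerate
#' all-in-one-cluster case).
#'
#' @param truth,pred equal-length category vectors, n >= 2.
#' @return scalar in \[-1, 1\].
#' @export
ari <- function(truth, pred) {
  truth <- as.character(truth); pred <- as.character(pred)
  n <- length(truth)
  stopifnot(length(pred) == n, n >= 2)
  # pair counts via the contingency table (equivalent to enumerating pairs)
  tab <- table(truth, pred)
  pairs2 <- function(v) sum(v * (v - 1) / 2)
  a <- pairs2(as.vector(tab))
  same_t <- pairs2(rowSums(tab))
  same_p <- pairs2(colSums(tab))
  tot <- n * (n - 1) / 2
  b <- same_p - a
  c <- same_t - a
  d <- tot - a - b - c
  if (b == 0 && c == 0) return(1)
  denom <- (a + b) * (b + d) + (a + c) * (c + d)
  out <- 2 * (a * d - b * c) / denom
  stopifnot(out >= -1 - 1e-12, out <= 1 + 1e-12)
  out
}

#' Pseudo-temporal ordering score
#'
#' Scores an inferred cell ordering against ordinal stage labels: each pair of
#' cells with different stages contributes +1 when the ordering places them in
#' stage order, -1 when opposed; same-stage pairs are skipped. The sum is
#' normalized by the number of stage-comparable pairs so the score lies in
#' \[-1, 1\].
#'
#' @param order_index per-cell position along the inferred path (a permutation
#'   of 1..n, or any numeric pseudotime; only its ranks matter).
#' @param stages per-cell ordinal stage labels (numeric or ordered-comparable).
#' @return scalar in \[-1, 1\].
#' @export
pos_score <- function(order_index, stages) {
  n <- length(order_index)
  stopifnot(length(stages) == n, n >= 2)
  stages <- as.numeric(factor(stages, levels = sort(unique(stages))))
  r <- rank(order_index, ties.method = "first")
  s <- 0; comparable <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ds <- stages[i] - stages[j]
    if (ds == 0) next
    comparable <- comparable + 1
    s <- s + sign(r[i] - r[j]) * sign(ds)
  }
  if (comparable == 0) stop("all stage labels identical: ordering score undefined")
  out <- s / comparable
  stopifnot(out >= -1, out <= 1)
  out
}

#' Kendall rank concordance (tau-a)
#'
#' `2 (J - W) / (n (n - 1))` where J and W count concordant and discordant
#' pairs between the inferred ordering and the stage labels; tied pairs count
#' in neither.
#'
#' @inheritParams pos_score
#' @return scalar in \[-1, 1\].
#' @export
kendall_tau <- function(order_index, stages) {
  n <- length(order_index)
  stopifnot(length(stages) == n, n >= 2)
  stages <- as.numeric(factor(stages, levels = sort(unique(stages))))
  r <- rank(order_index, ties.method = "first")
  J <- 0; W <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    p <- sign(r[i] - r[j]) * sign(stages[i] - stages[j])
    if (p > 0) J <- J + 1 else if (p < 0) W <- W + 1
  }
  out <- 2 * (J - W) / (n * (n - 1))
  stopifnot(out >= -1, out <= 1)
  out
}

#' ROC curve and AUC for a gene score against a reference set
#'
#' Sweeps a decision threshold over the score ranks (tied scores enter
#' simultaneously), computing TPR = TP/(TP+FN) and FPR = FP/(FP+TN) at each
#' threshold; the AUC is the trapezoidal area under the resulting curve.
#'
#' @param scores numeric score per gene (higher = more likely positive).
#' @param reference logical vector (or index/character subset of
#'   `names(scores)`) marking the reference positives; must be non-empty and
#'   not all genes.
#' @return list with `curve` (data.frame fpr/tpr, threshold sweep including the
#'   (0,0) and (1,1) endpoints) and `auc`.
#' @export
roc_auc <- function(scores, reference) {
  scores <- as.numeric(scores)
  n <- length(scores)
  if (is.logical(reference)) {
    stopifnot(length(reference) == n)
    pos <- reference
  } else {
    pos <- rep(FALSE, n)
    pos[reference] <- TRUE
  }
  P <- sum(pos); N <- n - P
  if (P == 0 || N == 0) stop("reference set must be a non-empty strict subset of the genes")
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- numeric(length(thr) + 1)
  fpr <- numeric(length(thr) + 1)
  for (t in seq_along(thr)) {
    call <- scores >= thr[t]
    tpr[t + 1] <- sum(call & pos) / P
    fpr[t + 1] <- sum(call & !pos) / N
  }
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  stopifnot(auc >= 0, auc <= 1)
  list(curve = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

#' Pearson correlation coefficient
#'
#' @param a,b equal-length numeric vectors (length >= 2) with non-zero
#'   variance.
#' @return scalar in \[-1, 1\].
#' @export
pcc <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("pcc undefined: zero variance input")
  }
  out <- stats::cor(a, b)
  stopifnot(out >= -1 - 1e-12, out <= 1 + 1e-12)
  out
}

#' Root mean square error
#'
#' @param a,b equal-length numeric vectors.
#' @return scalar >= 0.
#' @export
rmse <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 1)
  sqrt(mean((a - b)^2))
}
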