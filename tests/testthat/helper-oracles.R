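# Independent oracles used to cross-check package computations.

# Naive O(n^2) DeLong components: placement values by explicit pairwise
# comparison (Heaviside kernel with 1/2 for ties).
naive_delong <- function(scores_a, scores_b, labels) {
  y <- as.integer(labels == "ICAS" | labels == 1)
  comp <- function(scores) {
    x <- scores[y == 1]; yn <- scores[y == 0]
    m <- length(x); n <- length(yn)
    psi <- outer(x, yn, function(a, b) (a > b) + 0.5 * (a == b))
    list(auc = mean(psi), v01 = rowMeans(psi), v10 = colMeans(psi),
         m = m, n = n)
  }
  a <- comp(scores_a); b <- comp(scores_b)
  s01 <- stats::cov(cbind(a$v01, b$v01))
  s10 <- stats::cov(cbind(a$v10, b$v10))
  S <- s01 / a$m + s10 / a$n
  var_diff <- S[1, 1] + S[2, 2] - 2 * S[1, 2]
  d <- a$auc - b$auc
  z <- if (var_diff <= .Machine$double.eps) {
    if (abs(d) < .Machine$double.eps) 0 else sign(d) * Inf
  } else d / sqrt(var_diff)
  list(auc_a = a$auc, auc_b = b$auc, var_diff = var_diff, z = z,
       p = 2 * stats::pnorm(-abs(z)))
}

# Brute-force best Gini split over all features and thresholds (complete
# data): returns the maximal impurity decrease and the achieving features.
brute_best_split <- function(x, y) {
  y <- as.integer(y)
  gini <- function(v) {
    p <- mean(v)
    1 - p^2 - (1 - p)^2
  }
  best <- list(decrease = 0, feature = integer(0), threshold = numeric(0))
  n <- length(y)
  for (j in seq_len(ncol(x))) {
    v <- sort(unique(x[, j]))
    if (length(v) < 2) next
    for (i in seq_len(length(v) - 1)) {
      thr <- (v[i] + v[i + 1]) / 2
      l <- y[x[, j] <= thr]; r <- y[x[, j] > thr]
      dec <- gini(y) - length(l) / n * gini(l) - length(r) / n * gini(r)
      if (dec > best$decrease + 1e-12) {
        best <- list(decrease = dec, feature = j, threshold = thr)
      } else if (abs(dec - best$decrease) <= 1e-12) {
        best$feature <- union(best$feature, j)
      }
    }
  }
  best
}

# Trapezoidal AUC computed independently from an ROC constructed by hand.
trapezoid_auc <- function(scores, labels) {
  y <- as.integer(labels == "ICAS" | labels == 1)
  ths <- c(-Inf, sort(unique(scores)), Inf)
  tpr <- vapply(ths, function(t) mean(scores[y == 1] >= t), numeric(1))
  fpr <- vapply(ths, function(t) mean(scores[y == 0] >= t), numeric(1))
  ord <- order(fpr, tpr)
  fpr <- fpr[ord]; tpr <- tpr[ord]
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}
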