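# Independent brute-force oracles used by the property and acceptance tests.
# These deliberately avoid the package's own implementations.

# AUROC as the fraction of concordant positive/negative pairs (ties = 1/2)
oracle_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# direct evaluation of the four confusion-metric formulas
oracle_confusion <- function(tp, fn, tn, fp) {
  c(sn = if (tp + fn > 0) tp / (tp + fn) else 0,
    sp = if (tn + fp > 0) tn / (tn + fp) else 0,
    acc = (tp + tn) / (tp + fn + tn + fp),
    mcc = {
      den <- sqrt(tp + fn) * sqrt(tn + fn) * sqrt(tp + fp) * sqrt(tn + fp)
      if (den > 0) (tp * tn - fp * fn) / den else 0
    })
}

# exhaustive enumeration of all monotone warping paths (small profiles only)
oracle_dtw <- function(a, b) {
  n <- length(a); m <- length(b)
  best <- Inf
  recurse <- function(i, j, acc) {
    acc <- acc + abs(a[i] - b[j])
    if (acc >= best) return(invisible())
    if (i == n && j == m) { best <<- acc; return(invisible()) }
    if (i < n && j < m) recurse(i + 1, j + 1, acc)
    if (i < n) recurse(i + 1, j, acc)
    if (j < m) recurse(i, j + 1, acc)
  }
  recurse(1, 1, 0)
  best
}

# is p a valid warping path for profile lengths n x m?
valid_dtw_path <- function(p, n, m) {
  if (!all(p[1, ] == c(1, 1)) || !all(p[nrow(p), ] == c(n, m))) return(FALSE)
  if (nrow(p) == 1) return(TRUE)
  d <- diff(p)
  all(d >= 0 & d <= 1) && all(rowSums(d) >= 1)
}
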