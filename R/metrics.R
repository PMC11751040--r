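#' Confusion-matrix metrics
#'
#' Sensitivity, specificity, accuracy and the Matthews correlation
#' coefficient from the four confusion counts:
#' \deqn{Sn = TP/(TP+FN),\quad Sp = TN/(TN+FP),\quad
#'       Acc = (TP+TN)/(TP+TN+FP+FN)}
#' \deqn{MCC = (TP\,TN - FP\,FN) / \sqrt{(TP+FN)(TN+FN)(TP+FP)(TN+FP)}}
#' A zero denominator makes the affected metric 0 and sets its entry in the
#' \code{undefined} attribute.
#'
#' @param tp,fn,tn,fp Nonnegative confusion counts.
#' @return Named numeric vector \code{c(sn, sp, acc, mcc)} with an
#'   \code{undefined} attribute naming any zero-denominator metrics.
#' @export
#' @examples
#' confusion_metrics(40, 10, 35, 15)
confusion_metrics <- function(tp, fn, tn, fp) {
  counts <- c(tp = tp, fn = fn, tn = tn, fp = fp)
  stopifnot(all(counts >= 0))
  if (sum(counts) == 0) stop("all confusion counts are zero")
  undef <- character(0)
  sn <- if (tp + fn > 0) tp / (tp + fn) else { undef <- c(undef, "sn"); 0 }
  sp <- if (tn + fp > 0) tn / (tn + fp) else { undef <- c(undef, "sp"); 0 }
  acc <- (tp + tn) / sum(counts)
  denom <- (tp + fn) * (tn + fn) * (tp + fp) * (tn + fp)
  mcc <- if (denom > 0) (tp * tn - fp * fn) / sqrt(denom) else { undef <- c(undef, "mcc"); 0 }
  structure(c(sn = sn, sp = sp, acc = acc, mcc = mcc), undefined = undef)
}

#' Threshold-free ranking metrics: AUROC and AUPR
#'
#' AUROC is computed by the rank (concordant-pair) formula, which equals the
#' trapezoidal area under the ROC curve with tied scores rank-averaged.
#' AUPR uses step interpolation of precision over recall (ties processed as
#' one threshold).
#'
#' @param scores Numeric prediction scores (higher = more positive).
#' @param labels 0/1 labels, both classes present.
#' @return Named numeric vector \code{c(auroc, aupr)}.
#' @export
roc_pr_curves <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  npos <- sum(labels == 1); nneg <- sum(labels == 0)
  if (npos == 0 || nneg == 0) stop("both classes must be present")
  r <- rank(scores)  # average ranks under ties
  auroc <- (sum(r[labels == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
  # PR: walk thresholds from high to low, grouping tied scores
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  grp <- cumsum(!duplicated(s))
  tp_cum <- cumsum(y); n_cum <- seq_along(y)
  last_of_grp <- !duplicated(grp, fromLast = TRUE)
  tp <- tp_cum[last_of_grp]; n <- n_cum[last_of_grp]
  prec <- tp / n; rec <- tp / npos
  drec <- diff(c(0, rec))
  aupr <- sum(drec * prec)
  c(auroc = auroc, aupr = aupr)
}

#' Evaluate scored predictions against labels
#'
#' @param scores Positive-class probabilities.
#' @param labels 0/1 labels.
#' @param threshold Decision threshold for the confusion counts (default
#'   0.5; a score exactly at the threshold is called negative).
#' @return One-row data.frame: tp, fn, tn, fp, sn, sp, acc, mcc, auroc,
#'   aupr, threshold, n.
#' @export
evaluate_predictions <- function(scores, labels, threshold = 0.5) {
  pred <- as.integer(scores > threshold)
  tp <- sum(pred == 1 & labels == 1); fn <- sum(pred == 0 & labels == 1)
  tn <- sum(pred == 0 & labels == 0); fp <- sum(pred == 1 & labels == 0)
  m <- confusion_metrics(tp, fn, tn, fp)
  a <- roc_pr_curves(scores, labels)
  data.frame(tp = tp, fn = fn, tn = tn, fp = fp,
             sn = m[["sn"]], sp = m[["sp"]], acc = m[["acc"]], mcc = m[["mcc"]],
             auroc = a[["auroc"]], aupr = a[["aupr"]],
             threshold = threshold, n = length(labels))
}

#' Mann-Whitney U comparison of two metric samples
#'
#' Wraps [stats::wilcox.test()]: the exact distribution when both samples
#' have at most 8 values and no ties, the normal approximation with
#' continuity/tie correction otherwise. Significance tiers: NS (p > 0.05),
#' * (p < 0.05), ** (p < 0.01), *** (p < 0.001).
#'
#' @param a,b Numeric samples (each of size >= 3).
#' @return List with \code{U} (statistic for sample \code{a}), \code{p}
#'   (two-sided) and \code{tier}.
#' @export
mann_whitney_compare <- function(a, b) {
  stopifnot(length(a) >= 3, length(b) >= 3)
  if (length(unique(c(a, b))) == 1L)
    return(list(U = length(a) * length(b) / 2, p = 1, tier = "NS"))
  has_ties <- anyDuplicated(c(a, b)) > 0
  use_exact <- length(a) <= 8 && length(b) <= 8 && !has_ties
  wt <- suppressWarnings(wilcox.test(a, b, exact = use_exact, correct = TRUE))
  p <- wt$p.value
  tier <- if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else "NS"
  list(U = unname(wt$statistic), p = p, tier = tier)
}
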