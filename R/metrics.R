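# Multi-label evaluation: average precision / mAP, pooled ("overall") and
# per-label ("class-wise") precision, recall and F1, and rank-based AUC.

#' Average precision for one label
#'
#' All-points average precision over the descending-score ranking (stable
#' index order breaks ties): the mean, over the positive items, of the
#' precision at each positive's rank.
#'
#' @param scores numeric score column (higher = more confident positive).
#' @param truth binary column of the same length with at least one positive.
#' @return AP in `[0, 1]`.
#' @examples
#' average_precision(c(0.9, 0.8, 0.7), c(1, 0, 1))  # (1 + 2/3) / 2
#' @export
average_precision <- function(scores, truth) {
  if (length(scores) != length(truth)) stopf("length mismatch")
  if (any(truth != 0 & truth != 1)) stopf("truth must be binary")
  npos <- sum(truth)
  if (npos == 0) stopf("average precision needs at least one positive")
  ord <- order(-scores)                  # stable: ties keep index order
  rel <- truth[ord]
  prec_at_k <- cumsum(rel) / seq_along(rel)
  sum(prec_at_k * rel) / npos
}

#' Rank-based AUC (Mann-Whitney) for one label
#'
#' Probability that a random positive is scored above a random negative;
#' tied scores contribute 1/2.
#'
#' @param scores numeric score column.
#' @param truth binary column containing both classes.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, truth) {
  if (length(scores) != length(truth)) stopf("length mismatch")
  if (any(truth != 0 & truth != 1)) stopf("truth must be binary")
  npos <- sum(truth); nneg <- sum(1 - truth)
  if (npos == 0 || nneg == 0) stopf("auc needs both classes present")
  r <- rank(scores, ties.method = "average")
  (sum(r[truth == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Mean average precision over labels
#'
#' @param scores `n x C` score matrix.
#' @param truth `n x C` binary matrix.
#' @return mAP as a percentage in `[0, 100]`; labels with no positives are
#'   excluded from the mean and listed in attribute `"skipped"`.
#' @export
mean_average_precision <- function(scores, truth) {
  if (!all(dim(scores) == dim(truth))) stopf("shape mismatch")
  npos <- colSums(truth)
  keep <- which(npos > 0)
  if (length(keep) == 0L) stopf("no label has a positive example")
  ap <- vapply(keep, function(j) average_precision(scores[, j], truth[, j]),
               numeric(1))
  structure(100 * mean(ap), skipped = setdiff(seq_len(ncol(truth)), keep),
            per_label = ap)
}

.safe_div <- function(num, den) if (den > 0) num / den else 0
.f1 <- function(p, r) if (p + r > 0) 2 * p * r / (p + r) else 0

#' Overall and class-wise precision, recall and F1
#'
#' Predictions are `sigmoid(score) >= threshold` (equivalently a logit
#' threshold). Overall metrics pool every (image, label) decision into one
#' confusion count; class-wise metrics average per-label precision and
#' recall over labels, and both F1 values are the harmonic mean of the
#' aggregated precision and recall. Degenerate denominators yield 0 and are
#' recorded in `degenerate`.
#'
#' @param scores `n x C` matrix of logits.
#' @param truth `n x C` binary matrix.
#' @param threshold decision threshold in sigmoid space (default 0.5).
#' @return list with `OP`, `OR`, `OF1`, `CP`, `CR`, `CF1`, the per-label
#'   precision/recall table, and `degenerate` notes.
#' @export
overall_and_classwise_metrics <- function(scores, truth, threshold = 0.5) {
  if (!all(dim(scores) == dim(truth))) stopf("shape mismatch")
  assert_prob(threshold, "threshold")
  pred <- (sigmoid(scores) >= threshold) * 1
  tp <- sum(pred == 1 & truth == 1)
  fp <- sum(pred == 1 & truth == 0)
  fn <- sum(pred == 0 & truth == 1)
  degenerate <- character(0)
  if (tp + fp == 0) degenerate <- c(degenerate, "no positive predictions (OP := 0)")
  if (tp + fn == 0) degenerate <- c(degenerate, "no positive truths (OR := 0)")
  OP <- .safe_div(tp, tp + fp)
  OR <- .safe_div(tp, tp + fn)
  cl <- t(vapply(seq_len(ncol(truth)), function(j) {
    tpj <- sum(pred[, j] == 1 & truth[, j] == 1)
    fpj <- sum(pred[, j] == 1 & truth[, j] == 0)
    fnj <- sum(pred[, j] == 0 & truth[, j] == 1)
    c(precision = .safe_div(tpj, tpj + fpj), recall = .safe_div(tpj, tpj + fnj))
  }, numeric(2)))
  CP <- mean(cl[, "precision"]); CR <- mean(cl[, "recall"])
  list(OP = OP, OR = OR, OF1 = .f1(OP, OR),
       CP = CP, CR = CR, CF1 = .f1(CP, CR),
       per_label = cl, degenerate = degenerate)
}

#' Full metric report
#'
#' @param scores `n x C` matrix of logits.
#' @param truth `n x C` binary matrix.
#' @param threshold decision threshold in sigmoid space.
#' @return object of class `metric_report`: mAP (percent), OP/OR/OF1,
#'   CP/CR/CF1, per-label AUC (NA where a label has a single class, listed in
#'   `auc_skipped`), mean AUC over valid labels, and per-label tables.
#' @export
metric_report <- function(scores, truth, threshold = 0.5) {
  ocm <- overall_and_classwise_metrics(scores, truth, threshold)
  map <- mean_average_precision(scores, truth)
  aucs <- vapply(seq_len(ncol(truth)), function(j) {
    tj <- truth[, j]
    if (sum(tj) == 0 || sum(tj) == length(tj)) return(NA_real_)
    auc(scores[, j], tj)
  }, numeric(1))
  structure(list(
    mAP = as.numeric(map),
    OP = ocm$OP, OR = ocm$OR, OF1 = ocm$OF1,
    CP = ocm$CP, CR = ocm$CR, CF1 = ocm$CF1,
    auc_per_class = aucs,
    auc_mean = if (all(is.na(aucs))) NA_real_ else mean(aucs, na.rm = TRUE),
    auc_skipped = which(is.na(aucs)),
    map_skipped = attr(map, "skipped"),
    ap_per_label = attr(map, "per_label"),
    per_label = ocm$per_label,
    degenerate = ocm$degenerate,
    threshold = threshold
  ), class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("mAP: %.3f%%   mean AUC: %s\n", x$mAP,
              if (is.na(x$auc_mean)) "NA" else sprintf("%.4f", x$auc_mean)))
  cat(sprintf("overall   P %.4f  R %.4f  F1 %.4f\n", x$OP, x$OR, x$OF1))
  cat(sprintf("classwise P %.4f  R %.4f  F1 %.4f\n", x$CP, x$CR, x$CF1))
  if (length(x$map_skipped))
    cat("labels without positives (excluded from mAP):",
        paste(x$map_skipped, collapse = ", "), "\n")
  invisible(x)
}
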