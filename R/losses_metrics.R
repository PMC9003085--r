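# ---------------------------------------------------------------------------
# Losses and the confusion-count metric suite.
#
# Binary segmentation with a symmetric two-class formulation: for a pixel
# with foreground probability p and label y, pt = p if y = 1 and 1 - p
# otherwise.  Cross-entropy is -log(pt); focal loss multiplies it by
# (1 - pt)^gamma so confidently classified pixels (the overwhelming
# background majority) contribute almost nothing, concentrating the
# gradient on hard pixels.  gamma = 0 recovers cross-entropy exactly.
# Probabilities are clamped to [eps, 1 - eps] (eps = 1e-7) before the log.
# ---------------------------------------------------------------------------

.loss_eps <- 1e-7

check_probs_labels <- function(p, y) {
  if (!identical(dim(p), dim(y)) && length(p) != length(y)) {
    stop("probability and label arrays must have the same shape")
  }
  if (any(p < 0 | p > 1)) stop("probabilities must lie in [0, 1]")
  if (!all(y %in% c(0, 1))) stop("labels must be 0/1")
}

pt_of <- function(p, y) {
  pt <- ifelse(y == 1, p, 1 - p)
  pmin(pmax(pt, .loss_eps), 1 - .loss_eps)
}

#' Mean two-class cross-entropy
#'
#' @param p per-pixel foreground probabilities in \[0, 1\].
#' @param y per-pixel labels in \{0, 1\}, same shape.
#' @return scalar mean of -log(pt) over all pixels.
#' @export
cross_entropy <- function(p, y) {
  check_probs_labels(p, y)
  mean(-log(pt_of(p, y)))
}

#' Mean focal loss
#'
#' @inheritParams cross_entropy
#' @param gamma focusing exponent (>= 0); 0 gives cross-entropy.
#' @return scalar mean of (1 - pt)^gamma * (-log(pt)).
#' @export
focal_loss <- function(p, y, gamma = 2) {
  check_probs_labels(p, y)
  if (gamma < 0) stop("gamma must be >= 0")
  pt <- pt_of(p, y)
  mean((1 - pt)^gamma * (-log(pt)))
}

# training loss + gradient w.r.t. per-pixel class logits.
# probs: (H, W, K) softmax output; y: (H, W) labels in 0..K-1.
# class_weights: optional per-class pixel-loss multipliers.
focal_loss_grad <- function(probs, y, gamma, class_weights = NULL) {
  d <- dim(probs)
  n <- d[1L] * d[2L]
  k <- d[3L]
  ymat <- as.integer(y) + 1L                       # true-class index per pixel
  pm <- matrix(probs, nrow = n)                    # n x K
  idx <- cbind(seq_len(n), ymat)
  pt <- pmin(pmax(pm[idx], .loss_eps), 1 - .loss_eps)
  one_m <- 1 - pt
  wpx <- if (is.null(class_weights)) 1 else class_weights[ymat]
  loss <- mean(wpx * one_m^gamma * (-log(pt)))
  # dL/dpt, then chain through softmax: dL/dz_k = dL/dpt * pt * (1[k=t] - p_k)
  dpt <- -gamma * one_m^pmax(gamma - 1, 0) * (-log(pt)) - one_m^gamma / pt
  if (gamma == 0) dpt <- -1 / pt
  dpt <- dpt * wpx
  gz <- pm * (-(dpt * pt) / n)
  gz[idx] <- gz[idx] + dpt * pt / n
  list(loss = loss, glogits = array(gz, dim = d))
}

#' Pixelwise confusion counts between a prediction and ground truth
#'
#' @param pred_mask,gt_mask binary matrices of identical shape.
#' @return named integer vector `c(tp, fp, fn, tn)` summing to the pixel
#'   count.
#' @export
confusion_counts <- function(pred_mask, gt_mask) {
  if (!identical(dim(pred_mask), dim(gt_mask))) {
    stop("prediction and ground truth masks must have identical shapes")
  }
  p <- pred_mask > 0.5
  g <- gt_mask > 0.5
  c(tp = sum(p & g), fp = sum(p & !g), fn = sum(!p & g), tn = sum(!p & !g))
}

#' Precision, recall, F1 and IoU from confusion counts
#'
#' Standard pixel-count definitions: P = TP/(TP+FP), R = TP/(TP+FN),
#' F1 = 2PR/(P+R), IoU = TP/(TP+FP+FN).  True negatives do not enter any
#' score, as usual when background dominates.  For dataset-level scores,
#' pool (micro-average) the counts over all patches before calling this.
#'
#' @param counts named vector with tp, fp, fn (tn optional).
#' @param empty_agreement value to report when a score's denominator is 0
#'   (no positives anywhere): `0` (default) or `1` ("empty prediction of an
#'   empty truth is perfect").
#' @return object of class `seg_metrics`: list of the counts, the four
#'   scores, and `degenerate = TRUE` when any denominator was 0.
#' @export
compute_metrics <- function(counts, empty_agreement = 0) {
  tp <- as.numeric(counts[["tp"]]); fp <- as.numeric(counts[["fp"]])
  fn <- as.numeric(counts[["fn"]])
  tn <- if ("tn" %in% names(counts)) as.numeric(counts[["tn"]]) else NA_real_
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  degenerate <- FALSE
  safe_div <- function(num, den) {
    if (den == 0) { degenerate <<- TRUE; empty_agreement } else num / den
  }
  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  f1 <- safe_div(2 * precision * recall, precision + recall)
  iou <- safe_div(tp, tp + fp + fn)
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn,
                 precision = precision, recall = recall, f1 = f1, iou = iou,
                 degenerate = degenerate),
            class = "seg_metrics")
}

#' @export
print.seg_metrics <- function(x, ...) {
  cat(sprintf("precision %.3f  recall %.3f  F1 %.3f  IoU %.3f%s\n",
              x$precision, x$recall, x$f1, x$iou,
              if (x$degenerate) "  (degenerate)" else ""))
  invisible(x)
}

#' Write a metric report as JSON
#' @param metrics a `seg_metrics`.
#' @param path output file.
#' @export
write_metrics_json <- function(metrics, path) {
  jsonlite::write_json(unclass(metrics)[c("tp", "fp", "fn", "tn", "precision",
                                          "recall", "f1", "iou")],
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
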