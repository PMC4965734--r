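# Detection metrics (PASCAL VOC style, IoU > 0.5), pixel-level segmentation
# metrics, and precision-recall curves.

prf <- function(tp, fp, fn) {
  precision <- if (tp + fp > 0L) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0L) tp / (tp + fn) else NA_real_
  f <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  list(precision = precision, recall = recall, f_score = f)
}

#' Evaluate gland detection
#'
#' One-to-one greedy matching by decreasing IoU (the PASCAL VOC convention):
#' a detection is a true positive when it is matched to an unmatched
#' ground-truth instance with IoU strictly greater than 0.5. Unmatched
#' detections are false positives; unmatched ground-truth instances are false
#' negatives. Precision = TP/(TP+FP), recall = TP/(TP+FN), F = harmonic mean;
#' undefined ratios are flagged as NA.
#'
#' @param detections list of proposal regions flagged as glands
#' @param gt an instance mask (\code{gs_mask})
#' @return list of class \code{gs_detection_result} with counts, metrics and
#'   a \code{matches} data.frame (detection index, gt id, IoU)
#' @export
evaluate_detection <- function(detections, gt) {
  gt_areas <- tabulate(gt[gt > 0L])
  n_gt <- length(gt_areas)
  pairs <- NULL
  for (k in seq_along(detections)) {
    det <- detections[[k]]
    glab <- gt[det$pixels]
    glab <- glab[glab > 0L]
    if (length(glab) == 0L) next
    inter <- table(glab)
    ids <- as.integer(names(inter))
    iou <- as.numeric(inter) / (det$area + gt_areas[ids] - as.numeric(inter))
    pairs <- rbind(pairs, data.frame(det = k, gt = ids, iou = iou))
  }
  matches <- data.frame(det = integer(0), gt = integer(0), iou = numeric(0))
  if (!is.null(pairs)) {
    pairs <- pairs[pairs$iou > 0.5, , drop = FALSE]  # strict inequality
    pairs <- pairs[order(-pairs$iou, pairs$det, pairs$gt), , drop = FALSE]
    used_det <- logical(length(detections))
    used_gt <- logical(n_gt)
    for (rix in seq_len(nrow(pairs))) {
      d <- pairs$det[rix]; g <- pairs$gt[rix]
      if (!used_det[d] && !used_gt[g]) {
        used_det[d] <- TRUE
        used_gt[g] <- TRUE
        matches <- rbind(matches, pairs[rix, ])
      }
    }
  }
  tp <- nrow(matches)
  fp <- length(detections) - tp
  fn <- n_gt - tp
  structure(c(list(tp = tp, fp = fp, fn = fn, matches = matches),
              prf(tp, fp, fn)),
            class = "gs_detection_result")
}

#' @export
print.gs_detection_result <- function(x, ...) {
  cat(sprintf("<detection TP=%d FP=%d FN=%d P=%.3f R=%.3f F=%.3f>\n",
              x$tp, x$fp, x$fn, x$precision, x$recall, x$f_score))
  invisible(x)
}

#' Evaluate segmentation at the pixel level
#'
#' Pixel-by-pixel comparison of the union of detected gland pixels against
#' the union of ground-truth gland pixels. Counts conserve:
#' tp + fp + fn + tn = number of image pixels.
#'
#' @param detections list of proposal regions flagged as glands
#' @param gt an instance mask
#' @return list of class \code{gs_pixel_result} with counts and metrics
#' @export
evaluate_pixels <- function(detections, gt) {
  shape <- dim(gt)
  pred <- matrix(FALSE, shape[1L], shape[2L])
  for (det in detections) pred[det$pixels] <- TRUE
  truth <- unclass(gt) > 0L
  tp <- sum(pred & truth)
  fp <- sum(pred & !truth)
  fn <- sum(!pred & truth)
  tn <- sum(!pred & !truth)
  structure(c(list(tp = tp, fp = fp, fn = fn, tn = tn), prf(tp, fp, fn)),
            class = "gs_pixel_result")
}

#' @export
print.gs_pixel_result <- function(x, ...) {
  cat(sprintf("<pixels TP=%d FP=%d FN=%d TN=%d P=%.3f R=%.3f F=%.3f>\n",
              x$tp, x$fp, x$fn, x$tn, x$precision, x$recall, x$f_score))
  invisible(x)
}

#' Detection precision-recall curve and average precision
#'
#' For every threshold, proposals with score at or above it are treated as
#' detections and matched with [evaluate_detection()]. Average precision uses
#' step interpolation (no trapezoids): with points ordered by increasing
#' recall, \code{AP = sum((R_k - R_(k-1)) * P_k)} starting from recall 0;
#' points with undefined precision contribute nothing (their recall step is
#' zero).
#'
#' @param scored list of scored proposals
#' @param gt an instance mask
#' @param thresholds increasing vector of score thresholds
#' @return list with \code{curve} (data.frame threshold/recall/precision) and
#'   \code{average_precision}
#' @export
pr_curve <- function(scored, gt, thresholds = seq(0, 1, by = 0.05)) {
  stopifnot(!is.unsorted(thresholds))
  rows <- lapply(thresholds, function(th) {
    det <- lapply(Filter(function(s) s$score >= th, scored), `[[`, "region")
    r <- evaluate_detection(det, gt)
    data.frame(threshold = th, recall = r$recall, precision = r$precision,
               tp = r$tp, fp = r$fp, fn = r$fn)
  })
  curve <- do.call(rbind, rows)
  ord <- order(curve$recall, -curve$threshold, na.last = FALSE)
  rc <- curve$recall[ord]
  pc <- curve$precision[ord]
  rc[is.na(rc)] <- 0
  ap <- 0
  prev <- 0
  for (k in seq_along(rc)) {
    if (!is.na(pc[k]) && rc[k] > prev) {
      ap <- ap + (rc[k] - prev) * pc[k]
      prev <- rc[k]
    }
  }
  list(curve = curve, average_precision = ap)
}
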