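#' Match predictions to ground truth by IoU
#'
#' The TP/FP/FN bookkeeping behind every detection metric. Per image,
#' predictions are visited in order of descending confidence (ties by input
#' order) and each is greedily matched to the still-unmatched ground-truth
#' box of highest IoU, provided that IoU is at or above `iou_threshold`
#' (ties on IoU go to the lowest ground-truth index). A matched prediction
#' is a true positive; an unmatched prediction is a false positive ("no
#' associated GT bounding box"); a ground-truth box left unmatched is a
#' false negative. Each ground-truth box is matched at most once, so
#' `TP + FN` equals the number of ground-truth boxes, per image and in
#' aggregate.
#'
#' @param predictions A `"detections"` object. Every `image_id` must be in
#'   the ground-truth universe.
#' @param gt A `"ground_truth"` object.
#' @param iou_threshold Matching threshold; default 0.5.
#' @return A list of class `"match_result"`: `detections` (data frame with
#'   `image_id`, `score`, `label` in `"TP"`/`"FP"`, in input order),
#'   `fn_per_image` (named integer), `n_gt`, `tp`, `fp`, `fn`,
#'   `iou_threshold`.
#' @export
match_detections <- function(predictions, gt, iou_threshold = 0.5) {
  predictions <- validate_detections(predictions)
  stopifnot(inherits(gt, "ground_truth"))
  universe <- gt_images(gt)
  missing <- setdiff(unique(predictions$image_id), universe)
  if (length(missing) > 0) {
    stop("prediction image(s) absent from ground truth: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  label <- rep(NA_character_, nrow(predictions))
  fn_per_image <- stats::setNames(integer(length(universe)), universe)
  for (img in universe) {
    g <- gt_boxes(gt, img)
    pred_idx <- which(predictions$image_id == img)
    ord <- pred_idx[order(-predictions$score[pred_idx])]
    matched_gt <- rep(FALSE, nrow(g))
    for (i in ord) {
      if (nrow(g) == 0) { label[i] <- "FP"; next }
      ious <- iou(det_boxes(predictions[i, , drop = FALSE]), g)
      ious[matched_gt] <- -Inf
      best <- which.max(ious)   # ties -> lowest ground-truth index
      if (length(best) == 1 && ious[best] >= iou_threshold) {
        matched_gt[best] <- TRUE
        label[i] <- "TP"
      } else {
        label[i] <- "FP"
      }
    }
    fn_per_image[img] <- sum(!matched_gt)
  }
  structure(list(
    detections = data.frame(image_id = predictions$image_id,
                            score = predictions$score, label = label,
                            stringsAsFactors = FALSE),
    fn_per_image = fn_per_image,
    n_gt = nrow(gt),
    tp = sum(label == "TP"),
    fp = sum(label == "FP"),
    fn = sum(fn_per_image),
    iou_threshold = iou_threshold
  ), class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat("<match_result @ IoU >= ", x$iou_threshold, ": TP=", x$tp,
      " FP=", x$fp, " FN=", x$fn, " (GT boxes: ", x$n_gt, ")>\n", sep = "")
  invisible(x)
}

#' Precision-recall curve and average precision of matched detections
#'
#' Sweeps the ranked predictions from most to least confident (ties by
#' input order), accumulating precision `TP / (TP + FP)` and recall
#' `TP / (TP + FN)`. Average precision is the area under the precision
#' *envelope* — for each recall level the maximum precision achieved at
#' that recall or beyond — integrated over recall ("all-points"
#' interpolation, the discrete form of the continuous
#' `integral of P(R) dR`). With a single class, mAP equals this AP.
#'
#' @param match A `"match_result"` from [match_detections()].
#' @return A data frame of class `"pr_curve"` with columns `score`,
#'   `recall`, `precision`, `envelope`, and attributes `ap` and `n_gt`.
#'   `average_precision()` returns the scalar AP in `[0, 1]`.
#' @export
pr_curve <- function(match) {
  stopifnot(inherits(match, "match_result"))
  if (match$n_gt == 0) {
    stop("average precision is undefined with zero ground-truth boxes",
         call. = FALSE)
  }
  d <- match$detections
  ord <- order(-d$score)
  d <- d[ord, , drop = FALSE]
  tp <- cumsum(d$label == "TP")
  fp <- cumsum(d$label == "FP")
  precision <- if (nrow(d) > 0) tp / (tp + fp) else numeric()
  recall <- if (nrow(d) > 0) tp / match$n_gt else numeric()
  envelope <- if (nrow(d) > 0) rev(cummax(rev(precision))) else numeric()
  ap <- if (nrow(d) > 0) sum(diff(c(0, recall)) * envelope) else 0
  out <- data.frame(score = d$score, recall = recall, precision = precision,
                    envelope = envelope)
  attr(out, "ap") <- ap
  attr(out, "n_gt") <- match$n_gt
  class(out) <- c("pr_curve", "data.frame")
  out
}

#' @rdname pr_curve
#' @export
average_precision <- function(match) {
  attr(pr_curve(match), "ap")
}

#' @export
plot.pr_curve <- function(x, ..., main = "Precision-recall curve") {
  r <- c(0, x$recall)
  p <- c(if (nrow(x) > 0) x$envelope[1] else 1, x$envelope)
  graphics::plot(r, p, type = "s", xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "Recall", ylab = "Precision", main = main, ...)
  graphics::points(x$recall, x$precision, pch = 20, cex = 0.6)
  graphics::legend("topright", bty = "n",
                   legend = sprintf("AP = %.4f", attr(x, "ap")))
  invisible(x)
}

#' Binary classification metrics from confusion counts
#'
#' The standard suite reported for CXR abnormality classifiers: accuracy,
#' sensitivity (recall), precision, F-score, Matthews correlation
#' coefficient and Cohen's kappa. MCC uses all four confusion cells and is
#' therefore informative on imbalanced data; when its denominator is zero
#' (a degenerate all-one-class classifier) it is returned as 0 with
#' `mcc_undefined = TRUE`.
#'
#' @param tp,tn,fp,fn Non-negative confusion counts, `tp+tn+fp+fn > 0`.
#' @return A list with `accuracy`, `sensitivity`, `precision`, `f_score`,
#'   `mcc`, `kappa`, `mcc_undefined`.
#' @examples
#' classification_metrics(tp = 50, tn = 40, fp = 10, fn = 20)
#' @export
classification_metrics <- function(tp, tn, fp, fn) {
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(counts < 0) || any(!is.finite(counts))) {
    stop("confusion counts must be non-negative", call. = FALSE)
  }
  n <- sum(counts)
  if (n == 0) stop("empty confusion matrix", call. = FALSE)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  f <- if (isTRUE(prec + sens > 0)) 2 * prec * sens / (prec + sens) else 0
  mcc_den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc_undefined <- !is.finite(mcc_den) || mcc_den == 0
  mcc <- if (mcc_undefined) 0 else (tp * tn - fp * fn) / mcc_den
  po <- (tp + tn) / n
  pe <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2
  kappa <- if (pe < 1) (po - pe) / (1 - pe) else 1
  list(accuracy = po, sensitivity = sens, precision = prec, f_score = f,
       mcc = mcc, kappa = kappa, mcc_undefined = mcc_undefined)
}

#' Binomial proportion confidence intervals
#'
#' Two 95% (by default) intervals for a proportion: the exact
#' Clopper-Pearson interval from Beta-distribution quantiles (lower bound 0
#' when `k = 0`, upper bound 1 when `k = n`), and the normal approximation
#' `p +/- z * sqrt(p (1 - p) / n)` clipped to `[0, 1]`. Either the success
#' count `k` or the proportion `p` may be given (a non-integer `k = p * n`
#' is accepted by the Beta form).
#'
#' @param k Number of successes (or `NULL` if `p` is given).
#' @param n Number of trials, `> 0`.
#' @param p Proportion in `[0, 1]` (or `NULL` if `k` is given).
#' @param level Confidence level; default 0.95.
#' @param method `"clopper_pearson"` (default) or `"normal"`.
#' @return Named numeric vector `c(lower, upper)`.
#' @examples
#' binomial_ci(k = 0, n = 10)                      # (0, 0.3085)
#' binomial_ci(p = 0.2865, n = 1200, method = "normal")
#' @export
binomial_ci <- function(k = NULL, n, p = NULL, level = 0.95,
                        method = c("clopper_pearson", "normal")) {
  method <- match.arg(method)
  if (!is.finite(n) || n <= 0) stop("n must be > 0", call. = FALSE)
  if (is.null(k) && is.null(p)) stop("give k or p", call. = FALSE)
  if (is.null(k)) {
    if (p < 0 || p > 1) stop("p must lie in [0, 1]", call. = FALSE)
    k <- p * n
  }
  if (k < 0 || k > n) stop("k must lie in [0, n]", call. = FALSE)
  if (is.null(p)) p <- k / n
  alpha <- 1 - level
  if (method == "clopper_pearson") {
    lower <- if (k <= 0) 0 else stats::qbeta(alpha / 2, k, n - k + 1)
    upper <- if (k >= n) 1 else stats::qbeta(1 - alpha / 2, k + 1, n - k)
  } else {
    z <- stats::qnorm(1 - alpha / 2)
    half <- z * sqrt(p * (1 - p) / n)
    lower <- max(0, p - half)
    upper <- min(1, p + half)
  }
  c(lower = lower, upper = upper)
}

#' End-to-end detection evaluation
#'
#' The full evaluation pipeline for one prediction set: apply the strict
#' confidence filter (scores must exceed `confidence_threshold`), match
#' against ground truth at `iou_threshold`, compute the PR curve and AP
#' (single class, so mAP = AP), and attach a binomial confidence interval
#' for the mAP treated as a proportion at `n_for_ci` trials.
#'
#' @inheritParams match_detections
#' @param confidence_threshold Strict lower bound on scores; default 0.9.
#' @param n_for_ci Number of trials for the mAP confidence interval
#'   (typically the number of test images); `NULL` for no interval.
#' @param ci_method Passed to [binomial_ci()].
#' @param ci_level Confidence level; default 0.95.
#' @return A list of class `"detection_eval"`: `map`, `ap`, `ci`,
#'   `pr` (a `"pr_curve"`), `match` (the `"match_result"`), and the
#'   thresholds used.
#' @export
evaluate_detections <- function(predictions, gt, iou_threshold = 0.5,
                                confidence_threshold = 0.9,
                                n_for_ci = NULL,
                                ci_method = c("clopper_pearson", "normal"),
                                ci_level = 0.95) {
  ci_method <- match.arg(ci_method)
  kept <- filter_by_confidence(predictions, confidence_threshold)
  m <- match_detections(kept, gt, iou_threshold)
  pr <- pr_curve(m)
  ap <- attr(pr, "ap")
  ci <- if (!is.null(n_for_ci)) {
    binomial_ci(p = ap, n = n_for_ci, level = ci_level, method = ci_method)
  }
  structure(list(map = ap, ap = ap, ci = ci, ci_method = ci_method,
                 ci_level = ci_level, n_for_ci = n_for_ci, pr = pr,
                 match = m, iou_threshold = iou_threshold,
                 confidence_threshold = confidence_threshold),
            class = "detection_eval")
}

#' @export
print.detection_eval <- function(x, ...) {
  cat("Detection evaluation (IoU >= ", x$iou_threshold,
      ", confidence > ", x$confidence_threshold, ")\n", sep = "")
  cat("  TP=", x$match$tp, " FP=", x$match$fp, " FN=", x$match$fn,
      "  (GT boxes: ", x$match$n_gt, ")\n", sep = "")
  cat(sprintf("  mAP = %.4f", x$map))
  if (!is.null(x$ci)) {
    cat(sprintf("  %d%% CI (%s): (%.4f, %.4f)", round(100 * x$ci_level),
                x$ci_method, x$ci[["lower"]], x$ci[["upper"]]))
  }
  cat("\n")
  invisible(x)
}

#' @export
plot.detection_eval <- function(x, ...) {
  plot(x$pr, ...)
}
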