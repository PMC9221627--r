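# Independent brute-force oracles used to freeze expected values.
# These deliberately avoid the package's own code paths.

# All-points average precision by explicit suffix-max envelope integration:
# rank by descending score, and for every step where recall increases add
# (R_i - R_{i-1}) * max{ P_j : j >= i } computed by a literal loop.
ap_oracle <- function(labels, scores, n_gt) {
  ord <- order(-scores)
  labels <- labels[ord]
  n <- length(labels)
  if (n == 0 || n_gt == 0) return(if (n_gt == 0) NA_real_ else 0)
  tp <- 0; fp <- 0
  precision <- numeric(n)
  recall <- numeric(n)
  for (i in seq_len(n)) {
    if (labels[i] == "TP") tp <- tp + 1 else fp <- fp + 1
    precision[i] <- tp / (tp + fp)
    recall[i] <- tp / n_gt
  }
  ap <- 0
  prev_r <- 0
  for (i in seq_len(n)) {
    if (recall[i] > prev_r) {
      env <- 0
      for (j in i:n) if (precision[j] > env) env <- precision[j]
      ap <- ap + (recall[i] - prev_r) * env
      prev_r <- recall[i]
    }
  }
  ap
}

# Brute-force bilinear resampling with half-pixel centers and edge clamping,
# one output pixel at a time.
bilinear_oracle <- function(img, h_out, w_out) {
  h_in <- nrow(img); w_in <- ncol(img)
  out <- matrix(0, h_out, w_out)
  for (i in seq_len(h_out)) {
    for (j in seq_len(w_out)) {
      sy <- min(max((i - 0.5) * h_in / h_out - 0.5, 0), h_in - 1)
      sx <- min(max((j - 0.5) * w_in / w_out - 0.5, 0), w_in - 1)
      y0 <- min(floor(sy), h_in - 1); y1 <- min(y0 + 1, h_in - 1)
      x0 <- min(floor(sx), w_in - 1); x1 <- min(x0 + 1, w_in - 1)
      fy <- sy - y0; fx <- sx - x0
      out[i, j] <-
        img[y0 + 1, x0 + 1] * (1 - fy) * (1 - fx) +
        img[y0 + 1, x1 + 1] * (1 - fy) * fx +
        img[y1 + 1, x0 + 1] * fy * (1 - fx) +
        img[y1 + 1, x1 + 1] * fy * fx
    }
  }
  out
}

# Straightforward clip-and-rescale contrast oracle.
stretch_oracle <- function(img, lo_pct, hi_pct, range = c(0, 255)) {
  lo <- quantile(img, lo_pct / 100, names = FALSE, type = 7)
  hi <- quantile(img, hi_pct / 100, names = FALSE, type = 7)
  if (hi <= lo) return(img)
  clipped <- pmin(pmax(img, lo), hi)
  (clipped - lo) / (hi - lo) * (range[2] - range[1]) + range[1]
}

# Random small matching instance: a handful of GT boxes and predictions on
# one image, on a coarse grid so overlaps at every IoU level occur.
random_match_instance <- function(n_pred_max = 6, n_gt_max = 4) {
  n_gt <- sample(1:n_gt_max, 1)
  n_pred <- sample(0:n_pred_max, 1)
  mk <- function(n) {
    if (n == 0) {
      return(boxes(numeric(), numeric(), numeric(), numeric()))
    }
    x1 <- sample(0:8, n, replace = TRUE)
    y1 <- sample(0:8, n, replace = TRUE)
    boxes(x1, y1, x1 + sample(2:6, n, replace = TRUE),
          y1 + sample(2:6, n, replace = TRUE))
  }
  gt <- ground_truth_set(rep("img", n_gt), mk(n_gt))
  pred <- if (n_pred == 0) {
    detection_records(character(), mk(0), numeric(), character())
  } else {
    detection_records(rep("img", n_pred), mk(n_pred),
                      round(runif(n_pred), 3), "m1")
  }
  list(gt = gt, pred = pred)
}
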