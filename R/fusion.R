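#' Ensemble configuration
#'
#' Describes a weighted-averaging detection ensemble: the member models in
#' rank order (best first), their weights, the IoU threshold at which member
#' predictions are grouped into one cluster, the confidence filter applied
#' before fusion, and the minimum number of member votes a cluster needs to
#' emit a fused box.
#'
#' The default weights follow the empirical rank weighting 1, 0.9, 0.8 for
#' the 1st, 2nd and 3rd best member (extended by further 0.1 steps, floored
#' at 0.1, should more members be supplied).
#'
#' @param member_ids Character vector of model ids, best first.
#' @param member_weights Positive weights aligned with `member_ids`;
#'   default [rank_weights()].
#' @param iou_group_threshold IoU at or above which a member prediction
#'   joins a cluster seed; default 0.5.
#' @param confidence_threshold Scores must be strictly greater than this to
#'   survive filtering; default 0.9.
#' @param min_votes Minimum contributors for a cluster to yield a fused
#'   box; default 1 (single-model boxes survive).
#' @param normalize_score_by_all If `TRUE`, the fused score is divided by
#'   the sum of all member weights instead of the contributing weights,
#'   penalizing partial agreement; default `FALSE`.
#' @return A list of class `"ensemble_config"`.
#' @export
ensemble_config <- function(member_ids,
                            member_weights = rank_weights(length(member_ids)),
                            iou_group_threshold = 0.5,
                            confidence_threshold = 0.9,
                            min_votes = 1L,
                            normalize_score_by_all = FALSE) {
  member_ids <- as.character(member_ids)
  if (length(member_ids) == 0) stop("need at least one member", call. = FALSE)
  if (anyDuplicated(member_ids)) stop("duplicate member ids", call. = FALSE)
  if (length(member_weights) != length(member_ids)) {
    stop("member_weights must align with member_ids", call. = FALSE)
  }
  if (any(member_weights <= 0)) stop("weights must be > 0", call. = FALSE)
  if (iou_group_threshold < 0 || iou_group_threshold > 1) {
    stop("iou_group_threshold must lie in [0, 1]", call. = FALSE)
  }
  if (confidence_threshold < 0 || confidence_threshold > 1) {
    stop("confidence_threshold must lie in [0, 1]", call. = FALSE)
  }
  min_votes <- as.integer(min_votes)
  if (min_votes < 1) stop("min_votes must be >= 1", call. = FALSE)
  structure(list(member_ids = member_ids,
                 member_weights = as.numeric(member_weights),
                 iou_group_threshold = iou_group_threshold,
                 confidence_threshold = confidence_threshold,
                 min_votes = min_votes,
                 normalize_score_by_all = normalize_score_by_all),
            class = "ensemble_config")
}

#' @export
print.ensemble_config <- function(x, ...) {
  cat("<ensemble_config>\n")
  cat("  members:", paste(sprintf("%s (w=%g)", x$member_ids,
                                  x$member_weights), collapse = ", "), "\n")
  cat("  iou_group_threshold:", x$iou_group_threshold,
      " confidence_threshold: >", x$confidence_threshold,
      " min_votes:", x$min_votes, "\n")
  invisible(x)
}

#' Rank weights for ensemble members
#'
#' The empirical per-rank weights 1, 0.9, 0.8 assigned to the predictions
#' of the 1st, 2nd and 3rd best performing member, continued in 0.1 steps
#' (floored at 0.1) beyond rank 3.
#'
#' @param k Number of members.
#' @return Numeric vector of length `k`.
#' @export
rank_weights <- function(k) {
  pmax(1 - 0.1 * (seq_len(k) - 1), 0.1)
}

#' Rank validation scores and build the default ensemble
#'
#' Sorts candidate models by their validation mAP (descending; ties broken
#' by model id for a stable, documented order), keeps the top `top_k`, and
#' assigns the rank weights 1, 0.9, 0.8.
#'
#' @param validation_scores Named numeric vector (or list), model id ->
#'   validation mAP.
#' @param top_k How many members to keep; default 3 (or fewer if fewer
#'   candidates exist).
#' @param ... Further arguments passed to [ensemble_config()].
#' @return An `"ensemble_config"`.
#' @examples
#' rank_and_weight(c(A = 0.2865, B = 0.2859, C = 0.2763, D = 0.25))
#' @export
rank_and_weight <- function(validation_scores, top_k = 3L, ...) {
  scores <- unlist(validation_scores)
  if (length(scores) == 0) stop("no validation scores given", call. = FALSE)
  if (is.null(names(scores)) || any(!nzchar(names(scores)))) {
    stop("validation_scores must be named by model id", call. = FALSE)
  }
  ord <- order(-scores, names(scores))
  keep <- ord[seq_len(min(top_k, length(scores)))]
  ensemble_config(names(scores)[keep], rank_weights(length(keep)), ...)
}

#' Confidence filtering of predictions
#'
#' Keeps the records whose confidence score is strictly greater than the
#' threshold (the evaluation convention "all the predictions with a
#' confidence score over 0.9": a score of exactly 0.9 is dropped). Input
#' order is preserved.
#'
#' @param records A `"detections"` object.
#' @param threshold Probability; default 0.9.
#' @return A `"detections"` object.
#' @export
filter_by_confidence <- function(records, threshold = 0.9) {
  records <- validate_detections(records)
  validate_detections(records[records$score > threshold, , drop = FALSE])
}

#' Greedy non-maximum suppression
#'
#' Repeatedly keeps the highest-score record of one image and discards all
#' remaining records whose IoU with it is at or above the threshold. Ties
#' on score are broken by input order. Idempotent.
#'
#' @param records A `"detections"` object whose rows share one `image_id`.
#' @param iou_threshold Suppression threshold; default 0.5.
#' @return The surviving records, highest score first.
#' @export
nms <- function(records, iou_threshold = 0.5) {
  records <- validate_detections(records)
  if (nrow(records) <= 1) return(records)
  if (length(unique(records$image_id)) > 1) {
    stop("nms expects records of a single image; got: ",
         paste(unique(records$image_id), collapse = ", "), call. = FALSE)
  }
  ord <- order(-records$score)
  records <- records[ord, , drop = FALSE]
  b <- det_boxes(records)
  keep <- logical(nrow(records))
  alive <- rep(TRUE, nrow(records))
  for (i in seq_len(nrow(records))) {
    if (!alive[i]) next
    keep[i] <- TRUE
    rest <- which(alive & seq_len(nrow(records)) > i)
    if (length(rest) > 0) {
      ious <- iou(b[i, , drop = FALSE], b[rest, , drop = FALSE])
      alive[rest[ious >= iou_threshold]] <- FALSE
    }
  }
  validate_detections(records[keep, , drop = FALSE])
}

#' Per-image, per-model NMS over a full prediction set
#'
#' Convenience wrapper applying [nms()] within each (image, model) group,
#' mirroring the processing order in which suppression happens inside each
#' detector before ensembling.
#'
#' @inheritParams nms
#' @return A `"detections"` object.
#' @export
nms_by_image <- function(records, iou_threshold = 0.5) {
  records <- validate_detections(records)
  if (nrow(records) == 0) return(records)
  parts <- split(seq_len(nrow(records)),
                 list(records$image_id, records$model_id), drop = TRUE)
  out <- lapply(parts, function(idx) {
    nms(records[idx, , drop = FALSE], iou_threshold)
  })
  validate_detections(do.call(rbind, c(out, list(make.row.names = FALSE))))
}

#' Weighted-averaging bounding-box ensemble
#'
#' Fuses the (already confidence-filtered and per-member suppressed)
#' predictions of several detectors into ensemble boxes. Per image:
#'
#' 1. all member records are pooled, each tagged with its member's rank
#'    weight;
#' 2. clusters are seeded greedily in order of descending weighted score
#'    (`weight * score`; ties by input order). A remaining record joins the
#'    cluster when its IoU with the *seed* box reaches
#'    `iou_group_threshold` and its model is not yet represented in the
#'    cluster (at most one record per member per cluster);
#' 3. every cluster with at least `min_votes` contributors yields a fused
#'    box whose corner coordinates and score are the weighted means over
#'    the contributing members, normalized by the sum of the contributing
#'    weights (so unanimous identical predictions fuse to themselves).
#'
#' Fusion never consults ground truth: grouping is among predictions only,
#' and IoU against ground truth appears only in evaluation.
#'
#' @param records A `"detections"` object; every `model_id` must be one of
#'   `config$member_ids`.
#' @param config An [ensemble_config()].
#' @param apply_confidence_filter Apply the config's strict confidence
#'   filter before fusing; default `TRUE`.
#' @return A `"detections"` object with `model_id = "ensemble"`, one row
#'   per fused box, plus columns `n_votes` and attribute `contributors`
#'   (a list of the contributing records per fused box).
#' @export
fuse <- function(records, config, apply_confidence_filter = TRUE) {
  stopifnot(inherits(config, "ensemble_config"))
  records <- validate_detections(records)
  unknown <- setdiff(unique(records$model_id), config$member_ids)
  if (length(unknown) > 0) {
    stop("unknown model id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (apply_confidence_filter) {
    records <- filter_by_confidence(records, config$confidence_threshold)
  }
  weights <- stats::setNames(config$member_weights, config$member_ids)
  out <- list()
  contribs <- list()
  for (img in unique(records$image_id)) {
    rows <- records[records$image_id == img, , drop = FALSE]
    w <- weights[rows$model_id]
    ord <- order(-(w * rows$score))
    rows <- rows[ord, , drop = FALSE]
    w <- w[ord]
    b <- det_boxes(rows)
    assigned <- rep(FALSE, nrow(rows))
    for (i in seq_len(nrow(rows))) {
      if (assigned[i]) next
      cluster <- i
      assigned[i] <- TRUE
      for (j in seq_len(nrow(rows))) {
        if (assigned[j] || rows$model_id[j] %in% rows$model_id[cluster]) next
        if (iou(b[i, , drop = FALSE], b[j, , drop = FALSE]) >=
            config$iou_group_threshold) {
          cluster <- c(cluster, j)
          assigned[j] <- TRUE
        }
      }
      if (length(cluster) < config$min_votes) next
      cw <- w[cluster]
      wsum <- sum(cw)
      score_den <- if (config$normalize_score_by_all) {
        sum(config$member_weights)
      } else {
        wsum
      }
      fused <- data.frame(
        image_id = img,
        x1 = sum(cw * rows$x1[cluster]) / wsum,
        y1 = sum(cw * rows$y1[cluster]) / wsum,
        x2 = sum(cw * rows$x2[cluster]) / wsum,
        y2 = sum(cw * rows$y2[cluster]) / wsum,
        score = min(1, sum(cw * rows$score[cluster]) / score_den),
        model_id = "ensemble",
        n_votes = length(cluster),
        stringsAsFactors = FALSE
      )
      out[[length(out) + 1L]] <- fused
      contribs[[length(contribs) + 1L]] <- rows[cluster, , drop = FALSE]
    }
  }
  fused <- if (length(out) == 0) {
    data.frame(image_id = character(), x1 = numeric(), y1 = numeric(),
               x2 = numeric(), y2 = numeric(), score = numeric(),
               model_id = character(), n_votes = integer(),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, c(out, list(make.row.names = FALSE)))
  }
  fused <- validate_detections(fused)
  attr(fused, "contributors") <- contribs
  fused
}
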