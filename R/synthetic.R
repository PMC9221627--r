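#' Synthetic multi-detector scenario specification
#'
#' Describes a seeded simulation of a pneumonia-detection test set: per
#' image a small number of ground-truth boxes (0-2 by default, as in
#' RSNA-style pneumonia annotations), and `n_models` imperfect detectors
#' that each re-propose the ground-truth boxes with Gaussian corner jitter,
#' miss some (with probability `1 - detect_prob`), and add spurious
#' (Poisson) false positives. Confidence scores are IoU-correlated:
#' `score = score_base - score_slope * (1 - IoU with the source box) +
#' noise`, clipped to `[0, 1]`, so better-localized proposals rank higher —
#' the structure that makes ranking-based evaluation meaningful. Spurious
#' boxes have no source box and take IoU 0 in that formula.
#'
#' Identical seeds give identical output. Each model draws from a stream
#' derived as `seed + model index`, so adding a fourth model does not
#' perturb the first three.
#'
#' @param n_images Number of images; default 50.
#' @param boxes_per_image Integer range `c(min, max)` of ground-truth boxes
#'   per image (uniform); default `c(0, 2)`.
#' @param image_size Square image side in pixels; default 512.
#' @param box_size_range Box side range in pixels, uniform; default
#'   `c(48, 160)` (lesion-scale boxes on a 512-px chest image).
#' @param n_models Number of simulated detectors; default 3.
#' @param jitter_sd Gaussian SD of the corner jitter in pixels; default 12.
#' @param detect_prob Probability a ground-truth box is proposed by a
#'   model; default 0.9.
#' @param fp_rate Expected spurious boxes per image per model (Poisson);
#'   default 0.5.
#' @param score_base,score_slope,score_noise_sd Confidence model
#'   parameters; defaults 0.95, 0.3, 0.03.
#' @param seed Integer seed; default 1.
#' @return A list of class `"scenario_spec"`.
#' @export
scenario_spec <- function(n_images = 50L, boxes_per_image = c(0L, 2L),
                          image_size = 512, box_size_range = c(48, 160),
                          n_models = 3L, jitter_sd = 12, detect_prob = 0.9,
                          fp_rate = 0.5, score_base = 0.95,
                          score_slope = 0.3, score_noise_sd = 0.03,
                          seed = 1L) {
  spec <- list(n_images = as.integer(n_images),
               boxes_per_image = as.integer(boxes_per_image),
               image_size = as.numeric(image_size),
               box_size_range = as.numeric(box_size_range),
               n_models = as.integer(n_models),
               jitter_sd = as.numeric(jitter_sd),
               detect_prob = as.numeric(detect_prob),
               fp_rate = as.numeric(fp_rate),
               score_base = as.numeric(score_base),
               score_slope = as.numeric(score_slope),
               score_noise_sd = as.numeric(score_noise_sd),
               seed = as.integer(seed))
  if (spec$n_images < 1) stop("n_images must be >= 1", call. = FALSE)
  if (length(spec$boxes_per_image) != 2 ||
      spec$boxes_per_image[1] < 0 ||
      spec$boxes_per_image[2] < spec$boxes_per_image[1]) {
    stop("boxes_per_image must be c(min, max) with 0 <= min <= max",
         call. = FALSE)
  }
  if (spec$image_size <= 0) stop("image_size must be > 0", call. = FALSE)
  if (length(spec$box_size_range) != 2 || spec$box_size_range[1] <= 0 ||
      spec$box_size_range[2] < spec$box_size_range[1]) {
    stop("box_size_range must be an increasing positive pair", call. = FALSE)
  }
  if (spec$box_size_range[2] > spec$image_size) {
    stop("box_size_range exceeds image_size: boxes cannot fit", call. = FALSE)
  }
  if (spec$n_models < 1) stop("n_models must be >= 1", call. = FALSE)
  if (spec$jitter_sd < 0) stop("jitter_sd must be >= 0", call. = FALSE)
  if (spec$detect_prob < 0 || spec$detect_prob > 1) {
    stop("detect_prob must lie in [0, 1]", call. = FALSE)
  }
  if (spec$fp_rate < 0) stop("fp_rate must be >= 0", call. = FALSE)
  structure(spec, class = "scenario_spec")
}

random_box <- function(image_size, box_size_range) {
  w <- stats::runif(1, box_size_range[1], box_size_range[2])
  h <- stats::runif(1, box_size_range[1], box_size_range[2])
  x1 <- stats::runif(1, 0, image_size - w)
  y1 <- stats::runif(1, 0, image_size - h)
  c(x1, y1, x1 + w, y1 + h)
}

# Clamp a jittered box back to a valid 1-px-minimum extent inside the frame.
fix_degenerate <- function(v, image_size) {
  v[1] <- min(max(v[1], 0), image_size - 1)
  v[2] <- min(max(v[2], 0), image_size - 1)
  v[3] <- min(max(v[3], v[1] + 1), image_size)
  v[4] <- min(max(v[4], v[2] + 1), image_size)
  v
}

#' Generate a synthetic multi-detector scenario
#'
#' @param spec A [scenario_spec()].
#' @return A list with `ground_truth` (a `"ground_truth"` over all images,
#'   including those with zero boxes) and `predictions` (a `"detections"`
#'   object pooling every model, `model_id` of the form `"m1" ... "mK"`).
#' @examples
#' sc <- generate_scenario(scenario_spec(n_images = 5, seed = 7))
#' table(sc$predictions$model_id)
#' @export
generate_scenario <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  image_ids <- sprintf("img%04d", seq_len(spec$n_images))

  set.seed(spec$seed)
  support <- seq(spec$boxes_per_image[1], spec$boxes_per_image[2])
  n_boxes <- if (length(support) == 1) rep(support, spec$n_images) else
    sample(support, spec$n_images, replace = TRUE)
  gt_rows <- list()
  for (i in seq_len(spec$n_images)) {
    placed <- list()
    for (b in seq_len(n_boxes[i])) {
      # distinct lesions: resample boxes that collide with one already
      # placed in this image (annotations do not duplicate a finding)
      for (try in 1:20) {
        v <- random_box(spec$image_size, spec$box_size_range)
        clear <- all(vapply(placed, function(p) {
          iou(boxes(v[1], v[2], v[3], v[4]),
              boxes(p[1], p[2], p[3], p[4])) < 0.25
        }, logical(1)))
        if (clear) break
      }
      placed[[length(placed) + 1L]] <- v
      gt_rows[[length(gt_rows) + 1L]] <- c(i, v)
    }
  }
  gt_mat <- if (length(gt_rows) > 0) do.call(rbind, gt_rows) else
    matrix(numeric(), 0, 5)
  gt <- ground_truth_set(
    image_ids[gt_mat[, 1]],
    boxes(gt_mat[, 2], gt_mat[, 3], gt_mat[, 4], gt_mat[, 5]),
    images = image_ids
  )

  preds <- list()
  for (m in seq_len(spec$n_models)) {
    set.seed(spec$seed + m)
    model_id <- paste0("m", m)
    for (i in seq_len(spec$n_images)) {
      src <- gt_mat[gt_mat[, 1] == i, , drop = FALSE]
      for (b in seq_len(nrow(src))) {
        if (stats::runif(1) > spec$detect_prob) next
        v <- src[b, 2:5] + stats::rnorm(4, 0, spec$jitter_sd)
        v <- fix_degenerate(v, spec$image_size)
        overlap <- iou(boxes(v[1], v[2], v[3], v[4]),
                       boxes(src[b, 2], src[b, 3], src[b, 4], src[b, 5]))
        s <- spec$score_base - spec$score_slope * (1 - overlap) +
          stats::rnorm(1, 0, spec$score_noise_sd)
        preds[[length(preds) + 1L]] <-
          data.frame(image_id = image_ids[i], x1 = v[1], y1 = v[2],
                     x2 = v[3], y2 = v[4], score = min(max(s, 0), 1),
                     model_id = model_id, stringsAsFactors = FALSE)
      }
      n_fp <- stats::rpois(1, spec$fp_rate)
      for (k in seq_len(n_fp)) {
        v <- random_box(spec$image_size, spec$box_size_range)
        s <- spec$score_base - spec$score_slope +
          stats::rnorm(1, 0, spec$score_noise_sd)
        preds[[length(preds) + 1L]] <-
          data.frame(image_id = image_ids[i], x1 = v[1], y1 = v[2],
                     x2 = v[3], y2 = v[4], score = min(max(s, 0), 1),
                     model_id = model_id, stringsAsFactors = FALSE)
      }
    }
  }
  predictions <- if (length(preds) == 0) {
    detection_records(character(),
                      boxes(numeric(), numeric(), numeric(), numeric()),
                      numeric(), character())
  } else {
    validate_detections(do.call(rbind, c(preds, list(make.row.names = FALSE))))
  }
  list(ground_truth = gt, predictions = predictions)
}

#' Write the worked-example fixture suite
#'
#' Materializes the package's small hand-computed instances as
#' RSNA-dialect CSV files, together with a JSON manifest recording each
#' fixture's files and the outputs the package computes for them:
#'
#' * `ap_worked` — two ground-truth boxes and three ranked predictions
#'   (TP, FP, TP) whose all-points AP is 5/6;
#' * `fusion_worked` — three members with rank weights 1/0.9/0.8
#'   proposing overlapping boxes that fuse to a hand-checkable weighted
#'   mean;
#' * `identity` — three members proposing the identical box, which must
#'   fuse to itself.
#'
#' All fixtures are synthetic: they are constructed in code, not taken
#' from any dataset.
#'
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the manifest as a list.
#' @export
make_fixture_suite <- function(out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()

  # ap_worked: GT g1=(0,0,10,10), g2=(20,20,30,30); predictions
  # p1 = g1 (s=0.99), p2 disjoint (s=0.95), p3 = g2 (s=0.91)
  gt <- ground_truth_set(c("p1", "p1"),
                         boxes(c(0, 20), c(0, 20), c(10, 30), c(10, 30)))
  pred <- detection_records(rep("p1", 3),
                            boxes(c(0, 50, 20), c(0, 50, 20),
                                  c(10, 60, 30), c(10, 60, 30)),
                            c(0.99, 0.95, 0.91), "m1")
  write_rsna_csv(gt, file.path(out_dir, "ap_worked_gt.csv"))
  write_rsna_csv(pred, file.path(out_dir, "ap_worked_pred.csv"))
  ev <- evaluate_detections(pred, gt, confidence_threshold = 0)
  manifest$ap_worked <- list(
    files = c("ap_worked_gt.csv", "ap_worked_pred.csv"),
    kind = "synthetic worked example",
    expected = list(ap = ev$ap)
  )

  # fusion_worked: members m1/m2/m3 (weights 1/0.9/0.8)
  members <- detection_records(
    rep("p1", 3),
    boxes(c(0, 1, 1), c(0, 1, 0), c(10, 11, 11), c(10, 11, 10)),
    c(0.95, 0.92, 0.91), c("m1", "m2", "m3")
  )
  write_rsna_csv(members, file.path(out_dir, "fusion_worked_pred.csv"))
  cfg <- ensemble_config(c("m1", "m2", "m3"))
  fused <- fuse(members, cfg)
  manifest$fusion_worked <- list(
    files = "fusion_worked_pred.csv",
    kind = "synthetic worked example",
    expected = list(box = as.numeric(fused[1, c("x1", "y1", "x2", "y2")]),
                    score = fused$score[1])
  )

  # identity: all members agree exactly
  ident <- detection_records(rep("p1", 3), boxes(0, 0, 10, 10)[rep(1, 3), ],
                             0.95, c("m1", "m2", "m3"))
  write_rsna_csv(ident, file.path(out_dir, "identity_pred.csv"))
  fused_i <- fuse(ident, cfg)
  manifest$identity <- list(
    files = "identity_pred.csv",
    kind = "synthetic worked example",
    expected = list(box = as.numeric(fused_i[1, c("x1", "y1", "x2", "y2")]),
                    score = fused_i$score[1])
  )

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
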