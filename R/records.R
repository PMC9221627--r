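#' Detection records: predicted boxes with scores and source models
#'
#' A `"detections"` object is a data frame with one row per predicted box:
#' columns `image_id` (opaque string), `x1, y1, x2, y2` (corner-form box),
#' `score` (confidence in `[0, 1]`) and `model_id` (the source detector or
#' snapshot, non-empty). Duplicate rows are kept as-is: de-duplication is a
#' semantic choice that belongs to filtering, not storage.
#'
#' @param image_id Character vector of image identifiers.
#' @param boxes A `"boxes"` object (or data frame with `x1..y2`), one row
#'   per record.
#' @param score Numeric confidence scores in `[0, 1]`.
#' @param model_id Character; the source model of each record (recycled).
#' @return A data frame of class `"detections"`.
#' @examples
#' detection_records("p1", boxes(100, 100, 150, 180), 0.95, "m1")
#' @export
detection_records <- function(image_id, boxes, score, model_id = "model1") {
  boxes <- as_boxes(boxes)
  if (nrow(boxes) == 0) {
    df <- data.frame(image_id = character(), x1 = numeric(), y1 = numeric(),
                     x2 = numeric(), y2 = numeric(), score = numeric(),
                     model_id = character(), stringsAsFactors = FALSE)
    return(validate_detections(df))
  }
  df <- data.frame(
    image_id = as.character(image_id),
    x1 = boxes$x1, y1 = boxes$y1, x2 = boxes$x2, y2 = boxes$y2,
    score = as.numeric(score),
    model_id = as.character(model_id),
    stringsAsFactors = FALSE
  )
  validate_detections(df)
}

validate_detections <- function(df) {
  need <- c("image_id", "x1", "y1", "x2", "y2", "score", "model_id")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("detections require column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  validate_boxes(df[, c("x1", "y1", "x2", "y2")])
  if (nrow(df) > 0) {
    if (any(!is.finite(df$score)) || any(df$score < 0) || any(df$score > 1)) {
      stop("scores must lie in [0, 1]", call. = FALSE)
    }
    if (any(is.na(df$model_id)) || any(!nzchar(df$model_id))) {
      stop("model_id must be non-empty for predictions", call. = FALSE)
    }
  }
  df <- df[, union(need, names(df))]
  class(df) <- unique(c("detections", "data.frame"))
  df
}

#' @export
print.detections <- function(x, ...) {
  cat("<detections: ", nrow(x), " boxes, ",
      length(unique(x$image_id)), " image(s), ",
      length(unique(x$model_id)), " model(s)>\n", sep = "")
  print.data.frame(x, ...)
  invisible(x)
}

det_boxes <- function(d) {
  validate_boxes(as.data.frame(d[, c("x1", "y1", "x2", "y2")]))
}

#' Ground-truth box sets
#'
#' A `"ground_truth"` object maps every image in the evaluation universe to
#' its (possibly empty) list of reference boxes. Images with no boxes are
#' represented explicitly through the `images` attribute rather than being
#' omitted, so that negative images contribute to evaluation.
#'
#' @param image_id Character vector, one entry per ground-truth box (an
#'   image with several boxes appears several times; an image with none
#'   appears only in `images`).
#' @param boxes A `"boxes"` object aligned with `image_id`; may have zero
#'   rows.
#' @param images Character vector of all image ids in the universe; defaults
#'   to `unique(image_id)`. Must be a superset of `image_id`.
#' @return A data frame of class `"ground_truth"` with columns `image_id`,
#'   `x1, y1, x2, y2` and attribute `images`.
#' @examples
#' gt <- ground_truth_set(c("a", "a"), boxes(c(0, 20), c(0, 20), c(10, 30),
#'                        c(10, 30)), images = c("a", "b"))
#' gt_images(gt)    # "a" "b": image b has zero boxes
#' @export
ground_truth_set <- function(image_id = character(), boxes = NULL,
                             images = NULL) {
  if (is.null(boxes)) {
    boxes <- validate_boxes(data.frame(x1 = numeric(), y1 = numeric(),
                                       x2 = numeric(), y2 = numeric()))
  }
  boxes <- as_boxes(boxes)
  image_id <- as.character(image_id)
  if (length(image_id) != nrow(boxes)) {
    stop("image_id and boxes must have the same length", call. = FALSE)
  }
  if (is.null(images)) images <- unique(image_id)
  images <- unique(as.character(images))
  if (!all(image_id %in% images)) {
    stop("images must include every image_id carrying a box", call. = FALSE)
  }
  df <- data.frame(image_id = image_id, x1 = boxes$x1, y1 = boxes$y1,
                   x2 = boxes$x2, y2 = boxes$y2, stringsAsFactors = FALSE)
  attr(df, "images") <- images
  class(df) <- unique(c("ground_truth", "data.frame"))
  df
}

#' @rdname ground_truth_set
#' @param gt A `"ground_truth"` object.
#' @export
gt_images <- function(gt) {
  stopifnot(inherits(gt, "ground_truth"))
  attr(gt, "images")
}

#' @rdname ground_truth_set
#' @export
gt_boxes <- function(gt, image_id) {
  stopifnot(inherits(gt, "ground_truth"))
  if (!image_id %in% gt_images(gt)) {
    stop("unknown image: ", image_id, call. = FALSE)
  }
  rows <- gt$image_id == image_id
  validate_boxes(as.data.frame(gt[rows, c("x1", "y1", "x2", "y2")]))
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("<ground_truth: ", nrow(x), " boxes on ", length(gt_images(x)),
      " image(s), ", sum(!gt_images(x) %in% x$image_id),
      " without boxes>\n", sep = "")
  print.data.frame(x, ...)
  invisible(x)
}

# ---- RSNA-dialect CSV ------------------------------------------------------

#' Read and write RSNA-challenge-dialect detection CSV files
#'
#' The exchange format is one row per box with a header
#' `patientId,x,y,width,height` plus, for predictions, a `score` column
#' (accepted alias: `confidence`) and an optional `model` column. Rows with
#' empty `x,y,width,height` declare an image with zero boxes (the
#' negative-image convention of the RSNA pneumonia challenge). Files are
#' UTF-8, comma-separated, `.`-decimal; no locale inference.
#'
#' @param path File path.
#' @param kind `"ground_truth"` or `"prediction"`.
#' @param model_id Default model id for prediction files without a `model`
#'   column.
#' @return `"ground_truth"` or `"detections"` according to `kind`.
#' @export
read_rsna_csv <- function(path, kind = c("ground_truth", "prediction"),
                          model_id = "model1") {
  kind <- match.arg(kind)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(patientId = "character"),
                        encoding = "UTF-8")
  need <- c("patientId", "x", "y", "width", "height")
  if (kind == "prediction") {
    if ("confidence" %in% names(df) && !"score" %in% names(df)) {
      names(df)[names(df) == "confidence"] <- "score"
    }
    need <- c(need, "score")
  }
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  empty <- is.na(df$x) & is.na(df$y) & is.na(df$width) & is.na(df$height)
  full <- df[!empty, , drop = FALSE]
  if (nrow(full) > 0) {
    bad <- which(!is.finite(full$width) | !is.finite(full$height) |
                   full$width <= 0 | full$height <= 0)
    if (length(bad) > 0) {
      stop("non-positive width/height in ", path, " at data row(s) ",
           paste(which(!empty)[bad], collapse = ", "), call. = FALSE)
    }
  }
  b <- if (nrow(full) > 0) {
    boxes_from_xywh(full$x, full$y, full$width, full$height)
  } else {
    boxes(numeric(), numeric(), numeric(), numeric())
  }
  if (kind == "ground_truth") {
    ground_truth_set(full$patientId, b, images = unique(df$patientId))
  } else {
    mid <- if ("model" %in% names(df)) as.character(full$model) else model_id
    detection_records(full$patientId, b, full$score,
                      if (length(mid) == 0) character() else mid)
  }
}

#' @rdname read_rsna_csv
#' @param x A `"ground_truth"` or `"detections"` object.
#' @export
write_rsna_csv <- function(x, path) {
  if (inherits(x, "ground_truth")) {
    xy <- boxes_to_xywh(x[, c("x1", "y1", "x2", "y2")])
    out <- data.frame(patientId = x$image_id, x = xy$x, y = xy$y,
                      width = xy$w, height = xy$h)
    negatives <- setdiff(gt_images(x), x$image_id)
    if (length(negatives) > 0) {
      out <- rbind(out, data.frame(patientId = negatives, x = NA_real_,
                                   y = NA_real_, width = NA_real_,
                                   height = NA_real_))
    }
  } else if (inherits(x, "detections")) {
    xy <- boxes_to_xywh(det_boxes(x))
    out <- data.frame(patientId = x$image_id, x = xy$x, y = xy$y,
                      width = xy$w, height = xy$h, score = x$score,
                      model = x$model_id)
  } else {
    stop("x must be a ground_truth or detections object", call. = FALSE)
  }
  utils::write.csv(out, path, row.names = FALSE, na = "", quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Write predictions in the RSNA submission ("PredictionString") dialect
#'
#' One row per image, `patientId,PredictionString`, where the string packs
#' `score x y width height` quintuples for every predicted box on that
#' image. This is a write-side convenience for challenge submissions; the
#' canonical exchange format remains one row per box ([write_rsna_csv()]).
#'
#' @param d A `"detections"` object.
#' @param path Output file path.
#' @export
write_rsna_submission <- function(d, path) {
  stopifnot(inherits(d, "detections"))
  ids <- unique(d$image_id)
  strings <- vapply(ids, function(id) {
    rows <- d[d$image_id == id, , drop = FALSE]
    xy <- boxes_to_xywh(det_boxes(rows))
    paste(paste(format(rows$score, trim = TRUE, scientific = FALSE),
                format(xy$x, trim = TRUE, scientific = FALSE),
                format(xy$y, trim = TRUE, scientific = FALSE),
                format(xy$w, trim = TRUE, scientific = FALSE),
                format(xy$h, trim = TRUE, scientific = FALSE)),
          collapse = " ")
  }, character(1))
  utils::write.csv(data.frame(patientId = ids, PredictionString = strings),
                   path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

# ---- COCO-style JSON -------------------------------------------------------

#' Read and write COCO-style detection JSON
#'
#' A single JSON document holds `images` (with `id`), `categories` (with
#' `id`, `name`) and `annotations` with `bbox = [x, y, w, h]`. Annotations
#' carrying a `score` field are treated as predictions (with optional
#' `model_id`); annotations without one are ground truth. Only annotations
#' of the configured category are kept (the detection task has a single
#' class).
#'
#' @param path File path.
#' @param category_id Category to keep; default: the single category in the
#'   file (an error if there are several and none is named).
#' @param model_id Default model id for predictions without a `model_id`
#'   field.
#' @return A list with elements `ground_truth` and `predictions`.
#' @export
read_coco_json <- function(path, category_id = NULL, model_id = "model1") {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(doc$images)) stop("COCO file lacks an 'images' array", call. = FALSE)
  images <- vapply(doc$images, function(im) as.character(im$id), character(1))
  known <- if (is.null(doc$categories)) integer() else
    vapply(doc$categories, function(ct) as.integer(ct$id), integer(1))
  if (is.null(category_id)) {
    if (length(known) == 1) category_id <- known
    else if (length(known) == 0) category_id <- NA_integer_
    else stop("several categories present; pick one of: ",
              paste(known, collapse = ", "), call. = FALSE)
  } else if (length(known) > 0 && !category_id %in% known) {
    stop("unknown category id ", category_id, "; known ids: ",
         paste(known, collapse = ", "), call. = FALSE)
  }
  anns <- if (is.null(doc$annotations)) list() else doc$annotations
  gt_rows <- list()
  pred_rows <- list()
  for (a in anns) {
    cid <- if (is.null(a$category_id)) NA_integer_ else as.integer(a$category_id)
    if (!is.na(category_id) && !is.na(cid) && cid != category_id) next
    bb <- as.numeric(unlist(a$bbox))
    row <- list(image_id = as.character(a$image_id),
                x = bb[1], y = bb[2], w = bb[3], h = bb[4])
    if (!is.null(a$score)) {
      row$score <- as.numeric(a$score)
      row$model_id <- if (is.null(a$model_id)) model_id else
        as.character(a$model_id)
      pred_rows[[length(pred_rows) + 1L]] <- row
    } else {
      gt_rows[[length(gt_rows) + 1L]] <- row
    }
  }
  to_boxes <- function(rows) {
    if (length(rows) == 0) {
      return(boxes(numeric(), numeric(), numeric(), numeric()))
    }
    boxes_from_xywh(vapply(rows, `[[`, 0, "x"), vapply(rows, `[[`, 0, "y"),
                    vapply(rows, `[[`, 0, "w"), vapply(rows, `[[`, 0, "h"))
  }
  gt <- ground_truth_set(
    vapply(gt_rows, function(r) r$image_id, character(1)),
    to_boxes(gt_rows), images = images
  )
  preds <- detection_records(
    vapply(pred_rows, function(r) r$image_id, character(1)),
    to_boxes(pred_rows),
    vapply(pred_rows, function(r) r$score, numeric(1)),
    vapply(pred_rows, function(r) r$model_id, character(1))
  )
  list(ground_truth = gt, predictions = preds)
}

#' @rdname read_coco_json
#' @param gt A `"ground_truth"` object.
#' @param predictions A `"detections"` object (may have zero rows).
#' @param category_name Name recorded for the single category.
#' @export
write_coco_json <- function(gt, predictions = NULL, path,
                            category_id = 1L, category_name = "opacity") {
  stopifnot(inherits(gt, "ground_truth"))
  if (is.null(predictions)) {
    predictions <- detection_records(character(),
                                     boxes(numeric(), numeric(), numeric(),
                                           numeric()),
                                     numeric(), character())
  }
  images <- lapply(gt_images(gt), function(id) list(id = id))
  ann <- list()
  k <- 0L
  if (nrow(gt) > 0) {
    xy <- boxes_to_xywh(as.data.frame(gt[, c("x1", "y1", "x2", "y2")]))
    for (i in seq_len(nrow(gt))) {
      k <- k + 1L
      ann[[k]] <- list(id = k, image_id = gt$image_id[i],
                       category_id = category_id,
                       bbox = c(xy$x[i], xy$y[i], xy$w[i], xy$h[i]))
    }
  }
  if (nrow(predictions) > 0) {
    xy <- boxes_to_xywh(det_boxes(predictions))
    for (i in seq_len(nrow(predictions))) {
      k <- k + 1L
      ann[[k]] <- list(id = k, image_id = predictions$image_id[i],
                       category_id = category_id,
                       bbox = c(xy$x[i], xy$y[i], xy$w[i], xy$h[i]),
                       score = predictions$score[i],
                       model_id = predictions$model_id[i])
    }
  }
  doc <- list(images = images,
              categories = list(list(id = category_id, name = category_name)),
              annotations = ann)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
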