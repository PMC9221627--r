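#' Axis-aligned bounding boxes in corner form
#'
#' Construct a set of axis-aligned rectangles in continuous corner
#' coordinates, origin at the top-left of the image, with the half-open
#' interpretation `[x1, x2) x [y1, y2)`. Under this convention the area is
#' exactly `(x2 - x1) * (y2 - y1)` for integer and fractional (fused)
#' coordinates alike, and edge-touching boxes do not overlap. Pixel-inclusive
#' ("+1") area conventions are deliberately not used.
#'
#' @param x1,y1 Left and top coordinates (pixels).
#' @param x2,y2 Right and bottom coordinates (pixels); must satisfy
#'   `x2 > x1` and `y2 > y1` elementwise.
#' @return A data frame of class `"boxes"` with columns `x1`, `y1`, `x2`,
#'   `y2`, one row per box.
#' @examples
#' b <- boxes(0, 0, 10, 10)
#' box_area(b)
#' @export
boxes <- function(x1, y1, x2, y2) {
  df <- data.frame(
    x1 = as.numeric(x1), y1 = as.numeric(y1),
    x2 = as.numeric(x2), y2 = as.numeric(y2)
  )
  validate_boxes(df)
}

validate_boxes <- function(df) {
  if (!all(c("x1", "y1", "x2", "y2") %in% names(df))) {
    stop("boxes require columns x1, y1, x2, y2", call. = FALSE)
  }
  if (nrow(df) > 0) {
    bad <- !is.finite(df$x1) | !is.finite(df$y1) |
      !is.finite(df$x2) | !is.finite(df$y2)
    if (any(bad)) {
      stop("non-finite box coordinates in row(s) ",
           paste(which(bad), collapse = ", "), call. = FALSE)
    }
    degenerate <- df$x2 <= df$x1 | df$y2 <= df$y1
    if (any(degenerate)) {
      stop("zero or negative box extent (x2 <= x1 or y2 <= y1) in row(s) ",
           paste(which(degenerate), collapse = ", "), call. = FALSE)
    }
  }
  class(df) <- unique(c("boxes", class(df)))
  df
}

#' @export
print.boxes <- function(x, ...) {
  cat("<boxes: ", nrow(x), ">\n", sep = "")
  print.data.frame(x, ...)
  invisible(x)
}

as_boxes <- function(x) {
  if (inherits(x, "boxes")) return(x)
  validate_boxes(as.data.frame(x))
}

#' Convert between corner form and x/y/width/height form
#'
#' The RSNA challenge CSV dialect stores boxes as `x, y, width, height`
#' (top-left corner plus extent); everything in this package works in corner
#' form `(x1, y1, x2, y2)`. The two conversions are exact inverses.
#'
#' @param x,y Top-left corner (pixels).
#' @param w,h Width and height (pixels); must be strictly positive.
#' @return `boxes_from_xywh()` returns a `"boxes"` object;
#'   `boxes_to_xywh()` returns a data frame with columns `x, y, w, h`.
#' @examples
#' boxes_from_xywh(10, 20, 30, 40) # corners (10, 20, 40, 60)
#' @export
boxes_from_xywh <- function(x, y, w, h) {
  w <- as.numeric(w)
  h <- as.numeric(h)
  if (any(!is.finite(w)) || any(w <= 0)) {
    stop("width must be strictly positive (offending field: w)", call. = FALSE)
  }
  if (any(!is.finite(h)) || any(h <= 0)) {
    stop("height must be strictly positive (offending field: h)", call. = FALSE)
  }
  boxes(x, y, as.numeric(x) + w, as.numeric(y) + h)
}

#' @rdname boxes_from_xywh
#' @param b A `"boxes"` object.
#' @export
boxes_to_xywh <- function(b) {
  b <- as_boxes(b)
  data.frame(x = b$x1, y = b$y1, w = b$x2 - b$x1, h = b$y2 - b$y1)
}

#' Box areas
#'
#' @param b A `"boxes"` object.
#' @return Numeric vector of areas, `(x2 - x1) * (y2 - y1)`.
#' @export
box_area <- function(b) {
  b <- as_boxes(b)
  (b$x2 - b$x1) * (b$y2 - b$y1)
}

#' Intersection over union of box pairs
#'
#' `iou()` computes the IoU of paired boxes (rows recycled if one argument
#' has a single row); `iou_matrix()` computes the full cross matrix. IoU is
#' the agreement measure used everywhere in the package: grouping member
#' predictions during fusion, suppressing duplicates in NMS, and deciding
#' true positives when matching predictions against ground truth (a
#' prediction counts as a TP when its IoU with a ground-truth box reaches
#' the threshold, conventionally 0.5).
#'
#' Disjoint and edge-touching boxes have IoU 0 (half-open convention);
#' identical boxes have IoU exactly 1.
#'
#' @param a,b `"boxes"` objects.
#' @return `iou()`: numeric vector in `[0, 1]`. `iou_matrix()`: a
#'   `nrow(a) x nrow(b)` matrix.
#' @examples
#' iou(boxes(0, 0, 10, 10), boxes(5, 5, 15, 15)) # 25 / 175
#' @export
iou <- function(a, b) {
  a <- as_boxes(a)
  b <- as_boxes(b)
  if (nrow(a) != nrow(b)) {
    if (nrow(a) == 1) a <- a[rep(1L, nrow(b)), , drop = FALSE]
    else if (nrow(b) == 1) b <- b[rep(1L, nrow(a)), , drop = FALSE]
    else stop("iou: incompatible numbers of boxes (", nrow(a), " vs ",
              nrow(b), ")", call. = FALSE)
  }
  iw <- pmin(a$x2, b$x2) - pmax(a$x1, b$x1)
  ih <- pmin(a$y2, b$y2) - pmax(a$y1, b$y1)
  inter <- pmax(0, iw) * pmax(0, ih)
  inter / (box_area(a) + box_area(b) - inter)
}

#' @rdname iou
#' @export
iou_matrix <- function(a, b) {
  a <- as_boxes(a)
  b <- as_boxes(b)
  out <- matrix(0, nrow(a), nrow(b))
  for (i in seq_len(nrow(a))) {
    out[i, ] <- iou(a[i, , drop = FALSE], b)
  }
  out
}
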