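#' Image preprocessing configuration
#'
#' Settings for the two preprocessing steps applied to grayscale chest
#' X-rays before any detector consumes them: percentile contrast stretching
#' (saturating the darkest and brightest tails) and plain bilinear resizing
#' to a fixed spatial size.
#'
#' @param target_size Output size `c(height, width)` in pixels; default
#'   512 x 512.
#' @param low_saturation,high_saturation Percentiles (0-100) below/above
#'   which intensities are saturated; defaults 1 and 99 (clip the bottom 1%
#'   and top 1% of pixel values). Must satisfy `0 <= low < high <= 100`.
#' @param output_range Intensity bounds of the stretched image; default
#'   `c(0, 255)`.
#' @return A list of class `"image_prep_config"`.
#' @export
image_prep_config <- function(target_size = c(512L, 512L),
                              low_saturation = 1, high_saturation = 99,
                              output_range = c(0, 255)) {
  if (length(target_size) == 1) target_size <- rep(target_size, 2)
  target_size <- as.integer(target_size)
  if (any(target_size <= 0)) stop("target_size must be positive", call. = FALSE)
  if (!(low_saturation >= 0 && low_saturation < high_saturation &&
        high_saturation <= 100)) {
    stop("need 0 <= low_saturation < high_saturation <= 100", call. = FALSE)
  }
  if (length(output_range) != 2 || output_range[2] <= output_range[1]) {
    stop("output_range must be an increasing pair", call. = FALSE)
  }
  structure(list(target_size = target_size,
                 low_saturation = low_saturation,
                 high_saturation = high_saturation,
                 output_range = as.numeric(output_range)),
            class = "image_prep_config")
}

#' Percentile contrast stretching
#'
#' Increases image contrast by saturating the intensity tails: pixel values
#' are clipped at the `low_saturation` and `high_saturation` percentiles of
#' the input image (computed per image, with linear interpolation between
#' order statistics) and then rescaled linearly to `output_range`. A
#' constant image is returned unchanged, since it carries no contrast to
#' stretch. Multi-channel arrays are first collapsed to grayscale by the
#' channel mean.
#'
#' @param image Numeric matrix of intensities (rows = y, columns = x), or a
#'   3-d array with channels in the third dimension.
#' @param config An [image_prep_config()].
#' @return Numeric matrix with values inside `output_range`.
#' @export
contrast_stretch <- function(image, config = image_prep_config()) {
  image <- as_gray_matrix(image)
  lo <- stats::quantile(image, config$low_saturation / 100, names = FALSE,
                        type = 7)
  hi <- stats::quantile(image, config$high_saturation / 100, names = FALSE,
                        type = 7)
  if (hi <= lo) return(image)  # constant (or constant between percentiles)
  clipped <- pmin(pmax(image, lo), hi)
  r <- config$output_range
  out <- (clipped - lo) / (hi - lo) * (r[2] - r[1]) + r[1]
  matrix(out, nrow = nrow(image))
}

as_gray_matrix <- function(image) {
  if (length(dim(image)) == 3) {
    image <- apply(image, c(1, 2), mean)
  }
  if (!is.matrix(image)) image <- as.matrix(image)
  if (length(image) == 0) stop("empty image", call. = FALSE)
  storage.mode(image) <- "double"
  image
}

#' Bilinear image resizing
#'
#' Plain resize to a target size (aspect ratio is not preserved). Each
#' output pixel center is mapped back into the input with the half-pixel-
#' center convention `src = (dst + 0.5) * size_in / size_out - 0.5` (0-based
#' centers), the four surrounding input pixels are blended bilinearly, and
#' coordinates beyond the border are clamped to the edge pixels. Resizing to
#' the input size is the identity.
#'
#' @param image Numeric matrix (rows = y, columns = x).
#' @param target_size `c(height, width)` in pixels (a scalar is used for
#'   both).
#' @return Numeric matrix of dimension `target_size`.
#' @export
resize_image <- function(image, target_size) {
  image <- as_gray_matrix(image)
  if (length(target_size) == 1) target_size <- rep(target_size, 2)
  target_size <- as.integer(target_size)
  if (any(!is.finite(target_size)) || any(target_size <= 0)) {
    stop("target_size must be positive", call. = FALSE)
  }
  h_in <- nrow(image); w_in <- ncol(image)
  h_out <- target_size[1]; w_out <- target_size[2]
  if (h_in == h_out && w_in == w_out) return(image)
  # 0-based source center coordinates, clamped to the valid range
  src_y <- pmin(pmax((seq_len(h_out) - 0.5) * h_in / h_out - 0.5, 0), h_in - 1)
  src_x <- pmin(pmax((seq_len(w_out) - 0.5) * w_in / w_out - 0.5, 0), w_in - 1)
  y0 <- pmin(floor(src_y), h_in - 1); y1 <- pmin(y0 + 1, h_in - 1)
  x0 <- pmin(floor(src_x), w_in - 1); x1 <- pmin(x0 + 1, w_in - 1)
  fy <- src_y - y0; fx <- src_x - x0
  # blend rows first, then columns
  top <- image[y0 + 1, , drop = FALSE]
  bot <- image[y1 + 1, , drop = FALSE]
  rows <- top * (1 - fy) + bot * fy
  left <- rows[, x0 + 1, drop = FALSE]
  right <- rows[, x1 + 1, drop = FALSE]
  left * matrix(1 - fx, h_out, w_out, byrow = TRUE) +
    right * matrix(fx, h_out, w_out, byrow = TRUE)
}

#' Rescale box coordinates alongside a resized image
#'
#' When an image changes size, its annotations must follow. Corner
#' coordinates are multiplied by the per-axis scale factors
#' `target / source`.
#'
#' @param b A `"boxes"` object in the source image's coordinates.
#' @param from_size,to_size `c(height, width)` of the source and target
#'   images.
#' @return A `"boxes"` object in the target image's coordinates.
#' @export
scale_boxes <- function(b, from_size, to_size) {
  b <- as_boxes(b)
  if (length(from_size) == 1) from_size <- rep(from_size, 2)
  if (length(to_size) == 1) to_size <- rep(to_size, 2)
  sy <- to_size[1] / from_size[1]
  sx <- to_size[2] / from_size[2]
  boxes(b$x1 * sx, b$y1 * sy, b$x2 * sx, b$y2 * sy)
}

#' Read and write grayscale images
#'
#' PNG and TIFF input (by file extension), PNG output. Images are held as
#' numeric matrices in `[0, 1]`; color input is collapsed to grayscale by
#' the channel mean. `write_gray_image()` rescales from `range` to `[0, 1]`
#' before encoding.
#'
#' @param path File path (`.png`, `.tif`/`.tiff`).
#' @return `read_gray_image()`: a numeric matrix in `[0, 1]`.
#' @export
read_gray_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext, call. = FALSE)
  )
  as_gray_matrix(img)
}

#' @rdname read_gray_image
#' @param image Numeric matrix.
#' @param range Intensity range of `image`; default taken as `c(0, 1)`.
#' @export
write_gray_image <- function(image, path, range = c(0, 1)) {
  image <- as_gray_matrix(image)
  scaled <- (image - range[1]) / (range[2] - range[1])
  png::writePNG(pmin(pmax(scaled, 0), 1), path)
  invisible(path)
}

#' Full preprocessing of one grayscale image
#'
#' Applies the standard chest-X-ray preparation: percentile contrast
#' stretching followed by bilinear resizing to the configured target size.
#'
#' @param image Numeric matrix, or a path readable by [read_gray_image()].
#' @param config An [image_prep_config()].
#' @return Numeric matrix of dimension `config$target_size` with values in
#'   `config$output_range`.
#' @export
preprocess_image <- function(image, config = image_prep_config()) {
  if (is.character(image)) image <- read_gray_image(image)
  resize_image(contrast_stretch(image, config), config$target_size)
}
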