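#' Calibrated grayscale image
#'
#' Container for a 2D intensity grid together with its spatial calibration.
#' Intensities are kept on whatever scale the source provides (PNG/TIFF
#' readers yield the unit interval); thresholding handles arbitrary scales.
#'
#' @param pixels Numeric matrix of intensities, at least 2 x 2.
#' @param pixel_size Pixel size in micrometres per pixel; must be positive
#'   and finite.
#' @param source_id Free-text provenance label (defaults to "").
#'
#' @return An object of class `gray_image` with fields `pixels`,
#'   `pixel_size` and `source_id`.
#' @export
#' @examples
#' img <- gray_image(matrix(runif(100), 10, 10), pixel_size = 8.1)
#' dim(img$pixels)
gray_image <- function(pixels, pixel_size, source_id = "") {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  }
  if (nrow(pixels) < 2L || ncol(pixels) < 2L) {
    stop("image must have at least 2 rows and 2 columns", call. = FALSE)
  }
  check_pixel_size(pixel_size)
  structure(
    list(pixels = pixels, pixel_size = as.numeric(pixel_size),
         source_id = as.character(source_id)),
    class = "gray_image"
  )
}

#' Binary mask in the slice-foreground convention
#'
#' A 2D grid over \{0, 1\} in which foreground (1) denotes slice tissue and
#' background (0) denotes the agarose/field. The calibration is inherited
#' from the source image.
#'
#' @param pixels Matrix whose values are all exactly 0 or 1.
#' @param pixel_size Micrometres per pixel (> 0, finite).
#' @param threshold Optional intensity threshold that produced the mask,
#'   carried for provenance.
#'
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(pixels, pixel_size, threshold = NULL) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  }
  if (!all(pixels == 0 | pixels == 1)) {
    stop("mask values must all be exactly 0 or 1", call. = FALSE)
  }
  check_pixel_size(pixel_size)
  structure(
    list(pixels = pixels, pixel_size = as.numeric(pixel_size),
         threshold = threshold),
    class = "binary_mask"
  )
}

#' Rectangular region of interest
#'
#' Pixel-index rectangle in 0-based, half-open convention: rows
#' `[row_start, row_end)`, columns `[col_start, col_end)`. This convention
#' is used everywhere ROIs appear (cropping, measurement segments, the
#' command-line `--roi`/`--segments` flags).
#'
#' @param row_start,row_end,col_start,col_end Integer pixel indices,
#'   0-based, half-open; `start < end` on both axes.
#'
#' @return An object of class `rect_roi`.
#' @export
#' @examples
#' rect_roi(0, 10, 5, 20)  # rows 0..9, columns 5..19
rect_roi <- function(row_start, row_end, col_start, col_end) {
  v <- c(row_start, row_end, col_start, col_end)
  if (any(!is.finite(v)) || any(v != floor(v))) {
    stop("ROI bounds must be finite integers", call. = FALSE)
  }
  if (!(row_start < row_end && col_start < col_end)) {
    stop("ROI must satisfy row_start < row_end and col_start < col_end",
         call. = FALSE)
  }
  if (row_start < 0 || col_start < 0) {
    stop("ROI bounds must be non-negative", call. = FALSE)
  }
  structure(
    list(row_start = as.integer(row_start), row_end = as.integer(row_end),
         col_start = as.integer(col_start), col_end = as.integer(col_end)),
    class = "rect_roi"
  )
}

#' Endpoints of the slice principal axis
#'
#' Two distinct points, in 0-based (row, col) pixel coordinates, marking the
#' opposite extremities of the slice band along its long axis. These mirror
#' the two manual extremity picks of an interactive workflow; batch runs
#' obtain them from [estimate_axis()].
#'
#' @param p1,p2 Numeric length-2 vectors, (row, col); must differ.
#'
#' @return An object of class `axis_endpoints`.
#' @export
axis_endpoints <- function(p1, p2) {
  p1 <- as.numeric(p1); p2 <- as.numeric(p2)
  if (length(p1) != 2L || length(p2) != 2L || any(!is.finite(c(p1, p2)))) {
    stop("axis endpoints must be finite (row, col) pairs", call. = FALSE)
  }
  if (all(p1 == p2)) stop("axis endpoints must be distinct", call. = FALSE)
  structure(list(p1 = p1, p2 = p2), class = "axis_endpoints")
}

check_pixel_size <- function(pixel_size) {
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L ||
      !is.finite(pixel_size) || pixel_size <= 0) {
    stop("`pixel_size` must be a single finite positive number (um/pixel)",
         call. = FALSE)
  }
  invisible(pixel_size)
}

roi_check_bounds <- function(roi, dims) {
  stopifnot(inherits(roi, "rect_roi"))
  if (roi$row_end > dims[1L] || roi$col_end > dims[2L]) {
    stop(sprintf(
      "ROI [%d,%d)x[%d,%d) exceeds mask bounds %d x %d",
      roi$row_start, roi$row_end, roi$col_start, roi$col_end,
      dims[1L], dims[2L]), call. = FALSE)
  }
  invisible(roi)
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image> %d x %d px, %.4g um/px%s\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size,
              if (nzchar(x$source_id)) paste0(", ", x$source_id) else ""))
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %d x %d px, %.4g um/px, foreground %d px (%.1f%%)\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size,
              sum(x$pixels), 100 * mean(x$pixels)))
  invisible(x)
}

#' @export
print.rect_roi <- function(x, ...) {
  cat(sprintf("<rect_roi> rows [%d, %d), cols [%d, %d)\n",
              x$row_start, x$row_end, x$col_start, x$col_end))
  invisible(x)
}
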