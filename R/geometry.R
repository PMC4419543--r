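#' Crop a mask to a rectangular region of interest
#'
#' Pixel values are copied unchanged; the calibration is inherited. ROIs use
#' the package-wide 0-based half-open convention (see [rect_roi()]).
#'
#' @param mask A [binary_mask()].
#' @param roi A [rect_roi()] lying within the mask bounds.
#'
#' @return A [binary_mask()] of dimensions
#'   `(row_end - row_start) x (col_end - col_start)`.
#' @export
crop_mask <- function(mask, roi) {
  stopifnot(inherits(mask, "binary_mask"))
  roi_check_bounds(roi, dim(mask$pixels))
  sub <- mask$pixels[(roi$row_start + 1L):roi$row_end,
                     (roi$col_start + 1L):roi$col_end, drop = FALSE]
  binary_mask(sub, mask$pixel_size, mask$threshold)
}

#' Estimate the slice principal axis
#'
#' Batch replacement for manual extremity picks: the axis direction is the
#' first principal component of the foreground pixel coordinates (the
#' largest-eigenvalue eigenvector of their covariance), and the endpoints
#' are the two foreground pixels with extreme projections onto it.
#'
#' An isotropic foreground (equal eigenvalues, e.g. a filled square) has no
#' preferred axis and raises an error.
#'
#' @param mask A [binary_mask()] with at least 2 non-coincident foreground
#'   pixels.
#'
#' @return An [axis_endpoints()] in 0-based (row, col) coordinates, ordered
#'   by increasing projection onto the axis.
#' @export
estimate_axis <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  fp <- which(mask$pixels == 1, arr.ind = TRUE)
  if (nrow(fp) < 2L) {
    stop("axis estimation needs at least 2 foreground pixels", call. = FALSE)
  }
  co <- stats::cov(fp)
  if (all(co == 0)) {
    stop("foreground pixels are coincident; no axis", call. = FALSE)
  }
  e <- eigen(co, symmetric = TRUE)
  lam <- e$values
  if ((lam[1L] - lam[2L]) <= 1e-8 * max(lam[1L], 1)) {
    stop("foreground is isotropic (equal principal variances); axis is ambiguous",
         call. = FALSE)
  }
  v <- e$vectors[, 1L]
  # deterministic orientation: positive row component (ties: positive col)
  if (v[1L] < 0 || (v[1L] == 0 && v[2L] < 0)) v <- -v
  # endpoints are the extreme projections ON the axis line through the
  # centroid: the segment between the two extreme raw pixels would join
  # opposite band corners and tilt off-axis by atan(width/length)
  mu <- colMeans(fp)
  proj <- (fp[, 1L] - mu[1L]) * v[1L] + (fp[, 2L] - mu[2L]) * v[2L]
  p1 <- mu + min(proj) * v - 1
  p2 <- mu + max(proj) * v - 1
  axis_endpoints(unname(p1), unname(p2))
}

#' Angle of an axis from the vertical, in degrees
#'
#' Vertical means the row direction (constant column); after alignment the
#' per-row foreground width is the slice thickness. The angle is normalised
#' to (-90, 90].
#'
#' @param axis An [axis_endpoints()].
#' @return Angle in degrees.
#' @export
axis_angle <- function(axis) {
  stopifnot(inherits(axis, "axis_endpoints"))
  d <- axis$p2 - axis$p1
  ang <- atan2(d[2L], d[1L]) * 180 / pi
  if (ang > 90) ang <- ang - 180
  if (ang <= -90) ang <- ang + 180
  ang
}

#' Rotate a mask so the slice axis is vertical
#'
#' Rotates by the angle taking the axis direction to the vertical (row)
#' direction. The canvas is enlarged to contain all rotated foreground and
#' padded with background. Rotation uses nearest-neighbour interpolation and
#' a 0.5 threshold so the mask stays strictly binary: bilinear interpolation
#' would create fractional pixels that bias the pixel-sum thickness
#' statistic. The foreground count is preserved up to resampling error
#' (warning beyond 2%).
#'
#' @param mask A [binary_mask()].
#' @param axis An [axis_endpoints()]; estimated with [estimate_axis()] when
#'   omitted.
#'
#' @return An axis-aligned [binary_mask()]; `pixel_size` is unchanged.
#' @export
align_vertical <- function(mask, axis = NULL) {
  stopifnot(inherits(mask, "binary_mask"))
  if (is.null(axis)) axis <- estimate_axis(mask)
  ang <- axis_angle(axis)
  if (abs(ang) < 1e-9) return(mask)
  img <- EBImage::Image(t(mask$pixels))
  rot <- EBImage::rotate(img, ang, filter = "none", bg.col = 0)
  out <- (t(EBImage::imageData(rot)) > 0.5) * 1
  n_in <- sum(mask$pixels)
  n_out <- sum(out)
  if (n_in > 0 && abs(n_out - n_in) / n_in > 0.02) {
    warning(sprintf(
      "rotation changed the foreground count by %.1f%% (resampling)",
      100 * abs(n_out - n_in) / n_in), call. = FALSE)
  }
  binary_mask(out, mask$pixel_size, mask$threshold)
}

#' Keep the largest connected foreground object
#'
#' Batch images are assumed to contain a single slice band; isolated specks
#' left by thresholding noise would otherwise distort the coordinate
#' covariance that drives axis estimation and inflate the pixel-sum
#' statistic. Connectivity is 8-neighbour; ties go to the lowest label.
#'
#' @param mask A [binary_mask()] with at least one foreground pixel.
#' @return A [binary_mask()] retaining only the largest component.
#' @export
select_band <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  if (sum(mask$pixels) == 0) {
    stop("mask has no foreground; nothing to select", call. = FALSE)
  }
  lab <- EBImage::bwlabel(EBImage::Image(t(mask$pixels)))
  labs <- EBImage::imageData(lab)
  counts <- tabulate(labs[labs > 0])
  keep <- which.max(counts)
  binary_mask((t(labs) == keep) * 1, mask$pixel_size, mask$threshold)
}
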