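#' Thickness of one rectangular segment
#'
#' The core width statistic: over a rectangular segment of an
#' axis-aligned, foreground-oriented mask, sum the pixel values, divide by
#' the number of pixel rows in the segment, and convert to micrometres with
#' the pixel size. Because the slice axis is vertical, this is the mean
#' per-row foreground width of the band.
#'
#' The segment must span the full width of the band (every row's foreground
#' run inside its columns); rows are the along-axis direction. A segment
#' containing no foreground yields 0 um with a warning rather than an error,
#' so damaged inputs surface in QC reports instead of aborting batch runs.
#'
#' @param mask An aligned, foreground-oriented [binary_mask()].
#' @param segment A [rect_roi()] within the mask bounds.
#'
#' @return Thickness in micrometres (scalar).
#' @export
#' @examples
#' m <- binary_mask(matrix(rep(c(0, 1, 1, 1, 1, 1, 0, 0), each = 10),
#'                         10, 8), pixel_size = 10)
#' segment_thickness(m, rect_roi(0, 10, 0, 8))  # 5 px * 10 um
segment_thickness <- function(mask, segment) {
  stopifnot(inherits(mask, "binary_mask"))
  roi_check_bounds(segment, dim(mask$pixels))
  n_rows <- segment$row_end - segment$row_start
  sub <- mask$pixels[(segment$row_start + 1L):segment$row_end,
                     (segment$col_start + 1L):segment$col_end, drop = FALSE]
  s <- sum(sub)
  if (s == 0) {
    warning("segment contains no foreground; thickness is 0", call. = FALSE)
    return(0)
  }
  (s / n_rows) * mask$pixel_size
}

#' Place measurement segments automatically
#'
#' Batch replacement for interactively dragged rectangles: `n` disjoint
#' full-width horizontal bands, each covering `fraction` of the foreground's
#' row extent, centred at evenly spaced positions along the slice axis
#' (`k / (n + 1)` of the extent; for the default n = 3 that is 25%, 50% and
#' 75%).
#'
#' @param mask An aligned [binary_mask()] with foreground.
#' @param n Number of segments, at least 3.
#' @param fraction Fraction of the foreground row extent covered by each
#'   segment, in (0, 1). Disjointness requires roughly
#'   `fraction <= 1 / (n + 1)`.
#'
#' @return A list of `n` [rect_roi()]s, pairwise disjoint, inside the
#'   foreground row extent.
#' @export
auto_segments <- function(mask, n = 3L, fraction = 0.2) {
  stopifnot(inherits(mask, "binary_mask"))
  if (n < 3L) stop("at least 3 segments are required", call. = FALSE)
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1) {
    stop("`fraction` must lie in (0, 1)", call. = FALSE)
  }
  rows_fg <- which(rowSums(mask$pixels) > 0)
  if (length(rows_fg) == 0L) stop("mask has no foreground", call. = FALSE)
  r0 <- min(rows_fg) - 1L            # 0-based extent start
  extent <- max(rows_fg) - min(rows_fg) + 1L
  h <- max(1L, as.integer(round(fraction * extent)))
  spacing <- extent / (n + 1)
  starts <- integer(n)
  for (k in seq_len(n)) {
    centre <- r0 + spacing * k
    starts[k] <- as.integer(round(centre - h / 2))
  }
  if (any(starts < r0) || any(starts + h > r0 + extent) ||
      any(diff(starts) < h)) {
    stop(sprintf(
      "foreground row extent (%d rows) cannot host %d disjoint segments of %d rows",
      extent, n, h), call. = FALSE)
  }
  lapply(starts, function(s) rect_roi(s, s + h, 0L, ncol(mask$pixels)))
}

#' Measure a slice: per-segment thicknesses, mean, SD and the CV flag
#'
#' Applies [segment_thickness()] to each segment (at least three, the
#' minimum of the measurement protocol) and summarises: arithmetic mean,
#' standard deviation, coefficient of variation CV = SD/mean, and an
#' `irregular` flag raised when CV > 0.25 — the quality-control signal for
#' highly irregular slices. The flag is informative, never fatal.
#'
#' @param mask An aligned, foreground-oriented [binary_mask()].
#' @param segments List of [rect_roi()]s; placed by [auto_segments()] when
#'   omitted.
#' @param n,fraction Passed to [auto_segments()] when `segments` is `NULL`.
#' @param sd_type `"sample"` (n - 1 denominator, default) or
#'   `"population"` (n denominator).
#'
#' @return An object of class `thickness_result` with fields
#'   `segment_values` (um), `mean`, `sd`, `cv`, `n_segments`, `irregular`.
#' @export
measure_slice <- function(mask, segments = NULL, n = 3L, fraction = 0.2,
                          sd_type = c("sample", "population")) {
  stopifnot(inherits(mask, "binary_mask"))
  sd_type <- match.arg(sd_type)
  if (is.null(segments)) segments <- auto_segments(mask, n = n, fraction = fraction)
  if (!is.list(segments) || length(segments) < 3L) {
    stop("at least 3 rectangular segments are required", call. = FALSE)
  }
  vals <- vapply(segments, function(s) segment_thickness(mask, s), numeric(1))
  m <- mean(vals)
  s <- if (sd_type == "sample") stats::sd(vals)
       else sqrt(mean((vals - m)^2))
  cv <- if (m > 0) s / m else NA_real_
  structure(
    list(segment_values = vals, mean = m, sd = s, cv = cv,
         n_segments = length(vals), irregular = isTRUE(cv > 0.25),
         pixel_size = mask$pixel_size, sd_type = sd_type),
    class = "thickness_result"
  )
}

#' @export
print.thickness_result <- function(x, ...) {
  cat(sprintf("Slice thickness: %.2f +/- %.2f um (CV %.3f, n = %d segments)\n",
              x$mean, x$sd, x$cv, x$n_segments))
  if (x$irregular) {
    cat("Warning: highly irregular slice (CV > 0.25)\n")
  }
  invisible(x)
}
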