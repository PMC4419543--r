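#' Load a calibrated cross-section image
#'
#' Reads an 8/16-bit grayscale or 8-bit RGB raster (PNG or TIFF) and attaches
#' the micrometre-per-pixel calibration. RGB inputs are converted to
#' luminance with the BT.709 weights (0.2126 R + 0.7152 G + 0.0722 B); an
#' alpha channel, if present, is ignored. Intensities are returned on the
#' unit interval, as provided by the PNG/TIFF decoders.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @param pixel_size Micrometres per pixel (> 0).
#' @param source_id Provenance label stored with the image; defaults to the
#'   file name.
#'
#' @return A [gray_image()].
#' @export
load_image <- function(path, pixel_size, source_id = basename(path)) {
  check_pixel_size(pixel_size)
  if (!file.exists(path)) {
    stop(sprintf("image file not found: %s", path), call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  arr <- tryCatch(
    switch(ext,
      png  = png::readPNG(path),
      tif  = ,
      tiff = tiff::readTIFF(path),
      stop(sprintf("unsupported image format '.%s' (PNG/TIFF supported)", ext),
           call. = FALSE)
    ),
    error = function(e) {
      stop(sprintf("failed to decode '%s': %s", path, conditionMessage(e)),
           call. = FALSE)
    }
  )
  gray_image(to_luminance(arr), pixel_size, source_id)
}

to_luminance <- function(arr) {
  if (is.matrix(arr)) return(arr)
  if (length(dim(arr)) == 3L) {
    nc <- dim(arr)[3L]
    if (nc == 2L) return(arr[, , 1L])                       # gray + alpha
    if (nc >= 3L) {
      return(0.2126 * arr[, , 1L] + 0.7152 * arr[, , 2L] + 0.0722 * arr[, , 3L])
    }
    if (nc == 1L) return(arr[, , 1L])
  }
  stop("unsupported raster layout (expect 2D grayscale or RGB[A])",
       call. = FALSE)
}

#' Write a grayscale image or mask to PNG/TIFF
#'
#' Companion writer for synthetic fixtures and pipeline overlays. Values are
#' clamped to [0, 1] before encoding. The calibration is not embedded in the
#' file; keep it in the accompanying metadata.
#'
#' @param image A [gray_image()] or [binary_mask()] (masks are written as
#'   0/1 intensities).
#' @param path Output path; format chosen by extension (`.png`, `.tif`,
#'   `.tiff`).
#'
#' @return The path, invisibly.
#' @export
write_image <- function(image, path) {
  px <- image$pixels
  px <- pmin(pmax(px, 0), 1)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png  = png::writePNG(px, path),
    tif  = ,
    tiff = tiff::writeTIFF(px, path, bits.per.sample = 16L),
    stop(sprintf("unsupported output format '.%s'", ext), call. = FALSE)
  )
  invisible(path)
}
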