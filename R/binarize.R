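#' Threshold a grayscale image into a slice mask
#'
#' Separates the image into two intensity classes at a threshold and orients
#' the result so that the slice band carries value 1 (the field's
#' white-object-on-black convention). Cross-sections of stained or opaque
#' tissue in translucent agarose are near-bimodal, so Otsu's method is the
#' default; a fixed threshold is available for manual override.
#'
#' The class split uses the half-open convention: intensities strictly below
#' the threshold form one class, intensities at or above it the other.
#' Orientation is then resolved by `polarity`:
#' \describe{
#'   \item{`"auto"`}{the minority class is declared the slice (the band
#'     occupies less area than the field); see [ensure_foreground()].}
#'   \item{`"slice-dark"`}{pixels below the threshold become foreground.}
#'   \item{`"slice-bright"`}{pixels at/above the threshold become foreground.}
#' }
#'
#' @param image A [gray_image()].
#' @param method `"otsu"` (default) or `"fixed"`.
#' @param threshold Intensity threshold, required for `method = "fixed"`;
#'   must lie within the image's intensity range.
#' @param polarity `"auto"`, `"slice-dark"` or `"slice-bright"`.
#'
#' @return A [binary_mask()] carrying the threshold used.
#' @export
#' @examples
#' img <- gray_image(matrix(c(rep(0.1, 30), rep(0.9, 70)), 10, 10), 5)
#' m <- binarize(img)
#' sum(m$pixels)  # the 30 dark pixels are the slice
binarize <- function(image, method = c("otsu", "fixed"), threshold = NULL,
                     polarity = c("auto", "slice-dark", "slice-bright")) {
  stopifnot(inherits(image, "gray_image"))
  method <- match.arg(method)
  polarity <- match.arg(polarity)
  px <- image$pixels
  rng <- range(px)

  if (method == "otsu") {
    if (rng[1L] == rng[2L]) {
      stop("constant image: Otsu thresholding cannot separate two classes",
           call. = FALSE)
    }
    thr <- otsu_threshold(px)
  } else {
    if (is.null(threshold) || !is.finite(threshold)) {
      stop("method = 'fixed' requires a finite `threshold`", call. = FALSE)
    }
    if (threshold < rng[1L] || threshold > rng[2L]) {
      stop(sprintf(
        "fixed threshold %g lies outside the image intensity range [%g, %g]",
        threshold, rng[1L], rng[2L]), call. = FALSE)
    }
    thr <- threshold
  }

  bright <- (px >= thr) * 1
  mask <- switch(polarity,
    "slice-dark"   = binary_mask(1 - bright, image$pixel_size, thr),
    "slice-bright" = binary_mask(bright, image$pixel_size, thr),
    "auto" = ensure_foreground(binary_mask(bright, image$pixel_size, thr))
  )
  mask
}

# Otsu's between-class-variance threshold. EBImage::otsu works on unit-range
# images; arbitrary intensity scales are affinely mapped through it and the
# threshold mapped back.
otsu_threshold <- function(px) {
  rng <- range(px)
  unit <- (px - rng[1L]) / (rng[2L] - rng[1L])
  thr01 <- EBImage::otsu(EBImage::Image(t(unit)), range = c(0, 1))
  rng[1L] + thr01 * (rng[2L] - rng[1L])
}

#' Orient a mask so the slice is foreground
#'
#' Decides which of the two classes is the slice and flips the mask if
#' needed so the slice carries value 1. The decision rule is the minority
#' class: a slice band occupies less area than the surrounding field in a
#' cross-section photo. An exact 50/50 split is ambiguous and raises an
#' error unless `override` states the orientation explicitly.
#'
#' Applying this function twice equals applying it once.
#'
#' @param mask A [binary_mask()] containing at least one pixel of each class.
#' @param override `NULL` (auto), `"keep"` (assert current polarity is
#'   correct) or `"invert"` (flip unconditionally).
#'
#' @return A [binary_mask()] with slice pixels = 1.
#' @export
ensure_foreground <- function(mask, override = NULL) {
  stopifnot(inherits(mask, "binary_mask"))
  n1 <- sum(mask$pixels)
  n0 <- length(mask$pixels) - n1
  if (!is.null(override)) {
    override <- match.arg(override, c("keep", "invert"))
    if (override == "keep") return(mask)
    return(binary_mask(1 - mask$pixels, mask$pixel_size, mask$threshold))
  }
  if (n0 == 0L || n1 == 0L) {
    stop("mask contains a single class; nothing to orient", call. = FALSE)
  }
  if (n0 == n1) {
    stop(paste0("mask classes are exactly balanced; orientation is ",
                "ambiguous - pass override = 'keep' or 'invert'"),
         call. = FALSE)
  }
  if (n1 < n0) mask
  else binary_mask(1 - mask$pixels, mask$pixel_size, mask$threshold)
}
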