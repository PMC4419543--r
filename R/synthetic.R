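#' Specification of a synthetic cross-section band
#'
#' Parametrises the generator that emulates a cross-section photograph of an
#' agarose-embedded slice: one roughly rectangular band of known width at
#' arbitrary orientation, with rough edges and intensity noise, on a
#' contrasting field. Defaults emulate a dark (stained/opaque) band on a
#' bright translucent field.
#'
#' Edge roughness is per-position independent jitter: the band's axis is
#' divided into 1-px bins and each edge of each bin is displaced by an
#' integer drawn uniformly from `{-edge_roughness, ..., +edge_roughness}`.
#' The jitter is symmetric, so the expected measured width equals
#' `true_width` exactly — the closed form used by the validation tests.
#'
#' @param true_width Band width in pixels (>= 1).
#' @param length Band length in pixels (>= 3 * true_width).
#' @param angle Band axis angle from vertical, degrees.
#' @param edge_roughness Maximum per-bin edge displacement, pixels (>= 0).
#' @param fg_level,bg_level Band and field intensities (must differ).
#' @param noise_sd Additive Gaussian intensity noise SD (>= 0).
#' @param canvas `c(rows, cols)`; sized automatically to contain the rotated
#'   band when omitted.
#' @param pixel_size Micrometres per pixel.
#' @param seed Integer seed; identical seeds give bit-identical output.
#'
#' @return An object of class `band_spec`.
#' @export
band_spec <- function(true_width, length, angle = 0, edge_roughness = 0,
                      fg_level = 0.2, bg_level = 0.9, noise_sd = 0,
                      canvas = NULL, pixel_size = 1, seed = 1L) {
  if (true_width < 1) stop("true_width must be >= 1 px", call. = FALSE)
  if (length < 3 * true_width) {
    stop("band length must be at least 3 x true_width", call. = FALSE)
  }
  if (edge_roughness < 0) stop("edge_roughness must be >= 0", call. = FALSE)
  if (fg_level == bg_level) stop("fg_level and bg_level must differ", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  check_pixel_size(pixel_size)

  a <- angle * pi / 180
  half_w <- true_width / 2 + edge_roughness + 1
  need_r <- abs(cos(a)) * length / 2 + abs(sin(a)) * half_w
  need_c <- abs(sin(a)) * length / 2 + abs(cos(a)) * half_w
  if (is.null(canvas)) {
    # generous field margin: in a cross-section photo the band is a small
    # minority of the frame, which the foreground-orientation rule relies on
    margin <- max(10, true_width) + edge_roughness
    canvas <- c(2L * ceiling(need_r + margin) + 1L,
                2L * ceiling(need_c + margin) + 1L)
  } else {
    canvas <- as.integer(canvas)
    if ((canvas[1L] - 1) / 2 < need_r || (canvas[2L] - 1) / 2 < need_c) {
      stop("canvas too small to contain the rotated band", call. = FALSE)
    }
  }
  structure(
    list(true_width = true_width, length = length, angle = angle,
         edge_roughness = as.integer(edge_roughness),
         fg_level = fg_level, bg_level = bg_level, noise_sd = noise_sd,
         canvas = canvas, pixel_size = pixel_size, seed = as.integer(seed)),
    class = "band_spec"
  )
}

#' Generate a synthetic cross-section image with ground truth
#'
#' Rasterises the band described by a [band_spec()]: a pixel is foreground
#' when its along-axis coordinate lies within the band length and its
#' across-axis coordinate lies between the (jittered) edges. Returns the
#' noisy intensity image, the exact label mask, and metadata including the
#' analytically expected measured width.
#'
#' @param spec A [band_spec()].
#'
#' @return A list with elements `image` ([gray_image()]), `truth`
#'   ([binary_mask()]) and `meta` (list: `true_width`, `expected_width_px`,
#'   `expected_width_um`, `angle`, `fg_count`, `centre`, `seed`).
#' @export
#' @examples
#' b <- generate_band(band_spec(true_width = 12, length = 80, angle = 20,
#'                              pixel_size = 5, seed = 42))
#' b$meta$expected_width_um
generate_band <- function(spec) {
  stopifnot(inherits(spec, "band_spec"))
  with_seed(spec$seed, {
    rows <- spec$canvas[1L]; cols <- spec$canvas[2L]
    cr <- (rows + 1) / 2; cc <- (cols + 1) / 2
    a <- spec$angle * pi / 180
    dr <- cos(a); dc <- sin(a)

    R <- matrix(seq_len(rows), rows, cols) - cr
    C <- matrix(seq_len(cols), rows, cols, byrow = TRUE) - cc
    tt <- dr * R + dc * C          # along-axis coordinate
    dd <- -dc * R + dr * C         # across-axis coordinate

    nb <- as.integer(ceiling(spec$length))
    r <- spec$edge_roughness
    if (r > 0) {
      jl <- sample(seq.int(-r, r), nb, replace = TRUE)
      jr <- sample(seq.int(-r, r), nb, replace = TRUE)
    } else {
      jl <- jr <- integer(nb)
    }
    inside_t <- tt >= -spec$length / 2 & tt < spec$length / 2
    bin <- pmin(pmax(floor(tt + spec$length / 2) + 1L, 1L), nb)
    lo <- -spec$true_width / 2 + jl[bin]
    hi <- spec$true_width / 2 + jr[bin]
    mask <- (inside_t & dd >= lo & dd < hi) * 1
    dim(mask) <- c(rows, cols)

    img <- ifelse(mask == 1, spec$fg_level, spec$bg_level)
    if (spec$noise_sd > 0) {
      img <- img + stats::rnorm(length(img), sd = spec$noise_sd)
    }
    if (spec$fg_level >= 0 && spec$fg_level <= 1 &&
        spec$bg_level >= 0 && spec$bg_level <= 1) {
      img <- pmin(pmax(img, 0), 1)
    }
    dim(img) <- c(rows, cols)

    list(
      image = gray_image(img, spec$pixel_size,
                         sprintf("synthetic-band-w%g-a%g-seed%d",
                                 spec$true_width, spec$angle, spec$seed)),
      truth = binary_mask(mask, spec$pixel_size),
      meta = list(true_width = spec$true_width,
                  expected_width_px = spec$true_width,
                  expected_width_um = spec$true_width * spec$pixel_size,
                  angle = spec$angle, fg_count = sum(mask),
                  centre = c(cr, cc) - 1, seed = spec$seed)
    )
  })
}

#' Simulate a sectioning study of labelled slice thicknesses
#'
#' Draws per-slice thickness values from normal distributions with the
#' stated per-condition means and SDs — the generative counterpart of a
#' study in which several independent slices are measured for each step
#' size and sectioning speed. Normality is an assumption of the fixture,
#' not a claim about tissue.
#'
#' @param design Data frame with columns `tissue`, `step_size` (um),
#'   `speed` (mm/s), `mean` (um), `sd` (um, >= 0) and `n` (slices per cell,
#'   >= 2).
#' @param seed Integer seed; one seed gives a reproducible table.
#'
#' @return Data frame of slice records: `tissue`, `step_size`, `speed`,
#'   `thickness` (um).
#' @export
generate_study <- function(design, seed = 1L) {
  req <- c("tissue", "step_size", "speed", "mean", "sd", "n")
  if (!is.data.frame(design) || !all(req %in% names(design))) {
    stop(sprintf("design must contain columns: %s", paste(req, collapse = ", ")),
         call. = FALSE)
  }
  if (any(design$n < 2)) stop("each design cell needs n >= 2", call. = FALSE)
  if (any(design$sd < 0)) stop("design SDs must be >= 0", call. = FALSE)
  with_seed(seed, {
    recs <- lapply(seq_len(nrow(design)), function(i) {
      d <- design[i, ]
      data.frame(
        tissue = d$tissue, step_size = d$step_size, speed = d$speed,
        thickness = stats::rnorm(d$n, mean = d$mean, sd = d$sd),
        stringsAsFactors = FALSE
      )
    })
    do.call(rbind, recs)
  })
}

# Evaluate `code` under `seed` without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}
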