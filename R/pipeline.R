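#' Measure one cross-section image end to end
#'
#' The full measurement chain on a single image: threshold, orient the
#' slice as foreground, optionally crop to a region of interest, keep the
#' largest connected object, align the principal axis vertically and apply
#' the segment statistic. Mirrors the four interactive steps (calibrate +
#' load, binarize, crop/rotate, segment) as one call.
#'
#' @param image A [gray_image()], or a file path (then `pixel_size` is
#'   required).
#' @param pixel_size Micrometres per pixel, when `image` is a path.
#' @param threshold_method,threshold,polarity Passed to [binarize()].
#' @param roi Optional [rect_roi()] applied to the binarized mask before
#'   axis estimation, the programmatic equivalent of dragging a selection
#'   rectangle.
#' @param axis Optional [axis_endpoints()] (manual extremity picks); the
#'   axis is estimated by PCA when omitted.
#' @param keep_largest Keep only the largest connected foreground object
#'   before axis estimation and measurement (default `TRUE`).
#' @param segments Optional list of [rect_roi()] measurement segments in the
#'   aligned mask's coordinates; placed by [auto_segments()] when omitted.
#' @param n_segments,fraction Segment auto-placement policy.
#' @param sd_type Passed to [measure_slice()].
#'
#' @return A `thickness_result` (see [measure_slice()]) with added fields
#'   `source_id`, `threshold` and `axis_angle_deg`.
#' @export
#' @examples
#' b <- generate_band(band_spec(12, 120, angle = 25, noise_sd = 0.05,
#'                              pixel_size = 8, seed = 3))
#' measure_image(b$image)
measure_image <- function(image, pixel_size = NULL,
                          threshold_method = "otsu", threshold = NULL,
                          polarity = "auto", roi = NULL, axis = NULL,
                          keep_largest = TRUE, segments = NULL,
                          n_segments = 3L, fraction = 0.2,
                          sd_type = "sample") {
  if (is.character(image)) {
    if (is.null(pixel_size)) {
      stop("`pixel_size` is required when `image` is a file path",
           call. = FALSE)
    }
    image <- load_image(image, pixel_size)
  }
  stopifnot(inherits(image, "gray_image"))
  mask <- binarize(image, method = threshold_method, threshold = threshold,
                   polarity = polarity)
  if (!is.null(roi)) mask <- crop_mask(mask, roi)
  if (keep_largest) mask <- select_band(mask)
  if (is.null(axis)) axis <- estimate_axis(mask)
  ang <- axis_angle(axis)
  aligned <- align_vertical(mask, axis)
  res <- measure_slice(aligned, segments = segments, n = n_segments,
                       fraction = fraction, sd_type = sd_type)
  res$source_id <- image$source_id
  res$threshold <- mask$threshold
  res$axis_angle_deg <- ang
  res
}

#' Measure a batch of images
#'
#' Runs [measure_image()] over a set of files, collecting one record per
#' image. Per-image failures are logged and skipped — never silently
#' dropped — and reflected in the returned status: 0 all measured, 1 some
#' failed, 2 nothing measured.
#'
#' @param paths Character vector of image files.
#' @param pixel_size Micrometres per pixel (shared calibration).
#' @param ... Further arguments passed to [measure_image()].
#' @param out_dir Optional directory; when given, writes
#'   `measurements.csv`, `failures.csv` (if any) and per-image JSON records.
#'
#' @return List with `measurements` (data frame: `source_id`, `path`,
#'   `mean_um`, `sd_um`, `cv`, `irregular`, `n_segments`, `threshold`,
#'   `axis_angle_deg`, `segment_values` as a semicolon-joined string),
#'   `failures` (data frame: `path`, `error`), `warnings` (character log)
#'   and `status`.
#' @export
run_measure <- function(paths, pixel_size, ..., out_dir = NULL) {
  if (length(paths) == 0L) stop("no input images given", call. = FALSE)
  rows <- list(); fails <- list(); wlog <- character()
  for (p in paths) {
    res <- withCallingHandlers(
      tryCatch(measure_image(p, pixel_size = pixel_size, ...),
               error = function(e) e),
      warning = function(w) {
        wlog <<- c(wlog, sprintf("%s: %s", basename(p), conditionMessage(w)))
        invokeRestart("muffleWarning")
      }
    )
    if (inherits(res, "error")) {
      fails[[length(fails) + 1L]] <- data.frame(
        path = p, error = conditionMessage(res), stringsAsFactors = FALSE)
    } else {
      if (res$irregular) {
        wlog <- c(wlog, sprintf("%s: highly irregular slice (CV %.3f > 0.25)",
                                basename(p), res$cv))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        source_id = res$source_id, path = p, mean_um = res$mean,
        sd_um = res$sd, cv = res$cv, irregular = res$irregular,
        n_segments = res$n_segments,
        threshold = if (is.null(res$threshold)) NA_real_ else res$threshold,
        axis_angle_deg = res$axis_angle_deg,
        segment_values = paste(format(res$segment_values, digits = 10),
                               collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }
  measurements <- if (length(rows)) do.call(rbind, rows) else
    data.frame(source_id = character(), path = character(),
               mean_um = numeric(), stringsAsFactors = FALSE)
  failures <- if (length(fails)) do.call(rbind, fails) else
    data.frame(path = character(), error = character(),
               stringsAsFactors = FALSE)
  status <- if (nrow(measurements) == 0L) 2L
            else if (nrow(failures) > 0L) 1L else 0L

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(measurements, file.path(out_dir, "measurements.csv"),
                     row.names = FALSE)
    for (i in seq_len(nrow(measurements))) {
      rec <- as.list(measurements[i, ])
      rec$segment_values <- as.numeric(
        strsplit(rec$segment_values, ";", fixed = TRUE)[[1L]])
      jsonlite::write_json(
        rec,
        file.path(out_dir, paste0(
          tools::file_path_sans_ext(basename(measurements$path[i])), ".json")),
        auto_unbox = TRUE, digits = NA)
    }
    if (nrow(failures) > 0L) {
      utils::write.csv(failures, file.path(out_dir, "failures.csv"),
                       row.names = FALSE)
    }
    if (length(wlog)) {
      writeLines(wlog, file.path(out_dir, "warnings.log"))
    }
  }
  list(measurements = measurements, failures = failures,
       warnings = wlog, status = status)
}

#' Study-level report: condition summaries, overalls, ANOVA and Tukey
#'
#' Aggregates labelled slice records into the full statistics layer: per
#' (tissue, step, speed) summaries with thickness errors, per-tissue overall
#' errors, a per-tissue ANOVA (two-way with interaction when both step size
#' and speed vary, one-way on step size when only it varies), and Tukey HSD
#' letter groupings over the condition cells. Tissues whose design cannot
#' support an ANOVA (a single condition cell) are reported in `skipped`.
#'
#' @param records Slice records (see [summarize_combos()]) or a path to a
#'   CSV with columns `tissue`, `step_size_um`/`step_size`,
#'   `speed_mm_s`/`speed`, `thickness_um`/`thickness`.
#' @param alpha Significance level for the Tukey groupings.
#'
#' @return An object of class `study_report`: list with `combos`,
#'   `overalls`, `anova` (named per tissue), `tukey` (named per tissue) and
#'   `skipped` (named character reasons).
#' @export
run_study <- function(records, alpha = 0.05) {
  if (is.character(records)) records <- read_records(records)
  check_records(records)
  combos <- summarize_combos(records)
  overalls <- overall_error(combos)

  anovas <- list(); tukeys <- list(); skipped <- character()
  for (tis in unique(records$tissue)) {
    rt <- records[records$tissue == tis, ]
    n_steps <- length(unique(rt$step_size))
    n_speeds <- length(unique(rt$speed))
    if (n_steps >= 2L && n_speeds >= 2L) {
      anovas[[tis]] <- thickness_anova(rt, c("step_size", "speed"))
      tukeys[[tis]] <- tukey_grouping(rt, c("step_size", "speed"),
                                      alpha = alpha)
    } else if (n_steps >= 2L) {
      anovas[[tis]] <- thickness_anova(rt, "step_size")
      tukeys[[tis]] <- tukey_grouping(rt, "step_size", alpha = alpha)
    } else {
      skipped[tis] <- "single condition cell; ANOVA skipped"
    }
  }
  structure(list(combos = combos, overalls = overalls, anova = anovas,
                 tukey = tukeys, skipped = skipped, alpha = alpha),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("Per-condition thickness summaries:\n")
  print(x$combos, row.names = FALSE, digits = 6)
  cat("\nOverall thickness error per tissue:\n")
  print(x$overalls, row.names = FALSE, digits = 6)
  for (tis in names(x$anova)) {
    cat(sprintf("\nANOVA - %s:\n", tis))
    print(x$anova[[tis]], row.names = FALSE, digits = 4)
  }
  if (length(x$skipped)) {
    cat("\nSkipped:", paste(names(x$skipped), x$skipped, sep = ": ",
                            collapse = "; "), "\n")
  }
  invisible(x)
}

#' Read labelled slice records from CSV
#'
#' Accepts either the package's bare column names (`step_size`, `speed`,
#' `thickness`) or unit-suffixed ones (`step_size_um`, `speed_mm_s`,
#' `thickness_um`).
#'
#' @param path CSV file.
#' @return Slice-record data frame with bare column names.
#' @export
read_records <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  ali <- c(step_size_um = "step_size", speed_mm_s = "speed",
           thickness_um = "thickness")
  for (from in names(ali)) {
    if (from %in% names(df) && !(ali[[from]] %in% names(df))) {
      names(df)[names(df) == from] <- ali[[from]]
    }
  }
  check_records(df)
  df
}

#' Serialise a study report to CSV + JSON files
#'
#' Writes the condition summary table (with the per-tissue overall appended
#' as a column) as CSV and the ANOVA/Tukey results as JSON.
#'
#' @param report A `study_report` from [run_study()].
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_study <- function(report, out_dir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  combos <- merge(report$combos,
                  report$overalls[, c("tissue", "overall_error_pct")],
                  by = "tissue", all.x = TRUE)
  combos <- combos[order(combos$tissue, combos$step_size, combos$speed), ]
  utils::write.csv(combos, file.path(out_dir, "study_summary.csv"),
                   row.names = FALSE)
  stats_out <- list(
    alpha = report$alpha,
    anova = report$anova,
    tukey = lapply(report$tukey, function(t) {
      list(groups = t$groups, pairwise = t$pairwise)
    }),
    skipped = as.list(report$skipped)
  )
  jsonlite::write_json(stats_out, file.path(out_dir, "study_stats.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(out_dir)
}

#' Parse "r0,r1,c0,c1" into a [rect_roi()]
#'
#' Helper for command-line flags; 0-based half-open indices.
#' @param s Comma-separated bounds string.
#' @return A [rect_roi()].
#' @export
parse_roi <- function(s) {
  v <- as.numeric(strsplit(s, ",", fixed = TRUE)[[1L]])
  if (length(v) != 4L || any(!is.finite(v))) {
    stop("ROI must be 'row_start,row_end,col_start,col_end'", call. = FALSE)
  }
  rect_roi(v[1L], v[2L], v[3L], v[4L])
}

#' Parse "r1,c1,r2,c2" into [axis_endpoints()]
#'
#' Helper for command-line flags; 0-based (row, col) coordinates.
#' @param s Comma-separated coordinates string.
#' @return An [axis_endpoints()].
#' @export
parse_axis <- function(s) {
  v <- as.numeric(strsplit(s, ",", fixed = TRUE)[[1L]])
  if (length(v) != 4L || any(!is.finite(v))) {
    stop("axis must be 'r1,c1,r2,c2'", call. = FALSE)
  }
  axis_endpoints(v[1:2], v[3:4])
}
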