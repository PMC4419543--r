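#' Bar plot of condition means with Tukey letters
#'
#' Mean actual thickness per (step size, speed) condition with SD error
#' bars, one panel per tissue, annotated with the compact letter display
#' when the report carries Tukey groupings — the customary presentation of
#' sectioning-study results. Requires ggplot2.
#'
#' @param report A `study_report` from [run_study()].
#' @return A ggplot object.
#' @export
plot_study <- function(report) {
  stopifnot(inherits(report, "study_report"))
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_study() requires the ggplot2 package", call. = FALSE)
  }
  d <- report$combos
  d$step <- factor(d$step_size)
  d$speed_f <- factor(d$speed)
  d$letters <- NA_character_
  for (tis in names(report$tukey)) {
    g <- report$tukey[[tis]]$groups
    sel <- d$tissue == tis
    key <- if (all(grepl("x", g$group, fixed = TRUE))) {
      paste(d$step_size[sel], d$speed[sel], sep = "x")
    } else {
      as.character(d$step_size[sel])
    }
    d$letters[sel] <- g$letters[match(key, g$group)]
  }
  ggplot2::ggplot(d, ggplot2::aes(x = step, y = mean_um,
                                  fill = speed_f)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.9),
                      colour = "grey20") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = mean_um - sd_um,
                   ymax = mean_um + sd_um),
      position = ggplot2::position_dodge(0.9), width = 0.25) +
    ggplot2::geom_text(
      ggplot2::aes(y = mean_um + sd_um, label = letters),
      position = ggplot2::position_dodge(0.9), vjust = -0.5, na.rm = TRUE) +
    ggplot2::facet_wrap(~tissue, scales = "free_y") +
    ggplot2::labs(x = "Step size (um)", y = "Actual thickness (um)",
                  fill = "Speed (mm/s)") +
    ggplot2::theme_minimal()
}
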