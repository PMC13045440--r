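#' Raster plot of meal distribution
#'
#' One horizontal lane per animal-day, meals drawn as tiles at their onset
#' hour (from light onset) with width proportional to duration; faceted by
#' phase when present.
#'
#' @param meals Annotated meal tibble.
#' @return A ggplot object.
#' @export
plot_raster <- function(meals) {
  r <- raster_export(meals)
  r$lane <- interaction(r$animal_id, r$day, drop = TRUE)
  p <- ggplot2::ggplot(r, ggplot2::aes(
    xmin = .data$onset_bin_h, xmax = .data$onset_bin_h +
      pmax(.data$duration_min / 60, 0.08),
    ymin = as.integer(.data$lane) - 0.4,
    ymax = as.integer(.data$lane) + 0.4,
    fill = .data$cycle)) +
    ggplot2::annotate("rect", xmin = 12, xmax = 24, ymin = -Inf, ymax = Inf,
                      alpha = 0.12) +
    ggplot2::geom_rect() +
    ggplot2::scale_fill_manual(values = c(light = "#e0aa00", dark = "#30507a")) +
    ggplot2::labs(x = "hours from light onset", y = "animal x day",
                  title = "Meal raster") +
    ggplot2::theme_minimal()
  if ("phase" %in% names(r)) p <- p + ggplot2::facet_wrap(~phase)
  p
}

#' Heat map of hourly food intake
#'
#' Animal-days by clock-hour bins, tile fill = intake; the standard
#' visualisation for spotting multi-hour zero-intake blocks.
#'
#' @param hourly Output of [hourly_bin()].
#' @return A ggplot object.
#' @export
plot_hourly_heatmap <- function(hourly) {
  h <- hourly
  h$lane <- interaction(h$animal_id, h$day, drop = TRUE)
  p <- ggplot2::ggplot(h, ggplot2::aes(.data$hour_bin, .data$lane,
                                       fill = .data$intake_kcal)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(option = "B") +
    ggplot2::labs(x = "hours from light onset", y = "animal x day",
                  fill = "kcal/h", title = "Hourly food intake") +
    ggplot2::theme_minimal()
  if ("phase" %in% names(h)) p <- p + ggplot2::facet_wrap(~phase, scales = "free_y")
  p
}

#' Radial (24-h clock) plot of mean hourly intake
#'
#' @param radial Output of [radial_export()].
#' @return A ggplot object.
#' @export
plot_radial <- function(radial) {
  p <- ggplot2::ggplot(radial, ggplot2::aes(.data$clock_hour + 0.5,
                                            .data$mean_intake_kcal,
                                            fill = .data$cycle)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::coord_polar(start = 0) +
    ggplot2::scale_x_continuous(limits = c(0, 24),
                                breaks = c(0, 6, 12, 18)) +
    ggplot2::scale_fill_manual(values = c(light = "#e0aa00", dark = "#30507a")) +
    ggplot2::labs(x = NULL, y = "mean intake (kcal/h)",
                  title = "24-h feeding pattern") +
    ggplot2::theme_minimal()
  if ("phase" %in% names(radial)) p <- p + ggplot2::facet_wrap(~phase)
  p
}

#' @rdname fit_lmm
#' @param object A `meal_lmm` object (for `autoplot`).
#' @export
autoplot.meal_lmm <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(.data$phase, .data$emmean)) +
    ggplot2::geom_col(fill = "grey70", width = 0.6) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$emmean - .data$se,
                                        ymax = .data$emmean + .data$se),
                           width = 0.15) +
    ggplot2::labs(y = paste0(object$response, " (EMM ± SEM)"), x = NULL) +
    ggplot2::theme_minimal()
}
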