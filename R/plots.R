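#' Plot a velocity waveform, optionally with its segmentation
#'
#' @param object A [new_velocity_waveform()].
#' @param segmentation Optional [segment_twitch()] result; its three time
#'   points are drawn as vertical dashed lines.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.velocity_waveform <- function(object, segmentation = NULL, ...) {
  df <- as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$time_s,
                                        .data$velocity_mps * 1000)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60",
                        linewidth = 0.25) +
    ggplot2::labs(x = "Time (s)", y = "Tissue velocity (mm/s)")
  if (!is.null(segmentation)) {
    marks <- tibble(
      time_s = c(segmentation$t_onset, segmentation$t_zero,
                 segmentation$t_end),
      point = factor(c("onset", "zero-crossing", "end"),
                     levels = c("onset", "zero-crossing", "end")))
    p <- p + ggplot2::geom_vline(
      data = marks,
      ggplot2::aes(xintercept = .data$time_s, colour = .data$point),
      linetype = "dashed") +
      ggplot2::labs(colour = "Time point")
  }
  p
}

#' Plot a velocity field as a depth-time image
#'
#' @param object A [velocity_field()].
#' @param ... Unused.
#' @return A ggplot (depth increases downward, as on a scanner).
#' @export
autoplot.velocity_field <- function(object, ...) {
  depths_mm <- (depth_axis(object$params)[seq_len(nrow(object$velocities))]) * 1000
  df <- tidyr::expand_grid(depth_mm = depths_mm, time_s = object$times)
  df$velocity_mmps <- as.vector(t(object$velocities)) * 1000
  ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$depth_mm,
                                   fill = .data$velocity_mmps)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient2(low = "#313695", mid = "white",
                                  high = "#a50026") +
    ggplot2::labs(x = "Time (s)", y = "Depth (mm)",
                  fill = "v (mm/s)")
}

#' Plot a power-law recovery fit over its data
#'
#' @param object A [fit_power_trend()] result.
#' @param ... Unused.
#' @return A ggplot of the data points and fitted `b0 * x^b1` curve.
#' @export
autoplot.power_fit <- function(object, ...) {
  d <- object$fit$model
  df <- tibble(x = exp(d[["log(x)"]]), y = exp(d[["log(y)"]]))
  grid <- tibble(x = seq(min(df$x), max(df$x), length.out = 100))
  grid$y <- object$b0 * grid$x^object$b1
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_line(data = grid, colour = "#a50026") +
    ggplot2::labs(x = "Post-fatigue twitch index",
                  y = "Normalized value",
                  subtitle = sprintf("y = %.3f x^%.3f (R² = %.2f)",
                                     object$b0, object$b1, object$r_squared))
}

#' Plot normalized feature recovery across post-fatigue twitches
#'
#' Mean +/- standard error of each normalized measure over the recovery
#' twitch index, pooled across subjects and rounds.
#'
#' @param features A normalized feature table (see
#'   [normalize_to_baseline()]).
#' @param measures Measure columns to include.
#' @return A ggplot faceted by measure.
#' @export
plot_recovery <- function(features,
                          measures = intersect(
                            c("torque_nm", "peak_velocity_mps",
                              "time_to_zero_s", "total_duration_s",
                              "peak_vti_m", "peak_strain_rate_per_s"),
                            names(features))) {
  long <- tidyr::pivot_longer(
    dplyr::filter(features, .data$phase == "recovery"),
    dplyr::all_of(measures), names_to = "measure", values_to = "value")
  summ <- dplyr::summarise(
    dplyr::group_by(long, .data$measure, .data$twitch_index),
    mean = mean(.data$value), se = sd(.data$value) / sqrt(dplyr::n()),
    .groups = "drop")
  ggplot2::ggplot(summ, ggplot2::aes(.data$twitch_index, .data$mean)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dotted") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$se,
                                          ymax = .data$mean + .data$se)) +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::labs(x = "Post-fatigue twitch", y = "Normalized value")
}
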