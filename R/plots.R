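# ggplot2 visualisations for the result objects.

#' @importFrom rlang .data
NULL

#' Bland-Altman plot
#'
#' Pair means against differences with the bias line and limits of
#' agreement.
#'
#' @param object a `bland_altman` object.
#' @param ... unused.
#' @export
autoplot.bland_altman <- function(object, ...) {
  ggplot2::ggplot(object$pairs,
                  ggplot2::aes(x = .data$mean_deg, y = .data$diff_deg)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = object$bias_deg, linetype = "solid") +
    ggplot2::geom_hline(yintercept = c(object$loa_low_deg, object$loa_high_deg),
                        linetype = "dashed") +
    ggplot2::labs(x = "Mean of the two instruments (deg)",
                  y = "Difference, tracker - comparator (deg)",
                  title = "Bland-Altman agreement") +
    ggplot2::theme_minimal()
}

#' Scatter of the two instruments with regression lines, per axis
#'
#' @param object an `agreement_result`.
#' @param ... unused.
#' @export
autoplot.agreement_result <- function(object, ...) {
  ggplot2::ggplot(object$pairs,
                  ggplot2::aes(x = .data$instrument_a_deg,
                               y = .data$instrument_b_deg)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.6) +
    ggplot2::facet_wrap(~axis) +
    ggplot2::labs(x = "Comparator instrument (deg)",
                  y = "Video tracker (deg)",
                  title = "Method comparison by axis") +
    ggplot2::theme_minimal()
}

#' Heat map of actual versus predicted pose bins
#'
#' @param bins tibble from [heatmap_bins()].
#' @param title plot title.
#' @export
plot_heatmap_bins <- function(bins, title = "Predicted vs actual pose") {
  ggplot2::ggplot(bins, ggplot2::aes(x = .data$actual_center_deg,
                                     y = .data$predicted_center_deg,
                                     fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "Actual (deg)", y = "Predicted (deg)", fill = "frames",
                  title = title) +
    ggplot2::theme_minimal()
}

#' Error against eccentricity profile per axis
#'
#' Visualises how the combined absolute error grows toward extreme
#' postures, with the accuracy threshold marked.
#'
#' @param profile tibble from [error_by_eccentricity()].
#' @param threshold_deg horizontal reference line, degrees.
#' @export
plot_error_profile <- function(profile, threshold_deg = 5) {
  ggplot2::ggplot(profile, ggplot2::aes(x = .data$center_deg,
                                        y = .data$mean_err_deg)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(size = .data$n_frames), alpha = 0.6) +
    ggplot2::geom_hline(yintercept = threshold_deg, linetype = "dashed") +
    ggplot2::facet_wrap(~axis) +
    ggplot2::labs(x = "True pose (deg)", y = "Mean combined error (deg)",
                  title = "Accuracy across the pose range") +
    ggplot2::theme_minimal()
}
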