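#' Droplet amplitude plot with thresholds
#'
#' One-dimensional amplitude plot per well (points jittered horizontally),
#' with the plate x channel threshold overlaid — the standard visual check
#' that the control-derived cut separates the clusters and sits above the
#' rain.
#'
#' @param droplets Droplet-level table.
#' @param thresholds Optional output of [plate_thresholds()].
#' @param max_droplets Down-sample to at most this many droplets per well
#'   for plotting. Default 2000.
#' @return A ggplot object, faceted by plate and channel.
#' @export
plot_droplets <- function(droplets, thresholds = NULL, max_droplets = 2000) {
  check_droplet_table(droplets)
  d <- droplets |>
    dplyr::group_by(.data$plate_id, .data$well_id, .data$channel) |>
    dplyr::slice_sample(n = max_droplets) |>
    dplyr::ungroup()
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$well_id,
                                       y = .data$amplitude,
                                       colour = .data$role)) +
    ggplot2::geom_jitter(width = 0.3, size = 0.3, alpha = 0.4) +
    ggplot2::facet_grid(ggplot2::vars(.data$channel),
                        ggplot2::vars(.data$plate_id), scales = "free_x") +
    ggplot2::labs(x = NULL, y = "fluorescence amplitude (a.u.)",
                  colour = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       size = 6))
  if (!is.null(thresholds)) {
    p <- p + ggplot2::geom_hline(
      data = thresholds,
      ggplot2::aes(yintercept = .data$threshold), linetype = 2)
  }
  p
}

#' Kaplan-Meier curve plot
#'
#' @param object A `km_fit` from [km_estimate()].
#' @param ... Unused.
#' @return A ggplot step plot with censoring ticks.
#' @export
autoplot.km_fit <- function(object, ...) {
  steps <- object$steps
  grouped <- !is.null(object$group)
  start <- steps |>
    dplyr::distinct(.data$group) |>
    dplyr::mutate(time_months = 0, survival = 1, n_event = 0)
  d <- dplyr::bind_rows(start, steps)
  aes <- if (grouped) {
    ggplot2::aes(x = .data$time_months, y = .data$survival,
                 colour = .data$group)
  } else {
    ggplot2::aes(x = .data$time_months, y = .data$survival)
  }
  ggplot2::ggplot(d, aes) +
    ggplot2::geom_step() +
    ggplot2::geom_point(data = dplyr::filter(steps, .data$n_event == 0),
                        shape = 3, size = 1.5) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "months since inclusion", y = "survival probability",
                  colour = object$group) +
    ggplot2::theme_minimal()
}

#' Detection-rate bar plot
#'
#' @param detection Output of [detection_rate()].
#' @return A ggplot bar chart of per-timepoint ctDNA detection percentages,
#'   annotated with the positive/evaluable counts.
#' @export
plot_detection_rates <- function(detection) {
  ggplot2::ggplot(detection,
                  ggplot2::aes(x = .data$timepoint,
                               y = .data$rate_percent)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%d/%d",
                                                    .data$n_positive,
                                                    .data$n_evaluable)),
                       vjust = -0.4, size = 3) +
    ggplot2::labs(x = NULL, y = "ctDNA detected (%)") +
    ggplot2::ylim(0, 100) +
    ggplot2::theme_minimal()
}

#' ROC curve plot
#'
#' @param object A `roc_analysis`.
#' @param ... Unused.
#' @return A ggplot ROC curve with the chance diagonal.
#' @export
autoplot.roc_analysis <- function(object, ...) {
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(x = 1 - .data$specificity,
                               y = .data$sensitivity)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 3,
                         colour = "grey60") +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity",
                  title = sprintf("AUC = %.3f", object$auc)) +
    ggplot2::theme_minimal()
}
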