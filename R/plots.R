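#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a normalized bead distribution curve
#'
#' Depth below the mucus surface on the x axis (0 = surface, increasing
#' towards the tissue), normalized bead frequency on the y axis; the shaded
#' area is the normalized penetrability.
#'
#' @param object A `normalized_distribution` from [normalize_align()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.normalized_distribution <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$x_um, y = .data$f)) +
    ggplot2::geom_area(alpha = 0.3, fill = "steelblue") +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "depth below mucus surface (µm)",
      y = "normalized bead frequency",
      title = sprintf("normalized penetrability = %.2f µm",
                      penetrability_auc(object))
    ) +
    ggplot2::theme_minimal()
}

#' Plot per-mouse median penetrability curves
#'
#' @param curves Output of [median_curve()], optionally joined with a
#'   `group` column for colouring.
#' @return A ggplot.
#' @export
plot_penetrability_curves <- function(curves) {
  aes <- if ("group" %in% names(curves)) {
    ggplot2::aes(x = .data$x_um, y = .data$f_median,
                 group = .data$mouse, colour = .data$group)
  } else {
    ggplot2::aes(x = .data$x_um, y = .data$f_median, group = .data$mouse)
  }
  ggplot2::ggplot(curves, aes) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::labs(x = "depth below mucus surface (µm)",
                  y = "median normalized bead frequency") +
    ggplot2::theme_minimal()
}

#' Plot a growth-rate fit
#'
#' Thickness measurements by time with the fitted growth line.
#'
#' @param object A `growth_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.growth_fit <- function(object, ...) {
  d <- object$lm$model
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time_min, y = .data$thickness_um)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_abline(intercept = stats::coef(object$lm)[1],
                         slope = stats::coef(object$lm)[2],
                         colour = "steelblue") +
    ggplot2::labs(
      x = "time (min)", y = "mucus thickness (µm)",
      title = sprintf("growth rate %.2f ± %.2f µm/min, r² = %.3f",
                      object$rate, object$rate_se, object$r_squared)
    ) +
    ggplot2::theme_minimal()
}

#' Plot cohort group contrasts
#'
#' Per-mouse values of a readout by group, with group mean and SD overlaid —
#' the usual scatter-with-error-bar cohort panel.
#'
#' @param report A `mucus_report` from [run_pipeline()] (or any data frame
#'   with `group` and the chosen variable).
#' @param variable Column to plot (default `"auc_um"`).
#' @return A ggplot.
#' @export
plot_group_contrast <- function(report, variable = "auc_um") {
  d <- if (inherits(report, "mucus_report")) report$per_mouse else report
  if (!all(c("group", variable) %in% names(d))) {
    abort_data(sprintf("need columns `group` and `%s`", variable))
  }
  ggplot2::ggplot(d, ggplot2::aes(x = .data$group, y = .data[[variable]])) +
    ggplot2::stat_summary(fun.data = ggplot2::mean_sdl, fun.args = list(mult = 1),
                          geom = "errorbar", width = 0.2) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4,
                          linewidth = 0.3) +
    ggplot2::geom_jitter(width = 0.08, alpha = 0.7) +
    ggplot2::labs(x = NULL, y = variable) +
    ggplot2::theme_minimal()
}
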