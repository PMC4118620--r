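# ggplot2 views of the result objects.

#' Plot a density summary
#'
#' @param object A `glyco_density` from [density_summary()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.glyco_density <- function(object, ...) {
  ggplot2::ggplot(object$density, ggplot2::aes(.data$mid, .data$density)) +
    ggplot2::geom_col(width = NULL, fill = "grey35") +
    ggplot2::geom_vline(xintercept = object$mode, linetype = 2,
                        colour = "firebrick") +
    ggplot2::labs(x = "value", y = "probability density",
                  subtitle = sprintf("mode = %.3g%s", object$mode,
                                     if (object$bimodal) " (bimodal)" else
                                       "")) +
    ggplot2::theme_minimal()
}

#' Heatmap of a clustered control correlation map
#'
#' @param object A `glyco_control_map` from [cluster_control_map()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.glyco_control_map <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(.data$col, .data$row,
                                 fill = .data$correlation)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "darkgreen", mid = "white",
                                  high = "purple4", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL,
                  fill = paste0(object$method, "\ncorrelation")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Bar panel of Warburg-Effect correlations
#'
#' @param correlations Tibble from [correlate_we()].
#' @return A ggplot.
#' @export
plot_we_correlations <- function(correlations) {
  correlations |>
    dplyr::mutate(variable = factor(.data$variable,
                                    levels = .data$variable)) |>
    ggplot2::ggplot(ggplot2::aes(.data$variable, .data$correlation)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::labs(x = NULL, y = "Pearson correlation with W") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Dose-response view of a simulated or measured panel
#'
#' Lactate flux against fraction of the target inhibited, on the log-flux
#' axis used by the empirical FCC fit.
#'
#' @param panel Data frame with `fraction_inhibited` and `flux` columns.
#' @return A ggplot.
#' @export
plot_dose_response <- function(panel) {
  ggplot2::ggplot(panel, ggplot2::aes(.data$fraction_inhibited,
                                      .data$flux)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "fraction of enzyme inhibited",
                  y = "lactate flux (mM/hr)") +
    ggplot2::theme_minimal()
}

#' Fitted tracer time course
#'
#' @param object A `glyco_flux_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.glyco_flux_fit <- function(object, ...) {
  df <- object$fit$model
  ggplot2::ggplot(df, ggplot2::aes(.data$time_min, .data$lactate_conc)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "firebrick") +
    ggplot2::labs(x = "time (min)", y = "13C lactate (conc. units)",
                  subtitle = sprintf("slope = %.3g, R^2 = %.3f",
                                     object$slope, object$r_squared)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
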