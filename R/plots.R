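#' Plot depth-bin profiles with the selected analysis window
#'
#' @param profiles Output of [zbin_profile()].
#' @param selection Optional `zbin_selection` to shade the retained bins.
#' @param metric `"count"` or `"intensity"`.
#' @return A ggplot object.
#' @export
plot_zbin_profile <- function(profiles, selection = NULL,
                              metric = c("count", "intensity")) {
  metric <- match.arg(metric)
  d <- profiles |>
    mutate(value = if (metric == "count") as.numeric(.data$n_objects)
           else .data$mean_intensity)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$bin, y = .data$value,
                                       group = .data$stack_id)) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::facet_wrap(ggplot2::vars(.data$channel), scales = "free_y") +
    ggplot2::labs(x = "normalized depth bin (1 = coverslip)",
                  y = if (metric == "count") "objects per bin"
                      else "mean object intensity (a.u.)") +
    ggplot2::theme_minimal()
  if (!is.null(selection)) {
    p <- p + ggplot2::annotate(
      "rect", xmin = min(selection$z_bins) - 0.5,
      xmax = max(selection$z_bins) + 0.5, ymin = -Inf, ymax = Inf,
      alpha = 0.12, fill = "steelblue"
    )
  }
  p
}

#' Bar chart of GAD-class mixtures per marker
#'
#' @param result A `gp_pipeline_result`, or a tibble with columns `marker`,
#'   `gad_class`, `percent`.
#' @return A ggplot object.
#' @export
plot_gad_mixtures <- function(result) {
  d <- if (inherits(result, "gp_pipeline_result")) result$gad_mixtures else result
  ggplot2::ggplot(d, ggplot2::aes(x = .data$marker, y = .data$percent,
                                  fill = .data$gad_class)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "% of marker terminals", fill = "GAD class") +
    ggplot2::theme_minimal()
}

#' Bar chart of marker proportions
#'
#' @param result A `gp_pipeline_result`, or a tibble with columns `marker`,
#'   `percent`.
#' @return A ggplot object.
#' @export
plot_marker_proportions <- function(result) {
  d <- if (inherits(result, "gp_pipeline_result")) result$marker_proportions else result
  ggplot2::ggplot(d, ggplot2::aes(x = .data$marker, y = .data$percent)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::labs(x = NULL, y = "% of vGAT terminals") +
    ggplot2::theme_minimal()
}

#' @method autoplot gp_pipeline_result
#' @export
autoplot.gp_pipeline_result <- function(object, ...) {
  plot_gad_mixtures(object)
}
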