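# ggplot2 graphics: frequency histograms of SAS metrics and composition
# bar charts, the figures a morphometry study prints.

#' Frequency histograms of SAS metrics by class
#'
#' Histograms of area, perimeter and curvature, faceted by metric and
#' coloured by a class column (shape or target), the standard way SAS size
#' distributions are displayed.
#'
#' @param metrics Tibble with `corrected_area_nm2`, `corrected_perimeter_nm`,
#'   `curvature` and the grouping column.
#' @param by Bare column name to colour by (e.g. `shape_class`).
#' @param bins Histogram bin count.
#' @return A ggplot object.
#' @export
plot_sas_histograms <- function(metrics, by, bins = 30) {
  long <- metrics |>
    dplyr::select(group = {{ by }}, "corrected_area_nm2",
      "corrected_perimeter_nm", "curvature") |>
    tidyr::pivot_longer(-"group", names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value, fill = .data$group)) +
    ggplot2::geom_histogram(bins = bins, position = "identity", alpha = 0.55) +
    ggplot2::facet_wrap(~metric, scales = "free") +
    ggplot2::labs(x = NULL, y = "synapses", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Bar chart of classified composition
#'
#' Proportion of junctions per category, split by synapse type, for either
#' the shape or the target dimension.
#'
#' @param classified Per-synapse tibble with `type` and the category column.
#' @param by Bare column name (e.g. `shape_class` or `target_class`).
#' @return A ggplot object.
#' @export
plot_composition <- function(classified, by) {
  df <- classified |>
    dplyr::filter(.data$type %in% c("AS", "SS")) |>
    dplyr::count(.data$type, category = {{ by }}) |>
    dplyr::group_by(.data$type) |>
    dplyr::mutate(pct = 100 * .data$n / sum(.data$n)) |>
    dplyr::ungroup()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$category, y = .data$pct,
    fill = .data$type)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "% of synapses", fill = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn plot_composition Autoplot method for pipeline runs: shape and
#'   target composition of the classified scene.
#' @param object A `synmorph_run`.
#' @param ... Unused.
#' @export
autoplot.synmorph_run <- function(object, ...) {
  if (object$mode == "tables") {
    df <- object$reproduction$percentages
    return(
      ggplot2::ggplot(df, ggplot2::aes(x = .data$category,
        y = .data$computed_pct, fill = .data$type)) +
        ggplot2::geom_col(position = "dodge") +
        ggplot2::facet_grid(.data$table ~ .data$group, scales = "free_x") +
        ggplot2::labs(x = NULL, y = "% of synapses", fill = NULL) +
        ggplot2::theme_minimal()
    )
  }
  plot_composition(object$classified, .data$shape_class)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
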