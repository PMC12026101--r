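#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Cell-state quadrant plot
#'
#' Scatter of cells in the two-axis state space: OPC/NPC lineage above
#' the horizontal axis, AC/MES below, colored by assigned state.
#'
#' @param object A `cell_state_points` tibble from [state_coordinates()].
#' @param ... Passed to [ggplot2::geom_point()].
#' @return A ggplot object.
#' @export
autoplot.cell_state_points <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = .data$y,
                                       colour = .data$state)) +
    ggplot2::geom_point(...) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::labs(x = "within-lineage contrast (log2)",
                  y = "max(OPC, NPC) - max(AC, MES)",
                  colour = "state") +
    ggplot2::theme_minimal()
}

#' Correlation-panel heatmap
#'
#' @param object A `correlation_panel` from [correlation_panel()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.correlation_panel <- function(object, ...) {
  long <- tidy(object)
  both <- dplyr::bind_rows(
    long,
    dplyr::rename(long, var1 = "var2", var2 = "var1"),
    tibble(var1 = rownames(object$r), var2 = rownames(object$r),
           r = 1, p_value = NA_real_, padj = NA_real_,
           n = object$n, undefined = FALSE)
  )
  ggplot2::ggplot(both, ggplot2::aes(x = .data$var1, y = .data$var2,
                                     fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Pearson r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Score distribution by group
#'
#' Frequency-distribution view of a per-cell or per-sample signature
#' score split by a grouping label (e.g. GSC vs tumor cells).
#'
#' @param data A tibble.
#' @param score,group Column names (tidy-eval).
#' @return A ggplot object.
#' @export
plot_score_distribution <- function(data, score, group) {
  ggplot2::ggplot(data, ggplot2::aes(x = {{ score }},
                                     colour = {{ group }})) +
    ggplot2::geom_density() +
    ggplot2::labs(y = "density") +
    ggplot2::theme_minimal()
}
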