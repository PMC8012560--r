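#' Plot a resilience sweep
#'
#' The standard sweep display: multiplier on the x axis, ESA on the y axis,
#' line type by perturbation target, point size by SAS, and point color by
#' factor type (risk red, protective green, both/baseline black). Facets by
#' `density` or `condition` when present.
#'
#' @param object A `resilience_sweep` tibble (from [perturbation_sweep()],
#'   [run_study1()], or [run_study2()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.resilience_sweep <- function(object, ...) {
  p <- ggplot2::ggplot(
    object,
    ggplot2::aes(x = .data$multiplier, y = .data$esa)
  ) +
    ggplot2::geom_line(ggplot2::aes(linetype = .data$target)) +
    ggplot2::geom_point(
      ggplot2::aes(size = .data$sas, color = .data$factor_type)
    ) +
    ggplot2::scale_color_manual(values = c(
      risk = "#c0392b", protective = "#1e8449",
      both = "black", baseline = "black", mixed = "grey40"
    )) +
    ggplot2::labs(
      x = "multiplier constant", y = "Expected Symptom Activity (ESA)",
      size = "SAS", color = "factor type", linetype = "target"
    ) +
    ggplot2::theme_minimal()
  if ("density" %in% names(object)) {
    p <- p + ggplot2::facet_wrap(
      ~density, labeller = ggplot2::label_both
    )
  } else if ("condition" %in% names(object)) {
    p <- p + ggplot2::facet_wrap(~condition)
  }
  p
}

#' Plot node-strength centrality
#'
#' Nodes ordered from strongest to weakest, standardized strength on the
#' x axis.
#'
#' @param object A `centrality_table` from [node_strength()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.centrality_table <- function(object, ...) {
  df <- dplyr::arrange(object, .data$strength)
  df$label <- factor(df$label, levels = df$label)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$z, y = .data$label)) +
    ggplot2::geom_point() +
    ggplot2::geom_path(ggplot2::aes(group = 1)) +
    ggplot2::labs(x = "node strength (z)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
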