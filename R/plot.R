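#' Plot an edge-colored network as a status heatmap
#'
#' Tile plot of the ternary matrix with the conventional edge colors:
#' active green, inactive red, unknown black (shown grey for legibility on
#' white backgrounds when `true_black = FALSE`).
#'
#' @param object A `dtnet` object.
#' @param true_black Use pure black for unknown pairs? Default `FALSE`
#'   (dark grey).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dtnet
#' @export
autoplot.dtnet <- function(object, true_black = FALSE, ...) {
  df <- tidy(object)
  df$drug <- factor(df$drug, levels = rev(drugs(object)))
  df$target <- factor(df$target, levels = targets(object))
  df$status <- factor(df$status, levels = dt_statuses)
  fill <- c(active = "#2E7D32", inactive = "#C62828",
            unknown = if (true_black) "#000000" else "#424242")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$target, y = .data$drug,
                                   fill = .data$status)) +
    ggplot2::geom_tile(color = "white", linewidth = 0.4) +
    ggplot2::scale_fill_manual(values = fill, drop = FALSE) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "target", y = "drug", fill = "status") +
    ggplot2::theme_minimal()
}

#' Plot per-entity interaction profiles
#'
#' Scatter of active vs. inactive degrees, with point size encoding the
#' unknown degree (the third component of the profile vector). In a fully
#' determined dataset every point would have zero unknown degree and the
#' profiles would lie entirely in the active-inactive plane.
#'
#' @param network A `dtnet` object.
#' @param side `"both"`, `"drug"`, or `"target"`.
#' @return A ggplot object.
#' @export
plot_profiles <- function(network, side = c("both", "drug", "target")) {
  side <- match.arg(side)
  prof <- entity_profiles(network, side = side)
  ggplot2::ggplot(prof, ggplot2::aes(x = .data$active, y = .data$inactive,
                                     size = .data$unknown,
                                     color = .data$side)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_size_continuous(range = c(2, 7)) +
    ggplot2::labs(x = "active degree", y = "inactive degree",
                  size = "unknown", color = "side") +
    ggplot2::theme_minimal()
}
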