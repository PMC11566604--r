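# ggplot2 visualizations for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot normalized traces by region and channel
#'
#' @param traces Output of [process_traces()].
#' @param value Column to plot (`"z"`, `"dff"` or `"value"`).
#' @return A ggplot object, one facet per region, colored by channel.
#' @export
plot_traces <- function(traces, value = "z") {
  ggplot2::ggplot(traces, ggplot2::aes(x = .data$time_s, y = .data[[value]],
                                       color = .data$channel)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$region)) +
    ggplot2::scale_color_manual(values = c(astro = "#2e8b57", neuron = "#c71585",
                                           gfp = "#8fbc8f", mcherry = "#cd5c5c"),
                                na.value = "grey40") +
    ggplot2::labs(x = "time (s)", y = value) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.fp_ensemble <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time_s, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sem,
                                      ymax = .data$mean + .data$sem),
                         fill = "grey70", alpha = 0.6) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "time from event (s)", y = "z",
                  title = sprintf("Event-triggered average (n = %d trials)",
                                  nrow(object$matrix))) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.fp_connectivity <- function(object, ...) {
  d <- tibble::as_tibble(object$r, rownames = "region_i") |>
    tidyr::pivot_longer(-"region_i", names_to = "region_j", values_to = "r")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$region_j, y = .data$region_i,
                                  fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", midpoint = 0,
                                  limits = c(-1, 1)) +
    ggplot2::labs(title = sprintf("Spearman r (%s, %s)", object$cell_type,
                                  object$state),
                  x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.fp_crosscorr <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$lag_s, y = .data$r)) +
    ggplot2::geom_line() +
    ggplot2::annotate("point", x = object$peak_lag_s, y = object$peak_r,
                      color = "red") +
    ggplot2::labs(x = "lag (s; positive = astro follows neuron)", y = "r") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.fp_graph <- function(object, ...) {
  nodes <- object$nodes
  e <- object$edges
  e$x <- nodes$ml_mm[match(e$from, nodes$region)]
  e$y <- nodes$ap_mm[match(e$from, nodes$region)]
  e$xend <- nodes$ml_mm[match(e$to, nodes$region)]
  e$yend <- nodes$ap_mm[match(e$to, nodes$region)]
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = e,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend,
                                       linewidth = .data$width,
                                       color = .data$weight)) +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$ml_mm, y = .data$ap_mm), size = 6) +
    ggplot2::geom_text(data = nodes,
                       ggplot2::aes(x = .data$ml_mm, y = .data$ap_mm,
                                    label = .data$region), vjust = -1.5) +
    ggplot2::scale_linewidth_identity() +
    ggplot2::scale_color_gradient2(low = "#2166ac", mid = "grey80",
                                   high = "#b2182b", midpoint = 0,
                                   limits = c(-1, 1)) +
    ggplot2::labs(x = "ML (mm)", y = "AP (mm)",
                  title = sprintf("Connectivity graph (%s, %s)",
                                  object$cell_type, object$state)) +
    ggplot2::theme_minimal()
}

#' Plot the movement index with state segments
#'
#' @param behavior An `"fp_behavior"` object or tibble with `time_s`, `index`.
#' @param states Optional `"fp_states"` object to shade movement segments.
#' @return A ggplot object.
#' @export
plot_movement <- function(behavior, states = NULL) {
  d <- if (inherits(behavior, "fp_behavior")) behavior$movement else behavior
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$time_s, y = .data$index)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "movement index") +
    ggplot2::theme_minimal()
  if (!is.null(states)) {
    segs <- states$segments[states$segments$label == "movement", ]
    if (nrow(segs) > 0) {
      p <- p + ggplot2::geom_rect(data = segs,
                                  ggplot2::aes(xmin = .data$start_s,
                                               xmax = .data$end_s),
                                  ymin = -Inf, ymax = Inf,
                                  fill = "grey60", alpha = 0.3,
                                  inherit.aes = FALSE)
    }
  }
  p
}
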