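# ggplot2 views of the pipeline's result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Plot a raster surface
#' @param object An `fw_raster`.
#' @param name Fill legend label.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fw_raster <- function(object, name = "value", ...) {
  df <- as_tibble.fw_raster(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x / 1000, y = .data$y / 1000,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = name, na.value = "grey90") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (km)", y = "y (km)") +
    ggplot2::theme_minimal()
}

#' Plot a cumulative current map (log colour scale)
#' @param object A `current_map`.
#' @param ... Unused.
#' @export
autoplot.current_map <- function(object, ...) {
  df <- as_tibble.fw_raster(object$cumulative)
  df$value <- log10(pmax(df$value, 1e-12))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x / 1000, y = .data$y / 1000,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "log10 current", option = "magma",
                                  na.value = "grey90") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (km)", y = "y (km)") +
    ggplot2::theme_minimal()
}

#' Improvement-versus-cost view of the scenario grid
#'
#' One point per fence-removal scenario: removal cost against the
#' percentage of fencing-induced connectivity loss restored, labelled by
#' corridor width.
#'
#' @param object A `scenario_results` tibble from [run_scenarios()].
#' @param ... Unused.
#' @export
autoplot.scenario_results <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$cost_usd, y = .data$improvement_pct,
                               colour = .data$corridor_id)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$corridor_id),
                       linewidth = 0.4, alpha = 0.6) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_text(ggplot2::aes(label = .data$width_km), vjust = -0.9,
                       size = 3, show.legend = FALSE) +
    ggplot2::labs(x = "Removal cost (USD)",
                  y = "Connectivity loss restored (%)",
                  colour = "Corridor") +
    ggplot2::theme_minimal()
}

#' Plot trajectories over an optional background raster
#' @param traj Trajectory tibble.
#' @param background Optional `fw_raster`.
#' @return A ggplot.
#' @export
plot_trajectories <- function(traj, background = NULL) {
  p <- ggplot2::ggplot()
  if (!is.null(background)) {
    df <- as_tibble.fw_raster(background)
    p <- p + ggplot2::geom_raster(
      data = df, ggplot2::aes(x = .data$x / 1000, y = .data$y / 1000,
                              fill = .data$value)) +
      ggplot2::scale_fill_viridis_c(na.value = "grey90")
  }
  p + ggplot2::geom_path(
    data = traj, ggplot2::aes(x = .data$x / 1000, y = .data$y / 1000,
                              group = .data$animal_id,
                              colour = .data$animal_id),
    alpha = 0.7, show.legend = FALSE) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (km)", y = "y (km)") +
    ggplot2::theme_minimal()
}
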