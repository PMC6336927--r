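#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot methods for cortexgrid results
#'
#' `autoplot()` turns each report or fixture type into a standard
#' ggplot2 figure: feature placements as a labeled canvas, capacity
#' reports as empirical collision rates against the birthday curve,
#' recognition reports as the distribution of sensations-to-recognition
#' by column count, navigation reports as arrival-error positions.
#'
#' @param object The object to plot.
#' @param ... Unused.
#' @return A ggplot object.
#' @name cortexgrid-autoplot
NULL

#' @rdname cortexgrid-autoplot
#' @exportS3Method ggplot2::autoplot
autoplot.feature_placements <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = .data$y,
                                       label = .data$feature)) +
    ggplot2::geom_label() +
    ggplot2::coord_equal() +
    ggplot2::labs(title = "Feature placements", x = "x (world units)",
                  y = "y (world units)")
}

#' @rdname cortexgrid-autoplot
#' @exportS3Method ggplot2::autoplot
autoplot.capacity_report <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$n_modules)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$predicted),
                       linetype = "dashed") +
    ggplot2::geom_point(ggplot2::aes(y = .data$collision_rate), size = 2) +
    ggplot2::labs(
      title = "Anchor collision rate vs module count",
      subtitle = "points: empirical; dashed: birthday approximation",
      x = "modules", y = "collision rate"
    )
}

#' @rdname cortexgrid-autoplot
#' @exportS3Method ggplot2::autoplot
autoplot.recognition_report <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$n_columns <- factor(df$n_columns)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sensations,
                                   fill = .data$n_columns)) +
    ggplot2::geom_bar(position = "dodge") +
    ggplot2::labs(title = "Sensations to recognition",
                  x = "sensations", y = "trials", fill = "columns")
}

#' @rdname cortexgrid-autoplot
#' @exportS3Method ggplot2::autoplot
autoplot.navigation_report <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$bx - .data$ax,
                                       y = .data$by - .data$ay,
                                       colour = .data$outcome)) +
    ggplot2::geom_point() +
    ggplot2::coord_equal() +
    ggplot2::labs(title = "Decoded point-to-point vectors",
                  x = "true dx", y = "true dy")
}

#' @importFrom rlang .data
NULL
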