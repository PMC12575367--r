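# ggplot2 visualisations of the package's result types: displacement
# heatmap with arrows, gamma histogram with its Gaussian fit, the
# orientation-vs-sector regression, and rose (windrose) diagrams.

#' Displacement magnitude map with arrows
#'
#' Heatmap of the interpolated displacement magnitude with an arrow field
#' sub-sampled from the grid, mirroring the classic bead-displacement
#' figure of stretch-device validation.
#'
#' @param map A `displacement_magnitude_map` from [displacement_map()].
#' @param arrow_every Draw an arrow at every n-th grid node (default 4).
#' @param arrow_scale Multiplier applied to arrow lengths (default 1).
#' @return A ggplot object.
#' @export
plot_displacement_map <- function(map, arrow_every = 4, arrow_scale = 1) {
  ok <- map[!is.na(map$magnitude), ]
  xs <- sort(unique(ok$x)); ys <- sort(unique(ok$y))
  sub <- ok[ok$x %in% xs[seq(1, length(xs), arrow_every)] &
              ok$y %in% ys[seq(1, length(ys), arrow_every)], ]
  ggplot2::ggplot(ok, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$magnitude)) +
    ggplot2::geom_segment(
      data = sub,
      ggplot2::aes(xend = .data$x + arrow_scale * .data$ux,
                   yend = .data$y + arrow_scale * .data$uy),
      arrow = ggplot2::arrow(length = ggplot2::unit(1.5, "mm")),
      linewidth = 0.3, colour = "white") +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = "|u| (µm)") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)") +
    ggplot2::theme_minimal()
}

#' Angular-alignment histogram with Gaussian fit
#'
#' @param fit A `gamma_fit` from [fit_gamma()].
#' @return A ggplot object.
#' @export
plot_gamma_histogram <- function(fit) {
  h <- fit$histogram
  bw <- diff(h$mid[1:2])
  curve <- tibble::tibble(x = seq(-90, 90, length.out = 361))
  curve$y <- fit$n * bw * stats::dnorm(curve$x, fit$mu, max(fit$sigma, 1e-6))
  ggplot2::ggplot(h, ggplot2::aes(x = .data$mid, y = .data$count)) +
    ggplot2::geom_col(width = bw, fill = "grey65", colour = "grey30") +
    ggplot2::geom_line(data = curve, ggplot2::aes(x = .data$x, y = .data$y),
                       colour = "firebrick", linewidth = 0.8) +
    ggplot2::labs(x = "angular alignment γ (deg)", y = "count",
                  subtitle = sprintf("μ = %.2f°, σ = %.2f°",
                                     fit$mu, fit$sigma)) +
    ggplot2::theme_minimal()
}

#' Orientation-vs-sector regression plot
#'
#' @param reg An `alignment_regression` from [orientation_regression()].
#' @return A ggplot object.
#' @export
plot_orientation_regression <- function(reg) {
  ggplot2::ggplot(reg$per_sector,
                  ggplot2::aes(x = .data$sector_orientation,
                               y = .data$mean_unwrapped)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "firebrick", linewidth = 0.7) +
    ggplot2::labs(x = "sector orientation (deg)",
                  y = "mean object orientation (deg)",
                  subtitle = sprintf("slope = %.3f, r² = %.3f",
                                     reg$slope, reg$r_squared)) +
    ggplot2::theme_minimal()
}

#' Rose (windrose) diagram of directions
#'
#' @param rose A tibble from [rose_histogram()].
#' @param title Optional title.
#' @return A ggplot object in polar coordinates.
#' @export
plot_rose <- function(rose, title = NULL) {
  ggplot2::ggplot(rose, ggplot2::aes(x = .data$mid, y = .data$count)) +
    ggplot2::geom_col(width = diff(rose$mid[1:2]), fill = "steelblue",
                      colour = "grey20", linewidth = 0.2) +
    ggplot2::coord_polar(start = pi / 2, direction = -1) +
    ggplot2::scale_x_continuous(limits = c(-180, 180),
                                breaks = seq(-180, 135, by = 45)) +
    ggplot2::labs(x = NULL, y = "occurrences", title = title) +
    ggplot2::theme_minimal()
}

#' Turning-angle histogram
#'
#' @param angles Numeric vector of turning angles in degrees, or a
#'   `step_stats` object.
#' @param binwidth Bin width in degrees (default 20).
#' @return A ggplot object.
#' @export
plot_turning_histogram <- function(angles, binwidth = 20) {
  if (inherits(angles, "step_stats")) angles <- angles$turning$angle
  df <- tibble::tibble(angle = angles)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$angle)) +
    ggplot2::geom_histogram(breaks = seq(-180, 180, by = binwidth),
                            fill = "grey65", colour = "grey30") +
    ggplot2::labs(x = "turning angle (deg)", y = "count") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.gamma_fit <- function(object, ...) plot_gamma_histogram(object)

#' @export
autoplot.alignment_regression <- function(object, ...) {
  plot_orientation_regression(object)
}

#' @export
autoplot.displacement_magnitude_map <- function(object, ...) {
  plot_displacement_map(object, ...)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
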