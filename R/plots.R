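#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL

#' Plot a 2-D power spectrum as a heat map
#'
#' Log-scaled power over the centered spatial-frequency plane; the distance
#' from the origin is the spatial frequency in cycles/nm and the direction
#' is the orientation of the component waves in the image.
#'
#' @param object A `power_spectrum`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.power_spectrum <- function(object, ...) {
  d <- tidyr::expand_grid(ky = object$freq, kx = object$freq)
  d$power <- as.vector(t(object$power))
  ggplot2::ggplot(d, ggplot2::aes(.data$kx, .data$ky,
                                  fill = log10(.data$power + 1e-12))) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "log10 power") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "spatial frequency kx (cycles/nm)",
                  y = "spatial frequency ky (cycles/nm)") +
    ggplot2::theme_minimal()
}

#' Plot a radial power profile
#'
#' @param object A `radial_profile`.
#' @param ... Unused.
#' @return A ggplot of % power against spatial frequency.
#' @export
autoplot.radial_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$freq, .data$power_pct)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "spatial frequency (cycles/nm)",
                  y = "% of total Fourier power") +
    ggplot2::theme_minimal()
}

#' Plot a predicted reflectance spectrum
#'
#' Shades the visible band and marks the peak wavelength.
#'
#' @param object A `predicted_spectrum`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.predicted_spectrum <- function(object, ...) {
  d <- object$data
  ggplot2::ggplot(d, ggplot2::aes(.data$wavelength, .data$reflectance)) +
    ggplot2::annotate("rect",
                      xmin = object$visible_band[1],
                      xmax = object$visible_band[2],
                      ymin = -Inf, ymax = Inf, alpha = 0.08, fill = "blue") +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$lambda_max, linetype = 2) +
    ggplot2::coord_cartesian(
      xlim = c(object$visible_band[1] * 0.7, object$visible_band[2] * 1.6)) +
    ggplot2::labs(x = "wavelength (nm)",
                  y = "predicted reflectance (% power)") +
    ggplot2::theme_minimal()
}

#' Plot a zone color reconstruction as labeled swatches
#'
#' @param object A `zone_color_map` or the `zones` tibble of a
#'   `reconstruction_report`.
#' @param ... Unused.
#' @return A ggplot with one filled tile per zone, in map order.
#' @export
autoplot.zone_color_map <- function(object, ...) {
  d <- tibble::as_tibble(object)
  d$zone <- factor(d$zone, levels = d$zone)
  ggplot2::ggplot(d, ggplot2::aes(.data$zone, 1)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$zone),
                       width = 0.95, height = 1, show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = stats::setNames(d$hex, d$zone)) +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%s\n%.0f nm", .data$zone, .data$lambda_max)),
      vjust = 0.5, size = 3) +
    ggplot2::theme_void()
}

#' @export
autoplot.reconstruction_report <- function(object, ...) {
  z <- object$zones[!is.na(object$zones$lambda_max), ]
  autoplot.zone_color_map(z, ...)
}
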