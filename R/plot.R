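# ggplot2 visualisation: autoplot methods for panoramas, angular images,
# index series and index-GPP fits.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

.plot_angular <- function(df, fill_lab, title = NULL) {
  ggplot2::ggplot(df, ggplot2::aes(x = .data$azimuth, y = .data$elevation,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey85", name = fill_lab) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "azimuth (deg)", y = "elevation (deg)",
                  title = title) +
    ggplot2::theme_minimal()
}

#' Plot a reflectance panorama band
#'
#' @param object A `reflectance_panorama`.
#' @param band Band index or wavelength in nm (matched to the nearest band
#'   centre when > number of bands).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.reflectance_panorama <- function(object, band = 1, ...) {
  wl <- attr(object, "wavelength")
  if (band > length(wl)) band <- which.min(abs(wl - band))
  .plot_angular(as_tibble_panorama(object, band), "reflectance",
                sprintf("%.0f nm", wl[band]))
}

#' Plot a surface-temperature panorama
#'
#' @param object A `thermal_panorama`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.thermal_panorama <- function(object, ...) {
  .plot_angular(as_tibble_panorama(object), "T (K)")
}

#' Plot an angular image (range, Pgap, index map or mask)
#'
#' @param object An `angular_image`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.angular_image <- function(object, ...) {
  df <- as_tibble_panorama(object)
  if (is.character(df$value)) {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$azimuth, y = .data$elevation,
                                     fill = .data$value)) +
      ggplot2::geom_raster() +
      ggplot2::coord_fixed() +
      ggplot2::labs(x = "azimuth (deg)", y = "elevation (deg)",
                    fill = "class") +
      ggplot2::theme_minimal()
  } else {
    .plot_angular(df, "value")
  }
}

#' Plot an index--GPP regression
#'
#' Scatter of daily GPP against the index with the fitted line.
#'
#' @param object An `index_gpp_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.index_gpp_fit <- function(object, ...) {
  df <- object$model$model
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_abline(intercept = object$intercept, slope = object$slope,
                         colour = "firebrick") +
    ggplot2::labs(x = "vegetation index", y = "daily GPP",
                  subtitle = sprintf("R² = %.2f, slope = %.3g, n = %d",
                                     object$r_squared, object$slope,
                                     object$n)) +
    ggplot2::theme_minimal()
}

#' Plot a daily vegetation-index time series
#'
#' @param series Tibble with `date`, `value` and optionally `stability`
#'   (mapped to colour) and `index` (facetted).
#' @return A ggplot.
#' @export
plot_index_series <- function(series) {
  p <- ggplot2::ggplot(series, ggplot2::aes(x = .data$date, y = .data$value))
  p <- if ("stability" %in% names(series))
    p + ggplot2::geom_point(ggplot2::aes(colour = pmin(.data$stability, 100))) +
      ggplot2::scale_colour_viridis_c(name = "stability")
  else p + ggplot2::geom_point()
  if ("index" %in% names(series))
    p <- p + ggplot2::facet_wrap(~index, scales = "free_y")
  p + ggplot2::labs(x = NULL, y = "index value") + ggplot2::theme_minimal()
}
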