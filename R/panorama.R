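# Angular raster containers. A panorama is a base array [azimuth,
# elevation(, band)] carrying coordinate vectors as attributes; the angular
# grid is the common frame all imagery and TLS products are registered to.

.new_panorama <- function(x, azimuth, elevation, wavelength = NULL, class,
                          units = NULL) {
  if (is.matrix(x) && !is.null(wavelength)) x <- array(x, c(dim(x), 1))
  d <- dim(x)
  stopifnot(d[1] == length(azimuth), d[2] == length(elevation))
  if (!is.null(wavelength)) {
    stopifnot(d[3] == length(wavelength))
    if (is.unsorted(wavelength, strictly = TRUE))
      stop("band centres must be strictly increasing", call. = FALSE)
  }
  structure(x, azimuth = azimuth, elevation = elevation,
            wavelength = wavelength, units = units,
            class = c(class, "panorama"))
}

#' Construct a radiance panorama cube
#'
#' @param x Array `[azimuth, elevation, band]` of spectral radiance,
#'   W m-2 sr-1 um-1.
#' @param azimuth,elevation Cell-centre coordinate vectors, degrees.
#' @param wavelength Band centres, nm, strictly increasing.
#' @return A `radiance_panorama`.
#' @export
radiance_panorama <- function(x, azimuth, elevation, wavelength) {
  .new_panorama(x, azimuth, elevation, wavelength, "radiance_panorama",
                units = "W m-2 sr-1 um-1")
}

#' Construct a reflectance panorama cube
#'
#' Hemispherical-conical reflectance factors (unitless). Values above 1 are
#' physically possible on sunlit facets and are kept; values above
#' `flag_above` are flagged (attribute `n_flagged`), not clipped.
#'
#' @inheritParams radiance_panorama
#' @param flag_above Flag threshold for suspicious reflectance.
#' @return A `reflectance_panorama`.
#' @export
reflectance_panorama <- function(x, azimuth, elevation, wavelength,
                                 flag_above = 1.5) {
  p <- .new_panorama(x, azimuth, elevation, wavelength,
                     "reflectance_panorama", units = "unitless")
  attr(p, "n_flagged") <- sum(p > flag_above, na.rm = TRUE)
  p
}

#' Construct a surface-temperature panorama
#'
#' @param x Matrix `[azimuth, elevation]` of surface temperature, kelvin.
#' @param azimuth,elevation Cell-centre coordinates, degrees.
#' @param tau Optional matrix of per-cell path transmittance used.
#' @param path_length Optional matrix of per-cell path length (m).
#' @return A `thermal_panorama`.
#' @export
thermal_panorama <- function(x, azimuth, elevation, tau = NULL,
                             path_length = NULL) {
  p <- .new_panorama(x, azimuth, elevation, NULL, "thermal_panorama",
                     units = "K")
  attr(p, "tau") <- tau
  attr(p, "path_length") <- path_length
  p
}

#' Angular coordinate helper
#'
#' Cell-centre coordinates for a regular angular grid.
#'
#' @param from,to Grid limits, degrees.
#' @param step Cell size, degrees.
#' @return Numeric vector of cell centres.
#' @export
angular_axis <- function(from, to, step) {
  seq(from + step / 2, to - step / 2, by = step)
}

#' @export
print.panorama <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<%s> %d azimuth x %d elevation%s cells\n", class(x)[1], d[1],
              d[2], if (length(d) == 3) sprintf(" x %d band", d[3]) else ""))
  az <- attr(x, "azimuth"); el <- attr(x, "elevation")
  cat(sprintf("  azimuth %.2f..%.2f deg, elevation %.2f..%.2f deg\n",
              min(az), max(az), min(el), max(el)))
  wl <- attr(x, "wavelength")
  if (!is.null(wl))
    cat(sprintf("  bands %.1f..%.1f nm\n", min(wl), max(wl)))
  if (!is.null(attr(x, "units"))) cat("  units:", attr(x, "units"), "\n")
  invisible(x)
}

#' Convert a panorama band or image to a tidy tibble
#'
#' @param x A panorama object.
#' @param band Band index for cubes (default 1); ignored for single-band
#'   panoramas.
#' @param ... Unused.
#' @return Tibble with `azimuth`, `elevation`, `value`.
#' @export
as_tibble_panorama <- function(x, band = 1, ...) {
  az <- attr(x, "azimuth"); el <- attr(x, "elevation")
  v <- if (length(dim(x)) == 3) unclass(x)[, , band] else unclass(x)
  tibble::tibble(azimuth = rep(az, times = length(el)),
                 elevation = rep(el, each = length(az)),
                 value = as.vector(v))
}
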