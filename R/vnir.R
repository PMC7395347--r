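# VNIR radiometry: raw line-scan counts -> dark-corrected counts ->
# calibrated radiance -> hemispherical-conical reflectance rho = pi * L / E,
# with irradiance band-matching, per-column interpolation, spectral
# smoothing and end-member extraction.

#' Dark-current correction
#'
#' Subtracts the mean closed-shutter dark frame from every spatial and
#' spectral pixel, clipping negative results at zero. The clipped-count
#' fraction is recorded in the `n_clipped` attribute.
#'
#' @param raw Numeric array of raw counts; the first dimensions must match
#'   `dark` (frames may be stacked along one extra trailing dimension).
#' @param dark Dark model: per-(pixel, band) mean counts (matrix), e.g. the
#'   average of 100 closed-shutter frames.
#' @return Corrected counts, same shape as `raw`, with attribute
#'   `n_clipped`.
#' @export
dark_correct <- function(raw, dark) {
  rd <- dim(raw); dd <- dim(dark)
  if (is.null(dd)) dd <- length(dark)
  if (is.null(rd)) rd <- length(raw)
  if (length(rd) < length(dd) || !all(rd[seq_along(dd)] == dd))
    stop("raw and dark shapes do not match", call. = FALSE)
  out <- raw - as.vector(dark)   # dark recycles over trailing frame dim
  n_clipped <- sum(out < 0)
  out[out < 0] <- 0
  attr(out, "n_clipped") <- n_clipped
  out
}

#' Radiometric calibration model
#'
#' Linear counts-to-radiance model fitted against a calibrated uniform
#' radiance source: `L = gain * counts + offset` per pixel and band.
#'
#' @param gain Per-(pixel, band) gain, W m-2 sr-1 um-1 per count; must be
#'   positive. Scalars are recycled.
#' @param offset Per-(pixel, band) offset, same units.
#' @param integration_time_ms,gain_setting Settings the model is valid for.
#' @return A `calibration_model`.
#' @export
calibration_model <- function(gain, offset = 0, integration_time_ms = NULL,
                              gain_setting = NULL) {
  if (any(gain <= 0)) stop("gain must be positive", call. = FALSE)
  structure(list(gain = gain, offset = offset,
                 integration_time_ms = integration_time_ms,
                 gain_setting = gain_setting),
            class = "calibration_model")
}

#' Apply a radiometric calibration
#'
#' @param counts Dark-corrected counts (array; frames may be stacked along a
#'   trailing dimension over which gain/offset recycle).
#' @param cal A [calibration_model()].
#' @param integration_time_ms If given, must equal the model's validity
#'   setting.
#' @return Radiance, same shape, W m-2 sr-1 um-1.
#' @export
apply_calibration <- function(counts, cal, integration_time_ms = NULL) {
  stopifnot(inherits(cal, "calibration_model"))
  if (!is.null(integration_time_ms) && !is.null(cal$integration_time_ms) &&
      integration_time_ms != cal$integration_time_ms)
    stop("integration time does not match calibration validity", call. = FALSE)
  out <- as.vector(cal$gain) * counts + as.vector(cal$offset)
  attr(out, "n_clipped") <- NULL
  out
}

#' Gaussian spectral response for the line scanner's bands
#'
#' @param centre Band centres, nm, strictly increasing.
#' @param fwhm Full width at half maximum per band, nm; default twice the
#'   band spacing.
#' @return A `spectral_response` tibble with columns `centre`, `fwhm`.
#' @export
spectral_response <- function(centre, fwhm = NULL) {
  if (is.unsorted(centre, strictly = TRUE))
    stop("band centres must be strictly increasing", call. = FALSE)
  if (is.null(fwhm)) fwhm <- 2 * stats::median(diff(centre))
  fwhm <- rep_len(fwhm, length(centre))
  if (any(fwhm <= 0)) stop("FWHM must be positive", call. = FALSE)
  structure(tibble::tibble(centre = centre, fwhm = fwhm),
            class = c("spectral_response", class(tibble::tibble())))
}

#' Band-match an irradiance spectrum to the imager's bands
#'
#' Convolves the spectrometer irradiance to the line scanner's band centres
#' and widths: each output band is the unit-area Gaussian-SRF-weighted mean
#' of E(lambda) on the spectrometer grid (trapezoidal integration weights,
#' so non-uniform grids are handled).
#'
#' @param E Tibble with `wavelength` (nm, strictly increasing) and
#'   `irradiance` (W m-2 um-1).
#' @param srf A [spectral_response()].
#' @return Tibble with `wavelength` (= band centres) and `irradiance`.
#' @export
band_match_irradiance <- function(E, srf) {
  stopifnot(all(c("wavelength", "irradiance") %in% names(E)))
  wl <- E$wavelength
  if (is.unsorted(wl, strictly = TRUE))
    stop("spectrometer wavelengths must be strictly increasing", call. = FALSE)
  out_of_range <- srf$centre < min(wl) | srf$centre > max(wl)
  if (any(out_of_range))
    stop("band centres outside spectrometer range: ",
         paste(srf$centre[out_of_range], collapse = ", "), call. = FALSE)
  # trapezoid weights on the input grid
  dw <- diff(wl)
  tw <- c(dw[1] / 2, (dw[-length(dw)] + dw[-1]) / 2, dw[length(dw)] / 2)
  vals <- vapply(seq_len(nrow(srf)), function(i) {
    sig <- srf$fwhm[i] / (2 * sqrt(2 * log(2)))
    g <- exp(-((wl - srf$centre[i])^2) / (2 * sig^2)) * tw
    sum(g * E$irradiance) / sum(g)
  }, numeric(1))
  tibble::tibble(wavelength = srf$centre, irradiance = vals)
}

#' Interpolate irradiance across the columns of a panorama
#'
#' The scan-start and scan-end irradiance spectra are linearly interpolated
#' to every azimuth column, assuming sky conditions change linearly during
#' the sweep. With a dense irradiance series (spectra every few seconds)
#' time-linear interpolation between the bracketing spectra is used instead.
#'
#' @param E_start,E_end Tibbles (`wavelength`, `irradiance`) on the same
#'   band grid.
#' @param n_columns Number of azimuth columns (>= 1).
#' @param series Optional dense mode: a list with `times` (seconds from scan
#'   start) and `spectra` (matrix, one row per spectrum, columns = bands).
#' @param column_times Required with `series`: acquisition time (s) of each
#'   column.
#' @return Matrix `[n_columns, n_bands]` of irradiance.
#' @export
interpolate_irradiance <- function(E_start, E_end, n_columns, series = NULL,
                                   column_times = NULL) {
  if (n_columns < 1) stop("n_columns must be >= 1", call. = FALSE)
  if (!is.null(series)) {
    stopifnot(!is.null(column_times), length(column_times) == n_columns)
    nb <- ncol(series$spectra)
    out <- vapply(seq_len(nb), function(b) {
      approx(series$times, series$spectra[, b], xout = column_times,
             rule = 2)$y
    }, numeric(n_columns))
    return(matrix(out, nrow = n_columns))
  }
  stopifnot(identical(E_start$wavelength, E_end$wavelength))
  s <- E_start$irradiance; e <- E_end$irradiance
  f <- if (n_columns == 1) 0 else (seq_len(n_columns) - 1) / (n_columns - 1)
  outer(f, e - s) + matrix(s, n_columns, length(s), byrow = TRUE)
}

#' Compute hemispherical-conical reflectance
#'
#' `rho(lambda) = pi * L(lambda) / E(lambda)` per pixel and band, with E
#' interpolated per azimuth column. Cells where E <= 0 at a used band are
#' masked (NA) and counted in the `n_masked` attribute rather than raising.
#'
#' @param L A [radiance_panorama()].
#' @param E_columns Matrix `[n_azimuth, n_bands]` from
#'   [interpolate_irradiance()] (a single spectrum vector is recycled to all
#'   columns).
#' @param flag_above Reflectance flag threshold (see
#'   [reflectance_panorama()]).
#' @return A [reflectance_panorama()] with attribute `n_masked`.
#' @export
compute_reflectance <- function(L, E_columns, flag_above = 1.5) {
  stopifnot(inherits(L, "radiance_panorama"))
  d <- dim(L)
  if (is.vector(E_columns)) E_columns <- matrix(E_columns, d[1], d[3],
                                                byrow = TRUE)
  stopifnot(nrow(E_columns) == d[1], ncol(E_columns) == d[3])
  bad <- E_columns <= 0
  E_columns[bad] <- NA_real_
  # broadcast E over the elevation dimension
  Ef <- aperm(array(E_columns, c(d[1], d[3], d[2])), c(1, 3, 2))
  rho <- pi * unclass(L) / Ef
  p <- reflectance_panorama(rho, attr(L, "azimuth"), attr(L, "elevation"),
                            attr(L, "wavelength"), flag_above = flag_above)
  attr(p, "n_masked") <- sum(is.na(rho))
  p
}

# centred moving average with truncated edge windows, via cumulative sums
.moving_average <- function(m, half) {
  # m: matrix [series, bands]; average over band window [b-half, b+half]
  nb <- ncol(m)
  cs <- cbind(0, t(apply(m, 1, cumsum)))
  lo <- pmax(seq_len(nb) - half, 1)
  hi <- pmin(seq_len(nb) + half, nb)
  (cs[, hi + 1, drop = FALSE] - cs[, lo, drop = FALSE]) /
    matrix(hi - lo + 1, nrow(m), nb, byrow = TRUE)
}

#' Smooth spectra with a fixed-wavelength moving average
#'
#' Centred moving average over all bands within +/- `window_nm / 2` of each
#' band centre (an odd number of bands on a uniform grid); edge bands use
#' the truncated window. Raises the signal-to-noise ratio without erasing
#' pigment absorption features. If the window is narrower than the band
#' spacing the input is returned unchanged with a warning.
#'
#' @param x A `reflectance_panorama`, a numeric spectrum vector, or a matrix
#'   of spectra (rows = spectra, columns = bands).
#' @param wavelength Band centres, nm (taken from the panorama if omitted).
#' @param window_nm Window width, nm; default 10.
#' @return Same type as `x`, smoothed along the band dimension.
#' @export
smooth_spectrum <- function(x, wavelength = NULL, window_nm = 10) {
  if (inherits(x, "reflectance_panorama")) {
    wl <- attr(x, "wavelength")
    d <- dim(x)
    m <- matrix(unclass(x), d[1] * d[2], d[3])
    sm <- smooth_spectrum(m, wl, window_nm)
    return(reflectance_panorama(array(sm, d), attr(x, "azimuth"),
                                attr(x, "elevation"), wl))
  }
  if (is.null(wavelength)) stop("wavelength grid required", call. = FALSE)
  spacing <- stats::median(diff(wavelength))
  if (window_nm < spacing) {
    warning("smoothing window narrower than band spacing; returning input")
    return(x)
  }
  half <- floor((window_nm / 2) / spacing)
  if (is.matrix(x)) .moving_average(x, half)
  else as.vector(.moving_average(matrix(x, 1), half))
}

#' Extract an end-member spectrum from a pixel set
#'
#' Per-band mean and population standard deviation over a hand-picked
#' region (typically 30--50 pixels of pure foliage, bark or ground cover).
#'
#' @param pano A `reflectance_panorama`.
#' @param pixels Two-column matrix or data frame of (azimuth index,
#'   elevation index) pairs.
#' @return Tibble with `wavelength`, `mean`, `sd` (population) and `n`.
#' @export
extract_endmember <- function(pano, pixels) {
  stopifnot(inherits(pano, "reflectance_panorama"))
  pixels <- as.matrix(pixels)
  if (nrow(pixels) == 0) stop("pixel set is empty", call. = FALSE)
  d <- dim(pano)
  if (any(pixels[, 1] < 1 | pixels[, 1] > d[1] |
          pixels[, 2] < 1 | pixels[, 2] > d[2]))
    stop("pixel indices outside the cube", call. = FALSE)
  arr <- unclass(pano)
  spectra <- t(vapply(seq_len(nrow(pixels)),
                      function(i) arr[pixels[i, 1], pixels[i, 2], ],
                      numeric(d[3])))
  mu <- colMeans(spectra)
  pop_sd <- sqrt(colMeans(sweep(spectra, 2, mu)^2))
  tibble::tibble(wavelength = attr(pano, "wavelength"), mean = mu,
                 sd = pop_sd, n = nrow(pixels))
}

#' Flag oxygen-A absorption bands
#'
#' Bands in the 755--770 nm oxygen absorption region suffer from sub-band
#' misregistration between sensors and are conventionally excluded from
#' display; this returns a logical flag per band (no data are altered).
#'
#' @param wavelength Band centres, nm.
#' @param range Flag interval, nm.
#' @return Logical vector.
#' @export
o2a_flag <- function(wavelength, range = c(755, 770)) {
  wavelength >= range[1] & wavelength <= range[2]
}
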