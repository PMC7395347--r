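# Acquisition-level quality control: irradiance stability ratio, PAR-based
# sky-stability indicator and threshold filter, clearness index / diffuse
# fraction, and a PAR-consistency check of the irradiance spectrometer.
# All decisions are pure functions of inputs and thresholds.

#' Scan-start / scan-end irradiance ratio
#'
#' Ratio of the broadband integrals of the two irradiance spectra over the
#' stated band range; an acquisition passes when the ratio lies within
#' 1 +/- `tolerance`. A zero end-of-scan integral is a fail (flag, not
#' exception).
#'
#' @param E_start,E_end Tibbles (`wavelength` nm, `irradiance`) on a common
#'   grid.
#' @param band_range Integration limits, nm; default 400--900.
#' @param tolerance Pass band half-width; default 0.1.
#' @return Tibble with `ratio` and logical `pass`.
#' @export
irradiance_ratio <- function(E_start, E_end, band_range = c(400, 900),
                             tolerance = 0.1) {
  stopifnot(identical(E_start$wavelength, E_end$wavelength))
  keep <- E_start$wavelength >= band_range[1] &
    E_start$wavelength <= band_range[2]
  wl <- E_start$wavelength[keep]
  trap <- function(y) sum(diff(wl) * (head(y, -1) + tail(y, -1)) / 2)
  num <- trap(E_start$irradiance[keep])
  den <- trap(E_end$irradiance[keep])
  if (den <= 0)
    return(tibble::tibble(ratio = NA_real_, pass = FALSE))
  r <- num / den
  tibble::tibble(ratio = r, pass = abs(r - 1) <= tolerance)
}

#' PAR sky-stability indicator
#'
#' Mean divided by population standard deviation of the 1 Hz PAR trace
#' covering a scan; large values indicate steady sky conditions. A constant
#' trace has zero SD and returns `Inf` (a defined pass sentinel).
#'
#' @param par Numeric PAR vector (umol m-2 s-1) or tibble with a `par`
#'   column; needs at least 2 samples.
#' @return The indicator (scalar).
#' @export
stability_indicator <- function(par) {
  if (is.data.frame(par)) par <- par$par
  if (length(par) < 2) stop("need at least 2 PAR samples", call. = FALSE)
  pop_sd <- sqrt(mean((par - mean(par))^2))
  if (pop_sd == 0) return(Inf)
  mean(par) / pop_sd
}

#' Filter acquisitions by sky stability
#'
#' @param records Tibble with a `stability` column (one row per
#'   acquisition).
#' @param threshold Keep rows with `stability > threshold`; default 30.
#' @return `records` with logical column `kept` added; attributes `n_kept`
#'   and `n_discarded` record the partition sizes.
#' @export
stability_filter <- function(records, threshold = 30) {
  stopifnot("stability" %in% names(records))
  out <- dplyr::mutate(records, kept = .data$stability > threshold)
  attr(out, "n_kept") <- sum(out$kept)
  attr(out, "n_discarded") <- sum(!out$kept)
  out
}

#' Clearness index and diffuse fraction
#'
#' Ratio of observed to potential (clear-sky) shortwave irradiance, clamped
#' to \[0, 1\]; `diffuse_fraction = 1 - clearness`. Cloud-enhancement cases
#' (observed above clear-sky) clamp to 1 and are flagged. Undefined
#' (masked) when the clear-sky value is not positive, i.e. sun below the
#' horizon.
#'
#' @param sw_obs Observed shortwave down-welling, W m-2.
#' @param sw_clear Modelled clear-sky shortwave, W m-2 (see
#'   [potential_shortwave()]).
#' @return Tibble with `clearness`, `diffuse_fraction`, `enhanced` flag.
#'   Vectorised.
#' @export
clearness_index <- function(sw_obs, sw_clear) {
  ci <- ifelse(sw_clear > 0, sw_obs / sw_clear, NA_real_)
  enhanced <- !is.na(ci) & ci > 1
  ci <- pmin(pmax(ci, 0), 1)
  tibble::tibble(clearness = ci, diffuse_fraction = 1 - ci,
                 enhanced = enhanced)
}

#' Potential (clear-sky) shortwave irradiance
#'
#' Simple clear-sky model: solar constant, times the Earth--Sun distance
#' factor, times the sine of solar elevation, times a fixed broadband
#' atmospheric transmittance. Zero when the sun is at or below the horizon.
#'
#' @param site A [site_location()].
#' @param timestamp As in [solar_position()]; vectorised.
#' @param clear_sky_transmittance Broadband transmittance; default 0.75.
#' @param solar_constant W m-2.
#' @return Clear-sky shortwave, W m-2.
#' @export
potential_shortwave <- function(site, timestamp,
                                clear_sky_transmittance = 0.75,
                                solar_constant = 1361) {
  sp <- solar_position(site, timestamp)
  doy <- as.integer(format(sp$time, "%j"))
  dist_factor <- 1 + 0.033 * cos(2 * pi * doy / 365)
  ifelse(sp$elevation > 0,
         solar_constant * dist_factor * sin(sp$elevation * pi / 180) *
           clear_sky_transmittance,
         0)
}

#' PAR consistency check of the irradiance spectrometer
#'
#' Models PAR from the irradiance spectrum as the quantum (photon-flux)
#' integral over the PAR sensor response -- by default an ideal quantum
#' response over 400--700 nm -- and compares it with the independently
#' measured broadband PAR. The ratio observed/modelled is a first-order
#' correction factor for spectrometer temperature sensitivity; when
#' `correct = TRUE` the spectrum is rescaled by it.
#'
#' @param E Tibble (`wavelength` nm, `irradiance` W m-2 um-1) covering the
#'   PAR range.
#' @param par_obs Observed PAR, umol m-2 s-1.
#' @param par_range Response limits, nm.
#' @param correct Return a corrected spectrum?
#' @return List with `par_modeled` (umol m-2 s-1), `ratio`, and (when
#'   `correct`) `E_corrected`.
#' @export
par_consistency <- function(E, par_obs, par_range = c(400, 700),
                            correct = FALSE) {
  wl <- E$wavelength
  if (min(wl) > par_range[1] || max(wl) < par_range[2])
    stop("irradiance spectrum does not cover the PAR range ",
         par_range[1], "-", par_range[2], " nm", call. = FALSE)
  keep <- wl >= par_range[1] & wl <= par_range[2]
  wl_m <- wl[keep] * 1e-9
  # E per um -> per nm is /1000; photon energy h*c/lambda; to umol x 1e6
  h <- 6.62607015e-34; cc <- 2.99792458e8; n_a <- 6.02214076e23
  integrand <- (E$irradiance[keep] / 1000) * wl_m / (h * cc * n_a) * 1e6
  x <- wl[keep]
  par_mod <- sum(diff(x) * (head(integrand, -1) + tail(integrand, -1)) / 2)
  ratio <- par_obs / par_mod
  out <- list(par_modeled = par_mod, ratio = ratio)
  if (correct) {
    Ec <- E
    Ec$irradiance <- E$irradiance * ratio
    out$E_corrected <- Ec
  }
  out
}

#' Assemble a per-acquisition QC record
#'
#' Combines the irradiance ratio, PAR stability indicator and clearness
#' index into one row of deterministic pass flags.
#'
#' @param E_start,E_end Irradiance spectra for the scan.
#' @param par PAR trace over the scan window (vector or tibble).
#' @param sw_obs,sw_clear Daily or scan-time shortwave, W m-2.
#' @param stability_threshold Indicator threshold; default 30.
#' @param ratio_tolerance Irradiance-ratio tolerance; default 0.1.
#' @return One-row tibble: `irradiance_ratio`, `ratio_pass`, `stability`,
#'   `stability_pass`, `clearness`, `diffuse_fraction`, plus PAR summary
#'   columns (`par_mean`, `par_sd`, `par_min`, `par_max`).
#' @export
qc_record <- function(E_start, E_end, par, sw_obs, sw_clear,
                      stability_threshold = 30, ratio_tolerance = 0.1) {
  ir <- irradiance_ratio(E_start, E_end, tolerance = ratio_tolerance)
  if (is.data.frame(par)) par <- par$par
  ind <- stability_indicator(par)
  ci <- clearness_index(sw_obs, sw_clear)
  tibble::tibble(irradiance_ratio = ir$ratio, ratio_pass = ir$pass,
                 stability = ind, stability_pass = ind > stability_threshold,
                 clearness = ci$clearness,
                 diffuse_fraction = ci$diffuse_fraction,
                 par_mean = mean(par), par_sd = sd(par),
                 par_min = min(par), par_max = max(par))
}
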