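# Thermal radiometry: panorama assembly from overlapping frame stacks and
# inversion of sensor-reaching band radiance to surface temperature,
# correcting air-column transmission/emission and reflected sky radiance:
#
#   L_sensor = tau * [eps * B(T_obj) + (1 - eps) * B(T_sky)]
#                + (1 - tau) * B(T_air)
#
# with B the Planck radiance integrated over the camera band (7.5-14 um,
# flat response) and tau the water-vapour path transmittance.

.h_planck <- 6.62607015e-34
.c_light <- 2.99792458e8
.k_boltz <- 1.380649e-23

#' Band-integrated Planck radiance
#'
#' Integral of the Planck spectral radiance over a wavelength band assuming
#' a flat spectral response, by composite Simpson quadrature on a
#' log-wavelength grid (which resolves the emission peak equally well for
#' narrow and very wide bands). Strictly increasing in temperature.
#'
#' @param T_kelvin Temperature(s), K; must be positive.
#' @param band Length-2 wavelength band in micrometres.
#' @param n_nodes Odd number of quadrature nodes.
#' @return Band radiance, W m-2 sr-1; vectorised over `T_kelvin`.
#' @examples
#' planck_band_radiance(300, c(7.5, 14))
#' @export
planck_band_radiance <- function(T_kelvin, band = c(7.5, 14), n_nodes = 513) {
  if (any(T_kelvin <= 0)) stop("temperature must be > 0 K", call. = FALSE)
  stopifnot(length(band) == 2, band[1] > 0, band[2] > band[1])
  if (n_nodes %% 2 == 0) n_nodes <- n_nodes + 1
  u <- seq(log(band[1] * 1e-6), log(band[2] * 1e-6), length.out = n_nodes)
  lam <- exp(u)                             # metres
  h_step <- u[2] - u[1]
  w <- rep(c(2, 4), length.out = n_nodes); w[1] <- 1; w[n_nodes] <- 1
  w <- w * h_step / 3
  # B(lambda, T) * lambda  (d lambda = lambda d ln lambda)
  c1 <- 2 * .h_planck * .c_light^2
  c2 <- .h_planck * .c_light / .k_boltz
  integrand <- function(Tk) c1 / lam^4 / expm1(c2 / (lam * Tk))
  vapply(T_kelvin, function(Tk) sum(w * integrand(Tk)), numeric(1))
}

#' Invert band radiance to temperature
#'
#' Bracketed bisection of [planck_band_radiance()] on \[150, 400\] K to a
#' 1e-4 K tolerance; round-trip error is below 0.001 K.
#'
#' @param L_band Band radiance(s), W m-2 sr-1; must lie within the band's
#'   radiance range over \[150, 400\] K.
#' @param band Length-2 band, micrometres.
#' @param limits Bracket, K.
#' @param n_nodes Quadrature nodes passed through.
#' @return Temperature(s), K; `NA` inputs propagate.
#' @export
invert_band_radiance <- function(L_band, band = c(7.5, 14),
                                 limits = c(150, 400), n_nodes = 513) {
  ok <- !is.na(L_band)
  lo_val <- planck_band_radiance(limits[1], band, n_nodes)
  hi_val <- planck_band_radiance(limits[2], band, n_nodes)
  if (any(L_band[ok] < lo_val | L_band[ok] > hi_val))
    stop(sprintf("band radiance outside invertible range [%g, %g] W m-2 sr-1",
                 lo_val, hi_val), call. = FALSE)
  out <- rep(NA_real_, length(L_band))
  if (!any(ok)) return(out)
  lo <- rep(limits[1], sum(ok)); hi <- rep(limits[2], sum(ok))
  target <- L_band[ok]
  while (max(hi - lo) > 1e-4) {
    mid <- (lo + hi) / 2
    below <- planck_band_radiance(mid, band, n_nodes) < target
    lo[below] <- mid[below]
    hi[!below] <- mid[!below]
  }
  out[ok] <- (lo + hi) / 2
  out
}

#' Water vapour density from air temperature and relative humidity
#'
#' Relative humidity times the saturation vapour density. Saturation vapour
#' pressure follows the Magnus form
#' `e_s = 6.112 * exp(17.62 * t / (243.12 + t))` hPa (t in deg C), converted
#' to density with the ideal gas law (R_v = 461.5 J kg-1 K-1).
#'
#' @param t_air_k Air temperature, K.
#' @param rh Relative humidity as a fraction in \[0, 1\].
#' @return Water vapour density, g m-3.
#' @export
water_vapour_density <- function(t_air_k, rh) {
  if (any(rh < 0 | rh > 1)) stop("relative humidity must be in [0, 1]",
                                 call. = FALSE)
  stopifnot(all(t_air_k > 0))
  t_c <- t_air_k - 273.15
  e_s <- 6.112 * exp(17.62 * t_c / (243.12 + t_c))   # hPa
  rh * e_s * 100 / (461.5 * t_air_k) * 1000
}

#' Empirical broadband path-transmittance model
#'
#' Two-exponential attenuation law in the square roots of path length and
#' water-vapour density, the standard broadband surrogate for line-by-line
#' atmospheric simulation over the 7.5--14 um window:
#' `tau = X * exp(-sqrt(d) * (a1 + b1 * sqrt(w)))
#'        + (1 - X) * exp(-sqrt(d) * (a2 + b2 * sqrt(w)))`.
#' Defaults are the widely used broadband coefficients; all parameters are
#' exposed so a site-fitted set can be substituted.
#'
#' @param X Attenuation partition factor.
#' @param alpha1,alpha2 Attenuation terms, m^-1/2.
#' @param beta1,beta2 Water-vapour terms, m^-1/2 (g m-3)^-1/2.
#' @return A `transmission_model`.
#' @export
transmission_model <- function(X = 1.9, alpha1 = 0.006569, alpha2 = 0.01262,
                               beta1 = -0.002276, beta2 = -0.00667) {
  structure(list(X = X, alpha1 = alpha1, alpha2 = alpha2,
                 beta1 = beta1, beta2 = beta2),
            class = "transmission_model")
}

#' Air-column transmittance along a path
#'
#' @param distance Path length(s), m; `tau(0) = 1`.
#' @param w Water-vapour density, g m-3 (see [water_vapour_density()]).
#' @param model A [transmission_model()].
#' @return Transmittance in (0, 1\], same shape as `distance`.
#' @export
path_transmittance <- function(distance, w, model = transmission_model()) {
  if (any(distance < 0, na.rm = TRUE))
    stop("distance must be non-negative", call. = FALSE)
  sd_ <- sqrt(distance); sw <- sqrt(w)
  tau <- model$X * exp(-sd_ * (model$alpha1 + model$beta1 * sw)) +
    (1 - model$X) * exp(-sd_ * (model$alpha2 + model$beta2 * sw))
  pmin(1, pmax(tau, .Machine$double.eps))
}

#' Atmosphere state for thermal correction
#'
#' @param air_temperature K.
#' @param relative_humidity Fraction in \[0, 1\].
#' @param sky_temperature Effective radiometric sky temperature, K (sky
#'   emissivity is taken as 1, so downwelling radiance is `B(T_sky)`).
#' @param water_vapour Optional g m-3 override; computed from temperature
#'   and humidity when `NULL`.
#' @return An `atmosphere_state`.
#' @export
atmosphere_state <- function(air_temperature, relative_humidity,
                             sky_temperature, water_vapour = NULL) {
  stopifnot(air_temperature > 0, sky_temperature > 0)
  if (relative_humidity < 0 || relative_humidity > 1)
    stop("relative humidity must be in [0, 1]", call. = FALSE)
  if (is.null(water_vapour))
    water_vapour <- water_vapour_density(air_temperature, relative_humidity)
  structure(list(air_temperature = air_temperature,
                 relative_humidity = relative_humidity,
                 sky_temperature = sky_temperature,
                 water_vapour = water_vapour),
            class = "atmosphere_state")
}

#' Assemble a thermal panorama from an overlapping frame stack
#'
#' The camera records frames at `frame_rate` while the pan unit rotates at
#' `rotation_rate`, giving > 90 % frame-to-frame overlap; each frame
#' contributes its central `k` columns, where
#' `k = round(angular advance per frame / azimuth IFOV)`, and columns are
#' mapped to azimuth by frame timestamp. The output azimuth grid spacing is
#' the azimuth IFOV.
#'
#' @param stack List with `frames` (array `[rows, cols, n_frames]`, rows =
#'   elevation pixels) and `frame_rate`; e.g. from [read_raw_frames()].
#' @param scan A [scan_geometry()] with a set `rotation_rate`.
#' @param sensor A [sensor_spec()] giving the azimuth FOV and column count.
#' @return Single-band panorama (`band_radiance_panorama`) of sensor-reaching
#'   band radiance, `[azimuth, elevation]`.
#' @export
assemble_thermal_panorama <- function(stack, scan, sensor) {
  frames <- stack$frames
  stopifnot(length(dim(frames)) == 3)
  n_rows <- dim(frames)[1]; n_cols <- dim(frames)[2]; n_fr <- dim(frames)[3]
  if (is.null(scan$rotation_rate))
    stop("scan rotation_rate must be set for panorama assembly", call. = FALSE)
  ifov <- sensor$fov_azimuth / n_cols
  advance <- scan$rotation_rate / stack$frame_rate
  k <- round(advance / ifov)
  if (k < 1)
    stop("frames advance less than one azimuth column; use a faster ",
         "rotation or lower frame rate", call. = FALSE)
  if (advance > sensor$fov_azimuth)
    stop("gap between consecutive frames; use a slower rotation for this ",
         "frame rate", call. = FALSE)
  central <- floor((n_cols - k) / 2) + seq_len(k)
  n_az <- n_fr * k
  out <- matrix(NA_real_, n_az, n_rows)
  for (i in seq_len(n_fr)) {
    out[(i - 1) * k + seq_len(k), ] <- t(frames[, central, i])
  }
  azimuth <- scan$azimuth_start + (seq_len(n_az) - 0.5) * ifov
  el_ifov <- sensor$fov_elevation / n_rows
  ce <- scan$central_elevations[1]
  elevation <- ce - sensor$fov_elevation / 2 + (seq_len(n_rows) - 0.5) * el_ifov
  structure(out, azimuth = azimuth, elevation = elevation,
            units = "W m-2 sr-1", k_columns = k,
            class = c("band_radiance_panorama", "panorama"))
}

#' Retrieve surface temperature from a sensor-radiance panorama
#'
#' Solves the single-band radiative transfer equation for the object
#' temperature per cell:
#' `B(T_obj) = (L_sensor - tau * (1 - eps) * B(T_sky)
#'              - (1 - tau) * B(T_air)) / (tau * eps)`,
#' then inverts the Planck band integral by bracketed root finding. Path
#' transmittance comes from the per-cell path length (TLS range image
#' resampled to the panorama grid) and the water-vapour density of the
#' atmosphere state. Cells with unknown (non-finite) range are masked.
#'
#' @param L_sensor Matrix or `band_radiance_panorama` of sensor-reaching
#'   band radiance, W m-2 sr-1.
#' @param range_image Matrix of per-cell path length, m, same shape.
#' @param atm An [atmosphere_state()].
#' @param emissivity Scalar or per-cell matrix in (0, 1\].
#' @param model A [transmission_model()].
#' @param band Camera band, micrometres.
#' @return A [thermal_panorama()] of surface temperature (K) with per-cell
#'   `tau` and `path_length` attributes.
#' @export
surface_temperature <- function(L_sensor, range_image, atm,
                                emissivity = 0.95,
                                model = transmission_model(),
                                band = c(7.5, 14)) {
  stopifnot(inherits(atm, "atmosphere_state"))
  if (any(emissivity <= 0)) stop("emissivity must be in (0, 1]", call. = FALSE)
  if (any(emissivity > 1)) stop("emissivity must be in (0, 1]", call. = FALSE)
  L <- unclass(L_sensor)
  stopifnot(all(dim(L) == dim(range_image)))
  eps <- if (length(emissivity) == 1) {
    matrix(emissivity, nrow(L), ncol(L))
  } else as.matrix(emissivity)
  mask <- !is.finite(range_image) | !is.finite(L)
  tau <- path_transmittance(ifelse(mask, 0, range_image), atm$water_vapour,
                            model)
  B_sky <- planck_band_radiance(atm$sky_temperature, band)
  B_air <- planck_band_radiance(atm$air_temperature, band)
  B_obj <- (L - tau * (1 - eps) * B_sky - (1 - tau) * B_air) / (tau * eps)
  B_obj[mask] <- NA_real_
  T_obj <- matrix(invert_band_radiance(as.vector(B_obj), band),
                  nrow(L), ncol(L))
  tau[mask] <- NA_real_
  az <- attr(L_sensor, "azimuth"); el <- attr(L_sensor, "elevation")
  if (is.null(az)) az <- seq_len(nrow(L))
  if (is.null(el)) el <- seq_len(ncol(L))
  thermal_panorama(T_obj, az, el, tau = tau,
                   path_length = ifelse(mask, NA_real_, range_image))
}

#' Per-cell emissivity from a component class map
#'
#' @param class_map Character matrix with entries among
#'   `names(values)`.
#' @param values Named emissivities per class; defaults: foliage, bark and
#'   ground 0.95, sky 1.
#' @return Numeric matrix of emissivities.
#' @export
emissivity_map <- function(class_map,
                           values = c(foliage = 0.95, bark = 0.95,
                                      ground = 0.95, sky = 1)) {
  if (any(values <= 0 | values > 1))
    stop("emissivities must be in (0, 1]", call. = FALSE)
  unknown <- setdiff(unique(as.vector(class_map)), names(values))
  if (length(unknown))
    stop("no emissivity for class(es): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  matrix(values[as.vector(class_map)], nrow(class_map), ncol(class_map))
}
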