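# Acquisition geometry: solar ephemeris, trigger scheduling, field-of-view
# projection, pixel footprints, scan kinematics and data-volume accounting.

#' Describe an observation site
#'
#' @param latitude Degrees, positive north. Must lie in \[-90, 90\].
#' @param longitude Degrees, positive east. Must lie in \[-180, 180\].
#' @param elevation_m Site elevation above sea level in metres.
#' @param utc_offset Offset of local civil (standard) time from UTC in hours.
#' @return A `site_location` object (a named list).
#' @examples
#' site_location(-35.656, 148.152, 1200, utc_offset = 10)
#' @export
site_location <- function(latitude, longitude, elevation_m = 0, utc_offset = 0) {
  stopifnot(is.numeric(latitude), length(latitude) == 1,
            is.numeric(longitude), length(longitude) == 1)
  if (latitude < -90 || latitude > 90)
    stop("latitude must be in [-90, 90]", call. = FALSE)
  if (longitude < -180 || longitude > 180)
    stop("longitude must be in [-180, 180]", call. = FALSE)
  structure(list(latitude = latitude, longitude = longitude,
                 elevation_m = elevation_m, utc_offset = utc_offset),
            class = "site_location")
}

#' Demonstration site: a tall eucalypt forest flux-tower installation
#'
#' Coordinates of a wet sclerophyll forest tower site in south-eastern
#' Australia (40 m canopy, sensors at 68 m) used throughout the examples.
#'
#' @return A [site_location()].
#' @export
demo_site <- function() {
  site_location(latitude = -(35 + 39 / 60 + 20 / 3600),
                longitude = 148 + 9 / 60 + 7 / 3600,
                elevation_m = 1200, utc_offset = 10)
}

#' Describe an imaging sensor
#'
#' @param n_across Pixel count along the primary (elevation) axis.
#' @param n_along Pixel count along the secondary (azimuth) axis; 1 for a
#'   line scanner.
#' @param fov_elevation,fov_azimuth Full field of view along each axis,
#'   degrees.
#' @param frame_rate Frames per second.
#' @param bytes_per_sample Storage bytes per sample on disk.
#' @param n_bands Number of spectral bands per spatial pixel.
#' @param wavelength_range Length-2 numeric, micrometres.
#' @return A `sensor_spec` object.
#' @export
sensor_spec <- function(n_across, n_along = 1, fov_elevation, fov_azimuth,
                        frame_rate, bytes_per_sample = 2, n_bands = 1,
                        wavelength_range = NULL) {
  stopifnot(n_across >= 1, n_along >= 1, n_bands >= 1,
            fov_elevation > 0, fov_azimuth > 0, frame_rate > 0)
  structure(list(n_across = n_across, n_along = n_along,
                 fov_elevation = fov_elevation, fov_azimuth = fov_azimuth,
                 frame_rate = frame_rate, bytes_per_sample = bytes_per_sample,
                 n_bands = n_bands, wavelength_range = wavelength_range),
            class = "sensor_spec")
}

#' Default sensor suite for the demonstration installation
#'
#' Four sensors: a visible/near-infrared hyperspectral line scanner (HLS,
#' 1004 spatial pixels, 1004 bands over 0.4--1 um, 25 Hz), a thermal imager
#' (480 x 640, 7.5--14 um, 6.25 Hz, float32 storage), an irradiance
#' spectrometer (2048 bands, 0.2--1.1 um) and a hemispherical sky camera.
#'
#' @return Named list of [sensor_spec()] objects.
#' @export
default_sensors <- function() {
  list(
    hls = sensor_spec(n_across = 1004, n_along = 1, fov_elevation = 26.58,
                      fov_azimuth = 0.03, frame_rate = 25,
                      bytes_per_sample = 2, n_bands = 1004,
                      wavelength_range = c(0.4, 1.0)),
    thermal = sensor_spec(n_across = 480, n_along = 640,
                          fov_elevation = 18.75, fov_azimuth = 25,
                          frame_rate = 6.25, bytes_per_sample = 4,
                          n_bands = 1, wavelength_range = c(7.5, 14)),
    spectrometer = sensor_spec(n_across = 1, n_along = 1,
                               fov_elevation = 180, fov_azimuth = 180,
                               frame_rate = 1, bytes_per_sample = 2,
                               n_bands = 2048, wavelength_range = c(0.2, 1.1)),
    sky_camera = sensor_spec(n_across = 3072, n_along = 2048,
                             fov_elevation = 180, fov_azimuth = 180,
                             frame_rate = 1, bytes_per_sample = 1, n_bands = 3,
                             wavelength_range = c(0.4, 1.0))
  )
}

#' Describe a panoramic scan
#'
#' @param central_elevations Central elevation angle(s) of each azimuthal
#'   sweep, degrees (negative looks down).
#' @param azimuth_start,azimuth_end Azimuth limits, degrees from true north,
#'   positive eastward, in (-180, 180\].
#' @param rotation_rate Pan rotation rate in degrees per second, or `NULL`
#'   to derive it from the square-pixel condition (see [scan_duration()]).
#' @param sensor_height,canopy_height Metres above ground.
#' @return A `scan_geometry` object.
#' @export
scan_geometry <- function(central_elevations = c(-20, -32.5),
                          azimuth_start = -130, azimuth_end = 110,
                          rotation_rate = NULL,
                          sensor_height = 68, canopy_height = 40) {
  span <- azimuth_end - azimuth_start
  if (span <= 0 || span > 360)
    stop("azimuth span must be in (0, 360]", call. = FALSE)
  if (!is.null(rotation_rate) && rotation_rate <= 0)
    stop("rotation_rate must be > 0", call. = FALSE)
  structure(list(central_elevations = central_elevations,
                 azimuth_start = azimuth_start, azimuth_end = azimuth_end,
                 rotation_rate = rotation_rate,
                 sensor_height = sensor_height, canopy_height = canopy_height),
            class = "scan_geometry")
}

#' Trigger configuration for scheduled acquisitions
#'
#' @param reference_elevation Solar elevation angle (degrees) whose daily
#'   crossings trigger the morning and afternoon acquisitions. The
#'   conventional choice is the solar-noon elevation at winter solstice, so
#'   acquisitions happen year-round.
#' @param min_separation Minimum separation (minutes) between scheduled
#'   acquisitions; crossings closer than this to an already-scheduled time
#'   are dropped.
#' @param mode One of `"reference_angle"`, `"solar_noon"`, `"hourly"`,
#'   `"on_demand"`.
#' @return A `trigger_config` object.
#' @export
trigger_config <- function(reference_elevation, min_separation = 20,
                           mode = "reference_angle") {
  stopifnot(min_separation > 0)
  mode <- match.arg(mode, c("reference_angle", "solar_noon", "hourly",
                            "on_demand"))
  structure(list(reference_elevation = reference_elevation,
                 min_separation = min_separation, mode = mode),
            class = "trigger_config")
}

# --- solar ephemeris ---------------------------------------------------------

# Medium-accuracy ephemeris (geometric mean longitude / anomaly, equation of
# centre, apparent longitude, true obliquity, equation of time), refraction
# free; documented geometric accuracy better than 0.1 degrees for 1950-2050.
.solar_ephemeris <- function(time_utc) {
  jd <- as.numeric(time_utc) / 86400 + 2440587.5
  tc <- (jd - 2451545) / 36525
  d2r <- pi / 180
  L0 <- (280.46646 + tc * (36000.76983 + 0.0003032 * tc)) %% 360
  M  <- 357.52911 + tc * (35999.05029 - 0.0001537 * tc)
  ecc <- 0.016708634 - tc * (0.000042037 + 0.0000001267 * tc)
  C <- sin(M * d2r) * (1.914602 - tc * (0.004817 + 0.000014 * tc)) +
    sin(2 * M * d2r) * (0.019993 - 0.000101 * tc) +
    sin(3 * M * d2r) * 0.000289
  omega <- 125.04 - 1934.136 * tc
  app_long <- L0 + C - 0.00569 - 0.00478 * sin(omega * d2r)
  eps0 <- 23 + (26 + (21.448 -
    tc * (46.815 + tc * (0.00059 - tc * 0.001813))) / 60) / 60
  eps <- eps0 + 0.00256 * cos(omega * d2r)
  decl <- asin(sin(eps * d2r) * sin(app_long * d2r)) / d2r
  y <- tan(eps / 2 * d2r)^2
  eqtime <- 4 / d2r * (y * sin(2 * L0 * d2r) - 2 * ecc * sin(M * d2r) +
    4 * ecc * y * sin(M * d2r) * cos(2 * L0 * d2r) -
    0.5 * y^2 * sin(4 * L0 * d2r) - 1.25 * ecc^2 * sin(2 * M * d2r))
  list(declination = decl, eqtime = eqtime)
}

.to_utc <- function(timestamp, site) {
  if (inherits(timestamp, "POSIXct")) {
    as.POSIXct(as.numeric(timestamp), origin = "1970-01-01", tz = "UTC")
  } else {
    t_local <- as.POSIXct(timestamp, tz = "UTC")
    t_local - site$utc_offset * 3600
  }
}

#' Solar azimuth and elevation for a site and time
#'
#' Geometric (refraction-free) solar position from a medium-accuracy
#' ephemeris (declination, equation of time, hour angle), accurate to better
#' than 0.1 degrees. Azimuth follows the signed convention: degrees from
#' true north, positive toward east, in (-180, 180\]; at local solar noon in
#' the southern hemisphere the azimuth is 0.
#'
#' @param site A [site_location()].
#' @param timestamp Either a character/Date-time in local civil time at the
#'   site (interpreted with the site's `utc_offset`), or a `POSIXct` whose
#'   absolute instant is used directly. Vectorised.
#' @return A tibble with columns `time` (UTC), `azimuth`, `elevation`
#'   (degrees), `declination` and `eqtime` (minutes).
#' @examples
#' solar_position(demo_site(), "2018-01-01 07:45")
#' @export
solar_position <- function(site, timestamp) {
  stopifnot(inherits(site, "site_location"))
  time_utc <- .to_utc(timestamp, site)
  eph <- .solar_ephemeris(time_utc)
  d2r <- pi / 180
  mins <- (as.numeric(time_utc) %% 86400) / 60
  tst <- (mins + eph$eqtime + 4 * site$longitude) %% 1440
  ha <- tst / 4 - 180
  sin_el <- sin(site$latitude * d2r) * sin(eph$declination * d2r) +
    cos(site$latitude * d2r) * cos(eph$declination * d2r) * cos(ha * d2r)
  el <- asin(pmin(1, pmax(-1, sin_el))) / d2r
  cos_az <- (sin(eph$declination * d2r) - sin(el * d2r) * sin(site$latitude * d2r)) /
    (cos(el * d2r) * cos(site$latitude * d2r))
  az <- acos(pmin(1, pmax(-1, cos_az))) / d2r
  az <- ifelse(ha > 0, 360 - az, az)          # afternoon sun lies west
  az <- ifelse(az > 180, az - 360, az)        # wrap into (-180, 180]
  tibble::tibble(time = time_utc, azimuth = az, elevation = el,
                 declination = eph$declination, eqtime = eph$eqtime)
}

#' Scheduled acquisition times for one day
#'
#' Returns solar noon plus the (at most two) crossings of the reference
#' solar elevation. Crossings are found by bisection on a 1-minute sampled
#' elevation curve (ties broken toward the earlier minute); a crossing
#' closer than `cfg$min_separation` minutes to an already-scheduled time is
#' dropped, so near winter solstice only solar noon remains.
#'
#' @param site A [site_location()].
#' @param date A `Date` or "YYYY-MM-DD" string (local civil date).
#' @param cfg A [trigger_config()].
#' @return Tibble with columns `time` (UTC), `time_local`, `event` (one of
#'   `"morning_crossing"`, `"solar_noon"`, `"afternoon_crossing"`) and
#'   `elevation`.
#' @export
reference_trigger_times <- function(site, date, cfg) {
  stopifnot(inherits(site, "site_location"), inherits(cfg, "trigger_config"))
  day0 <- .to_utc(paste(as.character(as.Date(date)), "00:00:00"), site)
  elev_at <- function(min_of_day) {
    solar_position(site, day0 + min_of_day * 60)$elevation
  }
  grid <- 0:1439
  el <- elev_at(grid)

  # solar noon: continuous maximiser of the elevation curve
  i_max <- which.max(el)
  lo <- max(grid[i_max] - 2, 0); hi <- min(grid[i_max] + 2, 1439)
  noon_min <- optimize(elev_at, c(lo, hi), maximum = TRUE, tol = 1e-4)$maximum
  out <- tibble::tibble(minute = noon_min, event = "solar_noon")

  ref <- cfg$reference_elevation
  if (cfg$mode == "reference_angle" && max(el) > ref) {
    f <- function(m) elev_at(m) - ref
    dif <- el - ref
    cross_idx <- which(dif[-length(dif)] * dif[-1] < 0 |
                         (dif[-length(dif)] == 0))
    for (i in cross_idx) {
      m <- if (dif[i] == 0) grid[i] else
        uniroot(f, c(grid[i], grid[i + 1]), tol = 1e-4)$root
      event <- if (m < noon_min) "morning_crossing" else "afternoon_crossing"
      if (all(abs(m - out$minute) >= cfg$min_separation))
        out <- rbind(out, tibble::tibble(minute = m, event = event))
    }
  }
  out <- out[order(out$minute), ]
  times_utc <- day0 + out$minute * 60
  tibble::tibble(time = times_utc,
                 time_local = times_utc + site$utc_offset * 3600,
                 event = out$event,
                 elevation = solar_position(site, times_utc)$elevation)
}

#' Projected field-of-view area of an annular sector
#'
#' Top-of-canopy area covered by a panoramic scan whose footprint starts at
#' `inner_range` and ends at `outer_range` from the mast over the given
#' azimuth span: `(span/360) * pi * (r2^2 - r1^2)`.
#'
#' @param inner_range,outer_range Horizontal ranges in metres.
#' @param azimuth_span Degrees, in (0, 360\].
#' @return Area in square metres.
#' @examples
#' projected_fov_area(30, 320, 240) / 1e4  # hectares
#' @export
projected_fov_area <- function(inner_range, outer_range, azimuth_span) {
  if (inner_range < 0 || outer_range < 0)
    stop("ranges must be non-negative", call. = FALSE)
  if (inner_range > outer_range)
    stop("inner_range must not exceed outer_range", call. = FALSE)
  stopifnot(azimuth_span > 0, azimuth_span <= 360)
  (azimuth_span / 360) * pi * (outer_range^2 - inner_range^2)
}

#' Linear pixel footprint at a slant range
#'
#' Small-angle approximation: `(fov / n_pixels)` in radians times the slant
#' range, along one sensor axis.
#'
#' @param fov Full field of view along the axis, degrees.
#' @param n_pixels Pixel count along the axis.
#' @param slant_range Metres.
#' @return Footprint in metres.
#' @export
pixel_footprint <- function(fov, n_pixels, slant_range) {
  stopifnot(n_pixels >= 1, all(slant_range >= 0))
  (fov / n_pixels) * pi / 180 * slant_range
}

#' Elevation coverage of a multi-sweep scan
#'
#' Union span and pairwise overlap of the elevation intervals
#' `center +/- fov/2` for each central elevation.
#'
#' @param scan A [scan_geometry()].
#' @param sensor A [sensor_spec()]; its `fov_elevation` is used.
#' @return Tibble with `span` (union length, degrees) and `overlap`
#'   (total pairwise overlap, degrees).
#' @export
elevation_coverage <- function(scan, sensor) {
  ce <- sort(scan$central_elevations)
  half <- sensor$fov_elevation / 2
  lo <- ce - half; hi <- ce + half
  # union length by interval merging
  span <- 0; cur_lo <- lo[1]; cur_hi <- hi[1]
  if (length(ce) > 1) {
    for (i in 2:length(ce)) {
      if (lo[i] <= cur_hi) cur_hi <- max(cur_hi, hi[i])
      else { span <- span + (cur_hi - cur_lo); cur_lo <- lo[i]; cur_hi <- hi[i] }
    }
  }
  span <- span + (cur_hi - cur_lo)
  overlap <- 0
  if (length(ce) > 1) {
    for (i in 1:(length(ce) - 1)) for (j in (i + 1):length(ce)) {
      overlap <- overlap + max(0, min(hi[i], hi[j]) - max(lo[i], lo[j]))
    }
  }
  tibble::tibble(span = span, overlap = overlap)
}

#' Duration of one azimuthal sweep
#'
#' If the scan's `rotation_rate` is unset it is derived from the
#' square-pixel condition for the line sensor: azimuth IFOV times frame
#' rate, so successive scan lines abut without gap or overlap.
#'
#' @param scan A [scan_geometry()].
#' @param line_sensor A [sensor_spec()] for the line scanner.
#' @return Duration in seconds.
#' @export
scan_duration <- function(scan, line_sensor) {
  rate <- scan$rotation_rate
  if (is.null(rate)) {
    if (line_sensor$frame_rate <= 0)
      stop("frame_rate must be positive to derive rotation rate", call. = FALSE)
    az_ifov <- line_sensor$fov_azimuth / line_sensor$n_along
    rate <- az_ifov * line_sensor$frame_rate
  }
  (scan$azimuth_end - scan$azimuth_start) / rate
}

#' Raw data volume of an acquisition campaign
#'
#' Either from first principles (sum over sensors of frame bytes x frame
#' rate x duration) or from measured per-acquisition volumes. Frame bytes
#' are `n_across * n_along * bytes_per_sample` for frame imagers and
#' `n_across * n_bands * bytes_per_sample` for line scanners
#' (`n_along == 1`). Decimal units: 1 GB = 1e9 bytes.
#'
#' @param sensors List of [sensor_spec()]s, or `NULL` when
#'   `per_acquisition_bytes` is given.
#' @param duration_per_scan Seconds per azimuthal sweep.
#' @param scans_per_acq Sweeps per triggered acquisition (one per elevation).
#' @param acqs_per_day,days Campaign counts.
#' @param per_acquisition_bytes Optional measured bytes per acquisition,
#'   bypassing the per-sensor model.
#' @return Total bytes.
#' @export
data_volume <- function(sensors = NULL, duration_per_scan = 320,
                        scans_per_acq = 2, acqs_per_day = 3, days = 365,
                        per_acquisition_bytes = NULL) {
  stopifnot(scans_per_acq >= 0, acqs_per_day >= 0, days >= 0)
  if (!is.null(per_acquisition_bytes))
    return(per_acquisition_bytes * acqs_per_day * days)
  per_acq <- sum(vapply(sensors, function(s) {
    px <- if (s$n_along == 1) s$n_across * s$n_bands else s$n_across * s$n_along
    px * s$bytes_per_sample * s$frame_rate * duration_per_scan * scans_per_acq
  }, numeric(1)))
  per_acq * acqs_per_day * days
}

#' Summarise an acquisition plan
#'
#' Convenience wrapper combining trigger times, projected area, sweep
#' duration and annual data volume for a configured site.
#'
#' @param site A [site_location()].
#' @param scan A [scan_geometry()].
#' @param sensors Named list of [sensor_spec()]s with elements `hls` and
#'   `thermal`.
#' @param cfg A [trigger_config()].
#' @param date Local date for the trigger schedule.
#' @param inner_range,outer_range Footprint radii in metres.
#' @return List with `triggers` (tibble), `fov_area_m2`, `scan_duration_s`,
#'   `annual_volume_bytes`.
#' @export
acquisition_plan <- function(site, scan, sensors, cfg,
                             date = Sys.Date(),
                             inner_range = 30, outer_range = 320) {
  dur <- scan_duration(scan, sensors$hls)
  list(
    triggers = reference_trigger_times(site, date, cfg),
    fov_area_m2 = projected_fov_area(inner_range, outer_range,
                                     scan$azimuth_end - scan$azimuth_start),
    scan_duration_s = dur,
    annual_volume_bytes = data_volume(sensors[c("hls", "thermal")],
                                      duration_per_scan = dur,
                                      scans_per_acq = length(scan$central_elevations),
                                      acqs_per_day = 3, days = 365)
  )
}
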