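# Forward simulator: angular-native canopy scenes with known ground truth
# (per-cell class, reflectance spectra, temperature, emissivity, range),
# raw sensor streams, irradiance spectra, TLS clouds, PAR traces,
# meteorology and a GPP series coupled to a chosen index. Every generator
# is seed-deterministic and emits its ground truth next to the inputs.
#
# Geometry is angular-native (per-cell class and range) rather than full 3-D
# ray tracing: sufficient to exercise every pipeline equation at desk scale.

.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

# smooth parametric end-member spectra (sigmoid red edge + Gaussian pigment
# features), not measured libraries
.class_spectrum <- function(class, wavelength) {
  w <- wavelength
  switch(class,
    foliage = pmax(0.01,
      0.05 + 0.45 / (1 + exp(-(w - 715) / 12)) +
        0.06 * exp(-(w - 550)^2 / (2 * 20^2)) -
        0.03 * exp(-(w - 670)^2 / (2 * 15^2))),
    bark = pmax(0.01, 0.10 + 0.00035 * (w - 400) +
                  0.08 / (1 + exp(-(w - 720) / 20))),
    ground = pmax(0.01, 0.08 + 0.00045 * (w - 400) +
                    0.05 / (1 + exp(-(w - 710) / 15))),
    sky = rep(0, length(w)))
}

#' Scene specification for the forward simulator
#'
#' @param azimuth_range,elevation_range Angular extent of the truth grid,
#'   degrees.
#' @param cell_size Truth-grid cell size, degrees.
#' @param n_trees Number of angular crown discs.
#' @param crown_radius Range of angular crown radii, degrees.
#' @param crown_range Range of crown slant ranges, m.
#' @param cover Range of within-crown canopy cover fraction (TLS hit
#'   probability).
#' @param sensor_height,canopy_height Metres.
#' @param max_range TLS/visibility limit, m.
#' @param wavelength Band centres of the simulated line scanner, nm.
#' @param temperature_offsets Named offsets from air temperature, K:
#'   sunlit branches/stems run a few degrees warmer than foliage and the
#'   sunlit ground up to ~12 K warmer.
#' @param emissivities Named per-class emissivities.
#' @return A `scene_spec`.
#' @export
scene_spec <- function(azimuth_range = c(-60, 60),
                       elevation_range = c(-45, -7),
                       cell_size = 0.5,
                       n_trees = 14,
                       crown_radius = c(3, 8),
                       crown_range = c(40, 300),
                       cover = c(0.55, 0.95),
                       sensor_height = 68, canopy_height = 40,
                       max_range = 350,
                       wavelength = seq(405, 895, by = 10),
                       temperature_offsets = c(foliage = 0, bark = 3,
                                               ground = 8),
                       emissivities = c(foliage = 0.95, bark = 0.95,
                                        ground = 0.95, sky = 1)) {
  structure(as.list(environment()), class = "scene_spec")
}

#' Generate a ground-truth angular scene
#'
#' Deterministic for a given seed. Trees are angular crown discs with a
#' central bark stripe; cells not covered by a crown see the ground where
#' the slant range `sensor_height / sin(-elevation)` is within reach, and
#' sky otherwise. Per-cell truth: component class, slant range, canopy
#' cover, reflectance spectrum (class spectrum times a sunlit/shaded
#' brightness factor), surface temperature offset and emissivity.
#'
#' @param spec A [scene_spec()].
#' @param seed Integer RNG seed.
#' @return A `scene`: list with `azimuth`, `elevation`, `wavelength`,
#'   matrices `class_map`, `range`, `cover`, `brightness`, `temp_offset`,
#'   `emissivity`, and the truth reflectance cube `rho`
#'   `[azimuth, elevation, band]`.
#' @export
make_scene <- function(spec = scene_spec(), seed = 1) {
  .with_seed(seed, {
    az <- angular_axis(spec$azimuth_range[1], spec$azimuth_range[2],
                       spec$cell_size)
    el <- angular_axis(spec$elevation_range[1], spec$elevation_range[2],
                       spec$cell_size)
    n_az <- length(az); n_el <- length(el)
    class_map <- matrix("sky", n_az, n_el)
    range_m <- matrix(NA_real_, n_az, n_el)
    cover <- matrix(0, n_az, n_el)

    # ground visible where the slant path meets the ground within max_range
    el_grid <- matrix(el, n_az, n_el, byrow = TRUE)
    ground_slant <- spec$sensor_height / sin(-el_grid * pi / 180)
    ground_ok <- el_grid < 0 & ground_slant <= spec$max_range
    class_map[ground_ok] <- "ground"
    range_m[ground_ok] <- ground_slant[ground_ok]

    if (spec$n_trees > 0) {
      az_grid <- matrix(az, n_az, n_el)
      # crowns sit in the canopy band (upper part of the elevation range)
      el_band <- spec$elevation_range[1] +
        diff(spec$elevation_range) * c(0.35, 0.95)
      tree <- tibble::tibble(
        az = stats::runif(spec$n_trees, spec$azimuth_range[1],
                          spec$azimuth_range[2]),
        el = stats::runif(spec$n_trees, el_band[1], el_band[2]),
        radius = stats::runif(spec$n_trees, spec$crown_radius[1],
                              spec$crown_radius[2]),
        range = stats::runif(spec$n_trees, spec$crown_range[1],
                             spec$crown_range[2]),
        cover = stats::runif(spec$n_trees, spec$cover[1], spec$cover[2]))
      for (i in seq_len(spec$n_trees)) {
        d2 <- (az_grid - tree$az[i])^2 + (el_grid - tree$el[i])^2
        inside <- d2 <= tree$radius[i]^2
        nearer <- is.na(range_m) | tree$range[i] < range_m
        hit <- inside & nearer
        stripe <- hit & abs(az_grid - tree$az[i]) < 0.18 * tree$radius[i]
        class_map[hit] <- "foliage"
        class_map[stripe] <- "bark"
        range_m[hit] <- tree$range[i]
        cover[hit] <- tree$cover[i]
      }
    }

    brightness <- matrix(stats::runif(n_az * n_el, 0.75, 1.25), n_az, n_el)
    brightness[class_map == "sky"] <- 0
    temp_offset <- matrix(0, n_az, n_el)
    for (cl in names(spec$temperature_offsets))
      temp_offset[class_map == cl] <- spec$temperature_offsets[[cl]]
    temp_offset <- temp_offset +
      matrix(stats::runif(n_az * n_el, -1, 1), n_az, n_el) *
      (class_map != "sky")
    emis <- emissivity_map(class_map, spec$emissivities)

    nb <- length(spec$wavelength)
    base <- vapply(c("foliage", "bark", "ground", "sky"), .class_spectrum,
                   numeric(nb), wavelength = spec$wavelength)
    rho <- array(0, c(n_az, n_el, nb))
    for (b in seq_len(nb)) {
      rho[, , b] <- matrix(base[b, class_map], n_az, n_el) * brightness
    }
    structure(list(spec = spec, azimuth = az, elevation = el,
                   wavelength = spec$wavelength, class_map = class_map,
                   range = range_m, cover = cover, brightness = brightness,
                   temp_offset = temp_offset, emissivity = emis, rho = rho,
                   seed = seed),
              class = "scene")
  })
}

#' @export
print.scene <- function(x, ...) {
  tab <- table(x$class_map)
  cat(sprintf("<scene> %d x %d cells: %s\n", length(x$azimuth),
              length(x$elevation),
              paste(names(tab), as.integer(tab), sep = "=", collapse = ", ")))
  invisible(x)
}

#' Default smooth solar-like irradiance spectrum
#'
#' @param wavelength Fine spectrometer grid, nm.
#' @param scale Overall scale factor.
#' @return Tibble (`wavelength`, `irradiance` in W m-2 um-1).
#' @export
default_illumination <- function(wavelength = seq(350, 1000, by = 1),
                                 scale = 1) {
  tibble::tibble(
    wavelength = wavelength,
    irradiance = scale * (1800 * exp(-((wavelength - 520) / 320)^2) + 150))
}

#' Simulate a hyperspectral line-scan acquisition
#'
#' Inverts the reflectance equation per truth cell
#' (`L = rho * E / pi`, with E the band-matched irradiance drifting
#' linearly over the sweep), then maps radiance back to raw counts through
#' the calibration model and dark frame. Processing the returned stream
#' with [process_vnir_acquisition()] recovers the scene reflectance to
#' better than 1e-6 relative error when noise is off.
#'
#' @param scene From [make_scene()].
#' @param illumination Fine-grid irradiance at scan start (tibble).
#' @param drift End-of-scan illumination scale relative to start (1 =
#'   stable sky).
#' @param gain,offset,dark Calibration truth: scalar or per-(pixel, band)
#'   gain/offset and dark counts.
#' @param noise_sd Gaussian count noise SD (0 = off).
#' @param srf_fwhm_nm Band FWHM used to band-match the irradiance; default
#'   twice the band spacing.
#' @param seed RNG seed for the noise.
#' @return A `vnir_acquisition`: list with `stream` (frames
#'   `[elevation, band, azimuth]`, counts), `E_start`, `E_end` (fine-grid
#'   tibbles), `dark`, `cal`, `srf`, and ground truth `rho_true`
#'   (a [reflectance_panorama()]) plus the `scene`.
#' @export
simulate_vnir <- function(scene, illumination = default_illumination(),
                          drift = 1, gain = 0.01, offset = 0, dark = 40,
                          noise_sd = 0, srf_fwhm_nm = NULL, seed = 1) {
  n_az <- length(scene$azimuth); n_el <- length(scene$elevation)
  wl <- scene$wavelength; nb <- length(wl)
  srf <- if (is.null(srf_fwhm_nm)) spectral_response(wl)
         else spectral_response(wl, srf_fwhm_nm)
  E_band <- band_match_irradiance(illumination, srf)$irradiance
  f <- if (n_az == 1) 0 else (seq_len(n_az) - 1) / (n_az - 1)
  drift_col <- 1 + f * (drift - 1)
  E_cols <- outer(drift_col, E_band)                  # [az, band]
  gain_m <- matrix(gain, n_el, nb)
  offset_m <- matrix(offset, n_el, nb)
  dark_m <- matrix(dark, n_el, nb)
  frames <- array(0, c(n_el, nb, n_az))
  for (j in seq_len(n_az)) {
    L <- scene$rho[j, , ] * matrix(E_cols[j, ], n_el, nb, byrow = TRUE) / pi
    frames[, , j] <- (L - offset_m) / gain_m + dark_m
  }
  if (noise_sd > 0) {
    frames <- .with_seed(seed,
      frames + array(stats::rnorm(length(frames), 0, noise_sd), dim(frames)))
  }
  E_end <- illumination
  E_end$irradiance <- illumination$irradiance * drift
  rho_true <- reflectance_panorama(scene$rho, scene$azimuth, scene$elevation,
                                   wl)
  structure(list(stream = list(frames = frames, frame_rate = 25),
                 E_start = illumination, E_end = E_end,
                 dark = dark_m,
                 cal = calibration_model(gain_m, offset_m),
                 srf = srf, rho_true = rho_true, scene = scene),
            class = "vnir_acquisition")
}

#' Process a simulated VNIR acquisition to reflectance
#'
#' Runs the full chain: dark correction, radiometric calibration,
#' irradiance band-matching, per-column interpolation, reflectance.
#'
#' @param acq From [simulate_vnir()].
#' @return A [reflectance_panorama()].
#' @export
process_vnir_acquisition <- function(acq) {
  frames <- dark_correct(acq$stream$frames, acq$dark)
  L <- apply_calibration(frames, acq$cal)            # [el, band, az]
  cube <- aperm(L, c(3, 1, 2))                       # [az, el, band]
  scene <- acq$scene
  Lp <- radiance_panorama(cube, scene$azimuth, scene$elevation,
                          scene$wavelength)
  Es <- band_match_irradiance(acq$E_start, acq$srf)
  Ee <- band_match_irradiance(acq$E_end, acq$srf)
  E_cols <- interpolate_irradiance(Es, Ee, length(scene$azimuth))
  compute_reflectance(Lp, E_cols)
}

#' Simulate a thermal frame stack over a scene
#'
#' Forward model per truth cell:
#' `L = tau * (eps * B(T_surf) + (1 - eps) * B(T_sky)) + (1 - tau) * B(T_air)`
#' with `T_surf = T_air + class offset`, tau from the per-cell range; sky
#' cells carry `B(T_sky)`. Frames overlap so that each contributes
#' `k_columns` central columns when reassembled.
#'
#' @param scene From [make_scene()].
#' @param atm An [atmosphere_state()].
#' @param model A [transmission_model()].
#' @param band Camera band, um.
#' @param k_columns Central columns contributed per frame.
#' @param n_cols Frame width in columns (>= `k_columns`).
#' @param noise_sd Radiance noise SD, W m-2 sr-1.
#' @param seed RNG seed for the noise.
#' @return A `thermal_acquisition`: list with `stack` (frames
#'   `[elevation, column, frame]`), `scan`, `sensor`, `t_true`
#'   (truth surface-temperature matrix, sky = NA), `l_true` (truth
#'   panorama), `range` (truth range image) and the `scene`.
#' @export
simulate_thermal <- function(scene, atm, model = transmission_model(),
                             band = c(7.5, 14), k_columns = 4, n_cols = 16,
                             noise_sd = 0, seed = 1) {
  n_az <- length(scene$azimuth); n_el <- length(scene$elevation)
  if (n_az %% k_columns != 0)
    stop("number of azimuth cells must be a multiple of k_columns",
         call. = FALSE)
  t_surf <- atm$air_temperature + scene$temp_offset
  t_surf[scene$class_map == "sky"] <- NA_real_
  tau <- path_transmittance(ifelse(is.na(scene$range), 0, scene$range),
                            atm$water_vapour, model)
  B_sky <- planck_band_radiance(atm$sky_temperature, band)
  B_air <- planck_band_radiance(atm$air_temperature, band)
  B_surf <- matrix(NA_real_, n_az, n_el)
  ok <- !is.na(t_surf)
  B_surf[ok] <- planck_band_radiance(t_surf[ok], band)
  eps <- scene$emissivity
  L <- tau * (eps * B_surf + (1 - eps) * B_sky) + (1 - tau) * B_air
  L[!ok] <- B_sky
  if (noise_sd > 0)
    L <- .with_seed(seed, L + matrix(stats::rnorm(n_az * n_el, 0, noise_sd),
                                     n_az, n_el))
  n_frames <- n_az / k_columns
  central <- floor((n_cols - k_columns) / 2) + seq_len(k_columns)
  frames <- array(NA_real_, c(n_el, n_cols, n_frames))
  for (i in seq_len(n_frames)) {
    for (c0 in seq_len(n_cols)) {
      truth_col <- (i - 1) * k_columns + (c0 - central[1]) + 1
      truth_col <- min(max(truth_col, 1), n_az)
      frames[, c0, i] <- L[truth_col, ]
    }
  }
  cell <- scene$spec$cell_size
  sensor <- sensor_spec(n_across = n_el, n_along = n_cols,
                        fov_elevation = n_el * cell,
                        fov_azimuth = n_cols * cell,
                        frame_rate = 1, bytes_per_sample = 4,
                        wavelength_range = band)
  scan <- scan_geometry(
    central_elevations = mean(range(scene$elevation)),
    azimuth_start = scene$spec$azimuth_range[1],
    azimuth_end = scene$spec$azimuth_range[2],
    rotation_rate = k_columns * cell,   # deg/s at 1 Hz frame rate
    sensor_height = scene$spec$sensor_height,
    canopy_height = scene$spec$canopy_height)
  structure(list(stack = list(frames = frames, frame_rate = 1),
                 scan = scan, sensor = sensor, t_true = t_surf,
                 l_true = L, range = scene$range, scene = scene,
                 atm = atm, model = model, band = band),
            class = "thermal_acquisition")
}

#' Simulate a TLS point cloud over a scene
#'
#' Pulses sample each truth cell with uniform angular jitter. Crown cells
#' intercept the pulse with probability equal to the cell's cover; missed
#' pulses continue to the ground where it is within reach (that ground hit
#' is then the first return), otherwise no return. Intercepted pulses
#' occasionally produce a second return from the ground, exercising the
#' multi-return convention.
#'
#' @param scene From [make_scene()].
#' @param pulses_per_cell Pulses per truth cell.
#' @param second_return_prob Probability a canopy hit also yields a ground
#'   second return.
#' @param range_jitter Uniform range jitter half-width, m.
#' @param seed RNG seed.
#' @return Tibble of points (`x`, `y`, `z`, `return_number`) in the
#'   sensor-origin frame (+x north, +y east, +z up).
#' @export
simulate_tls <- function(scene, pulses_per_cell = 8,
                         second_return_prob = 0.25, range_jitter = 0.5,
                         seed = 1) {
  .with_seed(seed, {
    cell <- scene$spec$cell_size
    n_az <- length(scene$azimuth); n_el <- length(scene$elevation)
    idx <- expand.grid(a = seq_len(n_az), e = seq_len(n_el))
    idx <- idx[rep(seq_len(nrow(idx)), each = pulses_per_cell), ]
    az <- scene$azimuth[idx$a] + stats::runif(nrow(idx), -cell / 2, cell / 2)
    el <- scene$elevation[idx$e] + stats::runif(nrow(idx), -cell / 2, cell / 2)
    cls <- scene$class_map[cbind(idx$a, idx$e)]
    rng <- scene$range[cbind(idx$a, idx$e)]
    cov <- scene$cover[cbind(idx$a, idx$e)]
    h <- scene$spec$sensor_height
    ground_slant <- ifelse(el < 0, h / sin(-el * pi / 180), Inf)
    ground_ok <- ground_slant <= scene$spec$max_range

    canopy <- cls %in% c("foliage", "bark")
    hit_crown <- canopy & stats::runif(length(cls)) < cov
    to_ground <- (cls == "ground") | (canopy & !hit_crown & ground_ok)

    res <- list()
    r1 <- ifelse(hit_crown,
                 rng + stats::runif(length(cls), -range_jitter, range_jitter),
                 ifelse(to_ground, ground_slant, NA_real_))
    keep <- !is.na(r1)
    mk <- function(r, azd, eld, rn) {
      tibble::tibble(
        x = r * cos(eld * pi / 180) * cos(azd * pi / 180),
        y = r * cos(eld * pi / 180) * sin(azd * pi / 180),
        z = r * sin(eld * pi / 180),
        return_number = rn)
    }
    pts <- mk(r1[keep], az[keep], el[keep], 1L)
    second <- hit_crown & ground_ok &
      stats::runif(length(cls)) < second_return_prob
    if (any(second))
      pts <- dplyr::bind_rows(pts, mk(ground_slant[second], az[second],
                                      el[second], 2L))
    pts
  })
}

#' Simulate a year of PAR, meteorology and a GPP series coupled to an index
#'
#' Day types: clear days carry a smooth high PAR trace whose stability
#' indicator exceeds 30 by construction; broken-cloud days carry an
#' intermittent trace with an indicator below 30; overcast days a flat low
#' trace (indicator effectively infinite). The truth vegetation index
#' follows a seasonal cycle; daily GPP is `intercept + slope * index +
#' noise`, with the noise conditioned (orthogonalised against the index and
#' rescaled) so the sample R-squared equals `r_squared_design` exactly on
#' the available days.
#'
#' @param dates Vector of dates (default calendar year 2017).
#' @param clear_fraction Fraction of clear-sky days; assigned
#'   deterministically (every `1/clear_fraction`-th day) so the designed
#'   kept fraction is exact.
#' @param overcast_fraction Fraction of overcast days among the remainder.
#' @param n_available Number of days with valid data (instrument uptime);
#'   the rest are marked unavailable.
#' @param intercept,slope GPP coupling, umol m-2 s-1 (per index unit).
#' @param r_squared_design Designed index--GPP coefficient of
#'   determination.
#' @param unstable_noise_sd Extra index measurement noise on
#'   non-clear days (simulating unstable-sky retrieval error).
#' @param trace_seconds Length of each 1 Hz PAR trace, s.
#' @param site A [site_location()] for the clear-sky shortwave model.
#' @param seed RNG seed.
#' @return List with `daily` (tibble: `date`, `day_type`, `available`,
#'   `stability`, `index_truth`, `index_obs`, `gpp`, `sw_obs`, `sw_clear`,
#'   `t_air`, `rh`) and `par_traces` (list of 1 Hz vectors by date).
#' @export
simulate_par_and_meteo <- function(dates = seq(as.Date("2017-01-01"),
                                               as.Date("2017-12-31"), 1),
                                   clear_fraction = 1 / 3,
                                   overcast_fraction = 0,
                                   n_available = NULL,
                                   intercept = 1, slope = 60,
                                   r_squared_design = 0.52,
                                   unstable_noise_sd = 0.03,
                                   trace_seconds = 300,
                                   site = demo_site(), seed = 1) {
  .with_seed(seed, {
    n <- length(dates)
    day_type <- rep("broken", n)
    if (clear_fraction > 0)
      day_type[seq(1, n, by = round(1 / clear_fraction))] <- "clear"
    n_rest <- sum(day_type == "broken")
    if (overcast_fraction > 0) {
      oc <- sample(which(day_type == "broken"),
                   round(overcast_fraction * n))
      day_type[oc] <- "overcast"
    }
    available <- rep(TRUE, n)
    if (!is.null(n_available) && n_available < n)
      available[sample(n, n - n_available)] <- FALSE

    par_traces <- vector("list", n)
    stability <- numeric(n)
    for (i in seq_len(n)) {
      base <- 1500 * (0.7 + 0.3 * sin(2 * pi * (as.integer(
        format(dates[i], "%j")) + 80) / 365)^2)
      tr <- switch(day_type[i],
        clear = base + stats::rnorm(trace_seconds, 0, base / 100),
        broken = base * sample(c(0.25, 1), trace_seconds, TRUE) +
          stats::rnorm(trace_seconds, 0, base / 10),
        overcast = rep(0.15 * base, trace_seconds))
      par_traces[[i]] <- pmax(tr, 0)
      stability[i] <- stability_indicator(par_traces[[i]])
    }

    doy <- as.integer(format(dates, "%j"))
    index_truth <- 0.08 + 0.06 * sin(2 * pi * (doy - 50) / 365) +
      stats::rnorm(n, 0, 0.004)
    index_obs <- index_truth +
      ifelse(day_type == "clear", stats::rnorm(n, 0, 0.002),
             stats::rnorm(n, 0, unstable_noise_sd))

    # conditioned GPP noise: exact sample R^2 on the available days
    x <- index_truth[available]
    e <- stats::rnorm(length(x))
    xc <- x - mean(x)
    e <- e - mean(e) - sum(e * xc) / sum(xc^2) * xc
    sd_target <- abs(slope) * stats::sd(xc) *
      sqrt((1 - r_squared_design) / r_squared_design)
    e <- e / stats::sd(e) * sd_target
    gpp <- rep(NA_real_, n)
    gpp[available] <- intercept + slope * x + e

    noon <- paste(as.character(dates), "12:00")
    sw_clear <- potential_shortwave(site, noon)
    ci <- ifelse(day_type == "clear", stats::runif(n, 0.85, 0.98),
          ifelse(day_type == "overcast", stats::runif(n, 0.05, 0.2),
                 stats::runif(n, 0.3, 0.7)))
    list(daily = tibble::tibble(
           date = dates, day_type = day_type, available = available,
           stability = stability, index_truth = index_truth,
           index_obs = index_obs, gpp = gpp,
           sw_obs = ci * sw_clear, sw_clear = sw_clear,
           t_air = 283 + 10 * sin(2 * pi * (doy + 31) / 365) +
             stats::rnorm(n, 0, 1.5),
           rh = pmin(0.95, pmax(0.2, stats::runif(n, 0.35, 0.85)))),
         par_traces = setNames(par_traces, as.character(dates)))
  })
}
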