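# Shared fixtures: small scenes and spectra built in code at test time.

tiny_scene <- function(seed = 3, az = c(-20, 20), el = c(-40, -10),
                       cell = 1, n_trees = 8) {
  make_scene(scene_spec(azimuth_range = az, elevation_range = el,
                        cell_size = cell, n_trees = n_trees), seed = seed)
}

flat_spectrum <- function(value = 1, wavelength = seq(350, 1000, by = 1)) {
  tibble::tibble(wavelength = wavelength, irradiance = rep(value,
                                                           length(wavelength)))
}

# uniform reflectance cube as a panorama
uniform_pano <- function(value, n_az = 4, n_el = 3,
                         wavelength = seq(450, 850, by = 50)) {
  reflectance_panorama(array(value, c(n_az, n_el, length(wavelength))),
                       azimuth = seq_len(n_az), elevation = seq_len(n_el),
                       wavelength = wavelength)
}

# panorama with chosen reflectance values at chosen wavelengths (constant
# elsewhere), uniform across pixels
spectral_pano <- function(values_nm, default = 0.1, n_az = 4, n_el = 3,
                          wavelength = seq(400, 900, by = 1)) {
  spec <- rep(default, length(wavelength))
  for (nm in names(values_nm)) {
    spec[which.min(abs(wavelength - as.numeric(nm)))] <- values_nm[[nm]]
  }
  arr <- aperm(array(spec, c(length(wavelength), n_az, n_el)), c(2, 3, 1))
  reflectance_panorama(arr, azimuth = seq_len(n_az), elevation = seq_len(n_el),
                       wavelength = wavelength)
}

neutral_tau_model <- function() transmission_model(X = 1, alpha1 = 0,
                                                   alpha2 = 0, beta1 = 0,
                                                   beta2 = 0)

# brute-force per-point oracle used by several tests: independent loop
# implementation of angular binning and the per-cell statistics
brute_force_grid <- function(pts, cell, az_range, el_range) {
  n_az <- round(diff(az_range) / cell); n_el <- round(diff(el_range) / cell)
  n_first <- matrix(0L, n_az, n_el)
  rng_min <- matrix(NA_real_, n_az, n_el)
  beyond <- matrix(0L, n_az, n_el)
  for (i in seq_len(nrow(pts))) {
    if (pts$return_number[i] != 1) next
    r <- sqrt(pts$x[i]^2 + pts$y[i]^2 + pts$z[i]^2)
    az <- atan2(pts$y[i], pts$x[i]) * 180 / pi
    el <- atan2(pts$z[i], sqrt(pts$x[i]^2 + pts$y[i]^2)) * 180 / pi
    a <- ceiling((az - az_range[1]) / cell); if (a == 0) a <- 1
    e <- ceiling((el - el_range[1]) / cell); if (e == 0) e <- 1
    if (a < 1 || a > n_az || e < 1 || e > n_el) next
    n_first[a, e] <- n_first[a, e] + 1L
    if (r > 5) beyond[a, e] <- beyond[a, e] + 1L
    if (is.na(rng_min[a, e]) || r < rng_min[a, e]) rng_min[a, e] <- r
  }
  pg <- matrix(NA_real_, n_az, n_el)
  pg[n_first > 0] <- beyond[n_first > 0] / n_first[n_first > 0]
  list(n_first = n_first, range = rng_min, pgap = pg)
}
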