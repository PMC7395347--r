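test_that("scene generation is seed-deterministic", {
  s1 <- tiny_scene(seed = 42)
  s2 <- tiny_scene(seed = 42)
  expect_identical(s1$class_map, s2$class_map)
  expect_identical(s1$rho, s2$rho)
  s3 <- tiny_scene(seed = 43)
  expect_false(identical(s1$class_map, s3$class_map))
})

test_that("a treeless scene contains only ground and sky", {
  s <- tiny_scene(n_trees = 0)
  expect_true(all(s$class_map %in% c("ground", "sky")))
  # ground ranges follow the slant geometry
  occ <- which(s$class_map == "ground", arr.ind = TRUE)
  el <- s$elevation[occ[1, 2]]
  expect_equal(s$range[occ[1, 1], occ[1, 2]],
               s$spec$sensor_height / sin(-el * pi / 180))
})

test_that("denser canopies transmit less than sparse ones", {
  spec_dense <- scene_spec(azimuth_range = c(-30, 30),
                           elevation_range = c(-40, -15), cell_size = 1,
                           n_trees = 25, cover = c(0.9, 0.98),
                           crown_range = c(40, 60))
  spec_sparse <- scene_spec(azimuth_range = c(-30, 30),
                            elevation_range = c(-40, -15), cell_size = 1,
                            n_trees = 6, cover = c(0.2, 0.3),
                            crown_range = c(40, 60))
  pg <- function(spec) {
    sc <- make_scene(spec, seed = 7)
    g <- bin_to_angular_grid(simulate_tls(sc, seed = 8), 1)
    # threshold between the crowns and the ground so crown hits are "near"
    mean(unclass(gap_fraction(g, range_threshold = 80)), na.rm = TRUE)
  }
  expect_lt(pg(spec_dense), pg(spec_sparse))
})

test_that("a white scene processes to a reflectance panorama of ones", {
  scene <- tiny_scene(seed = 21)
  scene$rho[] <- 1
  acq <- simulate_vnir(scene)
  rho <- process_vnir_acquisition(acq)
  expect_equal(max(abs(unclass(rho) - 1)), 0, tolerance = 1e-9)
})

test_that("the noise-free VNIR chain recovers the scene exactly", {
  scene <- tiny_scene(seed = 22)
  acq <- simulate_vnir(scene, drift = 0.93)
  rho <- process_vnir_acquisition(acq)
  truth <- unclass(acq$rho_true)
  rel <- abs(unclass(rho) - truth) / pmax(truth, 1e-12)
  nonsky <- array(scene$class_map != "sky", dim(rel))
  expect_lt(max(rel[nonsky]), 1e-6)
})

test_that("reflectance recovery error scales linearly with count noise", {
  scene <- tiny_scene(seed = 23)
  rmse_at <- function(sd, seed) {
    acq <- simulate_vnir(scene, noise_sd = sd, seed = seed)
    rho <- process_vnir_acquisition(acq)
    d <- unclass(rho) - unclass(acq$rho_true)
    sqrt(mean(d[array(scene$class_map != "sky", dim(d))]^2))
  }
  r1 <- mean(vapply(1:3, function(s) rmse_at(2, s), numeric(1)))
  r2 <- mean(vapply(1:3, function(s) rmse_at(4, s), numeric(1)))
  expect_gt(r2 / r1, 1.6)
  expect_lt(r2 / r1, 2.4)
})

test_that("an isothermal scene with a neutral atmosphere is uniform", {
  scene <- tiny_scene(seed = 24)
  scene$temp_offset[] <- 0
  scene$emissivity[] <- 1
  atm <- atmosphere_state(296, 0.5, 296, water_vapour = 0)
  acq <- simulate_thermal(scene, atm, model = neutral_tau_model(),
                          n_cols = 8)
  pano <- assemble_thermal_panorama(acq$stack, acq$scan, acq$sensor)
  tp <- surface_temperature(pano, acq$range, atm, emissivity = 1,
                            model = neutral_tau_model())
  vals <- unclass(tp)[!is.na(unclass(tp))]
  expect_equal(max(abs(vals - 296)), 0, tolerance = 1e-3)
})

test_that("ground-foliage thermal contrast survives the full correction", {
  spec <- scene_spec(azimuth_range = c(-30, 30),
                     elevation_range = c(-44, -12), cell_size = 1,
                     temperature_offsets = c(foliage = 0, bark = 3,
                                             ground = 12))
  scene <- make_scene(spec, seed = 25)
  atm <- atmosphere_state(298, 0.6, 270)
  acq <- simulate_thermal(scene, atm, n_cols = 8)
  pano <- assemble_thermal_panorama(acq$stack, acq$scan, acq$sensor)
  tp <- surface_temperature(pano, acq$range, atm,
                            emissivity = scene$emissivity)
  t_ground <- mean(unclass(tp)[scene$class_map == "ground"])
  t_fol <- mean(unclass(tp)[scene$class_map == "foliage"])
  truth_contrast <- mean(scene$temp_offset[scene$class_map == "ground"]) -
    mean(scene$temp_offset[scene$class_map == "foliage"])
  expect_equal(t_ground - t_fol, truth_contrast, tolerance = 0.01)
  expect_equal(t_ground - t_fol, 12, tolerance = 0.5)
})

test_that("range-dependent corrections cancel for isothermal truth", {
  scene <- tiny_scene(seed = 26)
  scene$temp_offset[] <- 0
  atm <- atmosphere_state(300, 0.8, 260)
  acq <- simulate_thermal(scene, atm, n_cols = 8)
  pano <- assemble_thermal_panorama(acq$stack, acq$scan, acq$sensor)
  tp <- surface_temperature(pano, acq$range, atm,
                            emissivity = scene$emissivity)
  vals <- unclass(tp)[!is.na(unclass(tp))]
  expect_lt(diff(range(vals)), 0.01)
  # while the raw (uncorrected) brightness temperatures do vary with range
  raw <- invert_band_radiance(as.vector(unclass(pano)))
  raw <- raw[!is.na(acq$t_true)]
  expect_gt(diff(range(raw)), 0.05)
})

test_that("a single wall returns its distance everywhere", {
  spec <- scene_spec(azimuth_range = c(-10, 10), elevation_range = c(-25, -15),
                     cell_size = 1, n_trees = 1, crown_radius = c(60, 60),
                     crown_range = c(150, 150), cover = c(1, 1))
  scene <- make_scene(spec, seed = 27)
  expect_true(all(scene$class_map %in% c("foliage", "bark")))
  cloud <- simulate_tls(scene, range_jitter = 0, seed = 28)
  expect_equal(max(abs(sqrt(cloud$x^2 + cloud$y^2 + cloud$z^2)[
    cloud$return_number == 1] - 150)), 0, tolerance = 1e-9)
})

test_that("per-cell Pgap approaches the cover complement", {
  spec <- scene_spec(azimuth_range = c(-20, 20), elevation_range = c(-40, -25),
                     cell_size = 1, n_trees = 4, crown_radius = c(10, 12),
                     crown_range = c(50, 60), cover = c(0.6, 0.6))
  scene <- make_scene(spec, seed = 29)
  cloud <- simulate_tls(scene, pulses_per_cell = 60, seed = 30)
  g <- bin_to_angular_grid(cloud, 1, c(-20, 20), c(-40, -25))
  pg <- unclass(gap_fraction(g, range_threshold = 80))
  crown_cells <- scene$class_map %in% c("foliage", "bark") & scene$cover == 0.6
  est <- mean(pg[crown_cells], na.rm = TRUE)
  expect_equal(est, 1 - 0.6, tolerance = 0.05)
})

test_that("PAR generator separates the day types by construction", {
  met <- simulate_par_and_meteo(dates = seq(as.Date("2017-01-01"),
                                            by = 1, length.out = 60),
                                clear_fraction = 1 / 3,
                                overcast_fraction = 0.1, seed = 31)
  d <- met$daily
  expect_true(all(d$stability[d$day_type == "clear"] > 30))
  expect_true(all(d$stability[d$day_type == "broken"] < 30))
  expect_true(all(is.infinite(d$stability[d$day_type == "overcast"])))
  expect_true(all(d$sw_obs <= d$sw_clear))
})

test_that("the stability filter keeps exactly the designed stable days", {
  met <- simulate_par_and_meteo(seed = 32)
  d <- stability_filter(met$daily, 30)
  designed <- d$day_type == "clear"
  expect_identical(d$kept, designed)
  expect_equal(mean(d$kept), mean(designed))
})

test_that("raw frames to scene indices reproduces the truth cube's indices", {
  # full-chain composition at a few acquisitions across a season
  for (s in c(301, 302, 303)) {
    scene <- tiny_scene(seed = s)
    acq <- simulate_vnir(scene, drift = 0.97)
    rho <- process_vnir_acquisition(acq)
    got <- compute_indices(rho, span = NULL)
    want <- compute_indices(acq$rho_true, span = NULL)
    expect_equal(got$value, want$value, tolerance = 1e-8)
    expect_identical(got$index, want$index)
  }
})
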