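test_that("band selection picks the nearest centre and records it", {
  wl <- seq(400, 900, by = 10)
  sel <- band_selection(wl, c(531, 570, 800))
  expect_equal(sel$actual, c(530, 570, 800))
  expect_true(all(abs(sel$requested - sel$actual) <= 5))
})

test_that("NDVI matches its formula and boundary cases", {
  p <- spectral_pano(list(`800` = 0.5, `645` = 0.05))
  im <- index_map(p, "ndvi")
  expect_equal(im[1, 1], (0.5 - 0.05) / (0.5 + 0.05))
  expect_equal(im[1, 1], 0.81818, tolerance = 1e-5)
  flat <- uniform_pano(0.3, wavelength = seq(400, 900, by = 10))
  expect_true(all(index_map(flat, "ndvi") == 0))
  pb <- spectral_pano(list(`800` = 0.4, `645` = 0))
  expect_true(all(index_map(pb, "ndvi") == 1))
  # zero denominator masks
  pz <- spectral_pano(list(`800` = 0, `645` = 0))
  expect_true(all(is.na(index_map(pz, "ndvi"))))
})

test_that("CCI is implemented exactly as printed, with an optional flip", {
  p <- spectral_pano(list(`645` = 0.06, `531` = 0.04))
  expect_equal(index_map(p, "cci")[1, 1], 0.2)
  expect_equal(index_map(p, "cci", flip = TRUE)[1, 1], -0.2)
  flat <- uniform_pano(0.3, wavelength = seq(400, 900, by = 10))
  expect_true(all(index_map(flat, "cci") == 0))
  # antisymmetry under swapping the two bands
  q <- spectral_pano(list(`645` = 0.04, `531` = 0.06))
  expect_equal(index_map(q, "cci")[1, 1], -index_map(p, "cci")[1, 1])
})

test_that("PRI matches its formula and stays in [-1, 1]", {
  p <- spectral_pano(list(`531` = 0.055, `570` = 0.045))
  expect_equal(index_map(p, "pri")[1, 1], 0.1, tolerance = 1e-12)
  eq <- spectral_pano(list(`531` = 0.05, `570` = 0.05))
  expect_true(all(index_map(eq, "pri") == 0))
  set.seed(14)
  rnd <- spectral_pano(list(`531` = runif(1), `570` = runif(1)))
  expect_true(all(abs(index_map(rnd, "pri")) <= 1))
})

test_that("triangular PRI follows the three-band area formula", {
  p <- spectral_pano(list(`490` = 0.05, `520` = 0.08, `545` = 0.10))
  expect_equal(index_map(p, "tri_pri")[1, 1],
               0.5 * (30 * 0.05 - 55 * 0.03))
  expect_equal(index_map(p, "tri_pri")[1, 1], -0.075)
  flat <- uniform_pano(0.3, wavelength = seq(400, 900, by = 10))
  expect_true(all(index_map(flat, "tri_pri") == 0))
  # offset invariance: adding a constant to all bands changes nothing
  p2 <- spectral_pano(list(`490` = 0.15, `520` = 0.18, `545` = 0.20),
                      default = 0.2)
  expect_equal(index_map(p2, "tri_pri")[1, 1],
               index_map(p, "tri_pri")[1, 1], tolerance = 1e-12)
})

test_that("normalised-difference indices are scale invariant", {
  scene <- tiny_scene(seed = 15)
  pano <- reflectance_panorama(scene$rho, scene$azimuth, scene$elevation,
                               scene$wavelength)
  scaled <- reflectance_panorama(scene$rho * 3.7, scene$azimuth,
                                 scene$elevation, scene$wavelength)
  for (ix in c("ndvi", "cci", "pri")) {
    expect_equal(index_map(pano, ix), index_map(scaled, ix),
                 ignore_attr = TRUE)
  }
})

test_that("azimuth subsetting keeps the symmetric window", {
  az <- angular_axis(-130, 110, 1)
  arr <- array(runif(length(az) * 5 * 3), c(length(az), 5, 3))
  p <- reflectance_panorama(arr, az, 1:5, c(500, 600, 700))
  sub <- azimuth_subset(p, span = 80, center = 0)
  expect_true(all(attr(sub, "azimuth") >= -40 & attr(sub, "azimuth") <= 40))
  expect_equal(dim(sub)[1], 80)
  full <- azimuth_subset(p, span = 240, center = -10)
  expect_equal(dim(full), dim(p))
  expect_error(azimuth_subset(p, span = 0), "positive")
  expect_error(azimuth_subset(p, span = 1, center = 500), "no columns")
})

test_that("scene statistics honour masks and report pixel counts", {
  vals <- matrix(c(0, 0, 1, 1), 2, 2)
  st <- scene_statistic(vals)
  expect_equal(st$value, 0.5)
  expect_equal(st$n_pixels, 4L)
  same <- scene_statistic(matrix(0.7, 3, 3), statistic = "median")
  expect_equal(same$value, 0.7)
  # canopy-only mean on a scene with distinct canopy and ground values
  mask <- matrix(c("canopy", "ground", "canopy", "ground"), 2, 2)
  vals2 <- matrix(c(10, -5, 10, -5), 2, 2)
  stm <- scene_statistic(vals2, mask = mask)
  expect_equal(stm$value, 10)
  expect_equal(stm$n_pixels, 2L)
  empty <- scene_statistic(vals2, mask = matrix("ground", 2, 2),
                           keep_class = "canopy")
  expect_true(is.na(empty$value))
})

test_that("the pipeline smooths spectra before computing indices", {
  scene <- tiny_scene(seed = 16, cell = 2)
  pano <- reflectance_panorama(scene$rho, scene$azimuth, scene$elevation,
                               scene$wavelength)
  res <- compute_indices(pano, indices = "ndvi", span = NULL,
                         smooth_window_nm = 30)
  manual <- scene_statistic(index_map(smooth_spectrum(pano, window_nm = 30),
                                      "ndvi"))
  expect_equal(res$value, manual$value)
  # and the order matters: index-then-smooth is a different number
  other <- scene_statistic(index_map(pano, "ndvi"))
  expect_false(isTRUE(all.equal(res$value, other$value)))
})

test_that("OLS fit recovers exact linear relations", {
  df <- tibble::tibble(value = 1:10, gpp = 2 * (1:10))
  fit <- suppressWarnings(ols_fit(df))  # lm warns on a perfect fit
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 0)
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$n, 10)
  const <- suppressWarnings(ols_fit(tibble::tibble(value = 1:10,
                                                   gpp = rep(4, 10))))
  expect_equal(const$r_squared, 0)
  expect_equal(const$slope, 0)
  expect_error(ols_fit(tibble::tibble(value = rep(1, 5), gpp = 1:5)),
               "variance")
  expect_error(ols_fit(tibble::tibble(value = 1:2, gpp = 1:2)), "3 paired")
})

test_that("OLS agrees with the closed-form least-squares oracle", {
  set.seed(17)
  x <- runif(50); y <- 3 + 1.5 * x + rnorm(50, 0, 0.3)
  fit <- ols_fit(tibble::tibble(value = x, gpp = y))
  b_hat <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  a_hat <- mean(y) - b_hat * mean(x)
  pred <- a_hat + b_hat * x
  r2 <- 1 - sum((y - pred)^2) / sum((y - mean(y))^2)
  expect_equal(fit$slope, b_hat)
  expect_equal(fit$intercept, a_hat)
  expect_equal(fit$r_squared, r2)
})

test_that("tidy and glance expose broom-style summaries", {
  set.seed(18)
  df <- tibble::tibble(value = runif(30), gpp = runif(30))
  fit <- ols_fit(df)
  td <- tidy(fit)
  expect_identical(td$term, c("(Intercept)", "index"))
  expect_named(td, c("term", "estimate", "std.error", "statistic",
                     "p.value"))
  gl <- glance(fit)
  expect_equal(gl$n, 30)
  expect_equal(gl$slope, fit$slope)
})

test_that("index-GPP regression recovers the generator's coupling", {
  met <- simulate_par_and_meteo(n_available = 326, slope = 60,
                                intercept = 1, r_squared_design = 0.52,
                                seed = 19)
  daily <- met$daily[met$daily$available, ]
  expect_equal(nrow(daily), 326)
  fit <- ols_fit(daily, x = "index_truth", y = "gpp")
  se <- tidy(fit)$std.error[2]
  expect_lt(abs(fit$slope - 60), 3 * se)
  expect_lt(abs(fit$r_squared - 0.52), 0.05)
})

test_that("stricter stability filtering does not reduce R-squared", {
  met <- simulate_par_and_meteo(unstable_noise_sd = 0.05, seed = 20)
  daily <- met$daily
  r2_at <- function(thr) {
    kept <- stability_filter(daily, thr)
    ols_fit(kept[kept$kept, ], x = "index_obs", y = "gpp")$r_squared
  }
  r2 <- vapply(c(0, 30), r2_at, numeric(1))
  expect_true(all(diff(r2) >= 0))
})

test_that("daily joining matches acquisitions to flux dates", {
  idx <- tibble::tibble(date = as.Date("2017-01-01") + 0:4,
                        index = "tri_pri", value = runif(5))
  gpp <- tibble::tibble(date = as.Date("2017-01-03") + 0:4,
                        gpp = runif(5))
  j <- join_daily(idx, gpp)
  expect_equal(nrow(j), 3)
  expect_true(all(c("value", "gpp") %in% names(j)))
})
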