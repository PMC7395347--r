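test_that("angular binning follows the stated conventions", {
  # +x is north: a point straight north sits at azimuth 0
  pts <- tibble::tibble(x = 100, y = 0, z = 0, return_number = 1L)
  g <- bin_to_angular_grid(pts, 1, azimuth_range = c(-2, 2),
                           elevation_range = c(-2, 2))
  expect_equal(sum(g$n_first), 1)
  expect_equal(g$points$range, 100)
  expect_equal(g$points$azimuth, 0)
  # boundary values go to the lower-index bin
  ptsb <- tibble::tibble(x = cos(pi / 180), y = sin(pi / 180), z = 0,
                         return_number = 1L)  # azimuth exactly 1 deg
  gb <- bin_to_angular_grid(ptsb, 1, azimuth_range = c(0, 2),
                            elevation_range = c(-1, 1))
  expect_equal(gb$points$az_cell, 1L)
  # empty cloud gives an all-masked grid, not an error
  ge <- bin_to_angular_grid(tibble::tibble(x = numeric(), y = numeric(),
                                           z = numeric(),
                                           return_number = integer()))
  expect_equal(sum(ge$n_first), 0)
})

test_that("rotating the cloud shifts occupancy by one cell", {
  set.seed(5)
  n <- 500
  az <- runif(n, -30.4, 29.4); el <- runif(n, -40, -10); r <- runif(n, 20, 200)
  mk <- function(azd) tibble::tibble(
    x = r * cos(el * pi / 180) * cos(azd * pi / 180),
    y = r * cos(el * pi / 180) * sin(azd * pi / 180),
    z = r * sin(el * pi / 180), return_number = 1L)
  g0 <- bin_to_angular_grid(mk(az), 1, c(-31, 31), c(-41, -9))
  g1 <- bin_to_angular_grid(mk(az + 1), 1, c(-31, 31), c(-41, -9))
  n0 <- g0$n_first; n1 <- g1$n_first
  expect_equal(n1[2:nrow(n1), ], n0[1:(nrow(n0) - 1), ])
})

test_that("first-return counts are conserved", {
  scene <- tiny_scene(seed = 6)
  cloud <- simulate_tls(scene, seed = 2)
  g <- bin_to_angular_grid(cloud, 1)
  expect_equal(sum(g$n_first), sum(cloud$return_number == 1))
})

test_that("range image takes the nearest first return per cell", {
  pts <- tibble::tibble(x = c(40, 120), y = 0, z = 0, return_number = 1L)
  g <- bin_to_angular_grid(pts, 1, c(-1, 1), c(-1, 1))
  ri <- range_image(g)
  expect_equal(ri[!is.na(ri)], 40)
  expect_equal(range_image(g, statistic = "mean")[!is.na(ri)], 80)
  # empty cells are masked
  expect_true(anyNA(range_image(bin_to_angular_grid(pts, 1, c(-1, 3),
                                                    c(-1, 1)))))
})

test_that("a synthetic wall appears at its distance in every occupied cell", {
  set.seed(8)
  n <- 2000
  az <- runif(n, -10, 10); el <- runif(n, -10, 10)
  pts <- tibble::tibble(
    x = 150 * cos(el * pi / 180) * cos(az * pi / 180),
    y = 150 * cos(el * pi / 180) * sin(az * pi / 180),
    z = 150 * sin(el * pi / 180), return_number = 1L)
  ri <- range_image(bin_to_angular_grid(pts, 1))
  expect_equal(max(abs(ri[!is.na(ri)] - 150)), 0, tolerance = 1e-9)
})

test_that("gap fraction is the beyond-threshold share of first returns", {
  mk <- function(r) tibble::tibble(x = r, y = 0, z = 0,
                                   return_number = 1L)
  occupied <- function(img) img[!is.na(img)]
  all_beyond <- dplyr::bind_rows(lapply(rep(10, 5), mk))
  g <- bin_to_angular_grid(all_beyond, 1, c(-1, 1), c(-1, 1))
  expect_equal(occupied(gap_fraction(g)), 1)
  mixed <- dplyr::bind_rows(lapply(c(rep(2, 3), rep(10, 7)), mk))
  gm <- bin_to_angular_grid(mixed, 1, c(-1, 1), c(-1, 1))
  expect_equal(occupied(gap_fraction(gm)), 0.7)
  near <- dplyr::bind_rows(lapply(rep(2, 4), mk))
  gn <- bin_to_angular_grid(near, 1, c(-1, 1), c(-1, 1))
  expect_equal(occupied(gap_fraction(gn)), 0)
  expect_equal(sum(is.na(gap_fraction(g))), 3)  # no-return cells masked
})

test_that("height masks partition occupied cells into ground and canopy", {
  h <- 68
  # flat ground plane sampled below the horizon
  set.seed(9)
  el <- runif(400, -45, -12); az <- runif(400, -20, 20)
  r <- h / sin(-el * pi / 180)
  ground <- tibble::tibble(
    x = r * cos(el * pi / 180) * cos(az * pi / 180),
    y = r * cos(el * pi / 180) * sin(az * pi / 180),
    z = r * sin(el * pi / 180), return_number = 1L)
  gg <- bin_to_angular_grid(ground, 1)
  mg <- height_masks(gg, sensor_height = h)
  occ <- gg$n_first > 0
  expect_true(all(mg[occ] == "ground"))
  expect_true(all(mg[!occ] == "sky"))

  # canopy discs 40 m up
  crown <- tibble::tibble(x = c(30, 50), y = c(0, 5), z = c(-20, -25),
                          return_number = 1L)
  gc <- bin_to_angular_grid(crown, 1)
  mc <- height_masks(gc, sensor_height = h)
  expect_true(all(mc[gc$n_first > 0] == "canopy"))

  # mixed scene: classes are mutually exclusive and exhaustive
  mixed <- dplyr::bind_rows(ground, crown)
  gm <- bin_to_angular_grid(mixed, 1)
  mm <- height_masks(gm, sensor_height = h)
  expect_true(all(mm %in% c("ground", "canopy", "sky")))
  expect_true(all((mm != "sky") == (gm$n_first > 0)))
})

test_that("angular products equal the brute-force per-point oracle", {
  scene <- tiny_scene(seed = 10)
  cloud <- simulate_tls(scene, pulses_per_cell = 6, seed = 3)
  expect_lte(nrow(cloud), 1e4)
  az_r <- c(-21, 21); el_r <- c(-41, -9)
  g <- bin_to_angular_grid(cloud, 1, az_r, el_r)
  oracle <- brute_force_grid(cloud, 1, az_r, el_r)
  expect_identical(g$n_first, oracle$n_first)
  expect_equal(unclass(range_image(g)), oracle$range, ignore_attr = TRUE)
  expect_equal(unclass(gap_fraction(g, 5)), oracle$pgap, ignore_attr = TRUE)
})

test_that("per-cell Pgap of a cloud union is the count-weighted mean", {
  scene <- tiny_scene(seed = 12)
  c1 <- simulate_tls(scene, pulses_per_cell = 4, seed = 4)
  c2 <- simulate_tls(scene, pulses_per_cell = 4, seed = 5)
  az_r <- c(-21, 21); el_r <- c(-41, -9)
  g1 <- bin_to_angular_grid(c1, 1, az_r, el_r)
  g2 <- bin_to_angular_grid(c2, 1, az_r, el_r)
  gu <- bin_to_angular_grid(dplyr::bind_rows(c1, c2), 1, az_r, el_r)
  p1 <- unclass(gap_fraction(g1)); p2 <- unclass(gap_fraction(g2))
  pu <- unclass(gap_fraction(gu))
  w <- g1$n_first + g2$n_first
  both <- g1$n_first > 0 & g2$n_first > 0
  expected <- (g1$n_first * ifelse(is.na(p1), 0, p1) +
                 g2$n_first * ifelse(is.na(p2), 0, p2)) / w
  expect_equal(pu[both], expected[both])
})

test_that("resampling to the panorama grid is nearest-cell and mask-safe", {
  vals <- matrix(1:6, 3, 2)
  img <- structure(vals, azimuth = c(0.5, 1.5, 2.5), elevation = c(-1.5, -0.5),
                   class = c("angular_image", "panorama"))
  # identity grid
  same <- resample_to_panorama(img, attr(img, "azimuth"),
                               attr(img, "elevation"))
  expect_equal(unclass(same), vals, ignore_attr = TRUE)
  # 4x upsampling: each fine pixel equals its containing coarse cell
  fine_az <- seq(0.125, 2.875, by = 0.25)
  fine_el <- seq(-1.875, -0.125, by = 0.25)
  up <- resample_to_panorama(img, fine_az, fine_el)
  expect_equal(unclass(up)[1:4, 1], rep(1, 4))
  expect_equal(unclass(up)[5:8, 1], rep(2, 4))
  const <- structure(matrix(7, 3, 2), azimuth = c(0.5, 1.5, 2.5),
                     elevation = c(-1.5, -0.5),
                     class = c("angular_image", "panorama"))
  expect_true(all(resample_to_panorama(const, fine_az, fine_el) == 7))
  expect_error(resample_to_panorama(img, c(100, 101), c(50, 51)), "disjoint")
})
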