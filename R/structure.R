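# Canopy structure from TLS point clouds acquired at the sensor position:
# angular-grid binning, range image (distance to first return), gap
# fraction (Pgap) and canopy/ground component masks, all co-registerable to
# the imaging panoramas.
#
# Angular conventions match the panoramas: azimuth = degrees from +x
# (north), positive toward +y (east), in (-180, 180]; elevation = degrees
# above the horizontal plane. Bins are half-open [lo, hi).

#' Bin a point cloud to an angular grid
#'
#' Each return is assigned to exactly one cell of a regular
#' `cell_size x cell_size` degree grid by its azimuth and elevation seen
#' from the sensor origin; range is the Euclidean norm. All returns are
#' kept in the table; downstream products use first returns only.
#'
#' @param points Tibble with `x`, `y`, `z` (m, sensor-origin frame) and
#'   `return_number`.
#' @param cell_size Cell size in degrees (default 1).
#' @param azimuth_range,elevation_range Grid limits `c(lo, hi)` in degrees;
#'   derived from the data (floored/ceiled to whole cells) when `NULL`.
#' @return An `angular_grid`: list with `points` (the input plus `azimuth`,
#'   `elevation`, `range`, `az_cell`, `el_cell`), `azimuth` and `elevation`
#'   cell-centre vectors, `cell_size`, and matrices `n_first` (first-return
#'   count per cell).
#' @export
bin_to_angular_grid <- function(points, cell_size = 1,
                                azimuth_range = NULL,
                                elevation_range = NULL) {
  pts <- tibble::as_tibble(points)
  if (nrow(pts) > 0) {
    pts$range <- sqrt(pts$x^2 + pts$y^2 + pts$z^2)
    pts$azimuth <- atan2(pts$y, pts$x) * 180 / pi
    pts$azimuth[pts$azimuth <= -180] <- pts$azimuth[pts$azimuth <= -180] + 360
    pts$elevation <- atan2(pts$z, sqrt(pts$x^2 + pts$y^2)) * 180 / pi
  } else {
    pts$range <- pts$azimuth <- pts$elevation <- numeric(0)
  }
  rng <- function(v, given) {
    if (!is.null(given)) return(given)
    if (!length(v)) return(c(0, cell_size))
    out <- c(floor(min(v) / cell_size), ceiling(max(v) / cell_size)) * cell_size
    if (out[2] <= out[1]) out[2] <- out[1] + cell_size
    out
  }
  az_r <- rng(pts$azimuth, azimuth_range)
  el_r <- rng(pts$elevation, elevation_range)
  n_az <- max(1L, as.integer(round((az_r[2] - az_r[1]) / cell_size)))
  n_el <- max(1L, as.integer(round((el_r[2] - el_r[1]) / cell_size)))
  # boundary values go to the lower-index bin; the grid minimum opens bin 1
  bin_of <- function(v, lo, n) {
    i <- ceiling((v - lo) / cell_size)
    i[i == 0L] <- 1L
    pmin(pmax(as.integer(i), 0L), n + 1L)
  }
  pts$az_cell <- bin_of(pts$azimuth, az_r[1], n_az)
  pts$el_cell <- bin_of(pts$elevation, el_r[1], n_el)
  inside <- pts$az_cell >= 1 & pts$az_cell <= n_az &
    pts$el_cell >= 1 & pts$el_cell <= n_el
  pts <- pts[inside, ]
  first <- pts[pts$return_number == 1, ]
  n_first <- matrix(0L, n_az, n_el)
  if (nrow(first)) {
    tab <- table(factor(first$az_cell, levels = seq_len(n_az)),
                 factor(first$el_cell, levels = seq_len(n_el)))
    n_first <- matrix(as.integer(tab), n_az, n_el)
  }
  structure(list(points = pts,
                 azimuth = az_r[1] + (seq_len(n_az) - 0.5) * cell_size,
                 elevation = el_r[1] + (seq_len(n_el) - 0.5) * cell_size,
                 cell_size = cell_size, n_first = n_first),
            class = "angular_grid")
}

#' @export
print.angular_grid <- function(x, ...) {
  cat(sprintf("<angular_grid> %d x %d cells of %g deg, %d returns (%d first)\n",
              length(x$azimuth), length(x$elevation), x$cell_size,
              nrow(x$points), sum(x$n_first)))
  invisible(x)
}

.grid_image <- function(grid, values) {
  structure(values, azimuth = grid$azimuth, elevation = grid$elevation,
            class = c("angular_image", "panorama"))
}

.aggregate_first <- function(grid, fun) {
  first <- grid$points[grid$points$return_number == 1, ]
  out <- matrix(NA_real_, length(grid$azimuth), length(grid$elevation))
  if (nrow(first)) {
    idx <- (first$el_cell - 1L) * length(grid$azimuth) + first$az_cell
    agg <- tapply(seq_len(nrow(first)), idx, function(i) fun(first[i, ]))
    out[as.integer(names(agg))] <- as.numeric(agg)
  }
  out
}

#' Range image: distance to first return per cell
#'
#' @param grid An `angular_grid`.
#' @param statistic `"nearest"` (minimum first-return range, the
#'   nearest-object convention) or `"mean"`.
#' @return An `angular_image` matrix `[azimuth, elevation]` of range (m);
#'   cells with no first return are `NA`.
#' @export
range_image <- function(grid, statistic = c("nearest", "mean")) {
  statistic <- match.arg(statistic)
  f <- if (statistic == "nearest") function(p) min(p$range)
       else function(p) mean(p$range)
  .grid_image(grid, .aggregate_first(grid, f))
}

#' Gap fraction (Pgap) per cell
#'
#' Fraction of first returns with range beyond the threshold divided by all
#' first returns in the cell; a proxy for directional canopy transmittance.
#' Cells with no first returns are masked.
#'
#' @param grid An `angular_grid`.
#' @param range_threshold Metres (default 5).
#' @return An `angular_image` with values in \[0, 1\].
#' @export
gap_fraction <- function(grid, range_threshold = 5) {
  .grid_image(grid, .aggregate_first(grid, function(p) {
    mean(p$range > range_threshold)
  }))
}

#' Canopy/ground/sky component masks from return heights
#'
#' Classifies each cell by the minimum first-return height above ground
#' (conservative ground detection): ground if <= `height_threshold`, canopy
#' otherwise, sky where the cell has no first return. In the sensor-origin
#' frame the ground reference is `-sensor_height`, so height above ground
#' is `z + sensor_height`.
#'
#' @param grid An `angular_grid`.
#' @param sensor_height Sensor height above ground, m.
#' @param height_threshold Metres (default 0.5).
#' @return An `angular_image` character matrix with entries `"canopy"`,
#'   `"ground"`, `"sky"` (mutually exclusive, exhaustive).
#' @export
height_masks <- function(grid, sensor_height, height_threshold = 0.5) {
  h_min <- .aggregate_first(grid, function(p) min(p$z + sensor_height))
  cls <- ifelse(is.na(h_min), "sky",
                ifelse(h_min <= height_threshold, "ground", "canopy"))
  .grid_image(grid, matrix(cls, nrow(h_min), ncol(h_min)))
}

#' Resample an angular-grid product to a panorama grid
#'
#' Nearest-cell assignment from the coarse TLS grid (typically 1 deg) to
#' each (finer) panorama pixel; pixels whose containing source cell is
#' masked stay masked.
#'
#' @param image An `angular_image` (from [range_image()], [gap_fraction()]
#'   or [height_masks()]).
#' @param target_azimuth,target_elevation Target cell-centre vectors,
#'   degrees (e.g. `attr(pano, "azimuth")`).
#' @return Matrix on the target grid with the source values.
#' @export
resample_to_panorama <- function(image, target_azimuth, target_elevation) {
  az <- attr(image, "azimuth"); el <- attr(image, "elevation")
  if (max(target_azimuth) < min(az) - diff(az[1:2]) / 2 ||
      min(target_azimuth) > max(az) + diff(az[1:2]) / 2 ||
      max(target_elevation) < min(el) - diff(el[1:2]) / 2 ||
      min(target_elevation) > max(el) + diff(el[1:2]) / 2)
    stop("source and target angular extents are disjoint", call. = FALSE)
  nearest <- function(x, centres) {
    pmin(pmax(vapply(x, function(v) which.min(abs(centres - v)), integer(1)),
              1L), length(centres))
  }
  ai <- nearest(target_azimuth, az)
  ei <- nearest(target_elevation, el)
  out <- unclass(image)[ai, ei, drop = FALSE]
  structure(out, azimuth = target_azimuth, elevation = target_elevation,
            class = c("angular_image", "panorama"))
}
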