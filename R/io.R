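# Bit-exact readers/writers: raw frame streams, ENVI panorama cubes,
# ASCII point clouds, irradiance/PAR/meteorology CSV, MD5 run manifests.
#
# Raw streams are flat little-endian binary (uint16 or float32) with a JSON
# sidecar header (<path>.json) holding sample kind, frame shape, count,
# frame rate, start time and free-form metadata. Endianness is fixed
# little-endian on disk regardless of host.

#' Write a raw sensor frame stream
#'
#' @param frames Numeric array `[rows, cols, frames]` (a matrix is treated
#'   as a single frame).
#' @param path Output file; a JSON sidecar `<path>.json` is written next to
#'   it.
#' @param sample_kind `"uint16_le"` or `"float32_le"`.
#' @param frame_rate Frames per second (uniform frame timestamps are derived
#'   from this and `start_time`).
#' @param start_time Optional ISO-8601 stream start time.
#' @param metadata Optional named list stored verbatim in the header.
#' @return `path`, invisibly.
#' @export
write_raw_frames <- function(frames, path, sample_kind = c("float32_le", "uint16_le"),
                             frame_rate = 1, start_time = NULL, metadata = list()) {
  sample_kind <- match.arg(sample_kind)
  if (is.matrix(frames)) frames <- array(frames, c(dim(frames), 1))
  stopifnot(length(dim(frames)) == 3)
  d <- dim(frames)
  con <- file(path, "wb"); on.exit(close(con))
  if (sample_kind == "uint16_le") {
    v <- as.integer(frames)
    if (any(v < 0 | v > 65535)) stop("uint16 stream values must be in [0, 65535]",
                                     call. = FALSE)
    # writeBin has no unsigned 16-bit: map to signed representation
    v <- ifelse(v > 32767L, v - 65536L, v)
    writeBin(v, con, size = 2, endian = "little")
  } else {
    writeBin(as.numeric(frames), con, size = 4, endian = "little")
  }
  hdr <- list(sample_kind = sample_kind, rows = d[1], cols = d[2],
              frame_count = d[3], frame_rate = frame_rate,
              start_time = start_time, metadata = metadata)
  jsonlite::write_json(hdr, paste0(path, ".json"), auto_unbox = TRUE,
                       null = "null", digits = NA)
  invisible(path)
}

#' Read a raw sensor frame stream
#'
#' Inverts [write_raw_frames()] bit-exactly. The file size must equal
#' `rows * cols * frame_count * bytes_per_sample`; a truncated or padded
#' file raises a corrupt-stream error naming the expected and actual byte
#' counts (partial frames are never silently dropped).
#'
#' @param path Stream file written by [write_raw_frames()].
#' @return List with `frames` (array `[rows, cols, frames]`), `sample_kind`,
#'   `frame_rate`, `timestamps` (seconds from stream start) and `metadata`.
#' @export
read_raw_frames <- function(path) {
  hdr_path <- paste0(path, ".json")
  if (!file.exists(hdr_path)) stop("missing stream header: ", hdr_path,
                                   call. = FALSE)
  hdr <- jsonlite::read_json(hdr_path, simplifyVector = TRUE)
  bps <- if (hdr$sample_kind == "uint16_le") 2 else 4
  n <- hdr$rows * hdr$cols * hdr$frame_count
  expected <- n * bps
  actual <- file.size(path)
  if (is.na(actual) || actual != expected)
    stop(sprintf("corrupt stream %s: expected %d bytes, found %s bytes",
                 path, expected, ifelse(is.na(actual), "no", actual)),
         call. = FALSE)
  con <- file(path, "rb"); on.exit(close(con))
  if (hdr$sample_kind == "uint16_le") {
    v <- readBin(con, "integer", n = n, size = 2, signed = FALSE,
                 endian = "little")
  } else {
    v <- readBin(con, "numeric", n = n, size = 4, endian = "little")
  }
  list(frames = array(v, c(hdr$rows, hdr$cols, hdr$frame_count)),
       sample_kind = hdr$sample_kind, frame_rate = hdr$frame_rate,
       start_time = hdr$start_time,
       timestamps = (seq_len(hdr$frame_count) - 1) / hdr$frame_rate,
       metadata = hdr$metadata)
}

# --- ENVI panorama cubes -----------------------------------------------------

.envi_block <- function(x, digits = 10) {
  paste0("{ ", paste(formatC(x, digits = digits, format = "g"),
                     collapse = " , "), " }")
}

.envi_parse_block <- function(txt) {
  as.numeric(strsplit(gsub("[{}]", "", txt), ",")[[1]])
}

#' Write a panorama cube as an ENVI raster
#'
#' Band-sequential (BSQ) float32 little-endian binary plus a plain-text ENVI
#' header. Wavelengths (nm) go in the standard `wavelength` key; the angular
#' coordinate vectors go in `azimuth` / `elevation` keys so the cube is
#' self-describing, while remaining readable by standard remote-sensing
#' software.
#'
#' @param cube A panorama object (see [radiance_panorama()]) or a 3-D array
#'   with `azimuth`, `elevation`, `wavelength` attributes; single-band
#'   images (matrices with coordinates) are written as one-band rasters.
#' @param path Binary output path; the header is `<path>.hdr`.
#' @param interleave `"bsq"` (the only supported dialect).
#' @return `path`, invisibly.
#' @export
write_panorama <- function(cube, path, interleave = "bsq") {
  if (!identical(interleave, "bsq"))
    stop("unsupported interleave dialect: ", interleave, call. = FALSE)
  az <- attr(cube, "azimuth"); el <- attr(cube, "elevation")
  wl <- attr(cube, "wavelength")
  if (is.null(az) || is.null(el))
    stop("cube must carry azimuth and elevation coordinates", call. = FALSE)
  arr <- unclass(cube)
  if (is.matrix(arr)) arr <- array(arr, c(dim(arr), 1))
  stopifnot(length(dim(arr)) == 3, dim(arr)[1] == length(az),
            dim(arr)[2] == length(el))
  n_band <- dim(arr)[3]
  if (is.null(wl)) wl <- seq_len(n_band)
  stopifnot(length(wl) == n_band)
  # ENVI layout: per band, lines (rows) x samples; use elevation as lines,
  # azimuth as samples -> need [samples fastest] = azimuth fastest
  con <- file(path, "wb"); on.exit(close(con))
  for (b in seq_len(n_band)) {
    writeBin(as.numeric(arr[, , b]), con, size = 4, endian = "little")
  }
  hdr <- c("ENVI",
           "description = { canopyscan panorama cube }",
           paste0("samples = ", length(az)),
           paste0("lines = ", length(el)),
           paste0("bands = ", n_band),
           "header offset = 0",
           "file type = ENVI Standard",
           "data type = 4",
           paste0("interleave = ", interleave),
           "byte order = 0",
           "wavelength units = Nanometers",
           paste0("wavelength = ", .envi_block(wl)),
           paste0("azimuth = ", .envi_block(az)),
           paste0("elevation = ", .envi_block(el)))
  writeLines(hdr, paste0(path, ".hdr"))
  invisible(path)
}

#' Read a panorama cube written by [write_panorama()]
#'
#' Lossless at float32 precision. Returns a bare coordinate-carrying array;
#' wrap with [reflectance_panorama()] etc. to restore semantics.
#'
#' @param path Binary file path (header at `<path>.hdr`).
#' @return 3-D array `[azimuth, elevation, band]` with `azimuth`,
#'   `elevation`, `wavelength` attributes (single-band cubes keep a third
#'   dimension of extent 1).
#' @export
read_panorama <- function(path) {
  hdr_path <- paste0(path, ".hdr")
  if (!file.exists(hdr_path)) stop("missing ENVI header: ", hdr_path,
                                   call. = FALSE)
  lines <- readLines(hdr_path)
  get <- function(key) {
    hit <- grep(paste0("^", key, " ?="), lines, value = TRUE)
    if (!length(hit)) return(NULL)
    sub(paste0("^", key, " ?= ?"), "", hit[1])
  }
  ns <- as.integer(get("samples")); nl <- as.integer(get("lines"))
  nb <- as.integer(get("bands"))
  if (!identical(as.integer(get("data type")), 4L))
    stop("unsupported ENVI data type (only float32 supported)", call. = FALSE)
  n <- ns * nl * nb
  expected <- n * 4
  if (file.size(path) != expected)
    stop(sprintf("corrupt cube %s: expected %d bytes, found %d", path,
                 expected, file.size(path)), call. = FALSE)
  con <- file(path, "rb"); on.exit(close(con))
  v <- readBin(con, "numeric", n = n, size = 4, endian = "little")
  arr <- array(v, c(ns, nl, nb))
  attr(arr, "azimuth") <- .envi_parse_block(get("azimuth"))
  attr(arr, "elevation") <- .envi_parse_block(get("elevation"))
  wl <- get("wavelength")
  if (!is.null(wl)) attr(arr, "wavelength") <- .envi_parse_block(wl)
  arr
}

# --- point clouds ------------------------------------------------------------

#' Read a TLS point cloud from an ASCII XYZ file
#'
#' Whitespace-separated columns `x y z return_number` (metres, sensor-origin
#' Cartesian frame; return number >= 1). Comment lines starting with `#` are
#' skipped; any other malformed line raises a parse error naming the line
#' number.
#'
#' @param path File path.
#' @return Tibble with columns `x`, `y`, `z`, `return_number`.
#' @export
read_point_cloud <- function(path) {
  raw <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", raw)
  if (!any(keep))
    return(tibble::tibble(x = numeric(), y = numeric(), z = numeric(),
                          return_number = integer()))
  idx <- which(keep)
  parts <- strsplit(trimws(raw[keep]), "\\s+")
  bad <- which(vapply(parts, length, integer(1)) != 4)
  if (length(bad))
    stop("malformed point cloud line ", idx[bad[1]], " in ", path,
         call. = FALSE)
  m <- matrix(suppressWarnings(as.numeric(unlist(parts))),
              ncol = 4, byrow = TRUE)
  if (anyNA(m)) {
    bad <- idx[which(rowSums(is.na(m)) > 0)[1]]
    stop("malformed point cloud line ", bad, " in ", path, call. = FALSE)
  }
  tibble::tibble(x = m[, 1], y = m[, 2], z = m[, 3],
                 return_number = as.integer(m[, 4]))
}

#' Write a point cloud to ASCII XYZ
#'
#' @param points Tibble/data frame with `x`, `y`, `z`, `return_number`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_point_cloud <- function(points, path) {
  stopifnot(all(c("x", "y", "z", "return_number") %in% names(points)))
  lines <- sprintf("%.6f %.6f %.6f %d", points$x, points$y, points$z,
                   as.integer(points$return_number))
  writeLines(lines, path)
  invisible(path)
}

# --- run manifests -----------------------------------------------------------

#' Build an MD5 run manifest for a set of files
#'
#' @param paths Character vector of file paths.
#' @return Tibble with columns `file`, `bytes`, `md5`.
#' @export
build_manifest <- function(paths) {
  stopifnot(all(file.exists(paths)))
  tibble::tibble(file = paths,
                 bytes = file.size(paths),
                 md5 = unname(tools::md5sum(paths)))
}

#' Verify files against a manifest
#'
#' A missing file is reported as a failure, never as an exception.
#'
#' @param manifest Tibble from [build_manifest()].
#' @return The manifest with logical column `pass` added.
#' @export
verify_manifest <- function(manifest) {
  now <- ifelse(file.exists(manifest$file),
                unname(tools::md5sum(manifest$file)), NA_character_)
  dplyr::mutate(manifest, pass = !is.na(now) & now == .data$md5)
}

# --- tabular series ----------------------------------------------------------

#' Read a timestamped CSV series
#'
#' Thin wrapper standardising the package's tabular inputs (PAR traces,
#' meteorology, daily flux series): a CSV whose first column `time` (or
#' `date`) holds ISO-8601 timestamps.
#'
#' @param path CSV path.
#' @return Tibble; the `time` column is parsed to `POSIXct` (UTC) and a
#'   `date` column to `Date`.
#' @export
read_series_csv <- function(path) {
  df <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  if ("time" %in% names(df))
    df$time <- as.POSIXct(df$time, tz = "UTC",
                          tryFormats = c("%Y-%m-%dT%H:%M:%OS",
                                         "%Y-%m-%d %H:%M:%OS",
                                         "%Y-%m-%d %H:%M"))
  if ("date" %in% names(df)) df$date <- as.Date(df$date)
  df
}

#' Write a timestamped CSV series
#'
#' @param df Tibble with `time` and/or `date` column.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_series_csv <- function(df, path) {
  if ("time" %in% names(df))
    df$time <- format(df$time, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
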