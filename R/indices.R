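# Vegetation indices from reflectance panoramas, field-of-view subsetting,
# scene aggregation, daily time-series assembly and regression against a
# daily gross-primary-production (GPP) flux series.

#' Resolve requested wavelengths to band indices
#'
#' Nearest-band-centre lookup on the (smoothed) band grid; the actual
#' centres chosen are recorded so index definitions stay auditable.
#'
#' @param wavelength Band-centre grid, nm.
#' @param requested Requested wavelengths, nm.
#' @return Tibble with `requested`, `band` (index), `actual` (centre, nm).
#' @export
band_selection <- function(wavelength, requested) {
  band <- vapply(requested, function(w) which.min(abs(wavelength - w)),
                 integer(1))
  tibble::tibble(requested = requested, band = band,
                 actual = wavelength[band])
}

.band_image <- function(pano, nm) {
  sel <- band_selection(attr(pano, "wavelength"), nm)
  list(img = unclass(pano)[, , sel$band], actual = sel$actual)
}

.nd_index <- function(a, b) {
  den <- a + b
  out <- (a - b) / den
  out[den == 0] <- NA_real_
  out
}

#' Per-pixel vegetation index map
#'
#' Computes one of the package's narrow-band indices per pixel of a
#' reflectance panorama:
#' \itemize{
#'   \item `ndvi`: (R800 - R645) / (R800 + R645)
#'   \item `cci`:  (R645 - R531) / (R645 + R531) -- note the band order,
#'     which is sign-flipped relative to the index's original literature
#'     definition; set `flip = TRUE` for the conventional sign.
#'   \item `pri`:  (R531 - R570) / (R531 + R570)
#'   \item `tri_pri`: 0.5 * (30 * (R545 - R490) - 55 * (R520 - R490)), the
#'     triangular PRI over the 490/520/545 nm bands.
#' }
#' Pixels with a zero normalised-difference denominator are masked.
#'
#' @param pano A `reflectance_panorama` (smooth first: the pipeline order
#'   is smooth spectra, then compute indices).
#' @param index One of `"ndvi"`, `"cci"`, `"pri"`, `"tri_pri"`.
#' @param flip Flip the sign of `cci` to the conventional (R531 - R645)
#'   order.
#' @return Matrix `[azimuth, elevation]` with attribute `bands` (tibble of
#'   requested/actual centres).
#' @export
index_map <- function(pano, index = c("ndvi", "cci", "pri", "tri_pri"),
                      flip = FALSE) {
  index <- match.arg(index)
  stopifnot(inherits(pano, "reflectance_panorama"))
  wl <- attr(pano, "wavelength")
  get <- function(nm) .band_image(pano, nm)
  out <- switch(index,
    ndvi = {
      a <- get(800); b <- get(645)
      list(img = .nd_index(a$img, b$img), bands = c(800, 645),
           actual = c(a$actual, b$actual))
    },
    cci = {
      a <- get(645); b <- get(531)
      v <- .nd_index(a$img, b$img)
      list(img = if (flip) -v else v, bands = c(645, 531),
           actual = c(a$actual, b$actual))
    },
    pri = {
      a <- get(531); b <- get(570)
      list(img = .nd_index(a$img, b$img), bands = c(531, 570),
           actual = c(a$actual, b$actual))
    },
    tri_pri = {
      r490 <- get(490); r520 <- get(520); r545 <- get(545)
      list(img = 0.5 * (30 * (r545$img - r490$img) -
                          55 * (r520$img - r490$img)),
           bands = c(490, 520, 545),
           actual = c(r490$actual, r520$actual, r545$actual))
    })
  structure(out$img,
            azimuth = attr(pano, "azimuth"),
            elevation = attr(pano, "elevation"),
            bands = tibble::tibble(requested = out$bands,
                                   actual = out$actual),
            class = c("angular_image", "panorama"))
}

#' Subset a panorama to a symmetric azimuth window
#'
#' Restricting the scene statistic to a window centred on a fixed azimuth
#' (conventionally 80 degrees about 0, i.e. -40..40) limits bidirectional
#' reflectance (BRDF) effects from the changing sun-view geometry.
#'
#' @param x A panorama or angular image.
#' @param span Window width, degrees; must be positive.
#' @param center Window centre azimuth, degrees.
#' @return Same class as `x`, restricted to
#'   `azimuth in [center - span/2, center + span/2]`.
#' @export
azimuth_subset <- function(x, span = 80, center = 0) {
  if (span <= 0) stop("span must be positive", call. = FALSE)
  az <- attr(x, "azimuth")
  keep <- az >= center - span / 2 & az <= center + span / 2
  if (!any(keep)) stop("azimuth window contains no columns", call. = FALSE)
  idx <- which(keep)
  out <- if (length(dim(x)) == 3) unclass(x)[idx, , , drop = FALSE]
         else unclass(x)[idx, , drop = FALSE]
  attrs <- attributes(x)
  attrs$dim <- dim(out)
  attrs$azimuth <- az[idx]
  attributes(out) <- attrs
  out
}

#' Scene statistic over an index map
#'
#' Aggregates per-pixel values to a scene-level index, optionally masked to
#' one structural component (e.g. canopy-only via the co-registered TLS
#' mask).
#'
#' @param values Matrix of per-pixel values (e.g. from [index_map()]).
#' @param mask Optional character matrix (same shape) from [height_masks()]
#'   resampled to the panorama grid; only `keep_class` pixels are used.
#' @param keep_class Class retained when `mask` is given; default
#'   `"canopy"`.
#' @param statistic `"mean"` or `"median"`.
#' @return One-row tibble with `value` and `n_pixels` (`value` is `NA` when
#'   no unmasked pixels remain).
#' @export
scene_statistic <- function(values, mask = NULL, keep_class = "canopy",
                            statistic = c("mean", "median")) {
  statistic <- match.arg(statistic)
  v <- as.vector(unclass(values))
  if (!is.null(mask)) {
    stopifnot(all(dim(as.matrix(unclass(mask))) == dim(unclass(values))))
    v <- v[as.vector(unclass(mask)) == keep_class]
  }
  v <- v[!is.na(v)]
  if (!length(v))
    return(tibble::tibble(value = NA_real_, n_pixels = 0L))
  val <- if (statistic == "mean") mean(v) else median(v)
  tibble::tibble(value = val, n_pixels = length(v))
}

#' Scene-level vegetation indices for one acquisition
#'
#' Pipeline order is fixed: smooth the reflectance spectra first (10 nm
#' moving average), subset the azimuth window, compute per-pixel indices,
#' then aggregate.
#'
#' @param pano A `reflectance_panorama`.
#' @param indices Index names (see [index_map()]).
#' @param mask Optional component mask on the panorama grid.
#' @param span,center Azimuth window (see [azimuth_subset()]); `NULL` span
#'   disables subsetting.
#' @param statistic Scene statistic.
#' @param smooth_window_nm Spectral smoothing window; `NULL` skips
#'   smoothing (for pre-smoothed cubes).
#' @return Tibble with one row per index: `index`, `value`, `n_pixels`.
#' @export
compute_indices <- function(pano, indices = c("ndvi", "cci", "pri", "tri_pri"),
                            mask = NULL, span = 80, center = 0,
                            statistic = "mean", smooth_window_nm = 10) {
  if (!is.null(smooth_window_nm))
    pano <- smooth_spectrum(pano, window_nm = smooth_window_nm)
  if (!is.null(span)) {
    pano <- azimuth_subset(pano, span, center)
    if (!is.null(mask)) mask <- azimuth_subset(mask, span, center)
  }
  dplyr::bind_rows(lapply(indices, function(ix) {
    st <- scene_statistic(index_map(pano, ix), mask = mask,
                          statistic = statistic)
    tibble::tibble(index = ix, value = st$value, n_pixels = st$n_pixels)
  }))
}

#' Join an index series to a daily flux series
#'
#' Matches the solar-noon acquisition of each calendar date to the daily
#' mean GPP.
#'
#' @param index_series Tibble with `date`, `index`, `value` (and optionally
#'   QC columns such as `stability`).
#' @param daily_flux Tibble with `date` and `gpp`.
#' @return Inner-joined tibble.
#' @export
join_daily <- function(index_series, daily_flux) {
  dplyr::inner_join(index_series, daily_flux, by = "date")
}

#' Ordinary least squares fit of GPP on a vegetation index
#'
#' Linear model with intercept, GPP as the dependent variable. Wraps
#' `stats::lm`; the returned object carries broom-style [tidy()] and
#' [glance()] methods.
#'
#' @param data Tibble of paired daily observations.
#' @param x,y Column names (strings) of the index and GPP variables;
#'   defaults `"value"` and `"gpp"`.
#' @return An `index_gpp_fit`: list with `slope`, `intercept`, `r_squared`,
#'   `p_value`, `n` and the underlying `lm` in `$model`.
#' @export
ols_fit <- function(data, x = "value", y = "gpp") {
  stopifnot(all(c(x, y) %in% names(data)))
  df <- data.frame(x = data[[x]], y = data[[y]])
  df <- df[stats::complete.cases(df), ]
  if (nrow(df) < 3) stop("need at least 3 paired observations", call. = FALSE)
  if (var(df$x) == 0) stop("index series has zero variance", call. = FALSE)
  fit <- lm(y ~ x, data = df)
  sm <- summary(fit)
  r2 <- sm$r.squared
  if (var(df$y) == 0) r2 <- 0   # no variance to explain
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = r2,
                 p_value = unname(pf(sm$fstatistic[1], sm$fstatistic[2],
                                     sm$fstatistic[3], lower.tail = FALSE)),
                 n = nrow(df), model = fit),
            class = "index_gpp_fit")
}

#' @export
print.index_gpp_fit <- function(x, ...) {
  cat(sprintf(
    "<index_gpp_fit> GPP = %.4g + %.4g * index  (R2 = %.3f, p = %.3g, n = %d)\n",
    x$intercept, x$slope, x$r_squared, x$p_value, x$n))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy coefficients of an index--GPP fit
#'
#' @param x An `index_gpp_fit`.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `std.error`, `statistic`,
#'   `p.value`.
#' @export
tidy.index_gpp_fit <- function(x, ...) {
  cf <- summary(x$model)$coefficients
  tibble::tibble(term = c("(Intercept)", "index"),
                 estimate = cf[, 1], std.error = cf[, 2],
                 statistic = cf[, 3], p.value = cf[, 4])
}

#' One-row model summary of an index--GPP fit
#'
#' @param x An `index_gpp_fit`.
#' @param ... Unused.
#' @return Tibble with `r.squared`, `slope`, `intercept`, `p.value`, `n`.
#' @export
glance.index_gpp_fit <- function(x, ...) {
  tibble::tibble(r.squared = x$r_squared, slope = x$slope,
                 intercept = x$intercept, p.value = x$p_value, n = x$n)
}
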