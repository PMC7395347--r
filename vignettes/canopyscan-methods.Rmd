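---
title: "Models and methods behind canopyscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind canopyscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(canopyscan)
```

`canopyscan` processes imagery from a mast-mounted proximal sensing rig
pointed at a forest canopy: a visible/near-infrared hyperspectral line
scanner (HLS) and a thermal camera on a pan-tilt unit, an irradiance
spectrometer, a PAR sensor, standard tower meteorology, and a terrestrial
laser scan (TLS) of the same field of view. This vignette explains the
models implemented, the defaults and their units, what the synthetic-scene
generator does and does not emulate, and the numerical choices made where
the design was genuinely open.

## Acquisition geometry and scheduling

Solar position uses the standard medium-accuracy ephemeris: geometric mean
longitude and anomaly, the equation of centre, apparent longitude with the
leading nutation/aberration correction, true obliquity, and the equation of
time, giving geometric (refraction-free) azimuth and elevation to better
than 0.1° over 1950–2050. Azimuth is stored signed — degrees from true
north, positive eastward, in (−180, 180] — so a southern-hemisphere solar
noon sits at 0°, and morning/afternoon positions are symmetric in sign.
Refraction is deliberately omitted: the scheduler and the documented sun
positions it reproduces are quoted at whole-degree precision, far above the
~0.01° refraction effect at the elevations involved.

The trigger scheduler returns solar noon (continuous maximiser of the
elevation curve) plus the at most two crossings of a reference elevation,
found by scanning a 1-minute grid for sign changes and refining each by
bisection (ties broken toward the earlier minute). A crossing closer than
`min_separation` (default 20 min) to an already-scheduled time is dropped,
which is why near winter solstice — when the reference is chosen as the
winter-solstice noon elevation — only solar noon survives.

Footprint helpers use the small-angle linear approximation
(IFOV in radians × slant range); at the IFOVs involved (≤ 0.04°) the error
is negligible against the range uncertainty. The projected field of view of
a panoramic acquisition is the annular sector (span/360)·π·(r₂² − r₁²).
Data volumes use decimal units (1 GB = 10⁹ B), matching how campaign
figures are usually quoted. When no rotation rate is given, the sweep rate
is derived from the square-pixel condition — azimuth IFOV × frame rate — so
successive scan lines abut exactly; sweep duration is then span/rate.

Two documented conventions were genuinely ambiguous and are exposed as
configuration rather than resolved silently. First, quoting a two-sweep
scan (centres −20° and −32.5°, 26.58° FOV) as "about 40°" of zenith range
with "~12°" of overlap is not exactly reproduced by interval arithmetic,
which gives a 39.08° union and 14.08° overlap; the package reports the
interval-arithmetic values. Second, azimuth limits appear in the field both
as −130…110° and as 213…110°; these disagree (213° ≡ −147°), so the default
is −130…110° and both limits are plain constructor arguments.

## Hyperspectral radiometry

The chain is: subtract the closed-shutter dark frame (the mean of ~100 dark
acquisitions) from every spatial/spectral pixel, clipping negatives at zero
and logging the clipped count; apply the linear radiance calibration
`L = gain × counts + offset` per pixel and band; convert to
hemispherical-conical reflectance factors `ρ(λ) = π L(λ) / E(λ)`.

The irradiance spectrometer has much finer sampling than the imager, so
E(λ) is band-matched before division: each imager band is the weighted mean
of E under a unit-area Gaussian spectral response centred on the band. The
imager's true response width is not published, so the default FWHM is twice
the band spacing, and the whole response is a parameter. Sky conditions
drift during the ~5 min sweep; the scan-start and scan-end spectra are
interpolated linearly across the azimuth columns (and a dense irradiance
series, where available, is interpolated in time instead). Per-column
interpolation is the default; a single averaged E is available but couples
sky drift into the azimuthal gradient of every index.

Reflectance above 1 is physically legitimate on sunlit facets under
hemispherical normalisation and is never clipped; values above 1.5 are
counted in a flag attribute as a symptom of illumination mismatch. Columns
where E ≤ 0 at a used band are masked and counted rather than raising —
a dead spectrometer reading should fail QC, not crash a batch run. Bands in
the 755–770 nm oxygen-A region can be flagged (`o2a_flag()`): sub-band
misregistration between the two optical paths distorts them.

Spectra are smoothed with a centred 10 nm moving average (15 bands at the
native 0.7 nm spacing) before indices are computed; edge bands use the
truncated window, which preserves constants and affine spectra exactly and
reduces white-noise variance by ≈ 1/window. The pipeline order is fixed —
smooth first, then index — and tested, because the two orders differ for
any nonlinear index.

## Thermal radiometry

Thermal frames arrive as sensor-reaching band radiance while the pan unit
rotates, with > 90 % frame-to-frame overlap. The panorama assembler takes
from each frame its central k columns, k = round(angular advance per frame
/ azimuth IFOV), mapping columns to azimuth by frame timestamp; the output
grid spacing is the azimuth IFOV. Too-slow rotation (k < 1) and too-fast
rotation (inter-frame gaps) both raise informative errors.

Surface temperature solves, per cell,

```
L_sensor = τ · [ε·B(T_obj) + (1 − ε)·B(T_sky)] + (1 − τ)·B(T_air)
```

for `T_obj`. `B(T)` is the Planck spectral radiance integrated over the
camera band (7.5–14 µm, flat response — the vendor curve is not published)
by composite Simpson quadrature on a log-wavelength grid, which resolves
the emission peak equally well for narrow and very wide bands; 513 nodes
reproduce adaptive quadrature to better than five significant digits, and
the wide-band limit recovers σT⁴/π to 0.1 %. Inversion is vectorised
bisection on [150, 400] K to 10⁻⁴ K, so forward/inverse round trips are
good to < 10⁻³ K.

Path transmittance τ uses the standard empirical two-exponential broadband
law in √distance and √(water-vapour density), with the widely used
broadband coefficients (X = 1.9, α₁ = 0.006569, α₂ = 0.01262,
β₁ = −0.002276, β₂ = −0.00667) as defaults and every parameter exposed, so
a site-fitted or line-by-line-derived set drops in. Water-vapour density is
relative humidity × saturation density, with saturation vapour pressure
from the Magnus form `e_s = 6.112·exp(17.62 t / (243.12 + t))` hPa (t in
°C) and the ideal gas law (R_v = 461.5 J kg⁻¹ K⁻¹). Per-cell path length
comes from the TLS range image resampled to the panorama grid; cells with
no TLS return (sky) stay masked through the inversion. Emissivity defaults
are 0.95 for foliage, bark and ground and 1 for the sky — a single-leaf
scale value appropriate when pixels resolve individual crown elements;
multi-leaf pixels trend toward 0.98–0.99 and per-class or per-cell maps can
be supplied.

Reflected downwelling matters: with ε = 0.95 and a sky 30–40 K colder than
the canopy, dropping the (1 − ε)·B(T_sky) term biases retrieved
temperatures warm by several tenths of a kelvin; the test suite
demonstrates the bias and its removal.

## Canopy structure from TLS

Returns are binned by azimuth/elevation into 1°×1° cells (half-open bins,
boundary values to the lower-index bin; +x is north, +y east, +z up).
First returns only drive the products: range per cell is the minimum
first-return range (nearest-object convention; mean available), and Pgap is
the count of first returns beyond a 5 m threshold over all first returns —
masked where a cell has none. Component masks classify each cell by the
minimum first-return height above ground (conservative ground detection):
ground ≤ 0.5 m, canopy above, sky where empty. In the simulator's
sensor-origin frame the ground reference is −sensor_height; for field
clouds a per-azimuth lowest-return reference can stand in, since no ground
model is prescribed. Products resample to the (finer) panorama grid by
nearest-cell assignment, masked cells propagating. All three products are
verified cell-for-cell against a brute-force per-point loop on clouds up to
10⁴ points.

## Quality control

Four independent data streams gate each acquisition. (i) The ratio of
broadband integrals of the start and end irradiance spectra, integrated
over 400–900 nm by default (the exact band range is not prescribed
anywhere, so it is a parameter); pass within 1 ± 0.1. (ii) The PAR
stability indicator, mean over population SD of the 1 Hz trace spanning the
sweep — population SD because the trace is the complete window, not a
sample, and at n ≈ 300 the distinction is negligible anyway; a constant
trace returns +∞, a defined pass. The threshold filter keeps indicator
> 30. (iii) The clearness index, observed over modelled clear-sky
shortwave, clamped to [0, 1] with cloud-enhancement cases flagged; diffuse
fraction is its complement. The clear-sky model is deliberately simple —
solar constant × Earth–Sun distance factor × sin(elevation) × a fixed 0.75
transmittance — and pluggable. (iv) A PAR-consistency check: the quantum
integral of the irradiance spectrum over an ideal 400–700 nm response
(the actual sensor response is not published) against measured PAR, whose
ratio doubles as a first-order correction for spectrometer temperature
sensitivity. Every decision is a pure function of inputs and thresholds;
PAR mean/SD/min/max are carried as reporting columns without normative
thresholds of their own.

## Indices and regression

NDVI (R800, R645), PRI (R531, R570) and triangular PRI
(0.5·[30·(R545 − R490) − 55·(R520 − R490)]) follow their usual band
definitions with nearest-band-centre lookup on the smoothed grid, the
chosen centres recorded alongside every result. CCI is implemented as
(R645 − R531)/(R645 + R531) — the band order is sign-flipped relative to
the index's original literature definition; rather than silently "fixing"
it the package computes exactly this form and offers `flip = TRUE` for the
conventional sign. Scene statistics default to the mean over the 80°
azimuth window centred on 0° (median available; the two agree closely on
well-filtered data), optionally restricted to canopy pixels through the
co-registered TLS mask. Daily series join the solar-noon acquisition to
daily-mean GPP by calendar date; `ols_fit()` fits GPP = a + b·index through
`stats::lm`, reporting slope, intercept, R², the F-test p-value and n, with
`tidy()`/`glance()`/`autoplot()` methods.

## The synthetic-scene generator

The generator is angular-native: a scene is a grid of (azimuth, elevation)
cells, each carrying a class (foliage, bark, ground, sky), a slant range, a
canopy cover fraction, a brightness factor, a temperature offset and an
emissivity — sufficient to exercise every equation in the chain without a
3-D ray tracer. Trees are angular crown discs with a central bark stripe,
placed in the canopy elevation band; a cell with no crown sees ground where
the slant path `sensor_height / sin(−elevation)` is within the 350 m range
limit, and sky otherwise. Defaults emulate the motivating installation: a
sensor 68 m up over a 40 m canopy, crowns at 40–300 m, ground offsets up to
~12 K warmer and bark a few kelvin warmer than foliage, emissivity 0.95.
End-member spectra are smooth parametric curves (sigmoid red edge plus
Gaussian pigment features), not measured libraries; the default band grid
is 50 bands at 10 nm over 405–895 nm, and the default grid 240 × 76 cells
of 0.5° — desk-scale sizes chosen so the full suite runs in seconds while
every code path is exercised. Full-size sensor dimensions are ordinary
constructor arguments when realism matters more than speed.

Each forward model inverts the corresponding processing equation exactly
when noise is off, so recovery is a genuine end-to-end check rather than a
tautology about one function: VNIR counts are built from ρ·E/π through the
calibration and dark models and recovered to < 10⁻⁶ relative error; thermal
radiance is built from the full transfer equation and recovered to < 0.01 K
across 0.2–0.9 relative humidity; TLS pulses intercept crowns with
per-cell cover probability, continue to the ground otherwise, and
occasionally produce ground second returns, so per-cell Pgap converges on
the cover complement when the threshold separates crowns from background.

The PAR/meteorology/GPP generator assigns day types deterministically
(every third day clear by default) so the designed clear fraction — one
third, echoing how many scans typically survive stability filtering in the
field — is exact, not approximate: clear days carry smooth traces whose
indicator is ≈ 100, broken-cloud days intermittent traces with indicator
≈ 2, overcast days constant traces (indicator +∞). The truth index follows
a seasonal sinusoid and daily GPP is `a + b·index + ε` with ε conditioned —
orthogonalised against the index and rescaled — so the sample R² on the
available days equals the design value (0.52 by default, with slope
60 µmol m⁻² s⁻¹ per index unit and 326 available days as the reference
scenario) exactly rather than up to sampling noise. This conditioning is a
deliberate generator property: recovery checks then isolate defects in the
pipeline instead of re-testing the sampling distribution of R². Extra index
noise can be injected on non-clear days only, which makes R² non-decreasing
in the stability threshold — the qualitative signature one expects from
filtering real unstable-sky data.

What the simulator does *not* emulate — and what passing tests therefore do
not establish about field data: directional reflectance (BRDF) and the
sunlit/shaded mosaic, multiple scattering and diffuse-light normalisation
errors, emissivity heterogeneity within a class, wind-driven scene motion
during a sweep, sensor nonlinearity and temperature drift, TLS beam
divergence and partial hits. Field headline numbers (e.g. a particular
index–GPP R² over a specific year) depend on site data the package does not
ship and are design points of the generator here, not reproduced results.

## Numerical choices and limitations

* Planck band integrals: 513-node log-wavelength Simpson; inversion by
  bisection on [150, 400] K to 10⁻⁴ K; radiance outside the invertible
  range errors rather than extrapolating.
* Trigger crossings: 1-minute scan + bisection refinement, ties toward the
  earlier time; solar noon by golden-section maximisation of the continuous
  elevation.
* Binning: half-open angular bins with boundary values to the lower-index
  bin; nearest-cell resampling between angular grids.
* End-member statistics use the population SD (the pixel set is the whole
  region of interest, not a sample of it).
* Raw streams are little-endian on disk regardless of host; readers verify
  byte counts and refuse partial frames; panorama cubes round-trip at
  float32 precision through a plain-text-header raster format readable by
  standard remote-sensing software.
* The empirical transmittance law is a broadband surrogate: it is monotone
  and well-behaved over 0–350 m and 0–30 g m⁻³ but is not a line-by-line
  radiative transfer result, and the low-ambient-temperature camera bias
  reported for similar instruments below ~5 °C is out of scope.
* Height-above-ground classification assumes a usable ground reference;
  steep terrain would need a digital terrain model the package does not
  build.
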