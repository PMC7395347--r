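# canopyscan

Processing chain for tower-mounted proximal sensing of forest canopies.
`canopyscan` is aimed at ecosystem scientists running (or emulating) a
combined hyperspectral line scanner + thermal camera on a pan-tilt unit
above a flux-tower canopy: it turns raw sensor streams into calibrated
reflectance and surface-temperature panoramas, derives TLS structural
masks, applies sky-stability quality control, and relates vegetation-index
time series to daily carbon fluxes.

## What it computes

**Acquisition geometry.** A medium-accuracy solar ephemeris (declination,
equation of time, hour angle; geometric, refraction-free, better than 0.1°)
drives the trigger scheduler: acquisitions at solar noon plus the two daily
crossings of a reference solar elevation (conventionally the winter-solstice
noon elevation, so the schedule works year-round). Helpers give projected
field-of-view area of the annular scan footprint, per-pixel ground
footprints, elevation coverage of multi-sweep scans, sweep duration under
the square-pixel rotation condition, and campaign data volumes.

**Hyperspectral radiometry.** Raw line-scan counts are dark-corrected
(closed-shutter dark frame, clipped at zero), converted to spectral
radiance through a linear calibration, and normalised by down-welling
irradiance to hemispherical-conical reflectance factors

ρ(λ) = π L(λ) / E(λ),

with the irradiance band-matched to the imager (Gaussian spectral response,
unit area) and linearly interpolated across the sweep between the scan-start
and scan-end spectra. Spectra are smoothed with a 10 nm moving average
before any index is computed.

**Thermal radiometry.** Overlapping thermal frames are assembled into a
panorama (each frame contributes its central k columns, k set by the
rotation and frame rates). Sensor-reaching band radiance is inverted to
surface temperature through the single-band radiative transfer equation

L = τ [ε B(T_obj) + (1 − ε) B(T_sky)] + (1 − τ) B(T_air),

where B is the Planck radiance integrated over the 7.5–14 µm band, ε the
surface emissivity (default 0.95 for foliage, bark and ground; sky 1), and
τ the water-vapour path transmittance from a two-exponential broadband
model driven by the per-pixel TLS range and the Magnus saturation formula.

**Canopy structure.** TLS point clouds acquired from the sensor position
are binned to a 1°×1° angular grid: range to first return, gap fraction
(Pgap = share of first returns beyond a 5 m threshold), and canopy/ground
masks from a 0.5 m height-above-ground rule, all resampled onto the imaging
panorama grid.

**Quality control and time series.** Acquisitions are filtered on the
start/end irradiance ratio (pass inside 1 ± 0.1), the 1 Hz PAR stability
indicator (mean / SD, keep > 30) and the clearness index (observed over
clear-sky shortwave; diffuse fraction = 1 − clearness). Scene-level NDVI,
CCI, PRI and triangular PRI from an 80° azimuth window centred on 0° are
joined to daily GPP and fitted by ordinary least squares, with broom-style
`tidy()`/`glance()` accessors and `autoplot()` graphics.

**Synthetic scenes.** A seed-deterministic simulator generates angular
canopy scenes with known per-cell class, spectrum, temperature, emissivity
and range, then forward-models every input (raw counts, irradiance spectra,
thermal frame stacks, TLS clouds, PAR/meteorology/GPP series) so that each
stage of the chain can be verified against ground truth.

## Worked example

```r
library(canopyscan)

site <- demo_site()                       # tall eucalypt forest tower site
reference_trigger_times(site, "2018-01-01", trigger_config(31))
#>   time_local          event              elevation
#> 1 2018-01-01 07:40:57 morning_crossing        31.0
#> 2 2018-01-01 12:10:44 solar_noon              77.4
#> 3 2018-01-01 16:40:29 afternoon_crossing      31.0

projected_fov_area(30, 320, 240) / 1e4    # projected footprint, hectares
#> [1] 21.25811

scene <- make_scene(scene_spec(), seed = 42)
acq   <- simulate_vnir(scene, drift = 0.95)   # 5 % illumination drift
rho   <- process_vnir_acquisition(acq)        # dark -> cal -> pi L / E
compute_indices(rho, span = 80)
#>   index     value n_pixels
#> 1 ndvi     0.293     11339
#> 2 cci      0.1000    11339
#> 3 pri     -0.0410    11339
#> 4 tri_pri  0.0746    12160

atm  <- atmosphere_state(air_temperature = 298, relative_humidity = 0.55,
                         sky_temperature = 268)
tacq <- simulate_thermal(scene, atm)
tpan <- surface_temperature(
  assemble_thermal_panorama(tacq$stack, tacq$scan, tacq$sensor),
  tacq$range, atm, emissivity = scene$emissivity)
max(abs(unclass(tpan) - tacq$t_true), na.rm = TRUE)   # recovery error, K
#> [1] 2.97986e-05

met   <- simulate_par_and_meteo(n_available = 326, seed = 42)
daily <- stability_filter(met$daily, threshold = 30)
fit   <- ols_fit(daily[daily$available, ], x = "index_truth", y = "gpp")
fit
#> <index_gpp_fit> GPP = 1 + 60 * index  (R2 = 0.520, p = 1.41e-53, n = 326)
```

The trigger times bracket the day symmetrically around solar noon at the
31° reference elevation; the 240° two-sweep footprint covers ≈ 21.3 ha; the
full radiometric chain recovers the simulated surface temperatures to a few
times 10⁻⁵ K when noise is off; and the 326-day regression returns the
generator's designed coupling (slope 60 µmol m⁻² s⁻¹ per index unit,
R² 0.52).

A thin command-line wrapper over the same functions is installed at
`inst/scripts/canopyscan` with subcommands `plan`, `simulate`, `structure`,
`qc` and `indices` (run it without arguments for usage).

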