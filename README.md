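# avianradar

Verification of the detection performance of automated avian radar tracking
systems, using a radar-cross-section (RCS) calibrated UAV as a controllable
test target.

Automated track-while-scan bird radars (marine S-band hardware plus
proprietary detection/tracking software) are widely used to monitor bird
movements at wind-power plants and airports. Their actual detection envelope
is site- and system-specific and cannot be read off a datasheet: it depends
on range, ground clutter, the target's flight orientation and tortuosity,
and the black-box tracking algorithms. `avianradar` implements a complete
verification workflow for such a system: fly a UAV of known RCS on
controlled patterns, compare what the radar reports against the GPS truth,
model per-scan detection probability, and translate the calibrated detection
range into expected ranges for birds of any size.

## The method

**Synchronization.** UAV GPS clocks and radar clocks are not synchronized.
For each flight test the clock offset `T` (0–120 s) is estimated by
maximizing the Gaussian log-likelihood of the alignment model

    D² = β₀ + β₁·ΔR² + β₂·ΔB²

where `D` is the distance between a radar plot and the GPS position at the
shifted time, `ΔR` the range difference and `ΔB = sin(α/2)(R_radar + R_gps)`
the bearing-difference distance. Radar plots are then paired to GPS truth by
timestamp and *nondetections* are derived by laying out the expected scan
opportunities at the radar scan cadence (22.5 scans/min ≈ one per 2.7 s).

**Screening and clutter.** Ground clutter is the radar's viewshed: terrain
cells in line-of-sight of the antenna, computed from an elevation raster.
Low-altitude samples (terrain masking) and sharp turns (tracker limitation,
tortuosity `S = 1 − (cos ΔH + 1)/2` above a threshold) are screened out
using segmented regression on binned detection rates.

**Detection model.** Detection/nondetection is modelled as a binomial GLMM,

    logit(Pd) = β₀ + β_range·R + β_clutter·clutter + β_orient·across + β_tort·S + u_track

with a Gaussian random intercept per track, fitted by adaptive Gauss–Hermite
quadrature. The *detection range* is the range where the population-level
curve crosses Pd = 0.5 (a track-while-scan tracker can survive losing every
other detection), with delta-method confidence intervals. The classical
blip/scan ratio in 25-m range bins provides a model-free cross-check.

**Extrapolation.** Under the radar equation (SNR ∝ RCS/R⁴, Swerling-1
fluctuating targets), a detection range `R_d` calibrated with a reference
target of RCS `RCS_d` converts to a target of RCS `RCS_i` as

    R_i = (10^(RCS_i/10) / 10^(RCS_d/10))^(1/4) · R_d

Bird RCS values are obtained from body mass via the equivalent water-sphere
approximation, `RCS = 0.56·π·r²` with `r` the radius of a sphere holding
65% of the body mass as water.

## Worked example

Every stage can be exercised without field data through the built-in
synthetic campaign generator, whose defaults mirror a realistic calibration
study (7 range flights to 3,100 m at 70 m AGL, 6 clutter flights, true
Pd = 0.5 at 2,340 m, per-track random detectability, unknown clock offsets):

```r
library(avianradar)

cfg <- scenario_config(seed = 1)
scn <- generate_scenario(cfg)
types <- setNames(scn$truth$types, sort(unique(scn$gps$track_id)))
res <- run_pipeline(scn$gps, scn$radar, cfg$origin, cfg$params,
                    mask = scn$mask, track_types = types,
                    alt_min = 27, tort_max = 0.33)
res
#> Radar detection verification
#>   13 tracks; offsets 1.5-104.4 s
#>   screening: excluded 8.8% (alt < 27 m, tortuosity > 0.33)
#>   clutter: Pd 0.79 -> 0.58 inside clutter (27% reduction, 13-39% CI)
#>   detection range at Pd=0.50: 2305 m (2079-2532 m CI); blip/scan crossing 2062 m
#>   extrapolated ranges (m):
#>     passerines             688 (563-847)
#>     ...
#>     white-tailed eagle    1514 (1238-1863)
```

The estimated detection range (2,305 m) recovers the generator's true
2,340 m within sampling error; the per-flight clock offsets are recovered to
about a tenth of a second; the clutter contrast (detection probability 0.79
outside vs 0.58 inside line-of-sight clutter at the mean clutter-test range)
reflects the configured clutter penalty. The species table converts the
calibrated range to expected detection ranges with bounds from the quartiles
of the reference-target RCS calibration.

Individual stages are plain functions returning classed objects with the
usual methods (`print`, `summary`, `coef`, `vcov`, `predict`, `plot`,
`residuals`, `simulate`):

```r
obs <- res$observations
fit <- fit_detection(obs[!obs$in_clutter, ],
                     covariates = c("range", "orientation", "tortuosity"))
summary(fit)
detection_range(fit, pd = 0.5)
plot(fit)             # blip/scan bars + fitted curve
extrapolation_bounds(rcs_water_sphere(5000))   # a 5-kg raptor
```

Real data enter through `read_gps()` / `read_gpx()` (GPS fixes),
`read_radar()` (plot exports, planar or polar), and `read_asc()` /
`as_clutter_mask()` (terrain or a pre-computed GIS clutter mask);
`inst/scripts/convert_data_s2.py` converts a campaign Excel workbook to
these CSV schemas.

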