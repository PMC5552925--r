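---
title: "Verifying avian radar detection performance with a calibrated UAV"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Verifying avian radar detection performance with a calibrated UAV}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(avianradar)
```

## The problem

Automated avian radar tracking systems bolt detection and tracking software
onto off-the-shelf marine S-band radar. They are deployed to monitor bird
movement around wind-power plants, but their effective detection envelope is
not a property of the hardware alone: it is shaped by range (received energy
falls as $R^{-4}$), by ground clutter that the processing must suppress, by
the target's orientation relative to the fan beam, and by flight tortuosity
that strains the track-while-scan association logic. Because the processing
chain is proprietary, the only way to characterize the deployed system is
empirical: fly a cooperative target of known radar cross section (RCS) on
controlled patterns through the surveillance volume and compare what the
radar reports with the target's GPS truth.

This package implements that verification workflow end to end, plus a
synthetic-data generator that reproduces the statistical structure of such a
campaign with known ground truth, so that every stage is testable without
field data.

## Clock synchronization

The UAV's GPS and the radar record on unsynchronized clocks; the offset must
be estimated before detections can be paired with truth positions. For each
flight test we search the offset $T \in [0, 120]$ s maximizing the Gaussian
log-likelihood of the linear alignment model

$$D^2 = \beta_0 + \beta_1 \, \Delta R^2 + \beta_2 \, \Delta B^2,$$

where, for each radar plot paired with the GPS position interpolated at the
shifted time, $D$ is their planar distance, $\Delta R$ the difference in
range from the radar, and $\Delta B = \sin(\alpha/2)(R_{radar} + R_{gps})$
the distance equivalent of the bearing difference $\alpha$. Geometrically
$D^2 \approx \Delta R^2 + \Delta B^2$ when streams are aligned, with small
residuals; misalignment displaces each pair along-track and inflates the
residual variance, so the likelihood peaks sharply at the true offset. Since
the model's error law is unstated in this formulation, we take it as
Gaussian on $D^2$, in which case maximizing the likelihood over $T$ is
exactly minimizing the residual variance — the two views coincide.

Numerically, the search is a 1-s grid over the window followed by
golden-section refinement of the best bracket to $10^{-3}$ s, ties broken
toward the smaller offset. Offsets are estimated per flight test (the
default; a shared-offset mode would be a trivial extension but clocks drift
between tests). Two further choices are worth recording: truth positions are
always *interpolated* GPS fixes rather than nearest fixes (the UAV moves
about 20 m per GPS interval, so nearest-fix pairing would add metres of
spurious noise), and radar plot times are never interpolated — plots are
instantaneous scan events.

On synthetic campaigns with 5 m radar position noise the estimator recovers
injected offsets to well under half a second (the package's acceptance
tests require ±0.5 s in 95% of flights; observed errors are typically
±0.1 s).

## Scan opportunities and nondetections

The radar offers a detection opportunity once per antenna revolution
(22.5 scans/min, one per $60/22.5 \approx 2.67$ s). After synchronization,
opportunities are laid out on that grid from the first to the last detection
of a flight; an opportunity with a paired plot within half a scan interval
is a detection, and every other opportunity is a *nondetection* whose truth
position is the GPS interpolant at the opportunity time. We use GPS truth
rather than interpolating between neighbouring radar plots because the GPS
position exists for every opportunity, detected or not; a radar-interpolant
mode is available for sensitivity analysis (`truth = "radar"`).

Each opportunity carries the covariates used downstream: horizontal range
and bearing from the radar (geometry is deliberately 2-D — at 70 m altitude
and kilometre-scale ranges, slant-range corrections are sub-percent),
course, turning angle, tortuosity, beam-orientation class, and clutter
membership.

## Tortuosity and orientation

Tortuosity is the normalized cosine of the turning angle,
$S = 1 - (\cos\Delta H + 1)/2$: 0 for straight flight, 1 for a reversal,
0.33 at a 70° turn. Turning angles are computed from successive courses and
wrapped to $(-180°, 180°]$.

The orientation covariate classifies motion *along* versus *across* the
radar beam by the angle $\alpha$ between the course and the radial
direction: "along" when $|\cos\alpha| > \cos 45°$. Two conventions needed
fixing. First, the boundary case $|\cos\alpha| = \cos 45°$ is classified
"across" (the published inequality is strict). Second, $\alpha$ could be
read against the radial direction or the beam tangent; we default to the
radial reading (motion toward/away from the radar is "along") and expose
`reference = "tangent"` for the other.

## Ground clutter as a viewshed

Clutter areas are terrain in line-of-sight of the radar, computed from an
elevation raster: a cell is clutter when the sightline from the antenna
(ground elevation plus antenna height) to the cell centre clears the
bilinearly interpolated terrain profile, sampled at half-cell steps. Earth
curvature is ignored by default — at ≤4 km the curvature drop is under a
metre, far below typical DEM accuracy — with a 4/3-effective-Earth option.
Clutter membership of an observation is evaluated at the ground-projected
position under a half-open cell convention, matching how a 2-D GIS clutter
mask is used in practice; pre-computed masks from external GIS can be
supplied directly (`as_clutter_mask(read_asc(...))`), since viewshed
parameters (observer height, DEM resolution) are often inherited from an
existing site model.

## Screening

Take-off/landing samples (terrain-masked) and extreme turns are excluded
before modelling. Thresholds are found by segmented regression: detection
rates are computed in 50 equal-count bins of the covariate, and for every
interior bin edge a two-segment piecewise-constant model is scored by the
total sum of squared residuals; the minimizing edge is the threshold. We
chose binned rates with a piecewise-constant model as the simplest
formulation consistent with "optimal partitioning"; a raw-outcome binomial
deviance criterion is available (`criterion = "deviance"`) and agrees on
clean data. The companion diagnostic — the cumulative standard deviation of
detection rates along the covariate — is emitted in the fit's `diagnostics`
table for visual inspection but never drives selection, which keeps the
procedure reproducible.

Exclusions are then applied as altitude-minimum and tortuosity-maximum
rules; observations with undefined tortuosity (track ends) are retained.

## The detection model

Detection versus nondetection is a binomial GLMM on the logit scale:

$$\mathrm{logit}(P_d) = \beta_0 + \beta_R R + \beta_C \cdot \mathrm{clutter}
  + \beta_O \cdot \mathrm{across} + \beta_S S + u_{track}, \qquad
  u_{track} \sim N(0, \sigma^2_{track}).$$

Range enters linearly on the logit scale. The radar equation suggests an
$R^4$ term instead, but after the proprietary clutter-suppression and
tracking chain the effective range dependence is unknown, and the linear
form is the established convention for processed avian-radar data; an
$R^4$-scale mode (`range_power = 4`) is provided for sensitivity analysis.
The per-track random intercept absorbs inter-track differences in
detectability (battery state, mounting, aspect distribution). Tortuosity
enters per observation, not as a track summary — it varies within flights
and the tracker reacts to it locally.

Fitting uses adaptive Gauss–Hermite quadrature with 15 nodes (the package
verifies the reported likelihood against brute-force numerical integration
on small instances to $10^{-4}$), with Wald covariances from the observed
information. Internally range is rescaled to kilometres for optimizer
conditioning and the coefficient exactly back-transformed to per-metre.
Degenerate inputs are signalled honestly: single-track data fall back to a
plain GLM with the random effect pinned at zero, constant covariates are
dropped with a warning, and suspected complete separation clears the
convergence flag.

### Derived quantities

The **detection range** at threshold probability $p$ solves
$\beta_0 + \beta_R R = \mathrm{logit}(p)$ at reference covariate levels —
orientation "along", tortuosity 0, outside clutter. These reference levels
are a convention (the implicit baseline of the model); they are configurable
via `at =`. The default threshold 0.5 reflects the tracker's tolerance: a
track-while-scan system can maintain a track when every other detection is
lost, so the $P_d = 0.5$ range is the outer limit of reliable tracking.
Confidence intervals use the delta method with the exact gradient
$\partial R/\partial\beta_k = -x_k/\beta_R$,
$\partial R/\partial\beta_R = -R/\beta_R$; a seeded parametric bootstrap
(1,000 multivariate-normal draws of the fixed effects) is available and
agrees to first order.

The **clutter contrast** reports $P_d$ inside versus outside clutter at the
mean observed range of the clutter-test data (configurable), with intervals
computed on the logit scale for the probabilities and on the log-ratio for
the proportional reduction $1 - P_d^{in}/P_d^{out}$.

The **blip/scan ratio** — detections over opportunities in 25-m range bins —
is the classical model-free summary. Reading a detection range off that
curve is traditionally done by eye; the automated stand-in takes a centred
5-bin moving average and reports the midpoint of the first bin where it
drops below the threshold and stays below for 3 consecutive bins (returning
a beyond-data sentinel when it never does). On large samples this agrees
with the model-based range to within two bin widths.

### Extrapolation to other target sizes

With SNR $\propto$ RCS$\cdot R^{-4}$, a range $R_d$ calibrated with a
reference target of RCS$_d$ maps to a target of RCS$_i$ as
$R_i = (10^{\mathrm{RCS}_i/10} / 10^{\mathrm{RCS}_d/10})^{1/4} R_d$. Bird
RCS is estimated from body mass by the equivalent water-sphere model
(optical-region sphere factor 0.56, water fraction 0.65, density 1 g/cm³) —
a deliberate simplification that ignores body shape, aspect lobes and
frequency dependence, and is known to underestimate the detectability of
the smallest species. Uncertainty bounds propagate the quartiles of the
reference-target RCS calibration: the *lower* range uses the 75th-percentile
reference RCS (a stronger reference implies the system is less sensitive
than the median calibration suggests) and the *upper* the 25th. We propagate
the calibration quartiles only, not the detection-range CI in addition;
combining both is possible but double-counts in the common case where the
reported bounds are meant to reflect calibration spread.

A related theoretical layer (`swerling1_pd`, `snr_at_range`) expresses the
Swerling-1 relation $P_d = P_{fa}^{1/(1+\mathrm{SNR})}$ for a scan-to-scan
fluctuating target. Above $P_d \approx 0.3$ such a target suffers a
fluctuation loss (about 2 dB at $P_d = 0.5$) relative to a steady target of
the same mean RCS — recorded here as a documented constant, not derived. The
package uses the Swerling layer for theory checks and sensitivity analysis,
not in the empirical fit.

## The synthetic campaign generator

The generator's model is exactly the analysis model, run generatively, so
parameter recovery is well-posed: waypoint flights sampled at 1 Hz,
constant 20 m/s speed, 70 m cruise altitude (turbine hub height) with 5 m/s
climb/descent ramps; scan opportunities every 2.67 s; detection drawn from
the logistic truth; detected plots perturbed with 5 m isotropic Gaussian
noise and shifted by a per-flight clock offset drawn uniformly from
0–120 s.

Default truth parameters: $\beta_0 = 3.136$, $\beta_R = -0.00134$ per metre
(so the true $P_d = 0.5$ range is 2,340 m), clutter effect $-0.615$ (a drop
from 0.51 to 0.36 at the range where the baseline is 0.51), across-beam
effect $-0.3$ and tortuosity effect $-1$ (modest control-variable effects of
plausible sign and size), and $\sigma_{track} = 0.3$ (detection rates
varying by roughly ±7 percentage points across tracks at mid-range — what
one would expect from aspect and mounting differences between flights). The
campaign comprises 7 radial range flights to 3,100 m and 6 clutter flights
that repeatedly cross clutter patches; clutter-flight bearings are chosen
deterministically from the mask so each span straddles a clutter boundary,
mirroring how real clutter tests are routed over known problem areas.

Two fidelity details matter. Flights carry a deterministic cross-track
meander (80 m amplitude, 500 m wavelength, tapered at the ends): a piloted
UAV does not fly mathematical lines, and without the meander tortuosity and
orientation would be exactly constant and unidentifiable. The built-in
terrain is a smooth two-scale sinusoidal surface producing a patchy
viewshed from a 5 m antenna. Model-violation toggles (t-distributed
position noise, $R^4$ detection decay, a low-altitude detection penalty for
exercising the altitude screen) support robustness checks.

What passing recovery tests shows — and what it does not: the pipeline
correctly inverts its own generative assumptions (offsets to ±0.5 s,
detection range to <10% median absolute error, clutter reduction covered by
its CI at the nominal rate over 20 replicate campaigns). It cannot certify
behaviour under real-world features the generator omits: aspect-dependent
RCS lobes, weather and dynamic clutter, radar-plot association errors by
the tracker, or GPS altitude error.

## Numerical choices and degenerate inputs

* Offset search: 1-s grid + golden section to $10^{-3}$ s; ties toward
  smaller offsets; a residual-variance floor of $10^{-12}$ keeps the
  Gaussian log-likelihood finite for perfectly coincident streams; a flat
  objective (e.g. a hovering target) raises an error rather than returning
  an arbitrary offset.
* Rank-deficient alignment designs (constant $\Delta R^2$, $\Delta B^2$)
  fall back to an intercept-only fit and are flagged.
* Segmented regression reports the breakpoint at a bin edge; SSR ties are
  resolved toward retaining more data.
* GLMM convergence tolerance is lme4's default with 15 quadrature nodes;
  the convergence flag is stored, never silently cleared.
* Viewshed profiles treat nodata cells as blocking (with a warning), and
  cells are half-open so every point belongs to exactly one cell.
* All randomness flows from a single mandatory seed; `generate_scenario()`
  restores the caller's RNG state.

Problem sizes used in the shipped checks: recovery runs 20 replicate
campaigns of 13 flights (~1,200 scan opportunities each, ~100-cell terrain
profiles); null-coverage runs 100 replicates of 8 × 150 observations;
likelihood oracles use 3 × 20-observation instances where a 20,001-point
trapezoid grid is feasible.

## Known limitations

* The water-sphere RCS model is crude for small passerines; the
  extrapolated ranges for the smallest groups are likely conservative.
* The alignment likelihood assumes a constant clock offset per flight;
  clock drift within a flight is not modelled.
* The clutter mask is binary and static; precipitation and rotating
  turbines (dynamic clutter) are out of scope, as is modelling the radar's
  internal clutter-suppression.
* Detection ranges are horizontal; the vertical beam pattern (and hence the
  altitude dependence of detectability beyond line-of-sight masking) is not
  modelled.
* Wald/delta intervals are first-order; for very small campaigns the
  bootstrap option is preferable.
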