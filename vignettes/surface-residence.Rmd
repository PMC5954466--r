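---
title: "Surface residence time of a coastal hotspot: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surface residence time of a coastal hotspot: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(palmerdrift)
```

## The problem

Coastal biological hotspots — here, the Palmer Deep canyon off the West
Antarctic Peninsula — concentrate phytoplankton, Antarctic krill and their
predators. How long water (and the plankton it carries) lingers at the
surface over such a feature is a first-order control on local food-web
dynamics: short residence means the canyon acts as a conveyor delivering
prey, long residence means it acts as an incubator. Shore-based
high-frequency radar (HFR) networks measure hourly maps of the surface
current on a ~1 km grid over ~1500 km² of ocean, which is exactly the
substrate needed to answer the question with passive-particle kinematics.

`palmerdrift` implements that analysis chain as reusable, tested R code:

1. a schematic analysis **domain** (footprint, 1-km release grid, three
   sub-region polygons: central canyon CAN, Joubin Islands Flank JIF,
   Wauwermans Islands Flank WIF);
2. a seeded **synthetic generator** of radar-like current fields and
   two-station winds, so every stage is testable without any proprietary
   data;
3. least-squares **tidal harmonic analysis** and de-tiding;
4. fourth-order Runge–Kutta **particle advection** with hourly exit
   detection;
5. **e-folding residence time**, sub-region **connectivity** and the krill
   **grazing-impact** arithmetic;
6. the **wind response**: merged station winds, residence-window averaging,
   model-II (major-axis) regression, binned distributions and Tukey
   comparisons.

The real Palmer Deep radar and wind records are not publicly deposited, so
the package makes no attempt to reproduce the published real-data tables;
instead the synthetic generator imposes known structure and the test suite
verifies that every stage recovers it. The published self-contained numbers
(release-grid sizes, particle totals, e-folding counts, grazing rates) are
reproduced exactly.

## Domain geometry

Coordinates are local tangent-plane kilometres (equirectangular about a
geographic anchor); longitude/latitude appear only at I/O boundaries
(GeoJSON polygon interchange). The demo footprint is a 50 × 30 grid of 1-km
cells (1500 km²). The three sub-region polygons are schematic rectangles
(WIF carries a one-cell tab) sized so their 1-km release grids hold exactly
187 (CAN), 84 (JIF) and 61 (WIF) points — 332 in total. The true polygon
shapes follow unpublished bathymetry, so only these counts are treated as
constraints; `domain_config()` accepts arbitrary polygons and an optional
release mask for users with real geometry.

Point membership uses even-odd ray casting with boundary points counted
inside; a point on an edge shared by two regions goes to the first region
in configuration order (CAN → JIF → WIF), and polygons whose interiors
overlap are rejected outright. `build_domain()` also enforces that the
footprint area stays within 20% of its configured target.

```{r domain}
dom <- build_domain(demo_domain_config())
dom
```

## Synthetic currents and winds

`synth_currents()` composes hourly `u`, `v` maps (cm s⁻¹) from four parts:

* a **steady mean current** (default 20 cm s⁻¹ eastward — the persistent
  coastal current that sweeps the hotspot);
* **tidal harmonics** at the astronomical frequencies of O1, K1, M2 and S2
  (no nodal corrections). By default the amplitude vector is rescaled so
  the tide carries exactly 12.3% of the raw velocity variance — the share
  the de-tiding stage is expected to find;
* a **wind-coupled component**: a configurable fraction (default 3%) of the
  merged two-station wind speed, directed downwind with an optional
  rotation. The same seeded wind realisation is returned by
  `synth_winds()`, so the wind an analyst "measures" is the wind that
  forced the currents;
* a **mesoscale eddy field** built as the curl of a random-Fourier-mode
  streamfunction with AR(1) temporal evolution — non-divergent by
  construction, with configurable rms speed, wavelength and decorrelation
  time.

Coverage gaps are drawn i.i.d. per cell-hour (default 3%, i.e. 97% mean
coverage). Real HFR gaps are spatially coherent (they follow radial
geometry and interference); the i.i.d. model is a documented
simplification, so passing tests show robustness to scattered dropouts,
not to losing a whole radar sector.

Station winds are red noise: speed is a shared AR(1) about the configured
mean plus independent station noise, and direction is a mean-reverting
AR(1) about the prevailing direction ("from", degrees clockwise from true
north). A pure random walk in direction was rejected because over multi
month records it wanders arbitrarily far, leaving the regime
non-stationary; the mean-reverting form keeps a prevailing wind while
preserving synoptic variability. All randomness flows from one integer
seed; two calls with the same config are bitwise identical.

## Tidal harmonic analysis

`harmonic_fit()` solves ordinary least squares on the basis
$[1, \cos\omega_k t, \sin\omega_k t]$, dropping gap samples from the normal
equations (no interpolation). The mean term is always estimated and never
counted as tidal variance. The de-tided series is the raw series minus the
fitted tidal component, so the decomposition `raw = tide + residual` is
exact at every observed sample and the mean flow survives de-tiding.

Constituent screening works on the $(\cos, \sin)$ coefficient *pair*: a
joint F statistic from the coefficient covariance, tested at a
Šidák-adjusted level across the fitted constituent list. The reported
amplitude interval is the amplitude ± the joint confidence-ellipse radius
(floored at zero), and "significant" is exactly "this interval excludes
zero". Two properties motivated this choice over a naive delta-method
amplitude CI: (i) an amplitude estimate from pure noise is
Rayleigh-distributed, so the delta-method interval excludes zero far more
than 5% of the time; (ii) screening is a family decision — under pure
white noise the *whole* default list should pass clean with the stated
confidence, which the Šidák adjustment delivers (verified by Monte Carlo in
the test suite). Against coloured (red-noise) background the screen is
still anti-conservative — the principled fix is a spectral noise model as
in mature tidal toolboxes, which is out of scope and documented as a
limitation.

Unresolvable constituent pairs are refused by the Rayleigh criterion (two
frequencies closer than one cycle over the record span), naming the
offending pair. Cells with too few valid samples pass through unfitted and
flagged. `detide_field()` pools variance over all valid cell-hours of both
components: fitted tidal sum of squares over raw sum of squares about
per-cell means.

## Particle advection

Velocities are sampled bilinearly among the four surrounding grid nodes
with weights renormalised over the nodes holding valid data, and linearly
in time between bracketing hourly maps; if one bracketing hour has no valid
support the other is used alone, and if neither does the sample is a
data-gap signal. Beyond the outermost nodes the sampler clamps to the node
hull (edge-value extrapolation): a particle crossing the footprint edge
keeps a finite velocity until the next hourly check catches it — without
this, edge-bound particles would stall half a cell short of ever being
seen outside. At most one hour of motion ever uses extrapolated velocity.

Integration is classical RK4 with an internal step of 0.1 h by default
(velocity converted once from cm s⁻¹ to km h⁻¹; 1 cm s⁻¹ = 0.036 km h⁻¹).
Exit is decided **only at hourly log points**, matching the hourly tracking
cadence of the source analysis: a sub-hour excursion outside and back is
not an exit. A particle whose RK4 stages hit a data gap holds its position
for that hour; after more than 3 consecutive gap-hours it terminates as
`entered_persistent_gap` and is counted as having left (under 3% i.i.d.
gaps this is rare). The integrator's fourth-order convergence and exact
behaviour on uniform and solid-body-rotation fields are asserted in the
test suite (radius drift below 1 m over a 12-h orbit at dt = 0.1 h; error
ratio ≈ 16 per dt halving).

## Residence time, connectivity, grazing

Releases repeat every 6 h, both endpoints inclusive (1 Jan–1 Mar gives
237 releases; with 332 points that is 78 684 tracked particles for the
whole footprint). For each release and region the residence time is the
earliest hourly offset at which cumulative footprint exits reach
`exits_required(n)`, with the e-folding default
`n − round(n/e)` (rounding half away from zero — the integerisation that
reproduces the published "53 of 84"). Sub-region cohorts use their own
release points but are timed against exit from the *footprint*, not the
sub-region. Cohorts that never reach the threshold are censored at the
horizon (default 10 days), excluded from summary moments and reported
separately. A 90%-exit variant (`threshold = 0.9`) is available; it can
never report a shorter residence than the e-folding threshold, which the
suite asserts release-by-release.

Connectivity counts a particle once per destination region if any hourly
position falls inside it, regardless of re-entries; percentages are per
source region and release. Grazing impact is the published arithmetic:
ingestion rate (µg Chl *a* ind⁻¹ day⁻¹) × abundance (ind m⁻³) / 1000,
reported in mg Chl *a* m⁻³ day⁻¹ to one decimal.

## Wind response

The two station series are merged by vector averaging per 15-min timestamp
(speed = magnitude of the mean vector; a scalar-speed variant exists for
sensitivity checks; equal-and-opposite winds give speed 0 and an undefined
direction). For every non-censored release the merged wind is averaged over
exactly that release's residence window, inclusive at both ends on the
15-min grid — a 1.9-day window starting 1 Jan 00:00 includes samples
through 45.5 h, the last grid point at or before 45.6 h. (The window is
defined this way once and applied uniformly; the nine-minute ambiguity one
could read into a printed worked example elsewhere is not
reverse-engineered.) Direction is summarised by the circular mean.

The wind–residence relationship is quantified by **major-axis (model II)
regression**, appropriate because wind speed and residence time both carry
error:
$$ b \;=\; \frac{s_{yy}-s_{xx}+\sqrt{(s_{yy}-s_{xx})^2+4s_{xy}^2}}{2\,s_{xy}}, $$
the slope of the leading eigenvector of the sample covariance matrix. The
95% CI is the closed-form interval on the axis angle from the covariance
eigenvalues (Jolicoeur's form), mapped back through the tangent; its
coverage was verified by simulation with symmetric errors in both
variables. `r2` is the squared Pearson correlation with its test p-value.
Speed distributions use 1 m s⁻¹ bins centred on integers (`[k−0.5,
k+0.5)`); directions use 30° bins centred on multiples of 30 with
wraparound. Pairwise bin comparisons use Tukey–Kramer HSD via
`stats::aov()` + `TukeyHSD()`, with bins below a minimum size excluded and
reported.

## The parameter-recovery benchmark

`recovery_domain()` / `recovery_config()` / `recovery_replicate()` define a
scaled validation study: a 20 × 20 km footprint (88 release points in three
compact regions) and a 30-day, 6-hourly schedule, tracked with dt = 0.25 h.
The regime is deliberately *linearised*: a dominant 16 cm s⁻¹ mean flow
with a weak wind coupling (1.2% of wind speed), so residence responds
nearly linearly to the 2–12 m s⁻¹ wind range and the regression's estimand
is well defined; eddy noise is weak (1.5 cm s⁻¹ rms) with a short (12 h)
decorrelation time. Because consecutive 6-h releases share most of their
residence windows, their residuals are serially correlated and the
closed-form CI would be anti-conservative; the benchmark therefore fits the
regression on every 6th release (36 h spacing), where the correlation has
died out. The "true" slope is estimated empirically by pooling several
replicates of the identical design — same span, because the major-axis
estimand depends on the sampled wind distribution, which varies with
record length. Under this design the replicate CIs cover the reference
slope at close to their nominal rate, which is what the acceptance suite
asserts (≥ 90% of 20 replicates).

## Numerical choices and problem sizes

* Exit checks hourly; integrator dt 0.1 h (0.25 h in the scaled benchmark),
  with a convergence assertion in the tests.
* Residence times are quantised to the hourly tracking cadence; regimes for
  statistical tests are sized so residence spans many hours and
  quantisation noise is small.
* The tidal-share recovery test uses a 12 × 10 km grid over 60 days; the
  de-tiding fit needs ≥ 15 days to resolve M2 from S2 (Rayleigh), and the
  package refuses shorter records for that pair.
* The white-noise screening check uses 50 seeds on 151-day hourly series.
* Velocity fields live in memory as dense arrays; the demo 50 × 30 × 70-day
  field occupies ~80 MB across components.

## Known limitations

* Gap geometry is i.i.d. per cell-hour, not spatially coherent.
* The constituent screen assumes white residuals; no nodal/satellite
  corrections, no rotary ellipse analysis.
* Passive surface kinematics only: no diffusion, windage, vertical motion
  or behaviour (krill diel vertical migration is discussed in the source
  literature but deliberately not modelled).
* The demo sub-region polygons are schematic; real bathymetry-based
  polygons should be supplied as GeoJSON for real deployments.
* Winds are spatially uniform over the footprint — two stations cannot
  resolve topographic steering, and neither does the generator.
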