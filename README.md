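# palmerdrift

Lagrangian surface residence-time analysis for a coastal biological
hotspot, built on hourly gridded surface-current maps of the kind produced
by shore-based high-frequency radar (HFR) networks.

Over the Palmer Deep canyon (West Antarctic Peninsula), phytoplankton,
Antarctic krill and seabird foraging are all shaped by how long surface
water lingers over the feature. `palmerdrift` answers that question with
passive-particle kinematics:

* **particle advection** — classical fourth-order Runge–Kutta through
  bilinear-in-space, linear-in-time interpolated current maps, with hourly
  position logging and exit detection at the data-footprint boundary;
* **e-folding residence time** — for a cohort of `n` particles released on
  a 1-km grid, the first hour at which cumulative exits reach
  `n − round(n/e)` (36.79% retained), per release and per sub-region
  (central canyon CAN and the Joubin/Wauwermans Islands flanks JIF, WIF);
* **connectivity** — the percentage of a sub-region's particles whose
  trajectories ever enter another sub-region;
* **tidal harmonic analysis** — per-cell least-squares fits at the O1, K1,
  M2, S2 frequencies with family-wise constituent screening, variance
  accounting and exact de-tiding (`raw = tide + residual`);
* **wind response** — two-station wind merging by vector averaging,
  averaging over each release's own residence window, model-II
  (major-axis) regression of residence time on wind speed
  (slope `b = (s_yy − s_xx + √((s_yy−s_xx)² + 4 s_xy²)) / (2 s_xy)`),
  centred-bin distributions and Tukey–Kramer comparisons;
* **grazing impact** — ingestion rate × krill abundance / 1000 in
  mg Chl *a* m⁻³ day⁻¹;
* a seeded **synthetic generator** of radar-like current fields (mean
  coastal current + tides + wind-coupled component + non-divergent eddies +
  coverage gaps) and station winds, so the entire pipeline runs and is
  tested without any external data.

It is aimed at coastal physical oceanographers and ecosystem researchers
who have (or simulate) total-vector surface current maps and want
reproducible residence/connectivity statistics.

## A worked example

Ten days of synthetic currents over a scaled 20 × 20 km footprint,
6-hourly releases, residence and connectivity, and the wind regression:

```r
library(palmerdrift)

dom  <- recovery_domain()                       # 88 release points, 3 regions
cfg  <- recovery_config(seed = 1, span_days = 10)
res  <- run_pipeline(
  out_dir  = "report",
  domain   = dom,
  synth    = cfg,
  schedule = schedule_releases(cfg$start, cfg$start + 10 * 86400, 6),
  dt = 0.25
)
res$residence$raw$summary
#> # A tibble: 4 × 10
#>   region n_particles velocity_kind n_releases mean_days sd_days max_days min_days n_censored horizon_days
#>   <chr>        <int> <chr>              <int>     <dbl>   <dbl>    <dbl>    <dbl>      <int>        <dbl>
#> 1 ALL           3608 raw                   41     0.631  0.0471    0.75     0.542          0         -Inf
#> 2 CAN           1968 raw                   41     0.578  0.0458    0.708    0.5            0         -Inf
#> 3 JIF            820 raw                   41     0.920  0.0488    1.04     0.833          0         -Inf
#> 4 WIF            820 raw                   41     0.204  0.0292    0.292    0.167          0         -Inf

glance(res$wind_fits$raw$ALL)
#> # A tibble: 1 × 7
#>     slope intercept   ci_lo   ci_hi r.squared  p.value     n
#>     <dbl>     <dbl>   <dbl>   <dbl>     <dbl>    <dbl> <int>
#> 1 -0.0276     0.792 -0.0344 -0.0209     0.637 4.00e-10    41
```

The mean surface residence of the whole footprint in this regime is 0.63
days. The flow is eastward, so the upstream flank (JIF, 0.92 d) holds its
particles longest and the downstream flank (WIF, 0.20 d) flushes fastest —
a particle released there is already near the exit. The wind regression
says each additional m s⁻¹ of wind shortens residence by 0.028 days
(95% CI −0.034 to −0.021, r² = 0.64): stronger winds flush the footprint
faster. De-tided results sit in `res$residence$detided`, connectivity in
`res$connectivity`; `autoplot(res$wind_fits$raw$ALL)` draws the
wind–residence scatter with the fitted axis. The `report/` directory holds
the same tables as CSV plus a provenance manifest (seed, config hash).

The full-scale demo — the 50 × 30 km footprint with the 187/84/61 release
split and the 237-release January–March schedule, i.e. 78 684 tracked
particles per velocity field — runs the same way with
`build_domain(demo_domain_config())` and `synth_config()`; allow tens of
minutes.

## Package tour

| area | functions |
|---|---|
| domain | `domain_config()`, `demo_domain_config()`, `build_domain()`, `locate()`, `read/write_regions_geojson()` |
| synthesis | `synth_config()`, `synth_currents()`, `synth_winds()` |
| tides | `tidal_constituents()`, `harmonic_fit()`, `detide_field()`, `field_window()` |
| advection | `sample_velocity()`, `rk4_step()`, `track()` |
| residence | `schedule_releases()`, `efolding_exit_count()`, `residence_time()`, `run_release_experiments()`, `residence_records()`, `residence_summary()` |
| connectivity | `connectivity_records()`, `connectivity_summary()` |
| grazing | `grazing_impact()` |
| wind | `merge_winds()`, `window_mean()`, `major_axis_fit()`, `binned_distributions()`, `tukey_pairwise()` |
| orchestration | `run_pipeline()`, `wind_residence_pairs()` |
| validation | `recovery_domain()`, `recovery_config()`, `recovery_replicate()`, `recovery_reference_slope()` |

The methods vignette (`vignettes/surface-residence.Rmd`) documents the
models, parameter choices, numerical conventions and known limitations.
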