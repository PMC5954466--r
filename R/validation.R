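#' Built-in wind-response parameter-recovery benchmark
#'
#' A scaled-down, fully synthetic study used to validate that the pipeline
#' recovers an imposed wind-residence relationship: a 20 x 20 km footprint
#' with a compact three-region release grid (88 points), a 30-day 6-hourly
#' release schedule, and a current regime in which the wind-driven component
#' is a modest, nearly linear perturbation of a dominant steady eastward
#' flow (so the expected residence-wind relation is close to linear across
#' the simulated wind range). Tides carry the default 12.3% variance share
#' and mesoscale eddy noise is kept weak with a short decorrelation time, so
#' successive thinned releases are nearly independent.
#'
#' `recovery_replicate()` runs one seeded replicate of the full chain
#' (synthesise currents and winds, release experiments, residence records,
#' window-averaged winds) and fits the major-axis regression on every
#' `thin`-th release (36 h apart by default) so the regression's
#' independence assumptions hold despite overlapping residence windows.
#'
#' `recovery_reference_slope()` estimates the regime's true wind-residence
#' slope by pooling the paired observations of several replicates of the
#' identical design (same span, so the estimand matches) and fitting one
#' high-precision major-axis regression.
#'
#' @param seed Integer seed for the replicate.
#' @param span_days Length of the release window (days).
#' @param thin Keep every `thin`-th release for the regression.
#' @param dt Integrator step (hours).
#' @return `recovery_domain()`: a `drift_domain`. `recovery_config()`: a
#'   `synth_config`. `recovery_replicate()`: list with `fit` (an `ma_fit`
#'   on the thinned pairs) and `pairs` (all paired observations).
#'   `recovery_reference_slope()`: a number.
#' @export
recovery_domain <- function() {
  rect <- function(x0, y0, x1, y1) {
    cbind(x = c(x0, x1, x1, x0), y = c(y0, y0, y1, y1))
  }
  build_domain(domain_config(
    nx = 20, ny = 20,
    subregions = list(
      CAN = rect(6, 6, 14, 12),
      JIF = rect(1, 7, 5, 12),
      WIF = rect(15, 7, 19, 12)
    )
  ))
}

#' @rdname recovery_domain
#' @export
recovery_config <- function(seed, span_days = 30) {
  synth_config(
    duration_days = span_days + 11,  # releases + 10-day horizon + margin
    mean_uv = c(16, 0),
    wind_coupling = 0.012,
    eddy = list(amp = 1.5, length_km = 12, tau_h = 12, n_modes = 6),
    wind = list(mean = 6, sd = 2.5, tau_h = 6, dir_mean = 270,
                dir_sd = 15, station_sd = 0.5),
    seed = seed
  )
}

#' @rdname recovery_domain
#' @export
recovery_replicate <- function(seed, span_days = 30, thin = 6, dt = 0.25) {
  domain <- recovery_domain()
  cfg <- recovery_config(seed, span_days)
  field <- synth_currents(cfg, domain)
  winds <- synth_winds(cfg)
  merged <- merge_winds(winds[winds$station == "joubin", ],
                        winds[winds$station == "wauwermans", ])
  sched <- schedule_releases(cfg$start, cfg$start + span_days * 86400, 6)
  ex <- run_release_experiments(field, sched, dt = dt, horizon_h = 240)
  pairs <- wind_residence_pairs(residence_records(ex), merged, region = "ALL")
  kept <- pairs[seq(1, nrow(pairs), by = thin), ]
  list(fit = major_axis_fit(kept$speed, kept$residence_days), pairs = pairs)
}

#' @param seeds Seeds of the pooled reference replicates.
#' @rdname recovery_domain
#' @export
recovery_reference_slope <- function(seeds = 101:108, span_days = 30,
                                     dt = 0.25) {
  pooled <- dplyr::bind_rows(
    lapply(seeds, function(s) recovery_replicate(s, span_days, dt = dt)$pairs)
  )
  major_axis_fit(pooled$speed, pooled$residence_days)$slope
}
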