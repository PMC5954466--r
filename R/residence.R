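#' Build a release schedule
#'
#' Evenly spaced release times from `start` to `end` inclusive at `cadence_h`
#' hours. The cadence must divide the interval exactly, otherwise the last
#' release would be ambiguous.
#'
#' @param start,end POSIXct first and last release (inclusive).
#' @param cadence_h Hours between releases (default 6).
#' @return A `release_schedule`: list with `times` (POSIXct) and `cadence_h`.
#' @examples
#' sched <- schedule_releases(
#'   as.POSIXct("2015-01-01 00:00", tz = "UTC"),
#'   as.POSIXct("2015-03-01 00:00", tz = "UTC")
#' )
#' length(sched$times)  # 237
#' @export
schedule_releases <- function(start, end, cadence_h = 6) {
  start <- as.POSIXct(start, tz = "UTC")
  end <- as.POSIXct(end, tz = "UTC")
  if (end < start) rlang::abort("end must not precede start")
  if (cadence_h <= 0) rlang::abort("cadence must be positive")
  span_h <- as.numeric(difftime(end, start, units = "hours"))
  k <- span_h / cadence_h
  if (abs(k - round(k)) > 1e-9) {
    rlang::abort("cadence does not divide the release interval: last release ambiguous")
  }
  structure(
    list(times = start + 3600 * cadence_h * (0:round(k)), cadence_h = cadence_h),
    class = "release_schedule"
  )
}

#' @export
print.release_schedule <- function(x, ...) {
  cat(sprintf("<release_schedule> %d releases every %g h from %s to %s\n",
              length(x$times), x$cadence_h,
              format(x$times[1], "%Y-%m-%d %H:%M"),
              format(x$times[length(x$times)], "%Y-%m-%d %H:%M")))
  invisible(x)
}

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Exits required to reach the e-folding threshold
#'
#' Residence time is declared when the particles remaining in the footprint
#' have dropped to the first e-folding scale, 1/e = 36.79% of the number
#' released. The remaining count is integerised by rounding half away from
#' zero, so `efolding_exit_count(84) = 84 - round(84/e) = 53`.
#'
#' `exits_required()` generalises to any exited fraction (e.g. 0.9 for the
#' 90%-exited threshold): `n - round(n * (1 - exited_fraction))`.
#'
#' @param n_released Number of particles released (>= 1).
#' @param exited_fraction Fraction of particles that must have left.
#' @return Integer count of exits required.
#' @export
efolding_exit_count <- function(n_released) {
  exits_required(n_released, 1 - exp(-1))
}

#' @rdname efolding_exit_count
#' @export
exits_required <- function(n_released, exited_fraction = 1 - exp(-1)) {
  if (any(n_released < 1)) rlang::abort("n_released must be >= 1")
  stopifnot(exited_fraction > 0, exited_fraction <= 1)
  as.integer(n_released - round_half_away(n_released * (1 - exited_fraction)))
}

#' Residence time of one release cohort
#'
#' Given the hourly exit times of a cohort released together, the residence
#' time is the earliest hourly offset at which the cumulative number of
#' exits reaches the threshold count ([exits_required()]), expressed in
#' days. If the threshold is never reached before the horizon or record end,
#' the record is censored.
#'
#' @param exit_times_h Exit times in whole hours since release (`NA` for
#'   particles that never exited).
#' @param threshold `"efold"` or a numeric exited fraction in (0, 1].
#' @param horizon_h Hours of tracking available (used as the censoring bound
#'   reported for unresolved cohorts).
#' @return One-row tibble: `n_released`, `n_exited`, `residence_days`,
#'   `censored`.
#' @export
residence_time <- function(exit_times_h, threshold = "efold", horizon_h = 240) {
  n <- length(exit_times_h)
  if (n < 1) rlang::abort("empty cohort")
  frac <- if (identical(threshold, "efold")) 1 - exp(-1) else as.numeric(threshold)
  need <- exits_required(n, frac)
  et <- sort(exit_times_h[!is.na(exit_times_h)])
  if (length(et) >= need) {
    hrs <- et[need]
    tibble::tibble(n_released = n, n_exited = length(et),
                   residence_days = hrs / 24, censored = FALSE)
  } else {
    tibble::tibble(n_released = n, n_exited = length(et),
                   residence_days = horizon_h / 24, censored = TRUE)
  }
}

#' Run the full set of release experiments
#'
#' For every release time in the schedule, releases one particle from each
#' domain release point, tracks the cohort ([track()] semantics) and records
#' each particle's exit time plus which sub-regions its trajectory ever
#' entered. Residence and connectivity tables are then derived with
#' [residence_records()], [residence_summary()] and
#' [connectivity_summary()]; exit times are stored per particle so residence
#' can be re-derived under any threshold without re-tracking.
#'
#' @param field A `velocity_field`.
#' @param schedule A [schedule_releases()] result.
#' @param dt Integrator step (hours).
#' @param horizon_h Tracking horizon per release (hours); default 240 (10
#'   days).
#' @param max_gap_h Gap tolerance passed to the tracker.
#' @param progress Print a dot per release.
#' @return A `release_experiments` object: `exits` (tibble: `release_time`,
#'   `particle_id`, `region`, `exit_time_h`, `censored`, `exit_reason`),
#'   `entries` (tibble: `release_time`, `particle_id`, `source`,
#'   `destination` for every sub-region a particle entered), `schedule`,
#'   `horizon_h`, `domain`.
#' @export
run_release_experiments <- function(field, schedule, dt = 0.1,
                                    horizon_h = 240, max_gap_h = 3,
                                    progress = FALSE) {
  stopifnot(inherits(field, "velocity_field"),
            inherits(schedule, "release_schedule"))
  domain <- field$domain
  rp <- domain$release_points
  if (!nrow(rp)) rlang::abort("domain has no release points")
  rel_h <- field_hour(field, schedule$times)
  bad <- rel_h < 0 | rel_h > field$nt - 1
  if (any(bad)) {
    rlang::abort(paste0(
      "schedule extends past the field record; offending releases: ",
      paste(format(schedule$times[bad]), collapse = ", ")
    ))
  }
  regions <- names(domain$subregions)
  np <- nrow(rp)

  exits_list <- vector("list", length(rel_h))
  entries_list <- vector("list", length(rel_h))
  for (r in seq_along(rel_h)) {
    res <- track_cohort(field, rp$x, rp$y, rel_h[r], dt = dt,
                        horizon_h = horizon_h, max_gap_h = max_gap_h,
                        keep_positions = TRUE)
    exits_list[[r]] <- tibble::tibble(
      release_time = schedule$times[r],
      particle_id = seq_len(np),
      region = rp$region,
      exit_time_h = res$exit_time_h,
      censored = res$censored,
      exit_reason = res$exit_reason
    )
    # which sub-regions did each particle ever visit after release?
    entered <- matrix(FALSE, np, length(regions),
                      dimnames = list(NULL, regions))
    for (h in seq_len(res$n_hours)) {
      xs <- res$positions[, 1, h + 1]
      ys <- res$positions[, 2, h + 1]
      fin <- which(is.finite(xs))
      if (!length(fin)) break
      reg <- assign_region(xs[fin], ys[fin], domain)
      hit <- !is.na(reg)
      if (any(hit)) entered[cbind(fin[hit], match(reg[hit], regions))] <- TRUE
    }
    ij <- which(entered & (rp$region[row(entered)] != colnames(entered)[col(entered)]),
                arr.ind = TRUE)
    entries_list[[r]] <- tibble::tibble(
      release_time = schedule$times[r],
      particle_id = ij[, 1],
      source = rp$region[ij[, 1]],
      destination = regions[ij[, 2]]
    )
    if (progress) cat(".")
  }
  if (progress) cat("\n")
  structure(
    list(
      exits = dplyr::bind_rows(exits_list),
      entries = dplyr::bind_rows(entries_list),
      schedule = schedule, horizon_h = horizon_h, domain = domain,
      n_particles = np
    ),
    class = "release_experiments"
  )
}

#' @export
print.release_experiments <- function(x, ...) {
  cat(sprintf(
    "<release_experiments> %d releases x %d particles = %d tracked\n",
    length(x$schedule$times), x$n_particles,
    length(x$schedule$times) * x$n_particles
  ))
  invisible(x)
}

#' Per-release residence records
#'
#' Derives a [residence_time()] record for every release time and region:
#' `ALL` (the whole release grid) plus each sub-region's own release points —
#' in every case timed against exit from the data footprint, not from the
#' sub-region.
#'
#' @param experiments A [run_release_experiments()] result.
#' @param threshold `"efold"` or numeric exited fraction.
#' @return Tibble: `release_time`, `region`, `n_released`, `n_exited`,
#'   `residence_days`, `censored`.
#' @export
residence_records <- function(experiments, threshold = "efold") {
  ex <- experiments$exits
  hz <- experiments$horizon_h
  all_rec <- ex |>
    dplyr::group_by(.data$release_time) |>
    dplyr::summarise(
      residence_time(.data$exit_time_h, threshold, hz),
      .groups = "drop"
    ) |>
    dplyr::mutate(region = "ALL", .after = "release_time")
  sub_rec <- ex |>
    dplyr::group_by(.data$release_time, region = .data$region) |>
    dplyr::summarise(
      residence_time(.data$exit_time_h, threshold, hz),
      .groups = "drop"
    )
  dplyr::bind_rows(all_rec, sub_rec) |>
    dplyr::arrange(.data$release_time,
                   match(.data$region, c("ALL", names(experiments$domain$subregions))))
}

#' Summarise residence records per region
#'
#' Mean, standard deviation, maximum and minimum residence time per region
#' over all releases. Censored releases are excluded from the moments and
#' counted separately (`n_censored`, with the censoring bound in
#' `horizon_days`).
#'
#' @param records Output of [residence_records()].
#' @param velocity_kind Optional label (e.g. "raw"/"de-tided") stamped on
#'   the table.
#' @return Tibble: `region`, `n_particles` (total tracked over all
#'   releases), `n_releases`, `mean_days`, `sd_days`, `max_days`,
#'   `min_days`, `n_censored`, `horizon_days`.
#' @export
residence_summary <- function(records, velocity_kind = NULL) {
  out <- records |>
    dplyr::group_by(.data$region) |>
    dplyr::summarise(
      n_particles = sum(.data$n_released),
      n_releases = dplyr::n(),
      mean_days = mean(.data$residence_days[!.data$censored]),
      sd_days = stats::sd(.data$residence_days[!.data$censored]),
      max_days = max(.data$residence_days[!.data$censored], -Inf),
      min_days = min(.data$residence_days[!.data$censored], Inf),
      n_censored = sum(.data$censored),
      horizon_days = max(.data$residence_days[.data$censored], -Inf),
      .groups = "drop"
    )
  if (!is.null(velocity_kind)) {
    out <- dplyr::mutate(out, velocity_kind = velocity_kind,
                         .after = "n_particles")
  }
  out
}

#' Connectivity between sub-regions
#'
#' A particle released in one sub-region "enters" another if any of its
#' hourly positions falls inside the destination polygon; re-entries count
#' once. Per release the record is `100 x entrants / n released` from the
#' source; `connectivity_summary()` reduces over releases (mean, sd, max,
#' min per source-destination pair, source = destination excluded by
#' construction).
#'
#' @param experiments A [run_release_experiments()] result.
#' @return `connectivity_records()`: tibble `release_time`, `source`,
#'   `destination`, `pct`. `connectivity_summary()`: tibble `source`,
#'   `destination`, `mean_pct`, `sd_pct`, `max_pct`, `min_pct`.
#' @export
connectivity_records <- function(experiments) {
  regions <- names(experiments$domain$subregions)
  n_by_region <- experiments$domain$release_points |>
    dplyr::count(.data$region, name = "n_released")
  grid <- tidyr::expand_grid(
    release_time = experiments$schedule$times,
    source = regions, destination = regions
  ) |>
    dplyr::filter(.data$source != .data$destination)
  counts <- experiments$entries |>
    dplyr::count(.data$release_time, .data$source, .data$destination,
                 name = "entrants")
  grid |>
    dplyr::left_join(counts, by = c("release_time", "source", "destination")) |>
    dplyr::left_join(n_by_region, by = c("source" = "region")) |>
    dplyr::mutate(
      entrants = dplyr::coalesce(.data$entrants, 0L),
      pct = 100 * .data$entrants / .data$n_released
    ) |>
    dplyr::select("release_time", "source", "destination", "pct")
}

#' @rdname connectivity_records
#' @export
connectivity_summary <- function(experiments) {
  connectivity_records(experiments) |>
    dplyr::group_by(.data$source, .data$destination) |>
    dplyr::summarise(
      mean_pct = mean(.data$pct),
      sd_pct = stats::sd(.data$pct),
      max_pct = max(.data$pct),
      min_pct = min(.data$pct),
      .groups = "drop"
    )
}

#' Krill grazing impact
#'
#' Converts a per-individual chlorophyll ingestion rate and a krill
#' abundance into an aggregate grazing impact on the phytoplankton standing
#' stock: `rate x abundance / 1000`, reported in mg Chl a m^-3 day^-1 to
#' one decimal place.
#'
#' @param ingestion_rate Ingestion rate, ug Chl a per individual per day.
#' @param abundance Krill abundance, individuals m^-3.
#' @return Grazing impact, mg Chl a m^-3 day^-1, rounded to one decimal.
#' @examples
#' grazing_impact(6.37, 87)    # 0.6
#' grazing_impact(6.37, 2168)  # 13.8
#' @export
grazing_impact <- function(ingestion_rate, abundance) {
  if (any(ingestion_rate < 0) || any(abundance < 0)) {
    rlang::abort("ingestion rate and abundance must be non-negative")
  }
  round(ingestion_rate * abundance / 1000, 1)
}
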