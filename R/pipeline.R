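#' Pair residence times with window-averaged winds
#'
#' For every non-censored residence record of one region, averages the
#' merged wind over exactly that release's residence window
#' ([window_mean()] from the release time for the residence duration) and
#' returns the paired observations that feed [major_axis_fit()] and
#' [binned_distributions()]. Censored releases are excluded and counted in
#' the `dropped` attribute.
#'
#' @param records [residence_records()] output.
#' @param wind Merged wind tibble ([merge_winds()]).
#' @param region Region to pair (default `"ALL"`).
#' @return Tibble: `release_time`, `residence_days`, `speed`
#'   (window-mean m s^-1), `direction` (circular-mean deg), `n_samples`.
#' @export
wind_residence_pairs <- function(records, wind, region = "ALL") {
  rec <- records[records$region == region & !records$censored, ]
  dropped <- sum(records$region == region) - nrow(rec)
  out <- purrr::pmap_dfr(
    list(rec$release_time, rec$residence_days),
    function(t0, dur) {
      wm <- window_mean(wind, t0, dur)
      tibble::tibble(release_time = t0, residence_days = dur,
                     speed = wm$mean_speed_ms, direction = wm$mean_dir_deg,
                     n_samples = wm$n_samples)
    }
  )
  attr(out, "dropped_censored") <- dropped
  out
}

#' Run the whole analysis pipeline
#'
#' One-command orchestration: synthesise (or accept) the velocity field and
#' station winds, de-tide, run the release experiments on the raw and
#' de-tided fields, reduce to residence and connectivity tables, and regress
#' residence time on window-averaged wind speed per region. Writes a report
#' bundle of CSV tables plus a provenance manifest; idempotent under a fixed
#' seed.
#'
#' @param out_dir Output directory (created if missing); `NULL` to skip
#'   writing and just return results.
#' @param domain A `drift_domain`; default the demo domain.
#' @param synth A [synth_config()] for the synthetic regime, or an existing
#'   `velocity_field` to analyse (winds must then be supplied via `winds`).
#' @param winds Optional two-station wind tibble; defaults to
#'   [synth_winds()] under `synth`.
#' @param schedule A [schedule_releases()] result; default 6-hourly over
#'   1 Jan–1 Mar 2015.
#' @param dt,horizon_h,max_gap_h Tracker settings (see
#'   [run_release_experiments()]).
#' @param threshold Residence threshold (`"efold"` or exited fraction).
#' @param detide Also run the de-tided branch (default `TRUE`).
#' @param constituents Constituent table for de-tiding.
#' @param seed Optional override of the synthetic seed.
#' @param progress Print progress dots.
#' @return (Invisibly) a list: `field`, `detide`, `experiments_raw`,
#'   `experiments_detided`, `residence`, `connectivity`, `wind_fits`,
#'   `wind_pairs`, `manifest`.
#' @export
run_pipeline <- function(out_dir = NULL,
                         domain = build_domain(demo_domain_config()),
                         synth = synth_config(),
                         winds = NULL,
                         schedule = schedule_releases(
                           as.POSIXct("2015-01-01 00:00", tz = "UTC"),
                           as.POSIXct("2015-03-01 00:00", tz = "UTC")
                         ),
                         dt = 0.1, horizon_h = 240, max_gap_h = 3,
                         threshold = "efold", detide = TRUE,
                         constituents = tidal_constituents(),
                         seed = NULL, progress = FALSE) {
  if (inherits(synth, "synth_config")) {
    if (!is.null(seed)) synth$seed <- as.integer(seed)
    field <- synth_currents(synth, domain)
    if (is.null(winds)) winds <- synth_winds(synth)
  } else if (inherits(synth, "velocity_field")) {
    field <- synth
    if (is.null(winds)) rlang::abort("winds must be supplied with an external field")
  } else {
    rlang::abort("synth must be a synth_config or a velocity_field")
  }
  st <- unique(winds$station)
  merged <- merge_winds(winds[winds$station == st[1], ],
                        winds[winds$station == st[2], ])

  branches <- list(raw = field)
  dt_res <- NULL
  if (detide) {
    dt_res <- detide_field(field, constituents = constituents)
    branches$detided <- dt_res$detided
  }

  experiments <- list()
  residence <- list()
  connectivity <- list()
  wind_fits <- list()
  wind_pairs <- list()
  for (kind in names(branches)) {
    if (progress) cat(kind, "branch\n")
    exps <- run_release_experiments(branches[[kind]], schedule, dt = dt,
                                    horizon_h = horizon_h,
                                    max_gap_h = max_gap_h,
                                    progress = progress)
    recs <- residence_records(exps, threshold = threshold)
    experiments[[kind]] <- exps
    residence[[kind]] <- list(
      records = recs,
      summary = residence_summary(recs, velocity_kind = kind)
    )
    connectivity[[kind]] <- connectivity_summary(exps)

    fits <- list()
    pairs <- list()
    for (reg in c("ALL", names(domain$subregions))) {
      pr <- wind_residence_pairs(recs, merged, region = reg)
      pairs[[reg]] <- pr
      fits[[reg]] <- tryCatch(
        major_axis_fit(pr$speed, pr$residence_days),
        error = function(e) NULL
      )
    }
    wind_pairs[[kind]] <- pairs
    wind_fits[[kind]] <- fits
  }

  manifest <- list(
    seed = if (inherits(synth, "synth_config")) synth$seed else NA,
    config_hash = rlang::hash(list(
      domain = domain[c("nx", "ny", "spacing")],
      synth = if (inherits(synth, "synth_config")) unclass(synth) else "external",
      schedule = schedule$times, dt = dt, horizon_h = horizon_h,
      threshold = threshold
    )),
    n_releases = length(schedule$times),
    n_release_points = nrow(domain$release_points),
    threshold = threshold,
    package_version = as.character(utils::packageVersion("palmerdrift")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  )

  result <- list(field = field, detide = dt_res, experiments = experiments,
                 residence = residence, connectivity = connectivity,
                 wind_fits = wind_fits, wind_pairs = wind_pairs,
                 merged_wind = merged, manifest = manifest)
  class(result) <- "drift_pipeline"

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (kind in names(residence)) {
      utils::write.csv(residence[[kind]]$summary,
                       file.path(out_dir, paste0("residence_summary_", kind, ".csv")),
                       row.names = FALSE)
      utils::write.csv(residence[[kind]]$records,
                       file.path(out_dir, paste0("residence_records_", kind, ".csv")),
                       row.names = FALSE)
      utils::write.csv(connectivity[[kind]],
                       file.path(out_dir, paste0("connectivity_", kind, ".csv")),
                       row.names = FALSE)
      utils::write.csv(
        dplyr::bind_rows(purrr::imap(
          wind_fits[[kind]],
          function(f, reg) if (is.null(f)) NULL else
            dplyr::mutate(glance(f), region = reg, .before = 1)
        )),
        file.path(out_dir, paste0("wind_regression_", kind, ".csv")),
        row.names = FALSE
      )
    }
    if (!is.null(dt_res)) {
      # pooled per-constituent table from a central footprint cell
      utils::write.csv(
        dplyr::mutate(
          harmonic_fit(field$u[ceiling(domain$nx / 2), ceiling(domain$ny / 2), ],
                       constituents = constituents)$table,
          component = "u", .before = 1
        ),
        file.path(out_dir, "constituents_example.csv"), row.names = FALSE
      )
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(result)
}

#' @export
print.drift_pipeline <- function(x, ...) {
  cat("<drift_pipeline>\n")
  for (kind in names(x$residence)) {
    cat("--", kind, "residence summary --\n")
    print(x$residence[[kind]]$summary)
  }
  invisible(x)
}

#' Export a constituent table as CSV
#'
#' Writes the per-constituent results of a [harmonic_fit()] in the
#' interchange layout `constituent, component, amplitude, phase, ci_lo,
#' ci_hi, significant`.
#'
#' @param fit_u,fit_v `tidal_fit` objects for the two velocity components.
#' @param path Output file.
#' @export
write_constituents_csv <- function(fit_u, fit_v, path) {
  tbl <- dplyr::bind_rows(
    dplyr::mutate(fit_u$table, component = "u"),
    dplyr::mutate(fit_v$table, component = "v")
  ) |>
    dplyr::select("constituent", "component", amplitude = "amplitude",
                  phase = "phase_deg", "ci_lo", "ci_hi", "significant")
  utils::write.csv(tbl, path, row.names = FALSE)
  invisible(path)
}
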