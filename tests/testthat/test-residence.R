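test_that("release schedules include both endpoints at the stated cadence", {
  s <- schedule_releases(as.POSIXct("2015-01-01 00:00", tz = "UTC"),
                         as.POSIXct("2015-03-01 00:00", tz = "UTC"), 6)
  expect_equal(length(s$times), 237)
  expect_equal(s$times[1], as.POSIXct("2015-01-01 00:00", tz = "UTC"))
  expect_equal(s$times[237], as.POSIXct("2015-03-01 00:00", tz = "UTC"))

  one <- schedule_releases(T0, T0, 6)
  expect_equal(length(one$times), 1)

  day <- schedule_releases(T0, T0 + 24 * 3600, 1)
  expect_equal(length(day$times), 25)

  expect_error(schedule_releases(T0, T0 + 10 * 3600, 6), "ambiguous")
})

test_that("e-folding exit counts integerise the retained fraction as published", {
  expect_equal(efolding_exit_count(84), 53L)
  expect_equal(efolding_exit_count(332), 210L)
  expect_equal(efolding_exit_count(1), 1L)
  expect_equal(efolding_exit_count(187), 118L)
  expect_error(efolding_exit_count(0), ">= 1")
  # 90%-exit threshold generalisation
  expect_equal(exits_required(100, 0.9), 90L)
  expect_equal(exits_required(84, 0.9), 76L)
})

test_that("residence time reads the threshold exit off the hourly exit ladder", {
  # 10 particles; e-folding needs 10 - round(10/e) = 6 exits
  exits <- c(2, 5, 12, 24, 48, 48, 48, 60, NA, NA)
  rec <- residence_time(exits, "efold", horizon_h = 240)
  expect_equal(rec$residence_days, 2)  # 6th exit logged at hour 48
  expect_false(rec$censored)

  # all gone in the first hour
  rec2 <- residence_time(rep(1, 5))
  expect_equal(rec2$residence_days, 1 / 24)

  # threshold never reached: censored at the horizon
  rec3 <- residence_time(c(1, NA, NA, NA, NA), horizon_h = 240)
  expect_true(rec3$censored)
  expect_equal(rec3$residence_days, 10)
})

test_that("residence and connectivity match brute-force enumeration on a toy grid", {
  # 5 x 5 footprint, uniform eastward flow, releases on all 25 cells
  dom <- build_domain(domain_config(
    nx = 5, ny = 5,
    subregions = list(
      W = cbind(x = c(0, 2, 2, 0), y = c(0, 0, 5, 5)),
      E = cbind(x = c(3, 5, 5, 3), y = c(0, 0, 5, 5))
    )
  ))
  u_cms <- 20  # 0.72 km/h
  f <- uniform_field(dom, u_cms, 0, nt = 49)
  sched <- schedule_releases(T0, T0, 6)
  ex <- run_release_experiments(f, sched, dt = 0.1, horizon_h = 48)

  # oracle: pure arithmetic on the uniform flow
  rp <- dom$release_points
  oh <- oracle_exit_hours_uniform(rp$x, u_cms, east_edge_km = 5)
  expect_equal(ex$exits$exit_time_h, oh)

  need_all <- efolding_exit_count(nrow(rp))
  expect_equal(
    residence_records(ex)$residence_days[1] * 24,
    oracle_residence_hours(oh, need_all)
  )

  # connectivity: a W particle enters E iff some hourly position has x >= 3
  # (boundary inclusive); count directly
  enters <- vapply(which(rp$region == "W"), function(i) {
    hrs <- seq_len(oh[i])
    any(rp$x[i] + 0.72 * hrs >= 3 & rp$x[i] + 0.72 * hrs <= 5)
  }, logical(1))
  cs <- connectivity_summary(ex)
  expect_equal(cs$mean_pct[cs$source == "W" & cs$destination == "E"],
               100 * mean(enters))
  expect_equal(cs$mean_pct[cs$source == "E" & cs$destination == "W"], 0)
})

test_that("particles re-entering a destination count once; a zero field connects nothing", {
  dom <- tiny_domain()
  f0 <- uniform_field(dom, 0, 0)
  sched <- schedule_releases(T0, T0, 6)
  ex <- run_release_experiments(f0, sched, dt = 0.5, horizon_h = 24)
  cs <- connectivity_summary(ex)
  expect_true(all(cs$mean_pct == 0))
  expect_false(any(cs$source == cs$destination))

  # rotation carries particles through the other region repeatedly: per
  # release each particle still counts at most once per destination
  dom2 <- build_domain(domain_config(
    nx = 20, ny = 20,
    subregions = list(
      A = cbind(x = c(7, 13, 13, 7), y = c(2, 2, 8, 8)),
      B = cbind(x = c(7, 13, 13, 7), y = c(12, 12, 18, 18))
    )
  ))
  f2 <- rotation_field(dom2, period_h = 12, nt = 49)  # 4 full laps in 48 h
  ex2 <- run_release_experiments(f2, schedule_releases(T0, T0, 6),
                                 dt = 0.1, horizon_h = 48)
  cr <- connectivity_records(ex2)
  expect_true(all(cr$pct >= 0 & cr$pct <= 100))
  dup <- dplyr::count(ex2$entries, release_time, particle_id, destination)
  expect_true(all(dup$n == 1))
})

test_that("a schedule reaching past the field record is refused with the offenders", {
  dom <- tiny_domain()
  f <- uniform_field(dom, 10, 0, nt = 25)  # 24 h record
  sched <- schedule_releases(T0, T0 + 48 * 3600, 24)
  expect_error(run_release_experiments(f, sched, dt = 0.5),
               "2015-01-03")
})

test_that("summary bookkeeping multiplies releases by release points", {
  dom <- tiny_domain()
  f <- synth_currents(synth_config(duration_days = 3, seed = 17), dom)
  sched <- schedule_releases(T0, T0 + 12 * 3600, 6)
  ex <- run_release_experiments(f, sched, dt = 0.2, horizon_h = 24)
  recs <- residence_records(ex)
  expect_equal(nrow(recs), 3 * 3)  # 3 releases x (ALL, A, B)
  summ <- residence_summary(recs)
  np <- nrow(dom$release_points)
  expect_equal(summ$n_particles[summ$region == "ALL"], 3 * np)

  # identical field -> identical summaries on re-run
  ex2 <- run_release_experiments(f, sched, dt = 0.2, horizon_h = 24)
  expect_identical(residence_summary(residence_records(ex2)), summ)
})

test_that("relaxing the exit threshold never shortens residence", {
  dom <- tiny_domain()
  f <- synth_currents(synth_config(duration_days = 4, seed = 23), dom)
  sched <- schedule_releases(T0, T0 + 24 * 3600, 6)
  ex <- run_release_experiments(f, sched, dt = 0.2, horizon_h = 48)
  efold <- residence_records(ex, threshold = "efold")
  ninety <- residence_records(ex, threshold = 0.9)
  expect_true(all(ninety$residence_days >= efold$residence_days))
})

test_that("grazing impact arithmetic matches the published scale", {
  expect_equal(grazing_impact(6.37, 87), 0.6)
  expect_equal(grazing_impact(6.37, 2168), 13.8)
  expect_equal(grazing_impact(6.37, 0), 0)
  expect_error(grazing_impact(-1, 10), "non-negative")
})
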