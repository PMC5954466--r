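test_that("velocity sampling is exact for uniform, bilinear and time-linear cases", {
  dom <- tiny_domain()
  f <- uniform_field(dom, 10, 0)
  s <- sample_velocity(f, data.frame(x = c(3.7, 5.5), y = c(2.1, 8.8)), 0)
  expect_equal(s$u, c(10, 10))
  expect_equal(s$v, c(0, 0))

  # four nodes u = 0, 0, 20, 20: midpoint of the cell corner gives the mean
  f2 <- uniform_field(dom, 0, 0)
  f2$u[5, 5, ] <- 0; f2$u[6, 5, ] <- 0
  f2$u[5, 6, ] <- 20; f2$u[6, 6, ] <- 20
  mid <- sample_velocity(f2, data.frame(x = 5.0, y = 5.0), 0)  # between nodes
  expect_equal(mid$u, 10)

  # node value 0 at hour 0, 20 at hour 1: halfway in time gives 10
  f3 <- uniform_field(dom, 0, 0, nt = 3)
  f3$u[, , 2] <- 20
  half <- sample_velocity(f3, data.frame(x = 5.5, y = 5.5), 0.5)
  expect_equal(half$u, 10)
})

test_that("sampling outside the record errors; gaps renormalise weights", {
  dom <- tiny_domain()
  f <- uniform_field(dom, 10, 0, nt = 5)
  expect_error(sample_velocity(f, data.frame(x = 5, y = 5), 10), "outside")

  # mask three of the four surrounding nodes: value comes from the fourth
  f$mask[5, 5, ] <- FALSE
  f$mask[6, 5, ] <- FALSE
  f$mask[5, 6, ] <- FALSE
  f$u[6, 6, ] <- 40
  s <- sample_velocity(f, data.frame(x = 5.0, y = 5.0), 0)
  expect_equal(s$u, 40)

  # all four masked: NA signal
  f$mask[6, 6, ] <- FALSE
  s2 <- sample_velocity(f, data.frame(x = 5.0, y = 5.0), 0)
  expect_true(is.na(s2$u))
})

test_that("one RK4 step in a constant field displaces exactly u * dt", {
  dom <- tiny_domain()
  f <- uniform_field(dom, 10, 0)
  p <- rk4_step(f, c(5, 5), 0, dt = 1)
  expect_equal(p, c(x = 5.36, y = 5), tolerance = 1e-12)

  f0 <- uniform_field(dom, 0, 0)
  expect_equal(rk4_step(f0, c(5, 5), 3, dt = 1), c(x = 5, y = 5))
})

test_that("solid-body rotation preserves the orbit radius to under 1 m", {
  dom <- build_domain(domain_config(nx = 20, ny = 20))
  f <- rotation_field(dom, period_h = 12, nt = 25)
  centre <- c(10, 10)
  p <- c(10, 15)  # radius 5 km
  t <- 0
  while (t < 12 - 1e-9) {
    p <- rk4_step(f, p, t, dt = 0.1)
    t <- t + 0.1
  }
  r_end <- sqrt(sum((p - centre)^2))
  expect_lt(abs(r_end - 5), 1e-3)           # < 1 m radius drift
  expect_lt(sqrt(sum((p - c(10, 15))^2)), 5e-3)  # near-closed orbit
})

test_that("halving dt shows fourth-order error scaling on the rotation field", {
  dom <- build_domain(domain_config(nx = 20, ny = 20))
  f <- rotation_field(dom, period_h = 12, nt = 25)
  centre <- c(10, 10)
  run <- function(dt) {
    p <- c(10, 15)
    for (i in seq_len(round(12 / dt))) p <- rk4_step(f, p, (i - 1) * dt, dt)
    sqrt(sum((p - c(10, 15))^2))  # position error after one full period
  }
  e1 <- run(0.5)
  e2 <- run(0.25)
  ratio <- e1 / e2
  expect_gt(ratio, 8)   # 4th-order global error: ratio ~ 16 per halving
  expect_lt(ratio, 40)
})

test_that("24 h positions converge under dt halving in a smooth field", {
  dom <- build_domain(domain_config(nx = 20, ny = 20))
  cfg <- synth_config(duration_days = 2, gap_fraction = 0, seed = 21,
                      mean_uv = c(5, 0),
                      tidal = default_tidal_amplitudes()[0, ],
                      tidal_fraction = NULL,
                      eddy = list(amp = 10, length_km = 8, tau_h = 48,
                                  n_modes = 6))
  f <- synth_currents(cfg, dom)
  advance <- function(dt) {
    tr <- track(f, data.frame(x = 10, y = 10), 0, dt = dt, horizon_h = 24)
    tail(tr$positions, 1)[, c("x", "y")]
  }
  a <- advance(0.1)
  b <- advance(0.05)
  expect_lt(sqrt((a$x - b$x)^2 + (a$y - b$y)^2), 0.01)  # < 10 m
})

test_that("tracking in a non-divergent field conserves a small quadrilateral's area", {
  dom <- build_domain(domain_config(nx = 20, ny = 20))
  cfg <- synth_config(duration_days = 2, gap_fraction = 0, seed = 22,
                      mean_uv = c(0, 0), wind_coupling = 0,
                      tidal = default_tidal_amplitudes()[0, ],
                      tidal_fraction = NULL,
                      eddy = list(amp = 8, length_km = 40, tau_h = 96,
                                  n_modes = 6))
  f <- synth_currents(cfg, dom)
  corners <- data.frame(x = c(9.75, 10.25, 10.25, 9.75),
                        y = c(9.75, 9.75, 10.25, 10.25))
  tr <- track(f, corners, 0, dt = 0.1, horizon_h = 24)
  final <- dplyr::filter(tr$positions, hour == 24) |>
    dplyr::arrange(particle_id)
  shoelace <- function(x, y) {
    n <- length(x)
    abs(sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y)) / 2
  }
  a0 <- shoelace(corners$x, corners$y)
  a1 <- shoelace(final$x, final$y)
  expect_equal(a1, a0, tolerance = 0.01)
})

test_that("exit is detected at the hourly log matching hand integration", {
  dom <- tiny_domain()  # footprint 0..10 km
  f <- uniform_field(dom, 36, 0)  # 1.296 km/h eastward
  # release 6.5 km from the east edge: first hourly position past the edge
  # is hour 6 (6 x 1.296 = 7.78 km > 6.5; 5 x 1.296 = 6.48 < 6.5)
  tr <- track(f, data.frame(x = 3.5, y = 5), 0, dt = 0.1, horizon_h = 48)
  expect_equal(tr$summary$exit_time_h, 6)
  expect_equal(tr$summary$exit_reason, "left_footprint")

  # release in an edge cell moving outward: gone at the first hourly check
  tr2 <- track(f, data.frame(x = 9.5, y = 5), 0, dt = 0.1, horizon_h = 48)
  expect_equal(tr2$summary$exit_time_h, 1)
})

test_that("an interior orbit never exits and is censored at the horizon", {
  dom <- build_domain(domain_config(nx = 20, ny = 20))
  f <- rotation_field(dom, period_h = 12, nt = 49)
  tr <- track(f, data.frame(x = 10, y = 13), 0, dt = 0.1, horizon_h = 48)
  expect_true(tr$summary$censored)
  expect_equal(tr$summary$exit_reason, "record_end")
  expect_equal(nrow(tr$positions), 49)  # hourly log release..horizon
})

test_that("release outside the footprint is rejected", {
  dom <- tiny_domain()
  f <- uniform_field(dom, 10, 0)
  expect_error(track(f, data.frame(x = 20, y = 5), 0), "inside the footprint")
})

test_that("persistent data gaps terminate a particle as a gap exit", {
  dom <- tiny_domain()
  f <- uniform_field(dom, 36, 0, nt = 49)
  f$mask[, , 3:49] <- FALSE  # data disappear after hour 1
  tr <- track(f, data.frame(x = 2.5, y = 5), 0, dt = 0.1, horizon_h = 24)
  expect_equal(tr$summary$exit_reason, "entered_persistent_gap")
  # held position for the gap hours, then terminated after > 3 of them
  expect_equal(tr$summary$exit_time_h, 5)
})

test_that("trajectories are identical under re-run", {
  dom <- tiny_domain()
  cfg <- synth_config(duration_days = 2, seed = 31,
                      tidal = default_tidal_amplitudes()[0, ],
                      tidal_fraction = NULL)
  f <- synth_currents(cfg, dom)
  rp <- data.frame(x = c(2.5, 5.5), y = c(2.5, 5.5))
  t1 <- track(f, rp, 0, dt = 0.1, horizon_h = 24)
  t2 <- track(f, rp, 0, dt = 0.1, horizon_h = 24)
  expect_identical(t1$positions, t2$positions)
  expect_identical(t1$summary, t2$summary)
})
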