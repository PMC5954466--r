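wind_tbl <- function(speed, dir, n = length(speed), start = T0) {
  tibble::tibble(
    time = start + 900 * (seq_len(n) - 1),
    speed_ms = rep_len(speed, n),
    dir_deg = rep_len(dir, n)
  )
}

test_that("merging winds vector-averages the two stations", {
  a <- wind_tbl(5, 90, n = 8)
  expect_equal(merge_winds(a, a)$speed_ms, a$speed_ms)
  expect_equal(merge_winds(a, a)$dir_deg, a$dir_deg)

  # same direction, speeds 4 and 6 -> 5
  m <- merge_winds(wind_tbl(4, 45, n = 4), wind_tbl(6, 45, n = 4))
  expect_equal(m$speed_ms, rep(5, 4))
  expect_equal(m$dir_deg, rep(45, 4))

  # equal speeds, opposite directions -> zero speed, undefined direction
  m2 <- merge_winds(wind_tbl(5, 0, n = 4), wind_tbl(5, 180, n = 4))
  expect_equal(m2$speed_ms, rep(0, 4), tolerance = 1e-12)
  expect_true(all(is.na(m2$dir_deg)))

  expect_error(
    merge_winds(wind_tbl(5, 0, n = 4),
                wind_tbl(5, 0, n = 4, start = T0 + 86400)),
    "overlap"
  )
})

test_that("scalar-speed merging is available as a sensitivity option", {
  m <- merge_winds(wind_tbl(4, 0, n = 4), wind_tbl(6, 90, n = 4),
                   scalar_speed = TRUE)
  expect_equal(m$speed_ms, rep(5, 4))
})

test_that("window means are inclusive at both ends on the 15-min grid", {
  w <- wind_tbl(5, 270, n = 96 * 3 + 1)
  expect_equal(window_mean(w, T0, 1)$mean_speed_ms, 5)

  # linear ramp 0..10 over one day: mean 5 within one-sample discretisation
  n <- 97
  ramp <- tibble::tibble(
    time = T0 + 900 * (seq_len(n) - 1),
    speed_ms = seq(0, 10, length.out = n),
    dir_deg = 270
  )
  expect_equal(window_mean(ramp, T0, 1)$mean_speed_ms, 5, tolerance = 10 / n)

  # 1.9-day window: last included sample at or before t0 + 45.6 h
  wm <- window_mean(w, T0, 1.9)
  expect_equal(wm$n_samples, floor(45.6 * 4) + 1)  # samples at 0..45.5 h

  expect_error(window_mean(w, T0, 30), "beyond")
})

test_that("circular direction averaging respects wraparound", {
  w <- wind_tbl(c(5, 5), c(350, 10), n = 2)
  expect_equal(window_mean(w, T0, 900 / 86400)$mean_dir_deg, 0)
})

test_that("major-axis regression recovers a noiseless line and its symmetry", {
  x <- seq(1, 10, by = 0.5)
  y <- -0.18 * x + 3
  f <- major_axis_fit(x, y)
  expect_equal(f$slope, -0.18, tolerance = 1e-12)
  expect_equal(f$intercept, 3, tolerance = 1e-12)
  expect_equal(f$r2, 1, tolerance = 1e-12)
  expect_true(f$ci_lo <= f$slope && f$slope <= f$ci_hi)

  # swapping x and y transforms the slope to its reciprocal
  set.seed(1)
  xs <- rnorm(40)
  ys <- 0.7 * xs + rnorm(40, sd = 0.4)
  f1 <- major_axis_fit(xs, ys)
  f2 <- major_axis_fit(ys, xs)
  expect_equal(f2$slope, 1 / f1$slope, tolerance = 1e-10)
})

test_that("with equal variances the major axis bisects where OLS attenuates", {
  set.seed(3)
  x <- rnorm(60)
  y0 <- x + rnorm(60, sd = 0.5)
  # symmetrise the sample so s_xx = s_yy exactly
  xx <- c(x, y0)
  yy <- c(y0, x)
  f <- major_axis_fit(xx, yy)
  expect_equal(f$slope, 1, tolerance = 1e-10)
  ols <- stats::cov(xx, yy) / stats::var(xx)
  expect_lt(ols, 1)
})

test_that("major-axis slope matches the leading covariance eigenvector", {
  set.seed(9)
  x <- runif(80, 0, 10)
  y <- 2 - 0.4 * x + rnorm(80, sd = 0.8)
  f <- major_axis_fit(x, y)
  ev <- eigen(stats::cov(cbind(x, y)))$vectors[, 1]
  expect_equal(f$slope, ev[2] / ev[1], tolerance = 1e-10)
})

test_that("degenerate bivariate samples are rejected", {
  expect_error(major_axis_fit(c(1, 2), c(1, 2)), "at least 3")
  expect_error(major_axis_fit(rep(1, 5), rnorm(5)), "vary")
  # circular scatter: s_xy = 0 with s_xx = s_yy
  x <- c(1, -1, 0, 0)
  y <- c(0, 0, 1, -1)
  expect_error(major_axis_fit(x, y), "undefined")
})

test_that("the slope interval covers the axis under symmetric errors", {
  set.seed(101)
  cover <- replicate(60, {
    xt <- runif(50, 2, 12)
    x <- xt + rnorm(50, sd = 0.5)
    y <- 3 - 0.5 * xt + rnorm(50, sd = 0.5)
    f <- major_axis_fit(x, y)
    f$ci_lo <= -0.5 && -0.5 <= f$ci_hi
  })
  expect_gte(mean(cover), 0.85)
})

test_that("speed and direction binning follow the centred half-open rules", {
  pairs <- tibble::tibble(speed = c(7.4, 7.5, 0.2, 3.0),
                          residence_days = c(1, 2, 3, 4))
  b <- binned_distributions(pairs, "speed")
  expect_equal(b$bin[b$n > 0 & sapply(b$values, function(v) 1 %in% v)], 7)
  expect_equal(b$bin[sapply(b$values, function(v) 2 %in% v)], 8)
  expect_equal(b$bin[sapply(b$values, function(v) 3 %in% v)], 0)
  expect_equal(sum(b$n), 4)  # every sample in exactly one bin

  dirs <- tibble::tibble(direction = c(359, 14.9, 15, 345.1),
                         residence_days = 1:4)
  d <- binned_distributions(dirs, "direction")
  expect_equal(d$bin[sapply(d$values, function(v) 1 %in% v)], 0)   # wraparound
  expect_equal(d$bin[sapply(d$values, function(v) 2 %in% v)], 0)
  expect_equal(d$bin[sapply(d$values, function(v) 3 %in% v)], 30)  # half-open
  expect_equal(d$bin[sapply(d$values, function(v) 4 %in% v)], 0)
})

test_that("Tukey comparisons separate distinct groups and exclude tiny ones", {
  set.seed(4)
  mk <- function(bin, m, n, sd = 0.05) {
    tibble::tibble(speed = bin + runif(n, -0.4, 0.4),
                   residence_days = stats::rnorm(n, m, sd))
  }
  b <- binned_distributions(
    dplyr::bind_rows(mk(3, 1, 20), mk(6, 3, 20)), "speed"
  )
  tk <- tukey_pairwise(b)
  expect_lt(tk$comparisons$p_adj, 0.01)

  # two groups with identical member values: adjusted p ~ 1
  v <- stats::rnorm(15, 2, 0.5)
  same <- binned_distributions(
    tibble::tibble(speed = c(rep(3, 15), rep(6, 15)),
                   residence_days = c(v, v)),
    "speed"
  )
  expect_gt(tukey_pairwise(same)$comparisons$p_adj, 0.99)

  # three groups, one of size 1: excluded, one retained pair
  three <- binned_distributions(
    dplyr::bind_rows(mk(3, 1, 10), mk(6, 3, 10), mk(9, 2, 1)), "speed"
  )
  tk3 <- tukey_pairwise(three)
  expect_equal(nrow(tk3$comparisons), 1)
  expect_equal(tk3$excluded_bins, 9)

  expect_error(tukey_pairwise(binned_distributions(mk(3, 1, 1), "speed")),
               "fewer than two")
})

test_that("tidy and glance methods expose the regression results", {
  x <- seq(1, 10, 0.5)
  set.seed(2)
  f <- major_axis_fit(x, 2 - 0.3 * x + rnorm(length(x), sd = 0.2))
  td <- tidy(f)
  expect_equal(td$term, c("intercept", "slope"))
  gl <- glance(f)
  expect_true(all(c("slope", "ci_lo", "ci_hi", "r.squared", "p.value", "n")
                  %in% names(gl)))
  expect_s3_class(autoplot(f), "ggplot")
})
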