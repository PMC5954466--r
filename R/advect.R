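# Bilinear-in-space, linear-in-time velocity sampling, vectorised over
# particles. Returns km/h components; NA where no valid data supports the
# interpolation (all four neighbours masked out at both bracketing hours).

interp_hour <- function(field, x, y, it) {
  nx <- dim(field$u)[1]
  ny <- dim(field$u)[2]
  s <- field$domain$spacing
  # node (cell-centre) coordinates: (i - 0.5) s; fractional node index,
  # clamped to the node hull so a particle crossing the footprint edge keeps
  # a (edge-extrapolated) velocity until the hourly exit check catches it
  fi <- pmin(pmax(x / s + 0.5, 1), nx)
  fj <- pmin(pmax(y / s + 0.5, 1), ny)
  i0 <- pmin(floor(fi), nx - 1L)
  j0 <- pmin(floor(fj), ny - 1L)
  wx <- fi - i0
  wy <- fj - j0

  np <- length(x)
  usum <- numeric(np)
  vsum <- numeric(np)
  wsum <- numeric(np)
  base_t <- (it - 1L) * nx * ny
  for (corner in 1:4) {
    ii <- i0 + (corner == 2L | corner == 4L)
    jj <- j0 + (corner >= 3L)
    w <- (if (corner %% 2L == 1L) 1 - wx else wx) *
      (if (corner <= 2L) 1 - wy else wy)
    ok <- is.finite(ii) & is.finite(jj)  # NA positions sample nothing
    idx <- (jj - 1L) * nx + ii + base_t
    idx_ok <- idx[ok]
    valid <- ok
    valid[ok] <- field$mask[idx_ok]
    wv <- w * valid
    usum[valid] <- usum[valid] + wv[valid] * field$u[idx[valid]]
    vsum[valid] <- vsum[valid] + wv[valid] * field$v[idx[valid]]
    wsum <- wsum + wv
  }
  none <- wsum <= 0
  u <- ifelse(none, NA_real_, usum / wsum)
  v <- ifelse(none, NA_real_, vsum / wsum)
  cbind(u, v)
}

# velocity in km/h at arbitrary positions and one scalar time (hours since
# field start)
velocity_kmh <- function(field, x, y, t_h) {
  nt <- field$nt
  if (t_h < 0 || t_h > nt - 1) {
    rlang::abort("requested time lies outside the field record")
  }
  i0 <- min(floor(t_h), nt - 2)
  frac <- t_h - i0
  a <- interp_hour(field, x, y, i0 + 1L)
  if (frac == 0) {
    uv <- a
  } else {
    b <- interp_hour(field, x, y, i0 + 2L)
    # linear in time between the hourly maps; if one hour has no valid
    # support, fall back to the other
    uv <- (1 - frac) * a + frac * b
    only_a <- is.na(b[, 1]) & !is.na(a[, 1])
    only_b <- is.na(a[, 1]) & !is.na(b[, 1])
    uv[only_a, ] <- a[only_a, ]
    uv[only_b, ] <- b[only_b, ]
  }
  uv * CMS_TO_KMH
}

#' Sample the velocity field at points
#'
#' Interpolates the gridded currents bilinearly among the four grid nodes
#' surrounding each point, with weights renormalised over the nodes holding
#' valid data, and linearly in time between the bracketing hourly maps. If no
#' valid node supports a point at either bracketing hour the velocity is
#' `NA` (a data-gap signal). Points beyond the outermost nodes are clamped to
#' the node hull (edge-value extrapolation), so a particle crossing the
#' footprint edge keeps a finite velocity until the next hourly exit check.
#'
#' @param field A `velocity_field`.
#' @param points Data frame with `x`, `y` (km).
#' @param time POSIXct time, or numeric hours since the field start.
#' @return Tibble `x`, `y`, `u`, `v` in cm s^-1 (`NA` in gaps).
#' @export
sample_velocity <- function(field, points, time) {
  if (is.matrix(points)) points <- as.data.frame(points)
  t_h <- field_hour(field, time)
  uv <- velocity_kmh(field, points$x, points$y, t_h) / CMS_TO_KMH
  tibble::tibble(x = points$x, y = points$y,
                 u = as.numeric(uv[, 1]), v = as.numeric(uv[, 2]))
}

# One classical RK4 update for a batch of particles; rows with any NA stage
# come back NA (gap signal to the caller).
rk4_batch <- function(field, x, y, t_h, dt) {
  k1 <- velocity_kmh(field, x, y, t_h)
  k2 <- velocity_kmh(field, x + dt / 2 * k1[, 1], y + dt / 2 * k1[, 2], t_h + dt / 2)
  k3 <- velocity_kmh(field, x + dt / 2 * k2[, 1], y + dt / 2 * k2[, 2], t_h + dt / 2)
  k4 <- velocity_kmh(field, x + dt * k3[, 1], y + dt * k3[, 2], t_h + dt)
  cbind(
    x + dt / 6 * (k1[, 1] + 2 * k2[, 1] + 2 * k3[, 1] + k4[, 1]),
    y + dt / 6 * (k1[, 2] + 2 * k2[, 2] + 2 * k3[, 2] + k4[, 2])
  )
}

#' Advance a position by one Runge-Kutta step
#'
#' Classical fourth-order Runge-Kutta update of a particle position through
#' the space-time-interpolated currents. Velocities are converted internally
#' from cm s^-1 to km h^-1 (1 cm s^-1 = 0.036 km h^-1). If any of the four
#' stage evaluations lands where no velocity is sampleable the result is
#' `NA`, signalling exit-by-gap to the caller.
#'
#' @param field A `velocity_field`.
#' @param position Numeric `c(x, y)` km.
#' @param time POSIXct or hours since field start.
#' @param dt Step in hours (> 0).
#' @return Numeric `c(x, y)` after the step (`NA` on gap).
#' @export
rk4_step <- function(field, position, time, dt) {
  stopifnot(dt > 0)
  t_h <- field_hour(field, time)
  out <- rk4_batch(field, position[1], position[2], t_h, dt)
  c(x = unname(out[1, 1]), y = unname(out[1, 2]))
}

# Track a cohort of particles released together. Returns hourly positions and
# exit bookkeeping. Exit checks happen at hourly log points only; a particle
# whose RK4 stages hit a data gap holds position for that hour, and after
# more than `max_gap_h` consecutive gap-hours it terminates as
# `entered_persistent_gap`.
track_cohort <- function(field, x0, y0, release_h, dt = 0.1,
                         horizon_h = 240, max_gap_h = 3,
                         keep_positions = TRUE) {
  np <- length(x0)
  nt <- field$nt
  last_h <- min(release_h + horizon_h, nt - 1)
  n_hours <- max(0, floor(last_h - release_h))
  nsub <- max(1L, round(1 / dt))
  dt <- 1 / nsub

  x <- x0
  y <- y0
  active <- rep(TRUE, np)
  gap_streak <- integer(np)
  exit_time <- rep(NA_real_, np)
  exit_reason <- rep(NA_character_, np)
  pos <- if (keep_positions) {
    array(NA_real_, c(np, 2, n_hours + 1))
  } else NULL
  if (keep_positions && n_hours >= 0) {
    pos[, 1, 1] <- x
    pos[, 2, 1] <- y
  }

  loc0 <- in_footprint(x, y, field$domain)
  if (!all(loc0)) rlang::abort("all release positions must lie inside the footprint")

  if (n_hours > 0) {
    for (h in seq_len(n_hours)) {
      idx <- which(active)
      if (!length(idx)) break
      xa <- x[idx]
      ya <- y[idx]
      gap_hit <- rep(FALSE, length(idx))
      t0 <- release_h + (h - 1)
      for (ss in seq_len(nsub)) {
        stepped <- rk4_batch(field, xa, ya, t0 + (ss - 1) * dt, dt)
        bad <- !is.finite(stepped[, 1]) | !is.finite(stepped[, 2])
        gap_hit <- gap_hit | bad
        xa[!bad] <- stepped[!bad, 1]
        ya[!bad] <- stepped[!bad, 2]
        if (all(gap_hit)) break
      }
      # particles that hit a gap hold position this hour
      xa[gap_hit] <- x[idx][gap_hit]
      ya[gap_hit] <- y[idx][gap_hit]
      x[idx] <- xa
      y[idx] <- ya
      gap_streak[idx] <- ifelse(gap_hit, gap_streak[idx] + 1L, 0L)

      if (keep_positions) {
        pos[idx, 1, h + 1] <- xa
        pos[idx, 2, h + 1] <- ya
      }

      outside <- !in_footprint(xa, ya, field$domain)
      gone_gap <- gap_streak[idx] > max_gap_h
      exiting <- outside | gone_gap
      if (any(exiting)) {
        who <- idx[exiting]
        exit_time[who] <- h
        exit_reason[who] <- ifelse(outside[exiting], "left_footprint",
                                   "entered_persistent_gap")
        active[who] <- FALSE
      }
    }
  }
  censored <- is.na(exit_time)
  exit_reason[censored] <- "record_end"
  list(
    x = x, y = y,
    exit_time_h = exit_time, censored = censored, exit_reason = exit_reason,
    positions = pos, release_h = release_h, n_hours = n_hours
  )
}

#' Track particles through the velocity field
#'
#' Releases one passive particle per row of `releases` at `release_time` and
#' advects each with fourth-order Runge-Kutta integration (internal step
#' `dt`), logging positions hourly until the first hourly check finds the
#' particle outside the data footprint, until persistent data gaps strand it
#' (more than `max_gap_h` consecutive hours with no sampleable velocity,
#' counted as having left), or until `horizon_h`/record end (censored).
#'
#' @param field A `velocity_field`.
#' @param releases Data frame with release positions `x`, `y` (km), all
#'   inside the footprint.
#' @param release_time POSIXct or hours since field start.
#' @param dt Integrator step, hours.
#' @param horizon_h Maximum tracked duration, hours.
#' @param max_gap_h Consecutive gap-hours tolerated before termination.
#' @return A `trajectory_set`: `summary` tibble (one row per particle:
#'   `particle_id`, `x0`, `y0`, `exit_time_h`, `censored`, `exit_reason`)
#'   and `positions` tibble in long form (`particle_id`, `hour`, `time`,
#'   `x`, `y`).
#' @export
track <- function(field, releases, release_time, dt = 0.1,
                  horizon_h = 240, max_gap_h = 3) {
  if (is.matrix(releases)) releases <- as.data.frame(releases)
  release_h <- field_hour(field, release_time)
  res <- track_cohort(field, releases$x, releases$y, release_h,
                      dt = dt, horizon_h = horizon_h, max_gap_h = max_gap_h)
  np <- nrow(releases)
  hours <- 0:res$n_hours
  pos_tbl <- tibble::tibble(
    particle_id = rep(seq_len(np), times = length(hours)),
    hour = rep(hours, each = np),
    x = as.vector(res$positions[, 1, ]),
    y = as.vector(res$positions[, 2, ])
  ) |>
    dplyr::filter(is.finite(.data$x)) |>
    dplyr::mutate(time = field$start + 3600 * (release_h + .data$hour),
                  .after = "hour") |>
    dplyr::arrange(.data$particle_id, .data$hour)
  structure(
    list(
      summary = tibble::tibble(
        particle_id = seq_len(np),
        x0 = releases$x, y0 = releases$y,
        exit_time_h = res$exit_time_h,
        censored = res$censored,
        exit_reason = res$exit_reason
      ),
      positions = pos_tbl,
      release_time = field$start + 3600 * release_h
    ),
    class = "trajectory_set"
  )
}

#' @export
print.trajectory_set <- function(x, ...) {
  cat(sprintf(
    "<trajectory_set> %d particles released %s: %d exited, %d censored\n",
    nrow(x$summary), format(x$release_time, "%Y-%m-%d %H:%M"),
    sum(!x$summary$censored), sum(x$summary$censored)
  ))
  invisible(x)
}
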