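#' Merge two station wind series
#'
#' Vector-averages two wind series sample by sample on their common 15-minute
#' timestamps: speeds and directions are converted to velocity components,
#' the components averaged, and the merged speed/direction read back from the
#' mean vector. With equal and opposite winds the mean vector vanishes and
#' the merged direction is undefined (`NA`). Set `scalar_speed = TRUE` to
#' instead average the two speed scalars (direction still from the mean
#' vector), for sensitivity checks.
#'
#' @param a,b Wind tibbles (`time`, `speed_ms`, `dir_deg`), e.g. one station
#'   each from [synth_winds()].
#' @param scalar_speed Average speeds as scalars instead of as vectors.
#' @return Merged wind tibble (`time`, `speed_ms`, `dir_deg`) on the
#'   intersection of the two time grids.
#' @export
merge_winds <- function(a, b, scalar_speed = FALSE) {
  common <- intersect(a$time, b$time)
  if (!length(common)) rlang::abort("wind series do not overlap in time")
  a <- a[match(common, a$time), ]
  b <- b[match(common, b$time), ]
  ua <- wind_to_uv(a$speed_ms, a$dir_deg)
  ub <- wind_to_uv(b$speed_ms, b$dir_deg)
  mu <- (ua[, 1] + ub[, 1]) / 2
  mv <- (ua[, 2] + ub[, 2]) / 2
  sd_ <- uv_to_wind(mu, mv)
  speed <- if (scalar_speed) (a$speed_ms + b$speed_ms) / 2 else sd_[, "speed"]
  tibble::tibble(
    time = as.POSIXct(common, tz = "UTC",
                      origin = as.POSIXct("1970-01-01", tz = "UTC")),
    speed_ms = speed,
    dir_deg = sd_[, "dir"]
  )
}

#' Average a wind series over a residence window
#'
#' Summarises the wind felt by a particle cohort: all samples with
#' `t0 <= t <= t0 + duration` (both ends inclusive at the 15-minute cadence)
#' contribute. Speed is the arithmetic mean of the sampled speeds; direction
#' is the circular mean of unit vectors pointing in the "from" direction.
#'
#' @param wind Merged wind tibble (`time`, `speed_ms`, `dir_deg`).
#' @param t0 Window start (release time, POSIXct).
#' @param duration_days Window length in days (the cohort's residence time).
#' @return One-row tibble: `mean_speed_ms`, `mean_dir_deg`, `sd_speed_ms`,
#'   `n_samples`.
#' @export
window_mean <- function(wind, t0, duration_days) {
  t0 <- as.POSIXct(t0, tz = "UTC")
  t1 <- t0 + duration_days * 86400
  if (t0 < min(wind$time) || t1 > max(wind$time)) {
    rlang::abort("averaging window extends beyond the wind record")
  }
  sel <- wind$time >= t0 & wind$time <= t1
  sp <- wind$speed_ms[sel]
  dd <- wind$dir_deg[sel]
  dd <- dd[!is.na(dd)]
  mdir <- if (length(dd)) {
    (atan2(mean(sin(dd * pi / 180)), mean(cos(dd * pi / 180))) * 180 / pi) %% 360
  } else NA_real_
  if (isTRUE(abs(mdir - 360) < 1e-9)) mdir <- 0
  tibble::tibble(
    mean_speed_ms = mean(sp),
    mean_dir_deg = mdir,
    sd_speed_ms = stats::sd(sp),
    n_samples = length(sp)
  )
}

#' Model-II major-axis regression
#'
#' Fits the major axis of the bivariate sample — the line minimising
#' perpendicular distances — which is the appropriate model-II regression
#' when both variables carry error, as wind speed and residence time both do.
#' The slope is
#' \deqn{b = \frac{s_{yy} - s_{xx} + \sqrt{(s_{yy}-s_{xx})^2 + 4 s_{xy}^2}}{2 s_{xy}}}
#' with intercept \eqn{\bar y - b \bar x}. The slope confidence interval is
#' the closed-form interval from the sampling distribution of the major-axis
#' angle (via the eigenvalues of the covariance matrix); `r2` is the squared
#' Pearson correlation and `p` its correlation test p-value.
#'
#' @param x,y Numeric vectors (e.g. window-mean wind speed in m s^-1 and
#'   residence time in days).
#' @param conf Confidence level for the slope interval.
#' @return An object of class `ma_fit`; see [tidy.ma_fit()] and
#'   [glance.ma_fit()].
#' @examples
#' set.seed(1)
#' x <- runif(40, 2, 12)
#' y <- 3 - 0.18 * x + rnorm(40, sd = 0.3)
#' major_axis_fit(x, y)
#' @export
major_axis_fit <- function(x, y, conf = 0.95) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 3) rlang::abort("major-axis regression needs at least 3 points")
  sxx <- stats::var(x)
  syy <- stats::var(y)
  sxy <- stats::cov(x, y)
  if (sxx == 0 || syy == 0) rlang::abort("x and y must both vary")
  if (sxy == 0 && isTRUE(all.equal(sxx, syy))) {
    rlang::abort("major-axis slope undefined: circular scatter (s_xy = 0, s_xx = s_yy)")
  }
  slope <- if (sxy == 0) {
    if (syy > sxx) Inf else 0
  } else {
    (syy - sxx + sqrt((syy - sxx)^2 + 4 * sxy^2)) / (2 * sxy)
  }
  intercept <- mean(y) - slope * mean(x)

  # eigenvalues of the sample covariance matrix
  tr <- sxx + syy
  det_ <- sxx * syy - sxy^2
  disc <- sqrt(max(0, tr^2 / 4 - det_))
  l1 <- tr / 2 + disc
  l2 <- tr / 2 - disc

  # angular CI of the major axis (Jolicoeur): the axis angle theta has
  # H = F_{1,n-2} * l1*l2 / ((l1-l2)^2 (n-2)); CI = tan(theta +/- phi),
  # phi = asin(sqrt(... )) / 2 on the doubled angle
  if (l2 <= 0 || l1 == l2) {
    ci <- c(slope, slope)  # degenerate: perfectly collinear sample
  } else {
    Fq <- stats::qf(conf, 1, n - 2)
    H <- Fq * l1 * l2 / ((l1 - l2)^2 * (n - 2))
    if (2 * sqrt(H) >= 1) {
      ci <- c(-Inf, Inf)  # axis orientation not resolved at this confidence
    } else {
      theta <- atan(slope)
      phi <- 0.5 * asin(2 * sqrt(H))
      ci <- sort(tan(c(theta - phi, theta + phi)))
    }
  }

  ct <- stats::cor.test(x, y)
  structure(
    list(slope = slope, intercept = intercept,
         ci_lo = ci[1], ci_hi = ci[2], conf = conf,
         r2 = unname(ct$estimate)^2, p = ct$p.value, n = n,
         data = tibble::tibble(x = x, y = y)),
    class = "ma_fit"
  )
}

#' @export
print.ma_fit <- function(x, ...) {
  cat(sprintf(
    "<ma_fit> major-axis slope %.4f [%.4f, %.4f] (%.0f%% CI), intercept %.4f\n  r2 = %.3f, p = %.3g, n = %d\n",
    x$slope, x$ci_lo, x$ci_hi, 100 * x$conf, x$intercept, x$r2, x$p, x$n
  ))
  invisible(x)
}

#' Bin wind statistics against residence times
#'
#' Groups paired (wind statistic, residence time) observations into centred
#' bins: speed mode uses 1 m s^-1 bins centred on integers (`[k-0.5, k+0.5)`)
#' and direction mode 30-degree bins centred on multiples of 30 with
#' wraparound at 360 (so 359 degrees falls in the 0-degree bin).
#'
#' @param pairs Tibble with a wind column (`speed` or `direction` per
#'   `mode`) and a `residence_days` column.
#' @param mode `"speed"` or `"direction"`.
#' @return Tibble with one row per occupied bin: `bin` (centre), `n`,
#'   `median`, `sd`, `min`, `max`, and a list-column `values`.
#' @export
binned_distributions <- function(pairs, mode = c("speed", "direction")) {
  mode <- match.arg(mode)
  if (!nrow(pairs)) rlang::abort("no observations to bin")
  if (mode == "speed") {
    key <- floor(pairs$speed + 0.5)
  } else {
    key <- (floor(pairs$direction / 30 + 0.5) * 30) %% 360
  }
  pairs |>
    dplyr::mutate(bin = key) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(
      n = dplyr::n(),
      median = stats::median(.data$residence_days),
      sd = stats::sd(.data$residence_days),
      min = min(.data$residence_days),
      max = max(.data$residence_days),
      values = list(.data$residence_days),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$bin)
}

#' Tukey pairwise comparisons across bins
#'
#' Tukey-Kramer honest-significant-difference comparisons of residence time
#' across wind bins (unequal group sizes supported). Bins with fewer than
#' `min_n` members carry too little information and are excluded and
#' reported.
#'
#' @param binned Output of [binned_distributions()] (needs `bin`, `values`).
#' @param min_n Minimum bin size to retain (default 2).
#' @return List with `comparisons` (tibble: `pair`, `diff`, `lwr`, `upr`,
#'   `p_adj`) and `excluded_bins` (numeric vector of bin centres dropped).
#' @export
tukey_pairwise <- function(binned, min_n = 2) {
  keep <- binned$n >= min_n
  excluded <- binned$bin[!keep]
  binned <- binned[keep, ]
  if (nrow(binned) < 2) {
    rlang::abort("fewer than two bins large enough for a Tukey comparison")
  }
  df <- tibble::tibble(
    bin = factor(rep(binned$bin, binned$n)),
    value = unlist(binned$values)
  )
  hsd <- stats::TukeyHSD(stats::aov(value ~ bin, data = df))$bin
  list(
    comparisons = tibble::tibble(
      pair = rownames(hsd),
      diff = hsd[, "diff"],
      lwr = hsd[, "lwr"],
      upr = hsd[, "upr"],
      p_adj = hsd[, "p adj"]
    ),
    excluded_bins = excluded
  )
}
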