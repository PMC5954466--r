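#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a major-axis regression
#'
#' @param x An `ma_fit`.
#' @param ... Unused.
#' @return One row per term (`intercept`, `slope`) with `estimate` and, for
#'   the slope, the confidence bounds.
#' @method tidy ma_fit
#' @export
tidy.ma_fit <- function(x, ...) {
  tibble::tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope),
    conf.low = c(NA, x$ci_lo),
    conf.high = c(NA, x$ci_hi)
  )
}

#' @rdname tidy.ma_fit
#' @method glance ma_fit
#' @export
glance.ma_fit <- function(x, ...) {
  tibble::tibble(
    slope = x$slope, intercept = x$intercept,
    ci_lo = x$ci_lo, ci_hi = x$ci_hi,
    r.squared = x$r2, p.value = x$p, n = x$n
  )
}

#' Tidy a tidal fit
#'
#' @param x A `tidal_fit`.
#' @param ... Unused.
#' @return The per-constituent table.
#' @method tidy tidal_fit
#' @export
tidy.tidal_fit <- function(x, ...) x$table

#' @rdname tidy.tidal_fit
#' @method glance tidal_fit
#' @export
glance.tidal_fit <- function(x, ...) {
  tibble::tibble(
    variance_explained = x$variance_explained,
    mean = x$mean,
    n_valid = x$n_valid,
    n_significant = sum(x$table$significant),
    n_constituents = nrow(x$table)
  )
}

#' Plot wind speed against residence time with the major-axis line
#'
#' @param object An `ma_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ma_fit
#' @export
autoplot.ma_fit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "firebrick") +
    ggplot2::labs(
      x = "window-mean wind speed (m s⁻¹)",
      y = "residence time (days)",
      subtitle = sprintf("major-axis slope %.3f [%.3f, %.3f], r² = %.2f",
                         object$slope, object$ci_lo, object$ci_hi, object$r2)
    ) +
    ggplot2::theme_minimal()
}

#' Plot trajectories over the domain
#'
#' @param object A `trajectory_set` from [track()].
#' @param ... Unused.
#' @return A ggplot of hourly particle paths with sub-region outlines.
#' @method autoplot trajectory_set
#' @export
autoplot.trajectory_set <- function(object, ...) {
  p <- ggplot2::ggplot(object$positions,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    group = .data$particle_id)) +
    ggplot2::geom_path(alpha = 0.3, linewidth = 0.3) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (km)", y = "y (km)") +
    ggplot2::theme_minimal()
  p
}

#' Plot residence-time series per region
#'
#' @param object A residence-records tibble ([residence_records()]).
#' @param ... Unused.
#' @return A ggplot time series faceted by region.
#' @export
plot_residence <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$release_time,
                               y = .data$residence_days)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(shape = .data$censored), size = 0.8) +
    ggplot2::facet_wrap(~region, ncol = 1) +
    ggplot2::labs(x = NULL, y = "residence time (days)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
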