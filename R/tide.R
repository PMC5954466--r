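#' Least-squares tidal harmonic fit of a scalar series
#'
#' Fits `y(t) = m + sum_k [ a_k cos(w_k t) + b_k sin(w_k t) ]` by ordinary
#' least squares on the evenly sampled series, dropping gap samples (`NA`)
#' from the normal equations. The mean term `m` is always estimated and is
#' never counted as tidal variance.
#'
#' Constituent significance is a family-wise screen: each constituent's
#' `(cos, sin)` coefficient pair is tested jointly (F test from the
#' coefficient covariance) at a Sidak-adjusted level across the constituent
#' list, so that under pure noise the whole list passes the screen with
#' probability `confidence`. The reported amplitude interval is the
#' amplitude plus/minus the joint confidence-ellipse radius at that adjusted
#' level (floored at zero); a constituent is significant exactly when this
#' interval excludes zero. Insignificant constituents are zeroed out of the
#' fitted tidal series.
#'
#' @param y Numeric series sampled at uniform steps; `NA` marks gaps.
#' @param t_h Sample times in hours (default `0, dt, 2 dt, ...` with
#'   `dt = 1`).
#' @param constituents Constituent table from [tidal_constituents()] (or any
#'   tibble with `constituent` and `omega_rad_h`).
#' @param confidence Family-wise confidence level for the screen.
#' @return A `tidal_fit`: `table` (per-constituent tibble), `mean`, `fitted`
#'   (significant tidal component, zero-mean basis), `residual`
#'   (`y - fitted`, the de-tided series), `variance_explained` (share of the
#'   raw variance about the mean carried by the fitted tidal component) and
#'   `n_valid`.
#' @examples
#' t <- 0:999
#' y <- 10 * cos(2 * pi / 12.4206 * t - 0.5)
#' fit <- harmonic_fit(y, t, tidal_constituents("M2"))
#' fit$table$amplitude
#' @export
harmonic_fit <- function(y, t_h = seq_along(y) - 1,
                         constituents = tidal_constituents(),
                         confidence = 0.95) {
  stopifnot(length(y) == length(t_h))
  om <- constituents$omega_rad_h
  nm <- constituents$constituent
  K <- length(om)
  valid <- is.finite(y)
  n <- sum(valid)
  p <- 1 + 2 * K
  if (n < p + 1) rlang::abort("too few valid samples for the requested constituent list")

  span <- diff(range(t_h[valid]))
  if (K) {
    fastest <- min(2 * pi / om)
    dt <- min(diff(sort(unique(t_h[valid]))))
    if (dt > fastest / 2) {
      rlang::warn("sampling coarser than half the fastest constituent period; fit is aliased")
    }
    slowest <- max(2 * pi / om)
    if (span < slowest) {
      rlang::warn("record shorter than one cycle of the slowest constituent (Rayleigh criterion violated)")
    }
  }

  # Rayleigh pair criterion: two constituents are unresolvable when their
  # frequency separation is under one cycle over the record span
  if (K >= 2) {
    d <- abs(outer(om, om, "-")) * span
    diag(d) <- Inf
    if (min(d) < 2 * pi) {
      ij <- which(d == min(d), arr.ind = TRUE)[1, ]
      rlang::abort(sprintf(
        "constituents %s and %s are unresolvable for this record length (Rayleigh criterion)",
        nm[ij[1]], nm[ij[2]]
      ))
    }
  }

  X <- matrix(1, length(t_h), p)
  for (k in seq_len(K)) {
    X[, 2 * k] <- cos(om[k] * t_h)
    X[, 2 * k + 1] <- sin(om[k] * t_h)
  }
  Xv <- X[valid, , drop = FALSE]
  yv <- y[valid]
  qrX <- qr(Xv)
  if (qrX$rank < p) {
    pair <- closest_frequency_pair(nm, om, span)
    rlang::abort(sprintf(
      "harmonic basis is rank-deficient for this record length; constituents %s and %s are unresolvable",
      pair[1], pair[2]
    ))
  }
  beta <- qr.coef(qrX, yv)
  res <- yv - Xv %*% beta
  dof <- n - p
  sigma2 <- sum(res^2) / dof
  XtXinv <- chol2inv(qr.R(qrX))
  cov_beta <- sigma2 * XtXinv

  alpha_sidak <- if (K > 0) 1 - confidence^(1 / K) else 1 - confidence
  rows <- lapply(seq_len(K), function(k) {
    idx <- c(2 * k, 2 * k + 1)
    a <- beta[idx[1]]
    b <- beta[idx[2]]
    A <- sqrt(a^2 + b^2)
    S <- cov_beta[idx, idx]
    # joint confidence-ellipse radius for the coefficient pair, mapped to
    # an amplitude half-width (worst-case direction of the ellipse)
    Fq <- stats::qf(1 - alpha_sidak, 2, dof)
    r <- sqrt(2 * Fq * max(eigen(S, symmetric = TRUE, only.values = TRUE)$values))
    tibble::tibble(
      constituent = nm[k], omega_rad_h = om[k],
      a = a, b = b,
      amplitude = A,
      phase_deg = (atan2(b, a) * 180 / pi) %% 360,
      ci_lo = max(0, A - r), ci_hi = A + r,
      # scale-aware floor keeps machine-precision residual amplitudes out
      significant = (A - r) > 0 && A > 1e-8 * stats::sd(yv)
    )
  })
  table <- dplyr::bind_rows(rows)

  fitted <- rep(0, length(y))
  if (K && any(table$significant)) {
    for (k in which(table$significant)) {
      fitted <- fitted + X[, 2 * k] * table$a[k] + X[, 2 * k + 1] * table$b[k]
    }
  }
  residual <- y - fitted
  ss_raw <- sum((yv - mean(yv))^2)
  fv <- fitted[valid]
  ve <- if (ss_raw > 0) sum((fv - mean(fv))^2) / ss_raw else 0

  structure(
    list(table = table, mean = unname(beta[1]), fitted = fitted,
         residual = residual, variance_explained = min(1, ve),
         n_valid = n, confidence = confidence),
    class = "tidal_fit"
  )
}

closest_frequency_pair <- function(nm, om, span) {
  if (length(om) < 2) return(c(nm[1], "(mean)"))
  d <- abs(outer(om, om, "-"))
  diag(d) <- Inf
  ij <- which(d == min(d), arr.ind = TRUE)[1, ]
  nm[ij]
}

#' @export
print.tidal_fit <- function(x, ...) {
  cat(sprintf("<tidal_fit> %d constituents, %d valid samples, %.1f%% of variance tidal\n",
              nrow(x$table), x$n_valid, 100 * x$variance_explained))
  print(x$table)
  invisible(x)
}

#' De-tide a velocity-field series
#'
#' Applies [harmonic_fit()] independently to each grid cell's `u` and `v`
#' series and subtracts the significant tidal component, retaining all
#' non-tidal variability (the de-tided velocity is raw minus tidal fit, so
#' the mean flow survives). Cells with fewer valid samples than
#' `min_valid` are passed through unfitted and flagged.
#'
#' @param field A `velocity_field`.
#' @param constituents Constituent table, default [tidal_constituents()].
#' @param confidence Significance level passed to [harmonic_fit()].
#' @param min_valid Minimum valid samples per cell series to attempt a fit
#'   (default ten times the number of regression coefficients).
#' @return A `detide_result`: `detided` and `tidal` `velocity_field`s (raw =
#'   tidal + detided exactly wherever observed), pooled
#'   `variance_explained` (tidal-fit sum of squares over raw sum of squares
#'   about per-cell means, across all valid cell-hours of both components),
#'   and `cells` (tibble flagging unfitted cells).
#' @export
detide_field <- function(field, constituents = tidal_constituents(),
                         confidence = 0.95, min_valid = NULL) {
  stopifnot(inherits(field, "velocity_field"))
  p <- 1 + 2 * nrow(constituents)
  if (is.null(min_valid)) min_valid <- 10 * p
  nx <- dim(field$u)[1]
  ny <- dim(field$u)[2]
  nt <- field$nt
  t_h <- seq_len(nt) - 1

  um <- matrix(field$u, nx * ny, nt)
  vm <- matrix(field$v, nx * ny, nt)
  mk <- matrix(field$mask, nx * ny, nt)
  tidal_u <- matrix(0, nx * ny, nt)
  tidal_v <- matrix(0, nx * ny, nt)
  ss_fit <- 0
  ss_raw <- 0
  fitted_flag <- rep(FALSE, nx * ny)

  for (c_ in seq_len(nx * ny)) {
    ok <- mk[c_, ]
    if (sum(ok) < min_valid) next
    for (comp in 1:2) {
      yy <- if (comp == 1) um[c_, ] else vm[c_, ]
      yy[!ok] <- NA
      fit <- harmonic_fit(yy, t_h, constituents, confidence)
      if (comp == 1) tidal_u[c_, ] <- fit$fitted else tidal_v[c_, ] <- fit$fitted
      yv <- yy[ok]
      fv <- fit$fitted[ok]
      ss_fit <- ss_fit + sum((fv - mean(fv))^2)
      ss_raw <- ss_raw + sum((yv - mean(yv))^2)
    }
    fitted_flag[c_] <- TRUE
  }

  dims <- c(nx, ny, nt)
  detided <- velocity_field(
    array(as.vector(um - tidal_u), dims),
    array(as.vector(vm - tidal_v), dims),
    field$domain, start = field$start, mask = field$mask
  )
  tidal <- velocity_field(
    array(as.vector(tidal_u), dims), array(as.vector(tidal_v), dims),
    field$domain, start = field$start, mask = field$mask
  )
  centres <- grid_centres(field$domain)
  structure(
    list(
      detided = detided, tidal = tidal,
      variance_explained = if (ss_raw > 0) ss_fit / ss_raw else 0,
      cells = tibble::tibble(x = centres[, 1], y = centres[, 2],
                             fitted = fitted_flag)
    ),
    class = "detide_result"
  )
}

#' @export
print.detide_result <- function(x, ...) {
  cat(sprintf(
    "<detide_result> pooled tidal variance explained: %.2f%% (%d of %d cells fitted)\n",
    100 * x$variance_explained, sum(x$cells$fitted), nrow(x$cells)
  ))
  invisible(x)
}

#' Extract a time window of a velocity-field series
#'
#' Subsets whole hourly maps between two times (inclusive). Because the
#' de-tided residual is computed per sample, extracting an analysis window
#' after de-tiding equals de-tiding and then extracting, provided the fit
#' window itself is unchanged — supporting a fit window longer than the
#' analysis window.
#'
#' @param field A `velocity_field`.
#' @param from,to POSIXct bounds.
#' @return A `velocity_field` covering the window.
#' @export
field_window <- function(field, from, to) {
  tt <- field_times(field)
  sel <- tt >= as.POSIXct(from, tz = "UTC") & tt <= as.POSIXct(to, tz = "UTC")
  if (!any(sel)) rlang::abort("window contains no field times")
  velocity_field(field$u[, , sel, drop = FALSE], field$v[, , sel, drop = FALSE],
                 field$domain, start = tt[sel][1],
                 mask = field$mask[, , sel, drop = FALSE])
}
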