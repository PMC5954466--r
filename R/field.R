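#' Hourly gridded velocity-field series
#'
#' Container for hourly maps of surface velocity components on the domain
#' grid: `u` (eastward) and `v` (northward) in cm s^-1 as `nx x ny x nt`
#' arrays, plus a per-cell-hour logical coverage `mask` (`TRUE` = valid
#' observation). Values at masked-out cell-hours are retained but ignored by
#' every consumer. Internal time is hours since `start`.
#'
#' @param u,v Numeric arrays `nx x ny x nt`, cm s^-1.
#' @param mask Logical array of the same dimension (default all valid).
#' @param domain A `drift_domain`.
#' @param start POSIXct of the first map.
#' @return A `velocity_field` object.
#' @export
velocity_field <- function(u, v, domain, start, mask = NULL) {
  stopifnot(inherits(domain, "drift_domain"))
  du <- dim(u)
  stopifnot(length(du) == 3, identical(du, dim(v)),
            du[1] == domain$nx, du[2] == domain$ny)
  if (is.null(mask)) mask <- array(TRUE, du)
  stopifnot(identical(dim(mask), du))
  if (any(!is.finite(u[mask])) || any(!is.finite(v[mask]))) {
    rlang::abort("non-finite velocity at a valid (unmasked) cell-hour")
  }
  structure(
    list(u = u, v = v, mask = mask, domain = domain,
         start = as.POSIXct(start, tz = "UTC"), nt = du[3]),
    class = "velocity_field"
  )
}

#' @export
print.velocity_field <- function(x, ...) {
  cat(sprintf(
    "<velocity_field> %d x %d grid, %d hourly maps from %s (coverage %.1f%%)\n",
    dim(x$u)[1], dim(x$u)[2], x$nt, format(x$start, "%Y-%m-%d %H:%M"),
    100 * mean(x$mask)
  ))
  invisible(x)
}

#' Hourly map times of a velocity-field series
#'
#' @param field A `velocity_field`.
#' @return POSIXct vector, one element per hourly map.
#' @export
field_times <- function(field) field$start + 3600 * (seq_len(field$nt) - 1)

# hours since field start for a POSIXct (or numeric hours passed through)
field_hour <- function(field, time) {
  if (inherits(time, "POSIXt")) {
    as.numeric(difftime(as.POSIXct(time, tz = "UTC"), field$start, units = "hours"))
  } else {
    as.numeric(time)
  }
}

#' @method as_tibble velocity_field
#' @export
as_tibble.velocity_field <- function(x, ...) {
  centres <- grid_centres(x$domain)
  nxy <- nrow(centres)
  tms <- rep(field_times(x), each = nxy)
  xs <- rep(centres[, 1], times = x$nt)
  ys <- rep(centres[, 2], times = x$nt)
  us <- as.vector(x$u)
  vs <- as.vector(x$v)
  mk <- as.vector(x$mask)
  tibble::tibble(time = tms, x = xs, y = ys, u = us, v = vs, mask = mk)
}

#' Read and write a velocity-field series as long-form CSV
#'
#' Plain-text interchange format: one row per cell-hour with columns
#' `time` (ISO-8601 UTC), `x`, `y` (cell-centre km), `u`, `v` (cm s^-1) and
#' `mask` (logical). Masked-out velocities are written as empty fields.
#'
#' @param field A `velocity_field`.
#' @param path Output file.
#' @param domain Domain the file was written against (needed to rebuild the
#'   grid layout when reading).
#' @return `write_field_csv()` the path, invisibly; `read_field_csv()` a
#'   `velocity_field`.
#' @export
write_field_csv <- function(field, path) {
  df <- as_tibble(field)
  df$time <- format(df$time, "%Y-%m-%dT%H:%M:%SZ")
  df$u[!df$mask] <- NA
  df$v[!df$mask] <- NA
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_field_csv
#' @export
read_field_csv <- function(path, domain) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  times <- unique(df$time)
  nt <- length(times)
  nxy <- domain$nx * domain$ny
  stopifnot(nrow(df) == nt * nxy)
  dims <- c(domain$nx, domain$ny, nt)
  u <- array(df$u, dims)
  v <- array(df$v, dims)
  mask <- array(as.logical(df$mask), dims)
  u[!mask] <- 0
  v[!mask] <- 0
  velocity_field(u, v, domain,
                 start = as.POSIXct(times[1], tz = "UTC",
                                    format = "%Y-%m-%dT%H:%M:%OSZ"),
                 mask = mask)
}
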