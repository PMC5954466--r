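# Shared fixtures: small domains and analytically known velocity fields.

T0 <- as.POSIXct("2015-01-01 00:00:00", tz = "UTC")

# a small square domain with two rectangular sub-regions
tiny_domain <- function(nx = 10, ny = 10) {
  build_domain(domain_config(
    nx = nx, ny = ny,
    subregions = list(
      A = cbind(x = c(1, 4, 4, 1), y = c(1, 1, 4, 4)),
      B = cbind(x = c(5, 8, 8, 5), y = c(5, 5, 8, 8))
    )
  ))
}

# spatially uniform steady field, u/v in cm/s
uniform_field <- function(domain, u_cms, v_cms, nt = 49, mask = NULL) {
  dims <- c(domain$nx, domain$ny, nt)
  velocity_field(array(u_cms, dims), array(v_cms, dims), domain,
                 start = T0, mask = mask)
}

# solid-body rotation about the domain centre with the given period;
# linear in space, so bilinear interpolation reproduces it exactly
rotation_field <- function(domain, period_h = 12, nt = 49) {
  omega <- 2 * pi / period_h              # rad / h
  s <- domain$spacing
  xs <- (seq_len(domain$nx) - 0.5) * s
  ys <- (seq_len(domain$ny) - 0.5) * s
  centres <- cbind(rep(xs, times = domain$ny), rep(ys, each = domain$nx))
  cx <- domain$nx * s / 2
  cy <- domain$ny * s / 2
  u <- -omega * (centres[, 2] - cy) / 0.036  # km/h -> cm/s
  v <- omega * (centres[, 1] - cx) / 0.036
  dims <- c(domain$nx, domain$ny, nt)
  velocity_field(
    array(rep(u, nt), dims), array(rep(v, nt), dims),
    domain, start = T0
  )
}

# independent brute-force oracle for uniform eastward flow: exit hour of a
# particle is the first whole hour at which it has been carried past the
# footprint's east edge
oracle_exit_hours_uniform <- function(x0, u_cms, east_edge_km) {
  speed_kmh <- u_cms * 0.036
  vapply(x0, function(x) {
    h <- 0
    repeat {
      h <- h + 1
      if (x + speed_kmh * h >= east_edge_km) return(h)
      if (h > 10000) return(NA_real_)
    }
  }, numeric(1))
}

# brute-force residence: smallest h with (# exit hours <= h) >= need
oracle_residence_hours <- function(exit_hours, need) {
  for (h in sort(unique(exit_hours))) {
    if (sum(exit_hours <= h) >= need) return(h)
  }
  NA_real_
}
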