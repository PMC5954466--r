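#' @importFrom rlang .data abort warn %||%
#' @importFrom tibble tibble as_tibble
#' @importFrom stats var sd qt qf quantile cor cor.test setNames aggregate
#' @importFrom utils head tail
NULL

# 1 cm s^-1 expressed in km h^-1; velocities are carried in cm s^-1 at I/O
# and converted once on entry to the integrator.
CMS_TO_KMH <- 0.036

#' Domain configuration
#'
#' Describes the analysis footprint: a regular grid of square cells (release
#' points sit at cell centres), a geographic anchor for lon/lat conversion,
#' and a set of named sub-region polygons in local km coordinates.
#'
#' Coordinates are local tangent-plane Cartesian kilometres (equirectangular
#' projection about the anchor); cell `i, j` spans
#' `[(i-1) s, i s] x [(j-1) s, j s]` with centre `((i-0.5) s, (j-0.5) s)`.
#'
#' @param nx,ny Number of grid cells east and north.
#' @param spacing Grid spacing in km (default 1).
#' @param origin_lonlat Numeric `c(lon, lat)` of the grid origin (corner of
#'   cell 1,1), used only when converting to/from geographic coordinates.
#' @param subregions Named list of polygons, each a two-column matrix of
#'   vertex `(x, y)` km coordinates. Order matters: ties on shared edges are
#'   resolved first-region-wins.
#' @param footprint_mask Logical `nx x ny` matrix of cells with data coverage;
#'   default all `TRUE`.
#' @param release_mask Optional logical `nx x ny` matrix restricting which
#'   cell centres may carry release points (e.g. to drop near-shore cells).
#' @param target_area_km2 Intended footprint area; the built domain must be
#'   within 20% of this. Default `nx * ny * spacing^2`.
#' @return A `domain_config` list.
#' @seealso [build_domain()], [demo_domain_config()]
#' @export
domain_config <- function(nx, ny, spacing = 1,
                          origin_lonlat = c(-64.65, -64.95),
                          subregions = list(),
                          footprint_mask = NULL,
                          release_mask = NULL,
                          target_area_km2 = NULL) {
  stopifnot(nx >= 1, ny >= 1, spacing > 0)
  if (is.null(footprint_mask)) {
    footprint_mask <- matrix(TRUE, nx, ny)
  }
  stopifnot(identical(dim(footprint_mask), c(as.integer(nx), as.integer(ny))))
  structure(
    list(
      nx = as.integer(nx), ny = as.integer(ny), spacing = spacing,
      origin_lonlat = origin_lonlat,
      subregions = subregions,
      footprint_mask = footprint_mask,
      release_mask = release_mask,
      target_area_km2 = target_area_km2 %||% (nx * ny * spacing^2)
    ),
    class = "domain_config"
  )
}

#' Demonstration domain configuration
#'
#' A schematic 50 x 30 km footprint (1500 one-km cells) holding three
#' non-overlapping sub-regions named after the hotspot geography: the central
#' canyon (CAN) flanked by the Joubin Islands Flank (JIF) to the west and the
#' Wauwermans Islands Flank (WIF) to the east. The polygons are rectangles
#' (WIF carries a one-cell tab) sized so their release grids hold 187, 84 and
#' 61 one-km-spaced points respectively, 332 in total. The real sub-region
#' shapes follow unpublished bathymetry; only these counts are reproduced.
#'
#' @param nx,ny,spacing Grid dimensions, overridable for scaled-down runs.
#' @return A `domain_config`.
#' @export
demo_domain_config <- function(nx = 50, ny = 30, spacing = 1) {
  rect <- function(x0, y0, x1, y1) {
    cbind(x = c(x0, x1, x1, x0), y = c(y0, y0, y1, y1))
  }
  subregions <- list(
    CAN = rect(16, 9, 33, 20),
    JIF = rect(2, 11, 14, 18),
    # 10 x 6 block plus a single-cell tab at the south-east corner -> 61 pts
    WIF = cbind(x = c(35, 46, 46, 45, 45, 35),
                y = c(11, 11, 12, 12, 17, 17))
  )
  domain_config(nx = nx, ny = ny, spacing = spacing, subregions = subregions)
}

#' Build an analysis domain
#'
#' Validates a [domain_config()], enumerates the release grid (cell centres
#' inside each sub-region polygon, at the grid spacing), and returns the
#' assembled domain. Sub-region polygons must not overlap: a release point
#' strictly inside two polygons is an error, while points on a shared edge
#' are assigned to the first region in the configuration order.
#'
#' @param config A `domain_config`.
#' @return A `drift_domain` object: the config plus `release_points`, a tibble
#'   with columns `x`, `y`, `region`.
#' @examples
#' dom <- build_domain(demo_domain_config())
#' dplyr::count(dom$release_points, region)
#' @export
build_domain <- function(config) {
  stopifnot(inherits(config, "domain_config"))
  area <- sum(config$footprint_mask) * config$spacing^2
  if (area <= 0) {
    abort("domain footprint is empty")
  }
  if (abs(area - config$target_area_km2) > 0.2 * config$target_area_km2) {
    abort(sprintf(
      "footprint area %.0f km^2 deviates more than 20%% from target %.0f km^2",
      area, config$target_area_km2
    ))
  }
  for (nm in names(config$subregions)) {
    poly <- config$subregions[[nm]]
    if (polygon_self_intersects(poly)) {
      abort(sprintf("sub-region polygon '%s' is self-intersecting", nm))
    }
  }

  centres <- grid_centres(config)
  ok <- as.vector(config$footprint_mask)
  if (!is.null(config$release_mask)) ok <- ok & as.vector(config$release_mask)
  centres <- centres[ok, , drop = FALSE]

  nms <- names(config$subregions)
  if (length(nms)) {
    member <- vapply(
      config$subregions,
      function(p) point_in_polygon(centres[, 1], centres[, 2], p),
      logical(nrow(centres))
    )
    member <- matrix(member, nrow = nrow(centres))
    multi <- rowSums(member) > 1
    if (any(multi)) {
      # points on a shared boundary are tolerated (first region wins);
      # a strictly interior point claimed twice means overlapping polygons
      strict <- vapply(
        config$subregions,
        function(p) point_in_polygon(centres[, 1], centres[, 2], p,
                                     boundary = FALSE),
        logical(nrow(centres))
      )
      strict <- matrix(strict, nrow = nrow(centres))
      if (any(rowSums(strict[multi, , drop = FALSE]) > 1)) {
        abort("sub-region polygons overlap: release points must belong to exactly one region")
      }
    }
    first <- apply(member, 1, function(m) if (any(m)) which(m)[1] else NA_integer_)
    keep <- !is.na(first)
    release_points <- tibble(
      x = centres[keep, 1], y = centres[keep, 2],
      region = nms[first[keep]]
    )
  } else {
    release_points <- tibble(x = numeric(), y = numeric(), region = character())
  }

  structure(
    c(unclass(config), list(release_points = release_points, area_km2 = area)),
    class = c("drift_domain", "domain_config")
  )
}

grid_centres <- function(config) {
  s <- config$spacing
  xs <- (seq_len(config$nx) - 0.5) * s
  ys <- (seq_len(config$ny) - 0.5) * s
  cbind(x = rep(xs, times = config$ny), y = rep(ys, each = config$nx))
}

#' Locate points in the domain
#'
#' Point-membership query supporting exit detection and connectivity: is a
#' point inside the data footprint, and in which sub-region does it fall?
#' Sub-region membership uses the even-odd rule with boundary points counted
#' inside; a point on a shared edge goes to the first region in the domain's
#' configuration order. Non-finite or out-of-range points return
#' `in_footprint = FALSE` and no region.
#'
#' @param points A data frame (or matrix) with columns/cols `x`, `y` in km.
#' @param domain A `drift_domain` from [build_domain()].
#' @return A tibble with `x`, `y`, `in_footprint` (logical), `region`
#'   (character, `NA` if in no sub-region).
#' @export
locate <- function(points, domain) {
  stopifnot(inherits(domain, "drift_domain"))
  if (is.matrix(points)) points <- as.data.frame(points)
  x <- points$x
  y <- points$y
  tibble(
    x = x, y = y,
    in_footprint = in_footprint(x, y, domain),
    region = assign_region(x, y, domain)
  )
}

in_footprint <- function(x, y, domain) {
  s <- domain$spacing
  i <- floor(x / s) + 1
  j <- floor(y / s) + 1
  ok <- is.finite(x) & is.finite(y) &
    i >= 1 & i <= domain$nx & j >= 1 & j <= domain$ny
  out <- rep(FALSE, length(x))
  if (any(ok)) {
    out[ok] <- domain$footprint_mask[cbind(i[ok], j[ok])]
  }
  out
}

assign_region <- function(x, y, domain) {
  out <- rep(NA_character_, length(x))
  fin <- is.finite(x) & is.finite(y)
  for (nm in names(domain$subregions)) {
    hit <- fin & is.na(out) &
      point_in_polygon(x, y, domain$subregions[[nm]])
    out[hit] <- nm
  }
  out
}

# Even-odd rule ray casting, vectorised over points. boundary = TRUE counts
# points on an edge or vertex as inside (within eps).
point_in_polygon <- function(px, py, poly, boundary = TRUE, eps = 1e-9) {
  vx <- poly[, 1]
  vy <- poly[, 2]
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  on_edge <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- vx[i]; yi <- vy[i]; xj <- vx[j]; yj <- vy[j]
    # edge crossing test for the horizontal ray to +x
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    crosses[is.na(crosses)] <- FALSE
    inside <- xor(inside, crosses)
    # distance from point to segment for the boundary rule
    dx <- xj - xi; dy <- yj - yi
    len2 <- dx * dx + dy * dy
    t <- if (len2 > 0) pmin(1, pmax(0, ((px - xi) * dx + (py - yi) * dy) / len2)) else 0
    d2 <- (px - (xi + t * dx))^2 + (py - (yi + t * dy))^2
    on_edge <- on_edge | (d2 <= eps^2)
    j <- i
  }
  if (boundary) inside | on_edge else inside & !on_edge
}

polygon_self_intersects <- function(poly, eps = 1e-12) {
  n <- nrow(poly)
  if (n < 4) return(FALSE)
  seg <- function(i) list(p = poly[i, ], q = poly[if (i == n) 1 else i + 1, ])
  for (i in seq_len(n - 2)) {
    for (k in seq(i + 2, n)) {
      # skip adjacent segments (share a vertex)
      if (i == 1 && k == n) next
      a <- seg(i); b <- seg(k)
      if (segments_cross(a$p, a$q, b$p, b$q, eps)) return(TRUE)
    }
  }
  FALSE
}

segments_cross <- function(p1, p2, p3, p4, eps = 1e-12) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (((d1 > eps & d2 < -eps) | (d1 < -eps & d2 > eps)) &
     ((d3 > eps & d4 < -eps) | (d3 < -eps & d4 > eps)))
}

#' @export
print.drift_domain <- function(x, ...) {
  cat(sprintf(
    "<drift_domain> %d x %d cells at %.1f km (%.0f km^2 footprint)\n",
    x$nx, x$ny, x$spacing, x$area_km2
  ))
  if (nrow(x$release_points)) {
    cnt <- table(factor(x$release_points$region, levels = names(x$subregions)))
    cat("release points:", sum(cnt),
        paste(sprintf("%s=%d", names(cnt), cnt), collapse = " "), "\n")
  }
  invisible(x)
}

# ---- geographic conversion (equirectangular about the anchor) --------------

KM_PER_DEG_LAT <- 110.574

km_to_lonlat <- function(x, y, origin_lonlat) {
  lat0 <- origin_lonlat[2]
  lon <- origin_lonlat[1] + x / (111.320 * cos(lat0 * pi / 180))
  lat <- lat0 + y / KM_PER_DEG_LAT
  cbind(lon = lon, lat = lat)
}

lonlat_to_km <- function(lon, lat, origin_lonlat) {
  lat0 <- origin_lonlat[2]
  x <- (lon - origin_lonlat[1]) * 111.320 * cos(lat0 * pi / 180)
  y <- (lat - lat0) * KM_PER_DEG_LAT
  cbind(x = x, y = y)
}

#' Read and write sub-region polygons as GeoJSON
#'
#' Sub-region polygons are interchanged as a GeoJSON FeatureCollection of
#' Polygon features with a per-feature `name` property, coordinates in
#' lon/lat. Conversion between geographic and local km coordinates uses the
#' domain anchor with an equirectangular projection.
#'
#' @param domain A `drift_domain` (or `domain_config`) whose sub-regions to
#'   write.
#' @param path File path.
#' @return `write_regions_geojson()` returns `path` invisibly;
#'   `read_regions_geojson()` returns a named list of two-column vertex
#'   matrices in km, suitable for [domain_config()].
#' @export
write_regions_geojson <- function(domain, path) {
  features <- purrr::imap(domain$subregions, function(poly, nm) {
    ll <- km_to_lonlat(poly[, 1], poly[, 2], domain$origin_lonlat)
    ring <- rbind(ll, ll[1, , drop = FALSE])  # closed ring
    list(
      type = "Feature",
      properties = list(name = nm),
      geometry = list(
        type = "Polygon",
        coordinates = list(lapply(seq_len(nrow(ring)), function(i) unname(ring[i, ])))
      )
    )
  })
  gj <- list(type = "FeatureCollection", features = unname(features))
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = 10)
  invisible(path)
}

#' @param origin_lonlat Anchor used to project coordinates back to km.
#' @rdname write_regions_geojson
#' @export
read_regions_geojson <- function(path, origin_lonlat = c(-64.65, -64.95)) {
  gj <- jsonlite::read_json(path)
  stopifnot(identical(gj$type, "FeatureCollection"))
  out <- list()
  for (f in gj$features) {
    ring <- f$geometry$coordinates[[1]]
    ll <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
    # drop the closing vertex
    if (nrow(ll) > 1 && all(ll[1, ] == ll[nrow(ll), ])) ll <- ll[-nrow(ll), , drop = FALSE]
    out[[f$properties$name]] <- lonlat_to_km(ll[, 1], ll[, 2], origin_lonlat)
  }
  out
}
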