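# Independent oracles. These never call the hull/area implementation they
# check.

# Brute-force hull-vertex oracle: a distinct point is a hull vertex iff it
# is not contained in the convex hull of the remaining points; containment
# is decided by Caratheodory (some segment or triangle of the others
# contains it).
bf_in_conv <- function(p, others) {
  m <- nrow(others)
  if (m == 0) return(FALSE)
  if (m >= 2) {
    prs <- utils::combn(m, 2)
    a <- others[prs[1, ], , drop = FALSE]
    b <- others[prs[2, ], , drop = FALSE]
    cr <- (b[, 1] - a[, 1]) * (p[2] - a[, 2]) - (b[, 2] - a[, 2]) * (p[1] - a[, 1])
    on_seg <- cr == 0 &
      p[1] >= pmin(a[, 1], b[, 1]) & p[1] <= pmax(a[, 1], b[, 1]) &
      p[2] >= pmin(a[, 2], b[, 2]) & p[2] <= pmax(a[, 2], b[, 2])
    if (any(on_seg)) return(TRUE)
  }
  if (m < 3) return(FALSE)
  tri <- utils::combn(m, 3)
  a <- others[tri[1, ], , drop = FALSE]
  b <- others[tri[2, ], , drop = FALSE]
  cc <- others[tri[3, ], , drop = FALSE]
  d1 <- (b[, 1] - a[, 1]) * (p[2] - a[, 2]) - (b[, 2] - a[, 2]) * (p[1] - a[, 1])
  d2 <- (cc[, 1] - b[, 1]) * (p[2] - b[, 2]) - (cc[, 2] - b[, 2]) * (p[1] - b[, 1])
  d3 <- (a[, 1] - cc[, 1]) * (p[2] - cc[, 2]) - (a[, 2] - cc[, 2]) * (p[1] - cc[, 1])
  inbb <- p[1] >= pmin(a[, 1], b[, 1], cc[, 1]) & p[1] <= pmax(a[, 1], b[, 1], cc[, 1]) &
          p[2] >= pmin(a[, 2], b[, 2], cc[, 2]) & p[2] <= pmax(a[, 2], b[, 2], cc[, 2])
  any(inbb & ((d1 >= 0 & d2 >= 0 & d3 >= 0) | (d1 <= 0 & d2 <= 0 & d3 <= 0)))
}

bf_hull_vertices <- function(pts) {
  pts <- unique(pts)
  n <- nrow(pts)
  if (n <= 2) return(pts[order(pts[, 1], pts[, 2]), , drop = FALSE])
  is_vertex <- vapply(seq_len(n), function(i)
    !bf_in_conv(pts[i, ], pts[-i, , drop = FALSE]), logical(1))
  v <- pts[is_vertex, , drop = FALSE]
  v[order(v[, 1], v[, 2]), , drop = FALSE]
}

sort_ring <- function(ring) ring[order(ring[, 1], ring[, 2]), , drop = FALSE]

# Closed-form spherical-zone area of a lat-lon aligned rectangle (km^2).
zone_area <- function(lon1, lon2, lat1, lat2) {
  d2r <- pi / 180
  eooassess::EARTH_RADIUS_KM^2 * abs(lon2 - lon1) * d2r *
    abs(sin(lat2 * d2r) - sin(lat1 * d2r))
}

# Monte-Carlo point-in-region oracle for the triangle (0,0),(1,0),(0,1)
# (degrees), with edges straight in lon/lat space. Samples uniformly on the
# sphere over the bounding patch (longitude uniform, sine of latitude
# uniform).
mc_triangle_area <- function(n = 1e6, seed = 1) {
  set.seed(seed)
  d2r <- pi / 180
  lam <- stats::runif(n, 0, 1)
  phi <- asin(stats::runif(n, 0, sin(d2r))) / d2r
  mean(lam + phi <= 1) * zone_area(0, 1, 0, 1)
}

# Planar shoelace area (km^2) in a local equirectangular frame, for the
# small-extent consistency check.
planar_area_km2 <- function(ring) {
  kmlat <- eooassess::EARTH_RADIUS_KM * pi / 180
  lat0 <- mean(ring[, 2])
  x <- ring[, 1] * kmlat * cos(lat0 * pi / 180)
  y <- ring[, 2] * kmlat
  j <- c(seq_len(nrow(ring))[-1], 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}
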