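# Minimum convex polygon and geodesic area.
#
# The extent of occurrence (EOO) is operationalised as the area of the
# minimum convex polygon (MCP) enclosing a species' georeferenced records.
# The hull is built in planar lon/lat coordinates (valid for
# sub-hemispheric extents); its area is the exact area, on the authalic
# sphere, of the region bounded by edges that are straight in lon/lat
# space.  Per edge, Green's theorem on the sphere gives
#     dA = R^2 * dlambda * sin(phi_mid) * sinc(dphi / 2)
# which reduces to the classical zone formula R^2 * dlambda * (sin phi2 -
# sin phi1) for latitude-aligned rectangles, exactly.

#' Authalic Earth radius (km)
#'
#' Radius of the sphere with the same surface area as the WGS84 ellipsoid.
#' @export
EARTH_RADIUS_KM <- 6371.0072

as_lonlat_matrix <- function(points) {
  if (is.data.frame(points)) {
    if (all(c("longitude", "latitude") %in% names(points)))
      points <- cbind(points$longitude, points$latitude)
    else points <- as.matrix(points[, 1:2])
  }
  if (is.null(dim(points))) points <- matrix(points, ncol = 2, byrow = TRUE)
  storage.mode(points) <- "double"
  if (ncol(points) != 2) stop_stage("eoo_geometry", "points must have two columns (lon, lat)")
  if (anyNA(points)) stop_stage("eoo_geometry", "points contain missing coordinates")
  if (any(points[, 2] < -90 | points[, 2] > 90))
    stop_stage("eoo_geometry", "latitude out of [-90, 90]")
  points[, 1] <- normalize_lon(points[, 1])
  points
}

lon_span <- function(lon) if (length(lon) == 0) 0 else diff(range(lon))

#' Recentre longitudes on their circular mean
#'
#' Applied when a point set's longitudinal span exceeds 180 degrees, so that
#' ranges straddling the antimeridian get a contiguous planar frame.
#' @param points n x 2 matrix (lon, lat).
#' @return matrix with recentred, renormalised longitudes.
#' @keywords internal
recentre_lon <- function(points) {
  lam <- points[, 1] * pi / 180
  centre <- atan2(mean(sin(lam)), mean(cos(lam))) * 180 / pi
  points[, 1] <- normalize_lon(points[, 1] - centre)
  points
}

#' Convex hull of geographic points
#'
#' Andrew's monotone-chain hull over the distinct points, computed in planar
#' lon/lat coordinates. Returns the vertex ring in counter-clockwise order
#' starting from the lexicographically smallest vertex; collinear interior
#' points are excluded. Degenerate inputs yield degenerate rings: fewer than
#' three distinct points give a ring of the distinct points, fully collinear
#' sets give the two extreme endpoints.
#'
#' @param points n x 2 matrix, data.frame, or occ_set slice with longitude
#'   and latitude; duplicates allowed.
#' @return m x 2 matrix (columns lon, lat), unclosed ring; `NULL` for empty
#'   input.
#' @export
convex_hull <- function(points) {
  pts <- as_lonlat_matrix(points)
  if (nrow(pts) == 0) return(NULL)
  pts <- unique(pts)
  ord <- order(pts[, 1], pts[, 2])
  pts <- pts[ord, , drop = FALSE]
  n <- nrow(pts)
  if (n == 1) return(pts)
  if (n == 2) return(pts)
  cross <- function(o, a, b)
    (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  build <- function(idx) {
    h <- integer(0)
    for (i in idx) {
      while (length(h) >= 2 &&
             cross(pts[h[length(h) - 1], ], pts[h[length(h)], ], pts[i, ]) <= 0)
        h <- h[-length(h)]
      h <- c(h, i)
    }
    h
  }
  lower <- build(seq_len(n))
  upper <- build(rev(seq_len(n)))
  ring <- c(lower[-length(lower)], upper[-length(upper)])
  if (length(ring) < 2) { # fully collinear: keep the two extremes
    ring <- c(1L, n)
  }
  pts[ring, , drop = FALSE]
}

#' Geodesic area of a lon/lat polygon ring (km^2)
#'
#' Exact spherical area, on the authalic sphere, of the polygon whose edges
#' are straight lines in lon/lat space. For latitude-aligned rectangles this
#' equals the closed-form zone formula `R^2 * dlambda * (sin phi2 - sin
#' phi1)` to machine precision. Rings spanning more than 180 degrees of
#' longitude are recentred on the circular mean first; a ring still wider
#' than a hemisphere after recentring is an error.
#'
#' @param ring m x 2 matrix (lon, lat), unclosed; `NULL` or degenerate rings
#'   (fewer than 3 vertices, collinear) give 0.
#' @return non-negative area in km^2.
#' @export
geodesic_area <- function(ring) {
  if (is.null(ring)) return(0)
  ring <- as_lonlat_matrix(ring)
  if (nrow(ring) < 3) return(0)
  if (lon_span(ring[, 1]) > 180) {
    ring <- recentre_lon(ring)
    if (lon_span(ring[, 1]) > 180)
      stop_stage("eoo_geometry",
                 "ring spans more than a hemisphere of longitude (span %.1f deg)",
                 lon_span(ring[, 1]))
  }
  lam <- ring[, 1] * pi / 180
  phi <- ring[, 2] * pi / 180
  j <- c(seq_len(nrow(ring))[-1], 1L)
  dlam <- lam[j] - lam
  dphi <- phi[j] - phi
  hd <- dphi / 2
  sinc <- ifelse(abs(hd) < 1e-8, 1 - hd^2 / 6, sin(hd) / hd)
  abs(sum(dlam * sin((phi + phi[j]) / 2) * sinc)) * EARTH_RADIUS_KM^2
}

#' Extent of occurrence of a set of georeferenced records
#'
#' Builds the minimum convex polygon over the records and measures its
#' geodesic area. At least three data points are required to build the
#' polygon; with fewer, the area is undefined (`NA`) and the species will be
#' classified Data Deficient downstream. The three-point rule counts records
#' by default (`rule = "records"`); set `rule = "distinct"` to count
#' distinct coordinate pairs instead. Zero-area hulls from three or more
#' coincident/collinear records are a *defined* EOO of 0 km^2.
#'
#' @param records an `occ_set` (all records georeferenced), data.frame with
#'   longitude/latitude, or n x 2 matrix (lon, lat).
#' @param rule how to count the three-point minimum.
#' @return an `eoo_hull` object: list(n_records, n_distinct, hull, area_km2)
#'   with `area_km2 = NA` when undefined.
#' @export
eoo <- function(records, rule = c("records", "distinct")) {
  rule <- match.arg(rule)
  pts <- if (is.data.frame(records)) {
    if (anyNA(records$latitude) || anyNA(records$longitude))
      stop_stage("eoo_geometry", "eoo() requires georeferenced records; run filter_georeferenced() first")
    cbind(records$longitude, records$latitude)
  } else records
  pts <- if (length(pts) == 0) matrix(numeric(0), ncol = 2) else as_lonlat_matrix(pts)
  n_records <- nrow(pts)
  if (n_records > 0 && lon_span(pts[, 1]) > 180) pts <- recentre_lon(pts)
  n_distinct <- nrow(unique(pts))
  hull <- convex_hull(pts)
  effective_n <- if (rule == "records") n_records else n_distinct
  area <- if (effective_n < 3) NA_real_ else geodesic_area(hull)
  structure(list(n_records = n_records, n_distinct = n_distinct,
                 hull = hull, area_km2 = area),
            class = "eoo_hull")
}

#' @export
print.eoo_hull <- function(x, ...) {
  cat(sprintf("<eoo_hull> %d records (%d distinct), EOO = %s\n",
              x$n_records, x$n_distinct,
              if (is.na(x$area_km2)) "undefined (< 3 data points)"
              else sprintf("%.2f km^2", x$area_km2)))
  invisible(x)
}

#' Export hull rings as a GeoJSON FeatureCollection
#'
#' One Polygon feature per named hull (WGS84, lon-lat vertex order), for
#' visual inspection in any GIS viewer.
#'
#' @param hulls named list of `eoo_hull` objects or m x 2 rings.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
hulls_to_geojson <- function(hulls, path) {
  feats <- lapply(names(hulls), function(nm) {
    h <- hulls[[nm]]
    ring <- if (inherits(h, "eoo_hull")) h$hull else h
    if (is.null(ring) || nrow(ring) < 3) return(NULL)
    ring <- rbind(ring, ring[1, ])
    list(type = "Feature",
         properties = list(species = nm),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                                   function(i) unname(ring[i, ])))))
  })
  feats <- Filter(Negate(is.null), feats)
  gj <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
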