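# Reading, validating, labelling and filtering occurrence records.
#
# An occurrence set is a plain data.frame (class "occ_set") with columns
# species, latitude, longitude, source, record_id.  Coordinates may be NA
# (= absent).  Two attributes ride along:
#   - "all_species": the full species universe, so that species whose every
#     record is filtered away remain assessable (they classify as DD);
#   - "provenance": one note per input file.

OCC_SOURCES <- c("LITERATURE", "GBIF")

#' Construct an occurrence set
#'
#' Low-level constructor used by [read_occurrences()] and the synthetic
#' generator. Species names are canonicalised (trimmed, whitespace-squashed,
#' case-normalised binomials); longitudes are normalised to (-180, 180].
#'
#' @param species character vector of species names.
#' @param latitude,longitude numeric vectors in decimal degrees WGS84;
#'   `NA` marks an absent coordinate. A record with only one coordinate
#'   present has both set to `NA`.
#' @param source character vector, each `"LITERATURE"` or `"GBIF"`.
#' @param record_id opaque record identifiers; generated when `NULL`.
#' @param provenance character vector of per-file notes.
#' @param all_species optional species universe; defaults to the species
#'   present in the data.
#' @return an `occ_set` data.frame.
#' @export
occurrence_set <- function(species, latitude = numeric(0), longitude = numeric(0),
                           source = character(0), record_id = NULL,
                           provenance = character(0), all_species = NULL) {
  species <- canonical_species(species)
  n <- length(species)
  if (any(!nzchar(species)))
    stop_stage("occurrence_io", "empty species name in %d record(s)", sum(!nzchar(species)))
  latitude <- as.numeric(latitude)
  longitude <- as.numeric(longitude)
  if (length(latitude) != n || length(longitude) != n || length(source) != n)
    stop_stage("occurrence_io", "field lengths differ")
  bad_lat <- !is.na(latitude) & (latitude < -90 | latitude > 90)
  latitude[bad_lat] <- NA_real_
  longitude <- normalize_lon(longitude)
  # enforce paired coordinates: a half-georeferenced pair becomes absent
  half <- xor(is.na(latitude), is.na(longitude)) | (bad_lat & !is.na(longitude))
  latitude[half] <- NA_real_
  longitude[half] <- NA_real_
  if (!all(source %in% OCC_SOURCES))
    stop_stage("occurrence_io", "source must be one of %s", paste(OCC_SOURCES, collapse = ", "))
  if (is.null(record_id)) record_id <- sprintf("r%06d", seq_len(n))
  df <- data.frame(species = species, latitude = latitude, longitude = longitude,
                   source = as.character(source), record_id = as.character(record_id),
                   stringsAsFactors = FALSE)
  structure(df,
            all_species = sort(unique(c(canonical_species(all_species %||% character(0)),
                                        species))),
            provenance = provenance,
            class = c("occ_set", "data.frame"))
}

#' Default column profiles
#'
#' The GBIF profile follows Darwin Core export headers; `species` falls back
#' to `scientificName` when absent. The literature profile defaults to the
#' same coordinate headers and is meant to be overridden per file.
#'
#' @param species,latitude,longitude column names in the input file.
#' @return named character vector with entries species, latitude, longitude.
#' @export
occ_columns <- function(species = "species", latitude = "decimalLatitude",
                        longitude = "decimalLongitude") {
  c(species = species, latitude = latitude, longitude = longitude)
}

#' @rdname occ_columns
#' @export
gbif_columns <- function() occ_columns()

#' @rdname occ_columns
#' @export
literature_columns <- function() occ_columns()

sniff_sep <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0) return(",")
  if (lengths(regmatches(first, gregexpr("\t", first))) >
      lengths(regmatches(first, gregexpr(",", first)))) "\t" else ","
}

#' Read occurrence records from a GBIF-style or literature CSV
#'
#' Reads a comma- or tab-delimited UTF-8 table (delimiter auto-detected),
#' maps the configured columns, and returns all parseable rows labelled with
#' `source`. Rows whose coordinate cells are blank, unparseable, or out of
#' range are retained with absent coordinates; rows with an empty species
#' name are dropped as malformed. The attached ingest report (see
#' [ingest_report()]) accounts for every input row.
#'
#' @param path path to the input file.
#' @param source `"LITERATURE"` or `"GBIF"`.
#' @param columns a profile from [occ_columns()]; default chosen by source.
#' @return an `occ_set` with attribute `ingest_report`.
#' @export
read_occurrences <- function(path, source = c("LITERATURE", "GBIF"), columns = NULL) {
  source <- match.arg(source)
  if (!file.exists(path))
    stop_stage("occurrence_io", "input file not found: %s", path)
  columns <- columns %||% if (source == "GBIF") gbif_columns() else literature_columns()
  sep <- sniff_sep(path)
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE, fileEncoding = "UTF-8",
                           fill = TRUE, comment.char = "")
  sp_col <- columns[["species"]]
  if (!sp_col %in% names(raw) && sp_col == "species" && "scientificName" %in% names(raw))
    sp_col <- "scientificName"
  for (nm in c(species = sp_col, latitude = columns[["latitude"]],
               longitude = columns[["longitude"]])) {
    if (!nm %in% names(raw))
      stop_stage("occurrence_io", "required column '%s' absent from %s", nm, path)
  }
  total <- nrow(raw)
  if (total == 0) {
    occ <- occurrence_set(character(0), numeric(0), numeric(0), character(0),
                          provenance = sprintf("%s (%s, 0 rows)", path, source))
    attr(occ, "ingest_report") <- list(file = path, source = source, total_rows = 0L,
                                       parsed = 0L, missing_coords = 0L,
                                       dropped_malformed = 0L)
    return(occ)
  }
  species <- canonical_species(raw[[sp_col]])
  lat <- suppressWarnings(as.numeric(raw[[columns[["latitude"]]]]))
  lon <- suppressWarnings(as.numeric(raw[[columns[["longitude"]]]]))
  lat[!is.na(lat) & (lat < -90 | lat > 90)] <- NA_real_
  half_or_missing <- is.na(lat) | is.na(lon)
  lat[half_or_missing] <- NA_real_
  lon[half_or_missing] <- NA_real_
  malformed <- !nzchar(species)
  keep <- !malformed
  occ <- occurrence_set(species[keep], lat[keep], lon[keep],
                        rep(source, sum(keep)),
                        record_id = sprintf("%s-%06d", tolower(source), which(keep)),
                        provenance = sprintf("%s (%s, %d rows)", path, source, total))
  attr(occ, "ingest_report") <- list(
    file = path, source = source, total_rows = total, parsed = sum(keep),
    missing_coords = sum(half_or_missing & keep),
    dropped_malformed = sum(malformed))
  occ
}

#' Retrieve the ingest report attached by [read_occurrences()]
#' @param occ an `occ_set`.
#' @return a list with total_rows, parsed, missing_coords, dropped_malformed.
#' @export
ingest_report <- function(occ) attr(occ, "ingest_report")

#' Species universe of an occurrence set
#'
#' All species keys, including species whose records have been filtered away.
#' @param occ an `occ_set`.
#' @export
occ_species <- function(occ) attr(occ, "all_species") %||% sort(unique(occ$species))

#' Keep only fully georeferenced records
#'
#' Removes records lacking coordinates; non-georeferenced records cannot
#' enter the convex polygon. Species left with zero records stay in the
#' species universe and later classify as Data Deficient. Idempotent; input
#' order preserved.
#'
#' @param occ an `occ_set`.
#' @return an `occ_set` with attribute `dropped`: a named integer vector of
#'   per-species dropped counts (zero entries included).
#' @export
filter_georeferenced <- function(occ) {
  keep <- !is.na(occ$latitude) & !is.na(occ$longitude)
  out <- occ[keep, , drop = FALSE]
  universe <- occ_species(occ)
  dropped <- table(factor(occ$species[!keep], levels = universe))
  res <- structure(as.data.frame(out),
                   all_species = universe,
                   provenance = attr(occ, "provenance"),
                   class = c("occ_set", "data.frame"))
  attr(res, "dropped") <- stats::setNames(as.integer(dropped), universe)
  res
}

#' Merge two occurrence sets
#'
#' Union keyed by species; records from both inputs are retained without
#' cross-source deduplication (duplicate coordinates never change a convex
#' hull, so the EOO is unaffected). Commutative and associative in the
#' multiset of records per species.
#'
#' @param a,b `occ_set` objects.
#' @return an `occ_set`.
#' @export
merge_sources <- function(a, b) {
  df <- rbind(as.data.frame(a), as.data.frame(b))
  structure(df,
            all_species = sort(unique(c(occ_species(a), occ_species(b)))),
            provenance = c(attr(a, "provenance"), attr(b, "provenance")),
            class = c("occ_set", "data.frame"))
}

#' Write the canonical occurrence CSV
#'
#' Columns species, latitude, longitude, source, record_id; coordinates at
#' full precision (15 significant digits round-trips doubles to well past
#' the 6-decimal contract).
#'
#' @param occ an `occ_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_occurrences <- function(occ, path) {
  df <- as.data.frame(occ)[, c("species", "latitude", "longitude", "source", "record_id")]
  df$latitude <- ifelse(is.na(df$latitude), "", sprintf("%.10f", df$latitude))
  df$longitude <- ifelse(is.na(df$longitude), "", sprintf("%.10f", df$longitude))
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Define a study-region boundary polygon
#'
#' A closed ring of (longitude, latitude) vertices delimiting a study region,
#' used to flag records falling outside a species' known range. Validated on
#' construction: at least three vertices and no self-intersection.
#'
#' @param longitude,latitude numeric vectors of equal length (>= 3); the ring
#'   is closed implicitly (do not repeat the first vertex).
#' @return a `region_boundary` object.
#' @export
region_boundary <- function(longitude, latitude) {
  lon <- as.numeric(longitude); lat <- as.numeric(latitude)
  n <- length(lon)
  if (n != length(lat) || n < 3)
    stop_stage("occurrence_io", "region boundary needs >= 3 paired vertices")
  if (n > 1 && lon[1] == lon[n] && lat[1] == lat[n]) { # tolerate pre-closed rings
    lon <- lon[-n]; lat <- lat[-n]; n <- n - 1
    if (n < 3) stop_stage("occurrence_io", "region boundary needs >= 3 distinct vertices")
  }
  if (polygon_self_intersects(lon, lat))
    stop_stage("occurrence_io", "region boundary is self-intersecting")
  if (abs(ring_signed_area(lon, lat)) < .Machine$double.eps)
    stop_stage("occurrence_io", "region boundary is degenerate (zero area)")
  structure(list(longitude = lon, latitude = lat), class = "region_boundary")
}

#' Read a region boundary from a CSV of vertices
#' @param path CSV with columns longitude, latitude (ring order).
#' @return a `region_boundary`.
#' @export
read_region <- function(path) {
  if (!file.exists(path)) stop_stage("occurrence_io", "region file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("longitude", "latitude") %in% names(df)))
    stop_stage("occurrence_io", "region file needs longitude and latitude columns")
  region_boundary(df$longitude, df$latitude)
}

ring_signed_area <- function(x, y) {
  j <- c(seq_along(x)[-1], 1L)
  sum(x * y[j] - x[j] * y) / 2
}

segments_intersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2); d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
  on_seg <- function(a, b, c) {
    d(a, b, c) == 0 &&
      min(a[1], b[1]) <= c[1] && c[1] <= max(a[1], b[1]) &&
      min(a[2], b[2]) <= c[2] && c[2] <= max(a[2], b[2])
  }
  on_seg(p1, p2, p3) || on_seg(p1, p2, p4) || on_seg(p3, p4, p1) || on_seg(p3, p4, p2)
}

polygon_self_intersects <- function(x, y) {
  n <- length(x)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      # skip adjacent edges (share a vertex)
      if (abs(i - j) == 1 || (i == 1 && j == n)) next
      if (segments_intersect(c(x[i], y[i]), c(x[i %% n + 1], y[i %% n + 1]),
                             c(x[j], y[j]), c(x[j %% n + 1], y[j %% n + 1])))
        return(TRUE)
    }
  }
  FALSE
}

#' Inclusive point-in-polygon test (even-odd rule; boundary counts inside)
#' @param px,py point coordinates (vectors).
#' @param vx,vy polygon vertex coordinates (ring, unclosed).
#' @return logical vector.
#' @keywords internal
point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  m <- length(px)
  inside <- logical(m)
  for (k in seq_len(m)) {
    x <- px[k]; y <- py[k]
    inc <- FALSE
    on_edge <- FALSE
    j <- n
    for (i in seq_len(n)) {
      xi <- vx[i]; yi <- vy[i]; xj <- vx[j]; yj <- vy[j]
      cr <- (xj - xi) * (y - yi) - (yj - yi) * (x - xi)
      if (cr == 0 &&
          min(xi, xj) <= x && x <= max(xi, xj) &&
          min(yi, yj) <= y && y <= max(yi, yj)) { on_edge <- TRUE; break }
      if ((yi > y) != (yj > y)) {
        xint <- xi + (y - yi) / (yj - yi) * (xj - xi)
        if (x < xint) inc <- !inc
      }
      j <- i
    }
    inside[k] <- on_edge || inc
  }
  inside
}

#' Flag records falling outside a study region
#'
#' Point-in-polygon test per record; the boundary counts as inside. Flags
#' only — nothing is deleted, the flags support expert review of dubious
#' localities (e.g. supposed endemics recorded outside their region).
#'
#' @param occ an `occ_set`, all records georeferenced.
#' @param region a [region_boundary()].
#' @return data.frame with columns record_id, inside.
#' @export
flag_out_of_region <- function(occ, region) {
  if (!inherits(region, "region_boundary"))
    stop_stage("occurrence_io", "region must be a region_boundary")
  if (anyNA(occ$latitude) || anyNA(occ$longitude))
    stop_stage("occurrence_io", "flag_out_of_region requires georeferenced records; run filter_georeferenced() first")
  data.frame(record_id = occ$record_id,
             inside = point_in_polygon(occ$longitude, occ$latitude,
                                       region$longitude, region$latitude),
             stringsAsFactors = FALSE)
}

#' @export
print.occ_set <- function(x, ...) {
  cat(sprintf("<occ_set> %d records, %d species (%d georeferenced records)\n",
              nrow(x), length(occ_species(x)),
              sum(!is.na(x$latitude) & !is.na(x$longitude))))
  if (nrow(x) > 0) print(utils::head(as.data.frame(x)), ...)
  invisible(x)
}
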