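test_that("reading handles empty, delimiter variants, and default profiles", {
  empty <- write_occ_csv(data.frame(species = character(0), lat = numeric(0),
                                    lon = numeric(0)))
  occ <- read_occurrences(empty, "GBIF")
  expect_equal(nrow(occ), 0)
  expect_equal(length(occ_species(occ)), 0)
  expect_equal(ingest_report(occ)$total_rows, 0)

  df <- data.frame(species = "Aranea alba", lat = c(40.1, 40.2, 40.3),
                   lon = c(-3.1, -3.2, -3.3))
  for (sep in c(",", "\t")) {
    occ <- read_occurrences(write_occ_csv(df, sep = sep), "GBIF")
    expect_equal(nrow(occ), 3)
    expect_equal(occ_species(occ), "Aranea alba")
    expect_equal(sort(occ$longitude), c(-3.3, -3.2, -3.1))
  }

  # scientificName fallback for the GBIF profile
  p <- write_occ_csv(df, species_col = "scientificName")
  expect_equal(nrow(read_occurrences(p, "GBIF")), 3)

  # custom literature profile
  p <- write_occ_csv(df, species_col = "taxon", lat_col = "lat_dd", lon_col = "lon_dd")
  occ <- read_occurrences(p, "LITERATURE",
                          columns = occ_columns("taxon", "lat_dd", "lon_dd"))
  expect_equal(nrow(occ), 3)
  expect_true(all(occ$source == "LITERATURE"))
})

test_that("fatal errors: missing file, absent required column", {
  expect_error(read_occurrences(tempfile(), "GBIF"), "not found")
  p <- write_occ_csv(data.frame(species = "A b", lat = 1, lon = 2),
                     lat_col = "someOtherColumn")
  expect_error(read_occurrences(p, "GBIF"), "decimalLatitude")
})

test_that("missing, unparseable, half-present and out-of-range coordinates become absent", {
  df <- data.frame(species = rep("Aranea alba", 5),
                   lat = c("40.1", "", "abc", "95.0", "40.5"),
                   lon = c("-3.1", "-3.2", "-3.3", "-3.4", ""))
  occ <- read_occurrences(write_occ_csv(df), "GBIF")
  expect_equal(nrow(occ), 5)            # retained, not dropped
  expect_equal(ingest_report(occ)$missing_coords, 4)
  absent <- is.na(occ$latitude)
  expect_equal(sum(absent), 4)
  expect_true(all(is.na(occ$longitude[absent])))  # pair-wise absence
  # rows with empty species are the only dropped rows
  df2 <- rbind(df, data.frame(species = "  ", lat = "1", lon = "2"))
  occ2 <- read_occurrences(write_occ_csv(df2), "GBIF")
  expect_equal(nrow(occ2), 5)
  expect_equal(ingest_report(occ2)$dropped_malformed, 1)
})

test_that("species keys are canonicalised; longitudes normalised", {
  occ <- make_occ(c("  myrmarachne   BICOLOR ", "Myrmarachne bicolor"),
                  c(1, 2), c(370, -190))
  expect_equal(occ_species(occ), "Myrmarachne bicolor")
  expect_equal(occ$longitude, c(10, 170))
})

test_that("per-source counts for a split fixture are preserved through merge", {
  # 23 records for one species: 7 literature + 16 GBIF
  lit <- make_occ(rep("Myrmarachne bicolor", 7), 40 + (1:7) / 10, -3 - (1:7) / 10)
  gbif <- make_occ(rep("Myrmarachne bicolor", 16), 40 + (1:16) / 20, -3 - (1:16) / 20,
                   source = "GBIF")
  both <- merge_sources(lit, gbif)
  expect_equal(nrow(both), 23)
  expect_equal(as.vector(table(both$source)[c("LITERATURE", "GBIF")]), c(7, 16))
})

test_that("write -> read round-trip preserves records, keys, coordinates, sources", {
  occ <- make_occ(c("Aranea alba", "Aranea alba", "Zora nigra"),
                  c(40.123456, NA, -12.654321), c(-3.111111, NA, 7.222222),
                  source = c("LITERATURE", "LITERATURE", "GBIF"))
  path <- tempfile(fileext = ".csv")
  write_occurrences(occ, path)
  back <- utils::read.csv(path, stringsAsFactors = FALSE)
  expect_equal(nrow(back), 3)
  expect_equal(sort(unique(back$species)), c("Aranea alba", "Zora nigra"))
  expect_equal(back$source, occ$source)
  ok <- !is.na(occ$latitude)
  expect_equal(round(back$latitude[ok], 6), round(occ$latitude[ok], 6))
  expect_equal(round(back$longitude[ok], 6), round(occ$longitude[ok], 6))
})

test_that("filter_georeferenced keeps order, counts drops, retains empty species, idempotent", {
  occ <- make_occ(c("A b", "A b", "A b", "A b", "A b", "C d"),
                  c(1, NA, 2, NA, 3, NA), c(1, NA, 2, NA, 3, NA))
  geo <- filter_georeferenced(occ)
  expect_equal(nrow(geo), 3)
  expect_equal(attr(geo, "dropped"), c("A b" = 2L, "C d" = 1L))
  expect_equal(geo$latitude, c(1, 2, 3))
  # species with zero georeferenced records stays in the universe
  expect_true("C d" %in% occ_species(geo))
  # idempotent
  geo2 <- filter_georeferenced(geo)
  expect_equal(as.data.frame(geo2), as.data.frame(geo), ignore_attr = TRUE)
  expect_equal(sum(attr(geo2, "dropped")), 0)
  # identity on fully georeferenced input
  allgeo <- make_occ("A b", 1, 1)
  expect_equal(nrow(filter_georeferenced(allgeo)), 1)
})

test_that("merge_sources is commutative/associative in record multisets and unions universes", {
  a <- make_occ(c("A b", "A b"), c(1, 2), c(1, 2))
  b <- make_occ(c("A b", "C d"), c(3, 4), c(3, 4), source = "GBIF")
  c3 <- make_occ("E f", 5, 5)
  key <- function(o) {
    d <- as.data.frame(o)[c("species", "latitude", "longitude", "source")]
    d[do.call(order, d), ]
  }
  expect_equal(key(merge_sources(a, b)), key(merge_sources(b, a)),
               ignore_attr = TRUE)
  expect_equal(key(merge_sources(merge_sources(a, b), c3)),
               key(merge_sources(a, merge_sources(b, c3))), ignore_attr = TRUE)
  empty <- occurrence_set(character(0), numeric(0), numeric(0), character(0))
  expect_equal(key(merge_sources(a, empty)), key(a), ignore_attr = TRUE)
  expect_true("C d" %in% occ_species(merge_sources(a, b)))
  expect_setequal(occ_species(merge_sources(a, b)), c("A b", "C d"))
})

test_that("out-of-region flagging is inclusive on the boundary and flags only", {
  region <- region_boundary(c(-10, 4, 4, -10), c(36, 36, 44, 44))
  occ <- make_occ(rep("A b", 4),
                  lat = c(40, 50, 36, 40),   # centroid-ish, 10 deg out, on edge, inside
                  lon = c(-3, -3, -3, 3.9))
  flags <- flag_out_of_region(occ, region)
  expect_equal(flags$inside, c(TRUE, FALSE, TRUE, TRUE))
  # vertices count as inside too
  occ_v <- make_occ("A b", 36, -10)
  expect_true(flag_out_of_region(occ_v, region)$inside)
  # non-georeferenced records are rejected
  expect_error(flag_out_of_region(make_occ("A b", NA, NA), region), "georeferenced")
})

test_that("region boundaries are validated", {
  expect_error(region_boundary(c(0, 1), c(0, 1)), ">= 3")
  expect_error(region_boundary(c(0, 1, 0, 1), c(0, 1, 1, 0)), "self-intersecting")
  expect_error(region_boundary(c(0, 1, 2), c(0, 0, 0)), "degenerate")
  # pre-closed rings are tolerated
  r <- region_boundary(c(0, 1, 1, 0, 0), c(0, 0, 1, 1, 0))
  expect_length(r$longitude, 4)
})
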