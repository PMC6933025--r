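# Programmatic fixtures: tiny CSVs and occurrence sets built in code.

write_occ_csv <- function(df, path = tempfile(fileext = ".csv"), sep = ",",
                          species_col = "species", lat_col = "decimalLatitude",
                          lon_col = "decimalLongitude") {
  names(df)[match(c("species", "lat", "lon"), names(df))] <-
    c(species_col, lat_col, lon_col)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = TRUE)
  path
}

# occurrence set straight from vectors, defaulting to literature records
make_occ <- function(species, lat, lon, source = "LITERATURE", ...) {
  occurrence_set(species, lat, lon, rep(source, length.out = length(species)), ...)
}

# a cluster of n points around (lon0, lat0) with the given spread (degrees)
pt_cluster <- function(n, lon0, lat0, spread = 0.001, seed = 1) {
  set.seed(seed)
  cbind(lon0 + stats::runif(n, -spread, spread),
        lat0 + stats::runif(n, -spread, spread))
}

# literature + GBIF occurrence set for crafted comparison scenarios:
# each element of pts_lit / pts_gbif is an n x 2 (lon, lat) matrix or NULL
make_two_source_occ <- function(species, pts_lit, pts_gbif) {
  rows <- list()
  for (i in seq_along(species)) {
    if (!is.null(pts_lit[[i]]) && nrow(pts_lit[[i]]) > 0)
      rows[[length(rows) + 1]] <- data.frame(species = species[i],
                                             lat = pts_lit[[i]][, 2],
                                             lon = pts_lit[[i]][, 1],
                                             source = "LITERATURE")
    if (!is.null(pts_gbif[[i]]) && nrow(pts_gbif[[i]]) > 0)
      rows[[length(rows) + 1]] <- data.frame(species = species[i],
                                             lat = pts_gbif[[i]][, 2],
                                             lon = pts_gbif[[i]][, 1],
                                             source = "GBIF")
  }
  df <- do.call(rbind, rows)
  occurrence_set(df$species, df$lat, df$lon, df$source, all_species = species)
}
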