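# Shared fixtures, built in code.

# Hand-coded haversine (R = 6371.0088 km): the independent distance oracle.
haversine_oracle <- function(lon1, lat1, lon2, lat2) {
  r <- 6371.0088
  p1 <- lat1 * pi / 180; p2 <- lat2 * pi / 180
  dp <- p2 - p1; dl <- (lon2 - lon1) * pi / 180
  a <- sin(dp / 2)^2 + cos(p1) * cos(p2) * sin(dl / 2)^2
  2 * r * asin(pmin(1, sqrt(a)))
}

# Small co-registered stack from a list of matrices.
stack_from_matrices <- function(mats, origin = c(0, 1), cellsize = 0.1,
                                roles = NULL) {
  layers <- lapply(mats, raster_grid, origin = origin, cellsize = cellsize)
  predictor_stack(layers, roles = roles)
}

# A quick two-layer 6x6 gradient stack for plumbing tests.
tiny_stack <- function() {
  m1 <- matrix(seq(0, 35), 6, 6)
  m2 <- matrix(seq(35, 0), 6, 6)
  stack_from_matrices(list(a = m1, b = m2))
}

# Reduced-size scenario for tests that only need structure, not power.
small_scenario <- function(seed = 7L, presence_n = 40L, ...) {
  synthetic_scenario(grid_shape = c(30L, 30L), presence_n = presence_n,
                     seed = seed, ...)
}

# Occurrence set from bare coordinates.
occ_from_coords <- function(lon, lat) {
  flyrisk:::new_occurrence_set(data.frame(
    id = sprintf("r%03d", seq_along(lon)), lon = lon, lat = lat,
    status = "invaded", source = "test", stringsAsFactors = FALSE))
}

# Brute-force greedy thinning oracle (input order, all pairwise distances).
thin_oracle <- function(lon, lat, min_km) {
  kept <- integer(0)
  for (i in seq_along(lon)) {
    if (length(kept) == 0 ||
        all(haversine_oracle(lon[kept], lat[kept], lon[i], lat[i]) >= min_km))
      kept <- c(kept, i)
  }
  kept
}

# Write a small occurrence CSV and return its path.
write_occ_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}
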