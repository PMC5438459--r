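# Shared fixture builders and independent oracles.

# Small hand-written region table: three regions, one empty.
tiny_regions <- function() {
  data.frame(
    region_id = c("R1", "R2", "R3"),
    name = c("alpha", "beta", "gamma"),
    lat = c(40, 41, 42),
    lon = c(-100, -99, -98),
    land_area_km2 = c(1000, 2500, 500),
    population = c(1000, 3000, 0),
    stringsAsFactors = FALSE
  )
}

tiny_centers <- function() {
  data.frame(
    center_id = c("C1", "C2"),
    name = c("clinic-a", "clinic-b"),
    lat = c(40.2, 41.5),
    lon = c(-100.1, -98.6),
    s = c(5, 5),
    o = c(200, 200),
    stringsAsFactors = FALSE
  )
}

random_points <- function(n, lat_range = c(25, 49), lon_range = c(-124, -67)) {
  data.frame(
    lat = runif(n, lat_range[1], lat_range[2]),
    lon = runif(n, lon_range[1], lon_range[2])
  )
}

random_centers <- function(m, ...) {
  p <- random_points(m, ...)
  data.frame(
    center_id = sprintf("C%03d", seq_len(m)),
    name = sprintf("c%03d", seq_len(m)),
    lat = p$lat, lon = p$lon, s = 5, o = 200,
    stringsAsFactors = FALSE
  )
}

# Independent great-circle distance via geosphere on the same sphere radius,
# used as the oracle against the package's own haversine.
oracle_dist_km <- function(lat1, lon1, lat2, lon2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = 6371008.8) / 1000
}

# Exhaustive nearest-center oracle: full distance matrix + row argmin with
# smallest-id tie-break.
oracle_nearest <- function(pts, centers) {
  ord <- order(centers$center_id)
  centers <- centers[ord, , drop = FALSE]
  d <- sapply(seq_len(nrow(centers)), function(j) {
    oracle_dist_km(pts$lat, pts$lon, centers$lat[j], centers$lon[j])
  })
  d <- matrix(d, nrow = nrow(pts))
  idx <- apply(d, 1, which.min)
  data.frame(
    center_id = centers$center_id[idx],
    distance_km = d[cbind(seq_len(nrow(pts)), idx)],
    stringsAsFactors = FALSE
  )
}

# Exhaustive within-radius oracle.
oracle_within <- function(lat, lon, centers, radius_km) {
  d <- oracle_dist_km(lat, lon, centers$lat, centers$lon)
  sort(centers$center_id[d <= radius_km])
}
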