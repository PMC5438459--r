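#' Mean earth radius (km)
#'
#' IUGG mean radius of the spherical earth model used for all great-circle
#' distances in this package.
#' @export
EARTH_RADIUS_KM <- 6371.0088

#' Normalize longitudes to [-180, 180)
#'
#' @param lon numeric vector of longitudes in degrees.
#' @return longitudes wrapped into [-180, 180).
#' @export
normalize_lon <- function(lon) {
  out <- ((lon + 180) %% 360) - 180
  # %% maps -180 itself to -180 correctly; guard the 180 edge from fp wrap
  out[out >= 180] <- out[out >= 180] - 360
  out
}

check_latlon <- function(lat, lon, what = "point") {
  if (!is.numeric(lat) || !is.numeric(lon)) {
    stop(sprintf("%s coordinates must be numeric", what), call. = FALSE)
  }
  if (anyNA(lat) || anyNA(lon)) {
    stop(sprintf("%s coordinates contain NA", what), call. = FALSE)
  }
  if (any(lat < -90 | lat > 90)) {
    stop(sprintf("%s latitude out of [-90, 90]", what), call. = FALSE)
  }
  if (any(lon < -180 | lon >= 180)) {
    stop(sprintf("%s longitude out of [-180, 180)", what), call. = FALSE)
  }
  invisible(TRUE)
}

#' Great-circle distance between points (haversine)
#'
#' Vectorized haversine distance on a spherical earth. Arguments recycle as
#' usual, so one point against many works directly. Longitude differences are
#' taken on the circle, so the antimeridian needs no special casing.
#'
#' @param lat1,lon1 first point(s), degrees.
#' @param lat2,lon2 second point(s), degrees.
#' @param radius_km sphere radius in km.
#' @return distances in km, always in [0, pi * radius_km].
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2, radius_km = EARTH_RADIUS_KM) {
  if (!is.numeric(radius_km) || length(radius_km) != 1L || radius_km <= 0) {
    stop("radius_km must be a single positive number", call. = FALSE)
  }
  check_latlon(lat1, lon1, "first")
  check_latlon(lat2, lon2, "second")
  p1 <- lat1 * pi / 180
  p2 <- lat2 * pi / 180
  dphi <- (lat2 - lat1) * pi / 180
  dlam <- (lon2 - lon1) * pi / 180
  a <- sin(dphi / 2)^2 + cos(p1) * cos(p2) * sin(dlam / 2)^2
  a <- pmin(pmax(a, 0), 1)
  2 * radius_km * asin(sqrt(a))
}

#' Destination point along a great circle
#'
#' Exact spherical destination: starting at (lat, lon), travel
#' \code{distance_km} along initial bearing \code{bearing_deg}. Used by the
#' disc sampler so that sampled radial distances are exact great-circle
#' distances.
#'
#' @param lat,lon start point(s), degrees.
#' @param bearing_deg initial bearing, degrees clockwise from north.
#' @param distance_km travel distance, km.
#' @param radius_km sphere radius, km.
#' @return data.frame with columns \code{lat}, \code{lon}.
#' @export
geo_destination <- function(lat, lon, bearing_deg, distance_km,
                            radius_km = EARTH_RADIUS_KM) {
  check_latlon(lat, lon, "start")
  phi1 <- lat * pi / 180
  lam1 <- lon * pi / 180
  theta <- bearing_deg * pi / 180
  delta <- distance_km / radius_km
  phi2 <- asin(sin(phi1) * cos(delta) + cos(phi1) * sin(delta) * cos(theta))
  lam2 <- lam1 + atan2(
    sin(theta) * sin(delta) * cos(phi1),
    cos(delta) - sin(phi1) * sin(phi2)
  )
  data.frame(
    lat = phi2 * 180 / pi,
    lon = normalize_lon(lam2 * 180 / pi)
  )
}

#' Sample points uniformly from a disc on the sphere
#'
#' Draws \code{n} points uniformly per unit area from the disc of area
#' \code{area_km2} centred at (\code{lat}, \code{lon}). The disc radius is
#' \code{sqrt(area_km2 / pi)}; radial distances use the sqrt transform so the
#' density is uniform in area, and each point is placed with the exact
#' spherical destination formula, so its haversine distance to the centre
#' equals its sampled radius. Intended for county-scale discs; the locally
#' flat treatment of area is documented as valid for radii up to ~500 km.
#'
#' Uses the current RNG state; seed with \code{set.seed()} for
#' reproducibility.
#'
#' @param lat,lon disc centre, degrees.
#' @param area_km2 disc area, km^2 (>= 0; 0 returns \code{n} copies of the
#'   centre).
#' @param n number of points (>= 0).
#' @return data.frame with columns \code{lat}, \code{lon}.
#' @export
sample_uniform_disc <- function(lat, lon, area_km2, n) {
  check_latlon(lat, lon, "centre")
  if (length(area_km2) != 1L || is.na(area_km2) || area_km2 < 0) {
    stop("area_km2 must be a single non-negative number", call. = FALSE)
  }
  if (length(n) != 1L || is.na(n) || n < 0 || n != as.integer(n)) {
    stop("n must be a single non-negative integer", call. = FALSE)
  }
  n <- as.integer(n)
  if (n == 0L) {
    return(data.frame(lat = numeric(0), lon = numeric(0)))
  }
  R <- sqrt(area_km2 / pi)
  if (R == 0) {
    return(data.frame(lat = rep(lat, n), lon = rep(lon, n)))
  }
  r <- R * sqrt(stats::runif(n))
  bearing <- stats::runif(n, 0, 360)
  geo_destination(lat, lon, bearing, r)
}

#' Nearest diagnostic center for each point
#'
#' For each query point, finds the center minimizing haversine distance.
#' Exact distance ties are broken by the lexicographically smallest
#' \code{center_id}, so runs are reproducible.
#'
#' @param lat,lon query point(s), degrees.
#' @param centers center table with columns \code{center_id}, \code{lat},
#'   \code{lon} (see \code{\link{validate_centers}}).
#' @return data.frame with columns \code{center_id}, \code{distance_km}, one
#'   row per query point.
#' @export
nearest_center <- function(lat, lon, centers) {
  centers <- as.data.frame(centers)
  if (nrow(centers) == 0L) {
    stop("centers must be non-empty", call. = FALSE)
  }
  ord <- order(centers$center_id)
  centers <- centers[ord, , drop = FALSE]
  n <- length(lat)
  best_d <- rep(Inf, n)
  best_i <- rep(NA_integer_, n)
  # column sweep: one vectorized distance evaluation per center; which.min
  # semantics (first minimum) give the smallest-id tie-break because centers
  # are sorted by id
  for (j in seq_len(nrow(centers))) {
    d <- haversine_km(lat, lon, centers$lat[j], centers$lon[j])
    hit <- d < best_d
    best_d[hit] <- d[hit]
    best_i[hit] <- j
  }
  data.frame(
    center_id = centers$center_id[best_i],
    distance_km = best_d,
    stringsAsFactors = FALSE
  )
}

#' Centers within a radius of a point
#'
#' Returns the ids of all centers whose haversine distance from the point is
#' at most \code{radius_km} (inclusive, so a center exactly on the boundary
#' counts), in \code{center_id} order.
#'
#' @param lat,lon query point, degrees (length 1).
#' @param centers center table (columns \code{center_id}, \code{lat},
#'   \code{lon}).
#' @param radius_km search radius, km (>= 0).
#' @return character vector of center ids (possibly empty).
#' @export
centers_within_radius <- function(lat, lon, centers, radius_km) {
  if (length(radius_km) != 1L || is.na(radius_km) || radius_km < 0) {
    stop("radius_km must be a single non-negative number", call. = FALSE)
  }
  centers <- as.data.frame(centers)
  d <- haversine_km(lat, lon, centers$lat, centers$lon)
  ids <- centers$center_id[d <= radius_km]
  ids[order(ids)]
}
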