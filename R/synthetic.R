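# Synthetic scenario generator. Emulates the statistical structure the
# analysis assumes about real census/registry data: heavy-tailed (log-normal)
# region populations and land areas, centers placed preferentially where
# people are, and an optional diagnosis-distance bias in which diagnosed
# individuals cluster near centers. One master seed; per-stage substreams are
# derived deterministically so regions, centers and individuals can be
# regenerated independently.

#' Build a synthetic scenario configuration
#'
#' @param n_regions number of census-style regions (>= 1).
#' @param bbox named or positional numeric vector
#'   \code{c(lat_min, lat_max, lon_min, lon_max)}; region centroids are drawn
#'   uniformly inside it.
#' @param population_model list \code{(median, sigma)} of the log-normal
#'   region-population distribution (sigma on the log scale).
#' @param area_model list \code{(median, sigma)} of the log-normal land-area
#'   distribution, km^2.
#' @param n_centers number of diagnostic centers (>= 1).
#' @param center_placement \code{"population_weighted"} (host-region
#'   probability proportional to population) or \code{"uniform"}.
#' @param s_model,o_model integer distributions for specialists per center
#'   and annual per-specialist caseload: \code{list(dist = "constant",
#'   value = k)} or \code{list(dist = "poisson", lambda = k)} (shifted so the
#'   draw is >= 1). Defaults are the field estimates of 5 specialists seeing
#'   200 patients each per year.
#' @param diagnosis_bias fraction q in [0, 1] of diagnosed individuals drawn
#'   near a center rather than as general population.
#' @param bias_scale_km exponential scale (km) of the near-center radial
#'   distance for biased draws.
#' @param seed master integer seed.
#' @return object of class \code{scenario_config}.
#' @export
scenario_config <- function(n_regions = 300,
                            bbox = c(lat_min = 25, lat_max = 49,
                                     lon_min = -124, lon_max = -67),
                            population_model = list(median = 10000, sigma = 1.25),
                            area_model = list(median = 1600, sigma = 1.0),
                            n_centers = 80,
                            center_placement = c("population_weighted", "uniform"),
                            s_model = list(dist = "constant", value = 5),
                            o_model = list(dist = "constant", value = 200),
                            diagnosis_bias = 0,
                            bias_scale_km = 10,
                            seed = 1L) {
  center_placement <- match.arg(center_placement)
  bbox <- as.numeric(bbox)
  if (length(bbox) != 4L || anyNA(bbox)) {
    stop("bbox must be c(lat_min, lat_max, lon_min, lon_max)", call. = FALSE)
  }
  names(bbox) <- c("lat_min", "lat_max", "lon_min", "lon_max")
  if (bbox["lat_min"] >= bbox["lat_max"] || bbox["lon_min"] >= bbox["lon_max"]) {
    stop("bbox must be well-ordered (min < max on both axes)", call. = FALSE)
  }
  if (n_regions < 1 || n_centers < 1) {
    stop("n_regions and n_centers must be >= 1", call. = FALSE)
  }
  if (diagnosis_bias < 0 || diagnosis_bias > 1) {
    stop("diagnosis_bias must lie in [0, 1]", call. = FALSE)
  }
  if (bias_scale_km <= 0) stop("bias_scale_km must be > 0", call. = FALSE)
  structure(list(
    n_regions = as.integer(n_regions),
    bbox = bbox,
    population_model = population_model,
    area_model = area_model,
    n_centers = as.integer(n_centers),
    center_placement = center_placement,
    s_model = s_model,
    o_model = o_model,
    diagnosis_bias = diagnosis_bias,
    bias_scale_km = bias_scale_km,
    seed = as.integer(seed)
  ), class = "scenario_config")
}

#' Named scenario presets
#'
#' \code{"us_like_small"}: 300 regions, 80 centers, continental-US-like
#' bounding box, no diagnosis bias; with \code{sampling_fraction = 0.008} it
#' yields on the order of 5e4 individuals and runs in seconds.
#' \code{"biased_diagnosis"}: same geography with diagnosis bias q = 0.8 at
#' scale 10 km, the configuration used to check that the pipeline detects a
#' diagnosed-closer-to-centers effect.
#'
#' @param name preset name.
#' @param seed master seed to embed in the config.
#' @return a \code{scenario_config}.
#' @export
scenario_preset <- function(name = c("us_like_small", "biased_diagnosis"),
                            seed = 1L) {
  name <- match.arg(name)
  switch(name,
    us_like_small = scenario_config(seed = seed),
    biased_diagnosis = scenario_config(diagnosis_bias = 0.8,
                                       bias_scale_km = 10, seed = seed)
  )
}

# Deterministic per-stage substream seeds from the master seed, kept within
# 32-bit integer range.
stage_seed <- function(seed, stage) {
  offsets <- c(regions = 101L, centers = 202L, individuals = 303L,
               placement = 404L, assignment = 505L)
  if (!stage %in% names(offsets)) stop("unknown stage: ", stage, call. = FALSE)
  (abs(as.integer(seed)) + offsets[[stage]] * 7919L) %% 2147483629L
}

draw_integer_model <- function(model, n) {
  dist <- if (is.null(model$dist)) "constant" else model$dist
  switch(dist,
    constant = rep(as.integer(model$value), n),
    poisson = 1L + stats::rpois(n, lambda = model$lambda - 1),
    stop("unknown integer model: ", dist, call. = FALSE)
  )
}

#' Generate a synthetic region table
#'
#' Centroids uniform in the scenario bbox; populations and land areas drawn
#' from the configured log-normals (population rounded, floored at 1).
#'
#' @param config a \code{scenario_config}.
#' @return validated region table (see \code{\link{validate_regions}}).
#' @export
generate_regions <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(stage_seed(config$seed, "regions"))
  n <- config$n_regions
  bb <- config$bbox
  pm <- config$population_model
  am <- config$area_model
  regions <- data.frame(
    region_id = sprintf("R%04d", seq_len(n)),
    name = sprintf("region-%04d", seq_len(n)),
    lat = stats::runif(n, bb["lat_min"], bb["lat_max"]),
    lon = stats::runif(n, bb["lon_min"], bb["lon_max"]),
    land_area_km2 = stats::rlnorm(n, meanlog = log(am$median), sdlog = am$sigma),
    population = pmax(1, round(stats::rlnorm(n, meanlog = log(pm$median),
                                             sdlog = pm$sigma))),
    stringsAsFactors = FALSE
  )
  validate_regions(regions)
}

region_disc_radius <- function(regions) sqrt(regions$land_area_km2 / pi)

# Sample host regions with probability proportional to weight, then place one
# point uniformly inside each host's equal-area disc.
place_in_regions <- function(regions, n, weights) {
  idx <- sample.int(nrow(regions), n, replace = TRUE, prob = weights)
  R <- region_disc_radius(regions)
  r <- R[idx] * sqrt(stats::runif(n))
  bearing <- stats::runif(n, 0, 360)
  pts <- geo_destination(regions$lat[idx], regions$lon[idx], bearing, r)
  cbind(pts, region_idx = idx)
}

#' Generate a synthetic diagnostic-center registry
#'
#' Each center's host region is drawn with probability proportional to
#' population (\code{population_weighted}) or uniformly; the center is then
#' placed uniformly within the host's equal-area disc. Specialist counts
#' \code{s} and caseloads \code{o} come from the configured integer models.
#'
#' @param regions validated region table.
#' @param config a \code{scenario_config}.
#' @return validated center table (see \code{\link{validate_centers}}).
#' @export
generate_centers <- function(regions, config) {
  stopifnot(inherits(config, "scenario_config"))
  regions <- validate_regions(regions)
  if (nrow(regions) == 0L) stop("regions must be non-empty", call. = FALSE)
  set.seed(stage_seed(config$seed, "centers"))
  n <- config$n_centers
  w <- if (config$center_placement == "population_weighted") {
    regions$population
  } else {
    rep(1, nrow(regions))
  }
  if (sum(w) <= 0) stop("total placement weight must be positive", call. = FALSE)
  pts <- place_in_regions(regions, n, w)
  centers <- data.frame(
    center_id = sprintf("C%04d", seq_len(n)),
    name = sprintf("center-%04d", seq_len(n)),
    lat = pts$lat,
    lon = pts$lon,
    s = draw_integer_model(config$s_model, n),
    o = draw_integer_model(config$o_model, n),
    stringsAsFactors = FALSE
  )
  attr(centers, "host_region") <- regions$region_id[pts$region_idx]
  validate_centers(centers)
}

#' Generate diagnosed individuals, optionally biased toward centers
#'
#' Each diagnosed individual is, with probability \code{diagnosis_bias}, a
#' near-center draw: a uniformly chosen center plus an exponential
#' (\code{bias_scale_km}) radial displacement in a uniform direction (no
#' region id). Otherwise it is a general-population draw: a
#' population-weighted random region, uniform within its disc. Bias 0 makes
#' the diagnosed sample statistically identical to the general population;
#' bias 1 concentrates it entirely near centers.
#'
#' @param regions validated region table.
#' @param centers validated center table.
#' @param config a \code{scenario_config}.
#' @param n_diagnosed number of diagnosed individuals to generate.
#' @return validated individual table with \code{diagnosed = TRUE} rows.
#' @export
generate_individuals <- function(regions, centers, config, n_diagnosed) {
  stopifnot(inherits(config, "scenario_config"))
  regions <- validate_regions(regions)
  centers <- validate_centers(centers)
  if (nrow(regions) == 0L || nrow(centers) == 0L) {
    stop("regions and centers must be non-empty", call. = FALSE)
  }
  if (n_diagnosed < 0) stop("n_diagnosed must be >= 0", call. = FALSE)
  set.seed(stage_seed(config$seed, "individuals"))
  n <- as.integer(n_diagnosed)
  near <- stats::runif(n) < config$diagnosis_bias
  lat <- numeric(n); lon <- numeric(n); region_id <- character(n)
  if (any(near)) {
    k <- sum(near)
    ci <- sample.int(nrow(centers), k, replace = TRUE)
    r <- stats::rexp(k, rate = 1 / config$bias_scale_km)
    bearing <- stats::runif(k, 0, 360)
    pts <- geo_destination(centers$lat[ci], centers$lon[ci], bearing, r)
    lat[near] <- pts$lat; lon[near] <- pts$lon
    region_id[near] <- ""
  }
  if (any(!near)) {
    k <- sum(!near)
    pts <- place_in_regions(regions, k, regions$population)
    lat[!near] <- pts$lat; lon[!near] <- pts$lon
    region_id[!near] <- regions$region_id[pts$region_idx]
  }
  validate_individuals(data.frame(
    individual_id = sprintf("D%06d", seq_len(n)),
    lat = lat,
    lon = lon,
    region_id = region_id,
    diagnosed = TRUE,
    stringsAsFactors = FALSE
  ))
}
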