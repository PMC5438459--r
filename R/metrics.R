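# Stage 3: the core demand/supply metrics.
#
# Resource load for a center r:   RL_r = (N * p) / (s * o)
#   N  individuals assigned (nearby), p  fraction needing screening,
#   s  specialists at the center,    o  annual per-specialist caseload.
#
# Resource availability at a location l, under the default form:
#   RA_l = sum_r  [1 / max(RL_r, 1)] * decay(d(r, l); z)
# with capped-inverse decay (1 within the willingness-to-travel distance z,
# z/d beyond it), so a single adequately loaded resource (RL <= 1) within z
# yields RA exactly 1. A resource gap is RA < 1 (strict).

#' Metric parameters
#'
#' @param p fraction of the population in need of an autism screening;
#'   default 0.00195 (6.5\% of the population at diagnosis-appropriate age
#'   times 3\% of those needing screening).
#' @param z willingness-to-travel distance, km; default 30.
#' @param decay distance decay for availability: \code{"capped_inverse"}
#'   (1 for d <= z, z/d beyond; the default), \code{"exponential"}
#'   (\code{exp(-d/z)}), or \code{"hard_cutoff"} (1 for d <= z, 0 beyond).
#' @param clamp_load_floor when TRUE (default) a center's availability weight
#'   is \code{1 / max(RL, 1)}: spare capacity does not push a location's
#'   availability above what one adequate center provides. When FALSE the
#'   weight is the raw \code{1 / RL} (infinite for RL = 0).
#' @param tiers_km radius tiers for tiered-random assignment.
#' @return object of class \code{metric_params}.
#' @export
metric_params <- function(p = 0.00195, z = 30,
                          decay = c("capped_inverse", "exponential", "hard_cutoff"),
                          clamp_load_floor = TRUE,
                          tiers_km = DEFAULT_TIERS_KM) {
  decay <- match.arg(decay)
  if (p <= 0 || p >= 1) stop("p must lie in (0, 1)", call. = FALSE)
  if (z <= 0) stop("z must be > 0", call. = FALSE)
  structure(list(p = p, z = z, decay = decay,
                 clamp_load_floor = isTRUE(clamp_load_floor),
                 tiers_km = tiers_km),
            class = "metric_params")
}

#' Screening-need fraction from its two published components
#'
#' The fraction p of the population in need of an autism screening is the
#' product of the fraction at a diagnosis-appropriate age and the fraction of
#' those needing a screening: 6.5\% x 3\% = 0.195\%.
#'
#' @param age_fraction fraction at diagnosis-appropriate age, in (0, 1).
#' @param need_fraction fraction of those needing screening, in (0, 1).
#' @return the product.
#' @export
derive_screening_fraction <- function(age_fraction = 0.065, need_fraction = 0.03) {
  for (x in list(age_fraction, need_fraction)) {
    if (length(x) != 1L || is.na(x) || x <= 0 || x >= 1) {
      stop("fractions must lie in (0, 1)", call. = FALSE)
    }
  }
  age_fraction * need_fraction
}

#' Resource load for centers
#'
#' Computes RL = (n_assigned * p) / (s * o) for each center: annual screening
#' demand over annual service capacity. RL = 1 means the center exactly
#' meets its demand; RL = 6 means six times more demand than it can handle.
#' Linear in \code{n_assigned}.
#'
#' @param centers center table (columns \code{center_id, s, o}).
#' @param counts per-center counts (\code{center_id, n_assigned}), e.g. from
#'   \code{\link{per_center_counts}}.
#' @param p screening-need fraction.
#' @return data.frame \code{center_id, n_assigned, demand, capacity, rl}.
#' @export
resource_load <- function(centers, counts, p = 0.00195) {
  centers <- validate_centers(centers)
  counts <- as.data.frame(counts)
  require_columns(counts, c("center_id", "n_assigned"))
  if (any(counts$n_assigned < 0)) stop("n_assigned must be >= 0", call. = FALSE)
  i <- match(centers$center_id, counts$center_id)
  if (anyNA(i)) {
    stop("missing n_assigned for center(s): ",
         paste(centers$center_id[is.na(i)], collapse = ", "), call. = FALSE)
  }
  n_assigned <- counts$n_assigned[i]
  demand <- n_assigned * p
  capacity <- centers$s * centers$o
  data.frame(
    center_id = centers$center_id,
    n_assigned = n_assigned,
    demand = demand,
    capacity = capacity,
    rl = demand / capacity,
    stringsAsFactors = FALSE
  )
}

decay_weight <- function(d, z, decay) {
  switch(decay,
    capped_inverse = ifelse(d <= z, 1, z / d),
    exponential = exp(-d / z),
    hard_cutoff = as.numeric(d <= z),
    stop("unknown decay: ", decay, call. = FALSE)
  )
}

load_weight <- function(rl, clamp_load_floor) {
  if (clamp_load_floor) 1 / pmax(rl, 1) else 1 / rl
}

#' Resource availability at locations
#'
#' RA at a location is the sum over centers of the center's load weight times
#' its distance decay (see \code{\link{metric_params}}). With the defaults,
#' RA >= 1 whenever at least one center with RL <= 1 lies within z, and a
#' location with no reachable capacity scores 0. Vectorized over locations.
#'
#' @param lat,lon location(s), degrees.
#' @param loads load table (\code{center_id, rl}) joined against
#'   \code{centers}; every center must have a load row.
#' @param centers center table.
#' @param params a \code{metric_params}.
#' @return numeric vector of RA values, one per location.
#' @export
resource_availability <- function(lat, lon, loads, centers,
                                  params = metric_params()) {
  stopifnot(inherits(params, "metric_params"))
  centers <- as.data.frame(centers)
  loads <- as.data.frame(loads)
  if (nrow(centers) == 0L) return(rep(0, length(lat)))
  i <- match(centers$center_id, loads$center_id)
  if (anyNA(i)) {
    stop("missing resource load for center(s): ",
         paste(centers$center_id[is.na(i)], collapse = ", "), call. = FALSE)
  }
  w <- load_weight(loads$rl[i], params$clamp_load_floor)
  ra <- numeric(length(lat))
  for (j in seq_len(nrow(centers))) {
    d <- haversine_km(lat, lon, centers$lat[j], centers$lon[j])
    ra <- ra + w[j] * decay_weight(d, params$z, params$decay)
  }
  ra
}

#' Classify resource gaps
#'
#' A resource gap is a location whose resource availability is strictly less
#' than 1; RA = 1 exactly (one adequate resource within reach) is not a gap.
#'
#' @param ra non-negative availability value(s).
#' @return logical vector, TRUE where RA < 1.
#' @export
classify_gap <- function(ra) {
  if (any(is.na(ra)) || any(ra < 0)) {
    stop("ra must be non-negative", call. = FALSE)
  }
  ra < 1
}

#' Distance-to-care summary
#'
#' Mean, sample standard deviation (n - 1), median (midpoint for even n),
#' maximum, and the percentage of individuals within z km (inclusive) of
#' their assigned center.
#'
#' @param assignment assignment table.
#' @param z willingness-to-travel distance, km.
#' @param diagnosed_only when TRUE, restrict to diagnosed individuals;
#'   requires \code{individuals}.
#' @param individuals individual table used for the diagnosed filter.
#' @return list \code{mean_km, sd_km, median_km, max_km, pct_within_z, n}.
#' @export
summarize_distances <- function(assignment, z = 30, diagnosed_only = FALSE,
                                individuals = NULL) {
  assignment <- as.data.frame(assignment)
  d <- assignment$distance_km
  if (diagnosed_only) {
    if (is.null(individuals)) {
      stop("diagnosed_only = TRUE requires the individual table", call. = FALSE)
    }
    diag_ids <- individuals$individual_id[individuals$diagnosed]
    d <- d[assignment$individual_id %in% diag_ids]
  }
  if (length(d) == 0L) {
    stop("no individuals left to summarize after filtering", call. = FALSE)
  }
  list(
    mean_km = mean(d),
    sd_km = if (length(d) > 1L) stats::sd(d) else 0,
    median_km = stats::median(d),
    max_km = max(d),
    pct_within_z = 100 * mean(d <= z),
    n = length(d)
  )
}

#' Resource-availability grid for heatmapping
#'
#' Evaluates resource availability on a regular latitude/longitude lattice
#' over \code{bbox} with step \code{resolution_deg} (the lattice includes
#' both bbox edges: \code{ceiling(span / resolution) + 1} points per axis),
#' and flags gaps per \code{\link{classify_gap}}.
#'
#' @param bbox numeric \code{c(lat_min, lat_max, lon_min, lon_max)}.
#' @param resolution_deg lattice step, degrees (> 0); default 0.25.
#' @param loads,centers,params as in \code{\link{resource_availability}}.
#' @return data.frame \code{lat, lon, ra, gap}.
#' @export
availability_grid <- function(bbox, resolution_deg = 0.25, loads, centers,
                              params = metric_params()) {
  bbox <- as.numeric(bbox)
  if (length(bbox) != 4L || bbox[1] >= bbox[2] || bbox[3] >= bbox[4]) {
    stop("bbox must be well-ordered c(lat_min, lat_max, lon_min, lon_max)",
         call. = FALSE)
  }
  if (length(resolution_deg) != 1L || is.na(resolution_deg) || resolution_deg <= 0) {
    stop("resolution_deg must be > 0", call. = FALSE)
  }
  n_lat <- ceiling((bbox[2] - bbox[1]) / resolution_deg) + 1
  n_lon <- ceiling((bbox[4] - bbox[3]) / resolution_deg) + 1
  lats <- bbox[1] + (seq_len(n_lat) - 1) * resolution_deg
  lons <- bbox[3] + (seq_len(n_lon) - 1) * resolution_deg
  lats <- pmin(lats, 90)
  lons <- normalize_lon(lons)
  grid <- expand.grid(lat = lats, lon = lons, KEEP.OUT.ATTRS = FALSE)
  grid$ra <- resource_availability(grid$lat, grid$lon, loads, centers, params)
  grid$gap <- classify_gap(grid$ra)
  grid
}
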