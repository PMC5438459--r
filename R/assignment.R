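# Stage 2: map individuals to diagnostic centers. Two rules are used in the
# analyses: nearest-center (distance-to-care summaries) and tiered-radius
# random (resource-load computation), where each individual is assigned
# uniformly at random among the centers within the smallest radius tier that
# contains at least one center.

#' Default radius tiers (km) for tiered-random assignment
#' @export
DEFAULT_TIERS_KM <- c(25, 100, 500, 3000)

# Full n x m haversine distance matrix, individuals x centers.
distance_matrix_km <- function(individuals, centers) {
  n <- nrow(individuals)
  m <- nrow(centers)
  d <- matrix(0, n, m)
  for (j in seq_len(m)) {
    d[, j] <- haversine_km(individuals$lat, individuals$lon,
                           centers$lat[j], centers$lon[j])
  }
  d
}

new_assignment <- function(individual_id, center_id, distance_km,
                           tier_km = NA_real_, fallback = FALSE) {
  n <- length(individual_id)
  data.frame(
    individual_id = individual_id,
    center_id = center_id,
    distance_km = distance_km,
    tier_km = rep_len(tier_km, n),
    fallback = rep_len(fallback, n),
    stringsAsFactors = FALSE
  )
}

#' Assign every individual to its nearest center
#'
#' Distance ties are broken by smallest \code{center_id}. \code{tier_km} is
#' NA and \code{fallback} FALSE for every row.
#'
#' @param individuals individual table.
#' @param centers center table (non-empty).
#' @return assignment table: \code{individual_id, center_id, distance_km,
#'   tier_km, fallback}.
#' @export
assign_nearest <- function(individuals, centers) {
  individuals <- as.data.frame(individuals)
  centers <- as.data.frame(centers)
  if (nrow(centers) == 0L) stop("centers must be non-empty", call. = FALSE)
  nn <- nearest_center(individuals$lat, individuals$lon, centers)
  new_assignment(individuals$individual_id, nn$center_id, nn$distance_km)
}

#' Assign individuals uniformly at random within the smallest viable tier
#'
#' For each individual the smallest radius in \code{tiers_km} containing at
#' least one center (inclusive boundary) is found, and the assigned center is
#' drawn uniformly at random among the centers within that radius;
#' \code{tier_km} records the radius used. Individuals with no center within
#' the largest tier fall back to their nearest center with
#' \code{fallback = TRUE} — flagged, never dropped, so the assignment always
#' partitions the individuals.
#'
#' @param individuals individual table.
#' @param centers center table (non-empty).
#' @param tiers_km strictly ascending radii, km.
#' @param seed optional integer seeding an assignment substream; NULL uses
#'   the current RNG state.
#' @return assignment table (see \code{\link{assign_nearest}}).
#' @export
assign_tiered_random <- function(individuals, centers,
                                 tiers_km = DEFAULT_TIERS_KM, seed = NULL) {
  individuals <- as.data.frame(individuals)
  centers <- as.data.frame(centers)
  if (nrow(centers) == 0L) stop("centers must be non-empty", call. = FALSE)
  if (length(tiers_km) == 0L || any(diff(tiers_km) <= 0) || any(tiers_km < 0)) {
    stop("tiers_km must be a non-empty strictly ascending vector of radii",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(stage_seed(seed, "assignment"))
  n <- nrow(individuals)
  if (n == 0L) return(new_assignment(character(0), character(0), numeric(0)))
  d <- distance_matrix_km(individuals, centers)
  # smallest tier with >= 1 center, per individual (NA if none)
  tier_of <- rep(NA_real_, n)
  mind <- d[cbind(seq_len(n), max.col(-d, ties.method = "first"))]
  for (t in rev(tiers_km)) tier_of[mind <= t] <- t
  # uniform draw among in-tier centers via random-key argmin: keys are iid
  # uniform, keys outside the tier are pushed to +Inf, the row argmin is then
  # a uniform choice among in-tier centers
  key <- matrix(stats::runif(n * ncol(d)), n, ncol(d))
  key[d > ifelse(is.na(tier_of), Inf, tier_of)] <- Inf
  pick <- max.col(-key, ties.method = "first")
  out <- new_assignment(
    individuals$individual_id,
    centers$center_id[pick],
    d[cbind(seq_len(n), pick)],
    tier_km = tier_of,
    fallback = FALSE
  )
  # fallback: nothing within the largest tier -> nearest center, flagged
  fb <- is.na(tier_of)
  if (any(fb)) {
    nn <- nearest_center(individuals$lat[fb], individuals$lon[fb], centers)
    out$center_id[fb] <- nn$center_id
    out$distance_km[fb] <- nn$distance_km
    out$fallback[fb] <- TRUE
  }
  out
}

#' Per-center assignee counts
#'
#' Tallies the number of individuals assigned to each center; centers with no
#' assignees count 0. The counts always sum to the number of assignment rows
#' (the assignment partitions the individuals).
#'
#' @param assignment assignment table.
#' @param centers center table giving the full center universe.
#' @return data.frame \code{center_id, n_assigned} in center-id order.
#' @export
per_center_counts <- function(assignment, centers) {
  centers <- as.data.frame(centers)
  tab <- table(factor(assignment$center_id, levels = sort(centers$center_id)))
  data.frame(
    center_id = names(tab),
    n_assigned = as.integer(tab),
    stringsAsFactors = FALSE
  )
}
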