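#' Simulate individual locations from a census-style region table
#'
#' Stage 1 of the pipeline: for each region, draws
#' \code{round(population * sampling_fraction)} individuals uniformly within
#' the region's equal-area disc (radius \code{sqrt(land_area_km2 / pi)}),
#' tagged with the region id and \code{diagnosed = FALSE}. Rounding is R's
#' round-half-to-even, so halving the fraction halves expected totals exactly
#' and totals are reproducible. Regions with population 0 contribute no
#' individuals. A fraction of 1.0 simulates the full recorded population.
#'
#' @param regions region table (validated; see \code{\link{validate_regions}}).
#' @param sampling_fraction fraction in (0, 1] of each region's population to
#'   simulate.
#' @param seed optional integer; when given, seeds a placement substream so
#'   the draw is reproducible. When NULL the current RNG state is used.
#' @param id_prefix prefix for generated individual ids.
#' @return validated individual table.
#' @export
place_population <- function(regions, sampling_fraction = 1.0, seed = NULL,
                             id_prefix = "I") {
  regions <- validate_regions(regions)
  if (length(sampling_fraction) != 1L || is.na(sampling_fraction) ||
      sampling_fraction <= 0 || sampling_fraction > 1) {
    stop("sampling_fraction must lie in (0, 1]", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(stage_seed(seed, "placement"))
  counts <- round(regions$population * sampling_fraction)
  total <- sum(counts)
  if (total == 0L) {
    return(validate_individuals(data.frame(
      individual_id = character(0), lat = numeric(0), lon = numeric(0),
      region_id = character(0), diagnosed = logical(0)
    )))
  }
  idx <- rep(seq_len(nrow(regions)), counts)
  R <- region_disc_radius(regions)
  r <- R[idx] * sqrt(stats::runif(total))
  bearing <- stats::runif(total, 0, 360)
  pts <- geo_destination(regions$lat[idx], regions$lon[idx], bearing, r)
  validate_individuals(data.frame(
    individual_id = sprintf("%s%07d", id_prefix, seq_len(total)),
    lat = pts$lat,
    lon = pts$lon,
    region_id = regions$region_id[idx],
    diagnosed = FALSE,
    stringsAsFactors = FALSE
  ))
}
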