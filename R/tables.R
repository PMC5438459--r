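# Table validators for the three input schemas. Readers in io.R call these,
# and generated tables are run through them too, so every stage sees the same
# invariants: unique ids, coordinates in range, positive areas where people
# live, positive service capacity.

table_error <- function(file, row, field, msg) {
  loc <- if (is.null(file)) "" else sprintf(" in %s", file)
  stop(sprintf("invalid table%s (row %s, field %s): %s", loc, row, field, msg),
       call. = FALSE)
}

require_columns <- function(df, cols, file = NULL) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    stop(sprintf("missing column(s) %s%s",
                 paste(missing, collapse = ", "),
                 if (is.null(file)) "" else sprintf(" in %s", file)),
         call. = FALSE)
  }
}

check_numeric_field <- function(df, field, file) {
  x <- df[[field]]
  if (!is.numeric(x)) {
    suppressWarnings(xn <- as.numeric(x))
    bad <- which(is.na(xn) & !is.na(x))
    if (length(bad) > 0L) {
      table_error(file, bad[1L], field, sprintf("non-numeric value '%s'", x[bad[1L]]))
    }
    x <- xn
  }
  bad <- which(is.na(x))
  if (length(bad) > 0L) table_error(file, bad[1L], field, "missing value")
  x
}

check_coord_range <- function(df, file) {
  bad <- which(df$lat < -90 | df$lat > 90)
  if (length(bad) > 0L) {
    table_error(file, bad[1L], "lat", sprintf("latitude %g out of [-90, 90]", df$lat[bad[1L]]))
  }
  bad <- which(df$lon < -180 | df$lon >= 180)
  if (length(bad) > 0L) {
    table_error(file, bad[1L], "lon", sprintf("longitude %g out of [-180, 180)", df$lon[bad[1L]]))
  }
}

check_unique_id <- function(df, field, file) {
  dup <- which(duplicated(df[[field]]))
  if (length(dup) > 0L) {
    table_error(file, dup[1L], field, sprintf("duplicate id '%s'", df[[field]][dup[1L]]))
  }
}

#' Validate a region table
#'
#' Schema: \code{region_id, name, lat, lon, land_area_km2, population}.
#' Checks unique ids, coordinate ranges, non-negative integer-valued
#' populations, and that any region with population > 0 has positive land
#' area (people must have somewhere to stand).
#'
#' @param regions data.frame.
#' @param file optional source path, used in error messages.
#' @return the validated data.frame with numeric columns coerced.
#' @export
validate_regions <- function(regions, file = NULL) {
  regions <- as.data.frame(regions)
  require_columns(regions, c("region_id", "name", "lat", "lon",
                             "land_area_km2", "population"), file)
  regions$region_id <- as.character(regions$region_id)
  regions$name <- as.character(regions$name)
  for (f in c("lat", "lon", "land_area_km2", "population")) {
    regions[[f]] <- check_numeric_field(regions, f, file)
  }
  check_unique_id(regions, "region_id", file)
  check_coord_range(regions, file)
  bad <- which(regions$population < 0)
  if (length(bad) > 0L) table_error(file, bad[1L], "population", "negative population")
  bad <- which(regions$population > 0 & regions$land_area_km2 <= 0)
  if (length(bad) > 0L) {
    table_error(file, bad[1L], "land_area_km2",
                "non-positive land area with positive population")
  }
  regions
}

#' Validate a diagnostic-center table
#'
#' Schema: \code{center_id, name, lat, lon, s, o} where \code{s} is the
#' specialist headcount and \code{o} the annual per-specialist caseload.
#' Capacity \code{s * o} must be positive for every center.
#'
#' @inheritParams validate_regions
#' @param centers data.frame.
#' @return the validated data.frame.
#' @export
validate_centers <- function(centers, file = NULL) {
  centers <- as.data.frame(centers)
  require_columns(centers, c("center_id", "name", "lat", "lon", "s", "o"), file)
  centers$center_id <- as.character(centers$center_id)
  centers$name <- as.character(centers$name)
  for (f in c("lat", "lon", "s", "o")) {
    centers[[f]] <- check_numeric_field(centers, f, file)
  }
  check_unique_id(centers, "center_id", file)
  check_coord_range(centers, file)
  bad <- which(centers$s < 1 | centers$o < 1)
  if (length(bad) > 0L) {
    field <- if (centers$s[bad[1L]] < 1) "s" else "o"
    table_error(file, bad[1L], field, "s and o must each be >= 1 (capacity s*o > 0)")
  }
  centers
}

#' Validate an individual table
#'
#' Schema: \code{individual_id, lat, lon, region_id, diagnosed} with
#' \code{diagnosed} coded 0/1 (or logical). \code{region_id} may be empty for
#' individuals not placed from a region.
#'
#' @inheritParams validate_regions
#' @param individuals data.frame.
#' @return the validated data.frame with \code{diagnosed} as logical.
#' @export
validate_individuals <- function(individuals, file = NULL) {
  individuals <- as.data.frame(individuals)
  require_columns(individuals,
                  c("individual_id", "lat", "lon", "region_id", "diagnosed"),
                  file)
  individuals$individual_id <- as.character(individuals$individual_id)
  individuals$region_id <- as.character(individuals$region_id)
  individuals$region_id[is.na(individuals$region_id)] <- ""
  for (f in c("lat", "lon")) {
    individuals[[f]] <- check_numeric_field(individuals, f, file)
  }
  d <- individuals$diagnosed
  if (is.logical(d)) {
    dv <- d
  } else {
    suppressWarnings(dn <- as.numeric(d))
    bad <- which(!(dn %in% c(0, 1)))
    if (length(bad) > 0L) {
      table_error(file, bad[1L], "diagnosed", "diagnosed must be 0 or 1")
    }
    dv <- dn == 1
  }
  individuals$diagnosed <- dv
  check_unique_id(individuals, "individual_id", file)
  check_coord_range(individuals, file)
  individuals
}
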