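# Readers and writers for the pipeline's file interfaces, plus the seeded
# end-to-end driver. All files are UTF-8; CSV is comma-separated with a
# mandatory header; every output file is written atomically (temp file in the
# same directory, then rename) so a failing stage never leaves a partial
# artifact behind.

read_table_checked <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                  check.names = TRUE)
}

#' Read and validate a region table CSV
#'
#' Schema: \code{region_id,name,lat,lon,land_area_km2,population}. Parse
#' errors name the file, row, and field.
#'
#' @param path CSV path.
#' @return validated region table.
#' @export
read_regions <- function(path) validate_regions(read_table_checked(path), file = path)

#' Read and validate a center table CSV
#'
#' Schema: \code{center_id,name,lat,lon,s,o}.
#'
#' @param path CSV path.
#' @return validated center table.
#' @export
read_centers <- function(path) validate_centers(read_table_checked(path), file = path)

#' Read and validate an individual table CSV
#'
#' Schema: \code{individual_id,lat,lon,region_id,diagnosed} (diagnosed 0/1).
#'
#' @param path CSV path.
#' @return validated individual table.
#' @export
read_individuals <- function(path) validate_individuals(read_table_checked(path), file = path)

# Atomic writer: materialize via `writer(tmp)` then rename into place.
write_atomic <- function(path, writer) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) stop("could not write ", path, call. = FALSE)
  invisible(path)
}

# Format numerics at 6 significant digits so outputs are stable across runs.
format_num_cols <- function(df, digits = 6) {
  for (nm in names(df)) {
    if (is.double(df[[nm]])) df[[nm]] <- signif(df[[nm]], digits)
  }
  df
}

#' Write a data frame as CSV (atomic, 6 significant digits)
#'
#' @param df data.frame.
#' @param path output path.
#' @export
write_table_csv <- function(df, path) {
  df <- format_num_cols(as.data.frame(df))
  if ("diagnosed" %in% names(df)) df$diagnosed <- as.integer(df$diagnosed)
  if ("fallback" %in% names(df)) df$fallback <- as.integer(df$fallback)
  if ("gap" %in% names(df)) df$gap <- as.integer(df$gap)
  write_atomic(path, function(tmp) {
    utils::write.csv(df, tmp, row.names = FALSE, quote = FALSE, na = "")
  })
}

#' Write an availability grid as GeoJSON
#'
#' RFC 7946 FeatureCollection of Point features, coordinates in
#' \code{[lon, lat]} order, with properties \code{ra} and \code{gap}.
#'
#' @param grid grid table from \code{\link{availability_grid}}.
#' @param path output path.
#' @export
write_grid_geojson <- function(grid, path) {
  features <- lapply(seq_len(nrow(grid)), function(i) {
    list(
      type = "Feature",
      geometry = list(
        type = "Point",
        coordinates = c(signif(grid$lon[i], 6), signif(grid$lat[i], 6))
      ),
      properties = list(ra = signif(grid$ra[i], 6), gap = grid$gap[i])
    )
  })
  fc <- list(type = "FeatureCollection", features = features)
  write_atomic(path, function(tmp) {
    jsonlite::write_json(fc, tmp, auto_unbox = TRUE, digits = NA)
  })
}

#' Write a summary (or any list) as JSON
#'
#' @param x named list.
#' @param path output path.
#' @export
write_summary_json <- function(x, path) {
  write_atomic(path, function(tmp) {
    jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  })
}

#' Run the full accessibility pipeline
#'
#' End-to-end seeded run: obtain regions/centers/individuals (from a named
#' synthetic preset or from CSV paths), place the general population, assign
#' individuals to centers, compute per-center resource loads (from the
#' general-population assignment, with counts scaled back to the full
#' population by \code{1 / sampling_fraction}), distance
#' summaries (all individuals and the diagnosed subset when present), the
#' availability grid, and write every artifact plus a manifest sufficient to
#' reproduce the run. Identical config and seed give byte-identical outputs.
#'
#' @param out_dir output directory (created if needed).
#' @param preset synthetic preset name (see \code{\link{scenario_preset}});
#'   mutually exclusive with the path arguments.
#' @param regions_path,centers_path,individuals_path input CSVs; used when
#'   \code{preset} is NULL. \code{individuals_path} is optional (the general
#'   population is always simulated from the region table; a provided
#'   individual table contributes the diagnosed sample).
#' @param rule assignment rule, \code{"nearest"} or \code{"tiered"}.
#' @param params a \code{metric_params}.
#' @param sampling_fraction fraction of each region's population to simulate.
#' @param n_diagnosed diagnosed individuals to generate under a preset.
#' @param grid_resolution_deg availability-grid step, degrees.
#' @param seed master seed for every random stage.
#' @return invisibly, a list with the in-memory tables and artifact paths.
#' @export
run_pipeline <- function(out_dir,
                         preset = NULL,
                         regions_path = NULL, centers_path = NULL,
                         individuals_path = NULL,
                         rule = c("nearest", "tiered"),
                         params = metric_params(),
                         sampling_fraction = 0.008,
                         n_diagnosed = 2000,
                         grid_resolution_deg = 1,
                         seed = 1L) {
  rule <- match.arg(rule)
  stopifnot(inherits(params, "metric_params"))
  has_paths <- !is.null(regions_path) || !is.null(centers_path)
  if (is.null(preset) == !has_paths) {
    stop("provide exactly one of: a preset name, or regions/centers paths",
         call. = FALSE)
  }
  if (!is.null(preset)) {
    config <- scenario_preset(preset, seed = seed)
    regions <- generate_regions(config)
    centers <- generate_centers(regions, config)
    diagnosed <- generate_individuals(regions, centers, config, n_diagnosed)
  } else {
    regions <- read_regions(regions_path)
    centers <- read_centers(centers_path)
    diagnosed <- if (!is.null(individuals_path)) {
      read_individuals(individuals_path)
    } else {
      NULL
    }
  }
  general <- place_population(regions, sampling_fraction, seed = seed)
  individuals <- rbind(general, diagnosed)

  assignment <- if (rule == "nearest") {
    assign_nearest(individuals, centers)
  } else {
    assign_tiered_random(individuals, centers, params$tiers_km, seed = seed)
  }
  # Loads reflect full-population demand: only general-population rows are
  # counted (the diagnosed table is a convenience sample, not extra demand)
  # and counts are scaled back up by the sampling fraction.
  gen_assign <- assignment[assignment$individual_id %in% general$individual_id, ]
  counts <- per_center_counts(gen_assign, centers)
  counts$n_assigned <- round(counts$n_assigned / sampling_fraction)
  loads <- resource_load(centers, counts, p = params$p)

  summary_all <- summarize_distances(assignment, z = params$z)
  summary_diag <- if (any(individuals$diagnosed)) {
    summarize_distances(assignment, z = params$z, diagnosed_only = TRUE,
                        individuals = individuals)
  } else {
    NULL
  }

  bbox <- c(min(individuals$lat), max(individuals$lat),
            min(individuals$lon), max(individuals$lon))
  grid <- availability_grid(bbox, grid_resolution_deg, loads, centers, params)

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    assignment = file.path(out_dir, "assignment.csv"),
    loads = file.path(out_dir, "loads.csv"),
    summary = file.path(out_dir, "summary.json"),
    grid = file.path(out_dir, "availability_grid.geojson"),
    manifest = file.path(out_dir, "manifest.json")
  )
  write_table_csv(assignment, paths$assignment)
  write_table_csv(loads, paths$loads)
  summary_out <- list(all = lapply(summary_all, signif, 6))
  if (!is.null(summary_diag)) summary_out$diagnosed <- lapply(summary_diag, signif, 6)
  write_summary_json(summary_out, paths$summary)
  write_grid_geojson(grid, paths$grid)
  manifest <- list(
    package = "resourcegaps",
    version = as.character(utils::packageVersion("resourcegaps")),
    seed = seed,
    preset = if (is.null(preset)) NA else preset,
    inputs = list(regions = regions_path, centers = centers_path,
                  individuals = individuals_path),
    rule = rule,
    params = unclass(params),
    sampling_fraction = sampling_fraction,
    n_diagnosed = if (is.null(preset)) NA else n_diagnosed,
    grid_resolution_deg = grid_resolution_deg,
    rows = list(regions = nrow(regions), centers = nrow(centers),
                individuals = nrow(individuals), grid = nrow(grid))
  )
  write_summary_json(manifest, paths$manifest)

  invisible(list(
    regions = regions, centers = centers, individuals = individuals,
    assignment = assignment, loads = loads,
    summary_all = summary_all, summary_diagnosed = summary_diag,
    grid = grid, paths = paths
  ))
}
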