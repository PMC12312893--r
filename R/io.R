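#' Write / read telemetry CSV
#'
#' Schema: `animal_id`, `timestamp` (ISO-8601 UTC), `x`, `y` (projected
#' metres).
#'
#' @param fixes Fix data.frame.
#' @param path CSV path.
#' @export
write_telemetry_csv <- function(fixes, path) {
  out <- data.frame(animal_id = fixes$animal_id,
                    timestamp = iso8601(fixes$timestamp),
                    x = fixes$x, y = fixes$y)
  ok <- tryCatch({ utils::write.csv(out, path, row.names = FALSE); TRUE },
                 error = function(e) FALSE)
  if (!ok) stop("cannot write telemetry to ", path)
  invisible(path)
}

#' @rdname write_telemetry_csv
#' @export
read_telemetry_csv <- function(path) {
  if (!file.exists(path)) stop("no such telemetry file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$timestamp <- parse_iso8601(df$timestamp)
  df
}

#' Write / read a covariate stack as ASCII-grid rasters in a directory
#'
#' Files: `footprint.asc`, `elevation.asc`, `slope.asc`, `landcover.asc`
#' and `lcdist_<class>.asc` per land-cover class.
#'
#' @param stack A [covariate_stack()].
#' @param dir Directory (created if missing).
#' @export
write_covariate_stack <- function(stack, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_ascii_raster(stack$footprint, file.path(dir, "footprint.asc"))
  write_ascii_raster(stack$elevation, file.path(dir, "elevation.asc"))
  write_ascii_raster(stack$slope, file.path(dir, "slope.asc"))
  write_ascii_raster(stack$landcover, file.path(dir, "landcover.asc"))
  for (cl in landcover_classes())
    write_ascii_raster(stack$lc_dist[[cl]],
                       file.path(dir, paste0("lcdist_", cl, ".asc")))
  invisible(dir)
}

#' @rdname write_covariate_stack
#' @export
read_covariate_stack <- function(dir) {
  rd <- function(f) read_ascii_raster(file.path(dir, f))
  lc <- lapply(landcover_classes(), function(cl)
    rd(paste0("lcdist_", cl, ".asc")))
  names(lc) <- landcover_classes()
  fp <- rd("footprint.asc")
  covariate_stack(fp$grid, footprint = fp, elevation = rd("elevation.asc"),
                  slope = rd("slope.asc"), landcover = rd("landcover.asc"),
                  lc_dist = lc)
}

#' Write / read simulation truth as JSON
#'
#' @param truth A [truth_record()].
#' @param path JSON path.
#' @export
write_truth_json <- function(truth, path) {
  payload <- list(mu_beta = lapply(truth$mu_beta, as.list),
                  sd_beta = as.list(truth$sd_beta),
                  fr_intercept = as.list(truth$fr_intercept),
                  fr_slope = as.list(truth$fr_slope),
                  individual_betas = truth$individual_betas,
                  individual_exposures = truth$individual_exposures)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  if (!file.exists(path)) stop("no such truth file: ", path)
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  truth_record(
    mu_beta = lapply(p$mu_beta, unlist),
    sd_beta = unlist(p$sd_beta),
    fr_intercept = unlist(p$fr_intercept),
    fr_slope = unlist(p$fr_slope),
    individual_betas = p$individual_betas,
    individual_exposures = p$individual_exposures)
}

#' Write a complete synthetic fixture set to disk
#'
#' Generates a landscape and two-year telemetry and writes every artefact in
#' open text formats: `telemetry.csv`, `features.geojson`, `park.geojson`,
#' the covariate-stack ASCII rasters under `stack/`, and `truth.json`. The
#' files round-trip through the package's readers.
#'
#' @param dir Output directory (created if needed; must be writable).
#' @param config A [landscape_config()].
#' @param truth A [truth_record()] (defaults to [default_truth()]).
#' @param design Simulation design passed to [simulate_individuals()].
#' @param seed Integer RNG seed.
#' @return Invisibly, the named list of written paths.
#' @export
make_fixture_set <- function(dir, config = landscape_config(),
                             truth = default_truth(),
                             design = list(n_individuals = 3,
                                           n_used_per_individual = 60,
                                           home_range_radius_m = 800),
                             seed = 1) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  land <- generate_landscape(config, seed)
  sim <- simulate_individuals(truth, land, design, seed + 1)
  paths <- list(
    telemetry = file.path(dir, "telemetry.csv"),
    features = file.path(dir, "features.geojson"),
    park = file.path(dir, "park.geojson"),
    stack = file.path(dir, "stack"),
    truth = file.path(dir, "truth.json"))
  write_telemetry_csv(sim$fixes, paths$telemetry)
  write_geojson_layers(land$layers, paths$features)
  write_geojson_layers(
    list(feature_layer("park_boundary",
                       list(list(type = "polygon", coords = land$park)))),
    paths$park)
  write_covariate_stack(land$stack, paths$stack)
  write_truth_json(sim$truth, paths$truth)
  invisible(paths)
}
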