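# Shared small helpers and the covariate-stack container.

# Evaluate code under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Land-cover class names
#'
#' The five broad land-cover types used throughout, in the fixed
#' (alphabetical) order of the model's linear predictor.
#' @export
landcover_classes <- function() {
  c("barren", "forest", "herbaceous", "scrub", "water")
}

#' Aligned covariate stack
#'
#' Bundles all rasters of one study area on a shared grid: the raw `[0, 1]`
#' footprint index, elevation and slope, the land-cover class raster, and the
#' five raw distance-to-land-cover rasters (m).
#'
#' @param grid Shared [fp_grid()].
#' @param footprint,elevation,slope [fp_raster()] objects on `grid`.
#' @param landcover [fp_raster()] of integer class codes `1..5` indexing
#'   [landcover_classes()].
#' @param lc_dist Named list of five [fp_raster()] distance rasters, names
#'   equal to [landcover_classes()].
#' @return Object of class `covariate_stack`.
#' @export
covariate_stack <- function(grid, footprint, elevation, slope, landcover,
                            lc_dist) {
  rs <- c(list(footprint, elevation, slope, landcover), lc_dist)
  for (r in rs) {
    if (!identical(unclass(r$grid), unclass(grid)))
      stop("all rasters in a covariate_stack must share one grid")
  }
  if (!setequal(names(lc_dist), landcover_classes()))
    stop("lc_dist must be named by landcover_classes()")
  structure(list(grid = grid, footprint = footprint, elevation = elevation,
                 slope = slope, landcover = landcover,
                 lc_dist = lc_dist[landcover_classes()]),
            class = "covariate_stack")
}

#' @export
print.covariate_stack <- function(x, ...) {
  cat(sprintf("<covariate_stack> %d x %d @ %g m: footprint, elevation, slope, landcover, 5 land-cover distances\n",
              x$grid$nrow, x$grid$ncol, x$grid$res))
  invisible(x)
}

# Equal-tailed 95% interval of a draw vector.
ci95 <- function(x) stats::quantile(x, c(0.025, 0.975), names = FALSE,
                                    type = 7)

# format POSIXct as ISO-8601 UTC
iso8601 <- function(t) format(t, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
parse_iso8601 <- function(s) as.POSIXct(s, format = "%Y-%m-%dT%H:%M:%S",
                                        tz = "UTC")
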