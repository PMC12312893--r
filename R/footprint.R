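#' Distance-decay influence of infrastructure
#'
#' Exponential decay of an infrastructure feature's influence with distance,
#' `exp(-distance/scale)`. With the 750 m scale used for land-cover distances
#' the influence drops steeply over the first 500 m and reaches 5% of its
#' initial value at 2.25 km. An infinite distance (the "no feature anywhere"
#' sentinel of an empty layer) maps to 0.
#'
#' @param distance_m Non-negative distances in metres (may be `Inf`).
#' @param scale_m Positive e-folding scale in metres.
#' @return Influence values in `[0, 1]`.
#' @export
distance_decay <- function(distance_m, scale_m) {
  if (any(scale_m <= 0)) stop("scale_m must be positive")
  if (any(distance_m < 0, na.rm = TRUE)) stop("distance_m must be >= 0")
  out <- exp(-distance_m / scale_m)
  out[is.infinite(distance_m)] <- 0
  out
}

#' Per-class footprint parameters
#'
#' @param class_name One of `"road"`, `"trail"`, `"parking"`, `"building"`,
#'   `"campground"`.
#' @param weight Relative importance in `[0, 1]`.
#' @param decay_scale_m Positive e-folding distance of influence (m).
#' @return A `feature_class_params` list.
#' @export
feature_class_params <- function(class_name, weight, decay_scale_m) {
  if (weight < 0 || weight > 1) stop("weight must be in [0, 1]")
  if (decay_scale_m <= 0) stop("decay_scale_m must be > 0")
  structure(list(class_name = class_name, weight = weight,
                 decay_scale_m = decay_scale_m),
            class = "feature_class_params")
}

#' Feature classes of the footprint index
#' @export
footprint_classes <- function() {
  c("road", "trail", "parking", "building", "campground")
}

#' Default footprint parameters per feature class
#'
#' Permanent, high-occupancy structures (buildings, campgrounds, car parks)
#' are weighted above roads, and trails lowest; roads carry the longest decay
#' scale. All values are configurable.
#'
#' @return Named list of [feature_class_params()], one per class.
#' @export
default_footprint_params <- function() {
  list(
    building   = feature_class_params("building",   1.0, 500),
    campground = feature_class_params("campground", 0.9, 500),
    parking    = feature_class_params("parking",    0.8, 500),
    road       = feature_class_params("road",       0.8, 750),
    trail      = feature_class_params("trail",      0.4, 250))
}

#' Distance-to-feature raster
#'
#' Each cell holds the Euclidean distance (m) from its centre to the nearest
#' geometry of the layer; a cell whose centre lies on a geometry holds 0. An
#' empty layer yields `Inf` everywhere (the sentinel consumed by
#' [distance_decay()]).
#'
#' @param layer A [feature_layer()] in the grid's coordinate system.
#' @param grid An [fp_grid()].
#' @return An [fp_raster()] of distances.
#' @export
euclidean_distance_raster <- function(layer, grid) {
  ctr <- grid_centers(grid)
  pts <- cbind(rep(ctr$x, each = grid$nrow), rep(ctr$y, times = grid$ncol))
  d <- layer_distance(pts, layer)
  fp_raster(grid, matrix(d, grid$nrow, grid$ncol))
}

#' Aggregate human-footprint index raster
#'
#' Combines per-class decayed influences `w_c * exp(-d_c / s_c)` into a single
#' bounded index. The default rule is the saturating union
#' `1 - prod_c(1 - influence_c)`: it is symmetric in class order, monotone in
#' every influence, equals a lone class's influence exactly, and never leaves
#' `[0, 1]`, so a value of 1 marks the highest possible footprint. A
#' weight-normalised sum is available as an alternative aggregation.
#'
#' @param layers Named list of [feature_layer()] objects; classes without a
#'   layer contribute nothing.
#' @param params Named list of [feature_class_params()], one per class in
#'   [footprint_classes()].
#' @param grid An [fp_grid()].
#' @param aggregation `"saturating"` (default) or `"weighted_sum"`.
#' @return An [fp_raster()] with values in `[0, 1]`.
#' @export
build_footprint_index <- function(layers, params = default_footprint_params(),
                                  grid,
                                  aggregation = c("saturating",
                                                  "weighted_sum")) {
  aggregation <- match.arg(aggregation)
  classes <- footprint_classes()
  missing_p <- setdiff(classes, names(params))
  if (length(missing_p))
    stop("missing footprint params for class(es): ",
         paste(missing_p, collapse = ", "))
  infl <- list()
  for (cl in classes) {
    p <- params[[cl]]
    if (p$weight < 0 || p$weight > 1)
      stop("weight for class ", cl, " outside [0, 1]")
    lay <- layers[[cl]]
    if (is.null(lay) || length(lay$geoms) == 0) {
      infl[[cl]] <- matrix(0, grid$nrow, grid$ncol)
    } else {
      d <- euclidean_distance_raster(lay, grid)
      infl[[cl]] <- p$weight * distance_decay(d$values, p$decay_scale_m)
    }
  }
  if (aggregation == "saturating") {
    keep <- matrix(1, grid$nrow, grid$ncol)
    for (cl in classes) keep <- keep * (1 - infl[[cl]])
    vals <- 1 - keep
  } else {
    wsum <- sum(vapply(classes, function(cl) params[[cl]]$weight, numeric(1)))
    vals <- Reduce(`+`, infl) / wsum
  }
  fp_raster(grid, pmin(pmax(vals, 0), 1))
}
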