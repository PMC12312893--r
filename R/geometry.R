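#' Infrastructure feature layer
#'
#' A set of geometries of one infrastructure class (road, trail, parking,
#' building, campground). Geometries are points, polylines or polygons given
#' as two-column coordinate matrices in the shared projected CRS.
#'
#' @param class_name Feature class name.
#' @param geoms List of geometries, each `list(type = "point"|"line"|"polygon",
#'   coords = <n x 2 matrix>)`.
#' @return Object of class `feature_layer`.
#' @export
feature_layer <- function(class_name, geoms = list()) {
  stopifnot(is.character(class_name), length(class_name) == 1)
  for (g in geoms) {
    if (!g$type %in% c("point", "line", "polygon"))
      stop("unknown geometry type: ", g$type)
    if (!is.matrix(g$coords) || ncol(g$coords) != 2)
      stop("geometry coords must be an n x 2 matrix")
  }
  structure(list(class_name = class_name, geoms = geoms),
            class = "feature_layer")
}

#' @export
print.feature_layer <- function(x, ...) {
  cat(sprintf("<feature_layer> class '%s', %d geometries\n",
              x$class_name, length(x$geoms)))
  invisible(x)
}

# Decompose a layer into segment endpoints (points become zero-length
# segments; polygon boundaries are closed).
layer_segments <- function(layer) {
  a <- list(); b <- list()
  for (g in layer$geoms) {
    cc <- g$coords
    if (g$type == "point" || nrow(cc) == 1) {
      a[[length(a) + 1]] <- cc
      b[[length(b) + 1]] <- cc
    } else {
      if (g$type == "polygon" &&
          any(cc[1, ] != cc[nrow(cc), ]))
        cc <- rbind(cc, cc[1, ])
      a[[length(a) + 1]] <- cc[-nrow(cc), , drop = FALSE]
      b[[length(b) + 1]] <- cc[-1, , drop = FALSE]
    }
  }
  list(a = do.call(rbind, a), b = do.call(rbind, b))
}

# Minimum distance from each point (px, py) to segment (ax,ay)-(bx,by).
dist_points_segment <- function(px, py, ax, ay, bx, by) {
  dx <- bx - ax; dy <- by - ay
  len2 <- dx * dx + dy * dy
  if (len2 == 0) return(sqrt((px - ax)^2 + (py - ay)^2))
  t <- ((px - ax) * dx + (py - ay) * dy) / len2
  t <- pmin(1, pmax(0, t))
  sqrt((px - (ax + t * dx))^2 + (py - (ay + t * dy))^2)
}

#' Minimum distance from points to a feature layer
#'
#' @param xy Two-column matrix of point coordinates.
#' @param layer A [feature_layer()].
#' @return Numeric vector of Euclidean distances (m); `Inf` when the layer is
#'   empty.
#' @export
layer_distance <- function(xy, layer) {
  xy <- matrix(as.numeric(xy), ncol = 2)
  if (length(layer$geoms) == 0) return(rep(Inf, nrow(xy)))
  seg <- layer_segments(layer)
  d <- rep(Inf, nrow(xy))
  for (s in seq_len(nrow(seg$a))) {
    d <- pmin(d, dist_points_segment(xy[, 1], xy[, 2],
                                     seg$a[s, 1], seg$a[s, 2],
                                     seg$b[s, 1], seg$b[s, 2]))
  }
  d
}

#' Test whether points fall inside a polygon (with optional multiple rings)
#'
#' Boundary convention: points on the boundary count as inside.
#'
#' @param xy Two-column matrix of point coordinates.
#' @param rings A single two-column matrix, or a list of such matrices
#'   (disjoint rings; even-odd rule).
#' @param boundary_tol Distance (m) within which a point is treated as on the
#'   boundary and therefore inside.
#' @return Logical vector.
#' @export
points_in_polygon <- function(xy, rings, boundary_tol = 1e-9) {
  xy <- matrix(as.numeric(xy), ncol = 2)
  if (is.matrix(rings)) rings <- list(rings)
  bnd <- do.call(rbind, lapply(rings, function(r) rbind(r, c(NA, NA))))
  bnd <- bnd[-nrow(bnd), , drop = FALSE]
  inside <- mgcv::in.out(bnd, xy)
  if (boundary_tol > 0) {
    lay <- feature_layer("rings", lapply(rings, function(r)
      list(type = "polygon", coords = r)))
    inside <- inside | layer_distance(xy, lay) <= boundary_tol
  }
  inside
}

#' Polygon area by the shoelace formula
#'
#' @param rings A ring matrix or list of disjoint ring matrices; areas of
#'   rings are summed (rings are assumed not to be holes).
#' @return Area in square metres.
#' @export
polygon_area <- function(rings) {
  if (is.matrix(rings)) rings <- list(rings)
  sum(vapply(rings, function(r) {
    if (any(r[1, ] != r[nrow(r), ])) r <- rbind(r, r[1, ])
    x <- r[, 1]; y <- r[, 2]
    n <- nrow(r)
    abs(sum(x[-n] * y[-1] - x[-1] * y[-n])) / 2
  }, numeric(1)))
}

#' Write feature layers to GeoJSON
#'
#' Each geometry becomes one Feature with a `"class"` property naming its
#' infrastructure class.
#'
#' @param layers List of [feature_layer()] objects.
#' @param path Output path.
#' @export
write_geojson_layers <- function(layers, path) {
  feats <- list()
  for (lay in layers) {
    for (g in lay$geoms) {
      cc <- g$coords
      geom <- switch(g$type,
        point = list(type = "Point", coordinates = as.numeric(cc[1, ])),
        line = list(type = "LineString",
                    coordinates = lapply(seq_len(nrow(cc)),
                                         function(i) as.numeric(cc[i, ]))),
        polygon = {
          if (any(cc[1, ] != cc[nrow(cc), ])) cc <- rbind(cc, cc[1, ])
          list(type = "Polygon",
               coordinates = list(lapply(seq_len(nrow(cc)),
                                         function(i) as.numeric(cc[i, ]))))
        })
      feats[[length(feats) + 1]] <-
        list(type = "Feature",
             properties = list(class = lay$class_name),
             geometry = geom)
    }
  }
  fc <- list(type = "FeatureCollection", features = feats)
  ok <- tryCatch({
    jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop("cannot write GeoJSON to ", path)
  invisible(path)
}

#' Read feature layers from GeoJSON
#'
#' Inverse of [write_geojson_layers()]: features are grouped by their
#' `"class"` property into one [feature_layer()] per class.
#'
#' @param path GeoJSON file path.
#' @return Named list of [feature_layer()] objects.
#' @export
read_geojson_layers <- function(path) {
  if (!file.exists(path)) stop("no such GeoJSON file: ", path)
  fc <- jsonlite::read_json(path)
  out <- list()
  for (f in fc$features) {
    cls <- f$properties$class
    if (is.null(cls)) cls <- "unknown"
    geom <- f$geometry
    g <- switch(geom$type,
      Point = list(type = "point",
                   coords = matrix(unlist(geom$coordinates), ncol = 2,
                                   byrow = TRUE)),
      LineString = list(type = "line",
                        coords = do.call(rbind, lapply(geom$coordinates,
                                                       unlist))),
      Polygon = list(type = "polygon",
                     coords = do.call(rbind,
                                      lapply(geom$coordinates[[1]], unlist))),
      stop("unsupported GeoJSON geometry: ", geom$type))
    if (is.null(out[[cls]])) out[[cls]] <- feature_layer(cls)
    out[[cls]]$geoms[[length(out[[cls]]$geoms) + 1]] <- g
  }
  out
}
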