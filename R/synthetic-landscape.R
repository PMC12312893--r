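#' Synthetic landscape configuration
#'
#' Describes the simulated study area: extent, 30 m grid, five land-cover
#' classes, the autocorrelation length of the smoothed noise fields that
#' drive elevation and land cover, and how many infrastructure features of
#' each class to place. Features are concentrated in a "developed" sector on
#' the western side of the extent so that the resulting footprint index has a
#' strong spatial gradient, as in a park with a developed frontcountry and a
#' remote backcountry.
#'
#' @param extent_m Width and height of the landscape (m).
#' @param resolution_m Cell size (m), default 30.
#' @param n_landcover_classes Must be 5 (forest, herbaceous, scrub, barren,
#'   water).
#' @param autocorrelation_range_m Length scale of the smoothed noise fields.
#' @param feature_counts Named integer vector of feature counts per
#'   infrastructure class.
#' @return A `landscape_config` list.
#' @export
landscape_config <- function(extent_m = c(6000, 6000), resolution_m = 30,
                             n_landcover_classes = 5,
                             autocorrelation_range_m = 600,
                             feature_counts = c(road = 2, trail = 3,
                                                parking = 3, building = 5,
                                                campground = 2)) {
  if (n_landcover_classes != 5)
    stop("exactly 5 land-cover classes are supported")
  grid <- fp_grid(0, 0, extent_m, resolution_m)  # validates divisibility
  if (!all(names(feature_counts) %in% footprint_classes()))
    stop("feature_counts names must be footprint classes")
  if (any(feature_counts < 0)) stop("feature_counts must be >= 0")
  # the developed sector must hold at least a few cells to place features in
  if (sum(feature_counts) > 0 && grid$ncol < 10)
    stop("extent too small to place the requested features")
  structure(list(extent_m = extent_m, resolution_m = resolution_m,
                 n_landcover_classes = 5L,
                 autocorrelation_range_m = autocorrelation_range_m,
                 feature_counts = feature_counts),
            class = "landscape_config")
}

# Gaussian smoothing of a matrix field (separable kernel, zero-padded and
# renormalised at the edges) - gives seedable, spatially autocorrelated noise.
gauss_smooth <- function(m, sigma_cells) {
  r <- max(1L, as.integer(ceiling(3 * sigma_cells)))
  k <- stats::dnorm(seq(-r, r), sd = sigma_cells)
  smooth_cols <- function(mat) {
    n <- nrow(mat)
    den <- stats::filter(c(rep(0, r), rep(1, n), rep(0, r)), k,
                         sides = 2)[(r + 1):(r + n)]
    apply(mat, 2, function(col) {
      stats::filter(c(rep(0, r), col, rep(0, r)), k,
                    sides = 2)[(r + 1):(r + n)] / den
    })
  }
  t(smooth_cols(t(smooth_cols(m))))
}

# 1D squared distance transform (lower envelope of parabolas).
dt1d <- function(f) {
  n <- length(f)
  big <- 1e18
  f <- pmin(f, big)
  d <- numeric(n); v <- integer(n); z <- numeric(n + 1)
  k <- 1L; v[1] <- 1L; z[1] <- -Inf; z[2] <- Inf
  if (n > 1) {
    for (q in 2:n) {
      repeat {
        s <- ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2 * q - 2 * v[k])
        if (k > 1 && s <= z[k]) k <- k - 1L else break
      }
      k <- k + 1L; v[k] <- q; z[k] <- s; z[k + 1] <- Inf
    }
  }
  k <- 1L
  for (q in 1:n) {
    while (z[k + 1] < q) k <- k + 1L
    d[q] <- (q - v[k])^2 + f[v[k]]
  }
  d
}

#' Exact Euclidean distance transform of a cell mask
#'
#' Distance (m) from every cell centre to the nearest cell centre where
#' `mask` is TRUE; 0 on masked cells, `Inf` if the mask is empty.
#'
#' @param mask Logical matrix.
#' @param res_m Cell size (m).
#' @return Numeric matrix of distances.
#' @export
distance_transform <- function(mask, res_m) {
  if (!any(mask)) return(matrix(Inf, nrow(mask), ncol(mask)))
  f <- ifelse(mask, 0, Inf)
  d <- apply(f, 2, dt1d)              # along rows (within each column)
  d <- t(apply(t(d), 2, dt1d))        # along columns
  out <- sqrt(d) * res_m
  out[out > 1e8] <- Inf
  out
}

# Random-walk polyline starting at (x0, y0), heading `bearing` (radians),
# n steps of length step_m with wiggle; clamped to the extent.
rw_line <- function(x0, y0, bearing, n, step_m, wiggle, grid) {
  xs <- numeric(n + 1); ys <- numeric(n + 1)
  xs[1] <- x0; ys[1] <- y0
  b <- bearing
  for (i in seq_len(n)) {
    b <- b + stats::rnorm(1, 0, wiggle)
    xs[i + 1] <- min(max(xs[i] + step_m * cos(b), grid$xmin), grid$xmax)
    ys[i + 1] <- min(max(ys[i] + step_m * sin(b), grid$ymin), grid$ymax)
  }
  cbind(xs, ys)
}

#' Generate a synthetic landscape
#'
#' Builds the full landscape bundle used by the simulator and the pipeline:
#' smoothed elevation and derived slope, a five-class land-cover partition
#' (by thresholding a smoothed noise field at fixed quantiles), infrastructure
#' feature layers concentrated in the developed western sector, the park
#' boundary polygon (the extent inset by 4%), the aggregate footprint raster
#' and the five land-cover distance rasters. Deterministic under a fixed
#' seed.
#'
#' @param config A [landscape_config()].
#' @param seed Integer RNG seed.
#' @param footprint_params Per-class footprint parameters (default
#'   [default_footprint_params()]).
#' @return Object of class `fp_landscape`: list with `stack` (a
#'   [covariate_stack()]), `park` (boundary ring matrix), `layers` (named
#'   list of [feature_layer()]), and `config`.
#' @export
generate_landscape <- function(config, seed,
                               footprint_params = default_footprint_params()) {
  stopifnot(inherits(config, "landscape_config"))
  grid <- fp_grid(0, 0, config$extent_m, config$resolution_m)
  sigma_cells <- max(1, config$autocorrelation_range_m / grid$res / 2)
  with_seed(seed, {
    ## terrain
    elev_f <- gauss_smooth(matrix(stats::rnorm(grid$nrow * grid$ncol),
                                  grid$nrow, grid$ncol), sigma_cells)
    elev <- 2000 + 400 * (elev_f - mean(elev_f)) / stats::sd(elev_f)
    gx <- (elev[, c(2:grid$ncol, grid$ncol)] -
             elev[, c(1, 1:(grid$ncol - 1))]) / (2 * grid$res)
    gy <- (elev[c(2:grid$nrow, grid$nrow), ] -
             elev[c(1, 1:(grid$nrow - 1)), ]) / (2 * grid$res)
    slope <- atan(sqrt(gx^2 + gy^2)) * 180 / pi

    ## land cover: threshold a second smoothed field at fixed quantiles
    lc_f <- gauss_smooth(matrix(stats::rnorm(grid$nrow * grid$ncol),
                                grid$nrow, grid$ncol), sigma_cells)
    # class shares: water 8%, barren 12%, scrub 20%, herbaceous 25%, forest 35%
    qs <- stats::quantile(lc_f, c(0.08, 0.20, 0.40, 0.65))
    code <- matrix(0L, grid$nrow, grid$ncol)  # codes index landcover_classes()
    code[lc_f <= qs[1]] <- 5L                                   # water
    code[lc_f > qs[1] & lc_f <= qs[2]] <- 1L                    # barren
    code[lc_f > qs[2] & lc_f <= qs[3]] <- 4L                    # scrub
    code[lc_f > qs[3] & lc_f <= qs[4]] <- 3L                    # herbaceous
    code[lc_f > qs[4]] <- 2L                                    # forest

    ## infrastructure in the developed (western) sector
    W <- grid$xmax - grid$xmin
    sector <- c(grid$xmin + 0.03 * W, grid$xmin + 0.30 * W)
    fc <- config$feature_counts
    cnt <- function(cl) if (cl %in% names(fc)) fc[[cl]] else 0L
    layers <- list()
    road_pts <- NULL
    if (cnt("road") > 0) {
      geoms <- lapply(seq_len(cnt("road")), function(i) {
        x0 <- stats::runif(1, sector[1], sector[2])
        list(type = "line",
             coords = rw_line(x0, grid$ymin, pi / 2,
                              n = max(10, grid$nrow %/% 4),
                              step_m = 4 * grid$res, wiggle = 0.25, grid))
      })
      layers$road <- feature_layer("road", geoms)
      road_pts <- do.call(rbind, lapply(geoms, `[[`, "coords"))
    }
    if (cnt("trail") > 0) {
      layers$trail <- feature_layer("trail", lapply(
        seq_len(cnt("trail")), function(i) {
          x0 <- stats::runif(1, sector[1], sector[2])
          y0 <- stats::runif(1, grid$ymin + 0.2 * (grid$ymax - grid$ymin),
                             grid$ymax - 0.2 * (grid$ymax - grid$ymin))
          list(type = "line",
               coords = rw_line(x0, y0, 0,  # heads east into the interior
                                n = max(10, grid$ncol %/% 5),
                                step_m = 3 * grid$res, wiggle = 0.35, grid))
        }))
    }
    anchor <- function() {
      # point features cluster near roads when roads exist
      if (!is.null(road_pts)) {
        p <- road_pts[sample.int(nrow(road_pts), 1), ]
        c(min(max(p[1] + stats::rnorm(1, 0, 3 * grid$res), grid$xmin),
              grid$xmax),
          min(max(p[2] + stats::rnorm(1, 0, 3 * grid$res), grid$ymin),
              grid$ymax))
      } else {
        c(stats::runif(1, sector[1], sector[2]),
          stats::runif(1, grid$ymin, grid$ymax))
      }
    }
    for (cl in c("parking", "building", "campground")) {
      if (cnt(cl) > 0) {
        layers[[cl]] <- feature_layer(cl, lapply(
          seq_len(cnt(cl)), function(i)
            list(type = "point", coords = matrix(anchor(), 1, 2))))
      }
    }

    ## park boundary: extent inset by 4%
    mx <- 0.04 * (grid$xmax - grid$xmin)
    my <- 0.04 * (grid$ymax - grid$ymin)
    park <- rbind(c(grid$xmin + mx, grid$ymin + my),
                  c(grid$xmax - mx, grid$ymin + my),
                  c(grid$xmax - mx, grid$ymax - my),
                  c(grid$xmin + mx, grid$ymax - my),
                  c(grid$xmin + mx, grid$ymin + my))

    footprint <- build_footprint_index(layers, footprint_params, grid)

    lc_dist <- lapply(seq_along(landcover_classes()), function(ci)
      fp_raster(grid, distance_transform(code == ci, grid$res)))
    names(lc_dist) <- landcover_classes()

    stack <- covariate_stack(grid,
                             footprint = footprint,
                             elevation = fp_raster(grid, elev),
                             slope = fp_raster(grid, slope),
                             landcover = fp_raster(grid, code),
                             lc_dist = lc_dist)
    structure(list(stack = stack, park = park, layers = layers,
                   config = config),
              class = "fp_landscape")
  })
}

#' @export
print.fp_landscape <- function(x, ...) {
  cat(sprintf("<fp_landscape> %g x %g m @ %g m, %d feature layers\n",
              x$config$extent_m[1], x$config$extent_m[2],
              x$config$resolution_m, length(x$layers)))
  invisible(x)
}
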