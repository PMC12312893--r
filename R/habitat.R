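#' Kernel utilization distribution home range
#'
#' Bivariate normal kernel density over the fix coordinates with the
#' normal-scale reference bandwidth per axis, evaluated on a fixed grid finer
#' than the covariate rasters; the home range is the smallest-density contour
#' enclosing `isopleth` of the probability mass (the 95% KUD by default),
#' possibly several disjoint rings.
#'
#' @param track Fix data.frame (`x`, `y`) with at least 5 fixes.
#' @param isopleth Probability mass to enclose, in (0, 1); default 0.95.
#' @param bandwidth Optional length-2 bandwidth (the normal-scale reference
#'   rule per axis when `NULL`).
#' @param res_m Covariate raster resolution (m); the density grid spacing is
#'   `res_m / grid_factor`.
#' @param grid_factor Density-grid refinement factor (default 4).
#' @param id,year Optional labels stored on the result.
#' @return Object of class `home_range`: `rings` (list of closed ring
#'   matrices), `bandwidth`, `area` (m^2), `isopleth`, `level`, `id`, `year`.
#' @export
estimate_kud <- function(track, isopleth = 0.95, bandwidth = NULL,
                         res_m = 30, grid_factor = 4, id = NULL,
                         year = NULL) {
  if (isopleth <= 0 || isopleth >= 1) stop("isopleth must be in (0, 1)")
  if (nrow(track) < 5) stop("at least 5 fixes are required")
  x <- track$x; y <- track$y
  if (is.null(bandwidth)) {
    bandwidth <- c(MASS::bandwidth.nrd(x), MASS::bandwidth.nrd(y))
  }
  if (any(!is.finite(bandwidth)) || any(bandwidth <= 0) ||
      stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("degenerate geometry: fixes are coincident or colinear")
  pad <- max(bandwidth)  # kernel sd is bandwidth/4; 4 sd of padding
  lims <- c(range(x) + c(-pad, pad), range(y) + c(-pad, pad))
  spacing <- res_m / grid_factor
  n <- c(max(32, ceiling((lims[2] - lims[1]) / spacing) + 1),
         max(32, ceiling((lims[4] - lims[3]) / spacing) + 1))
  kd <- MASS::kde2d(x, y, h = bandwidth, n = n, lims = lims)
  zv <- sort(as.numeric(kd$z), decreasing = TRUE)
  target <- isopleth * sum(zv)
  level <- zv[which(cumsum(zv) >= target)[1]]
  cl <- grDevices::contourLines(kd$x, kd$y, kd$z, levels = level)
  if (length(cl) == 0) stop("no contour at the requested isopleth")
  rings <- lapply(cl, function(cc) {
    r <- cbind(cc$x, cc$y)
    if (any(r[1, ] != r[nrow(r), ])) r <- rbind(r, r[1, ])
    r
  })
  structure(list(rings = rings, bandwidth = bandwidth,
                 area = polygon_area(rings), isopleth = isopleth,
                 level = level, id = id, year = year),
            class = "home_range")
}

#' @export
print.home_range <- function(x, ...) {
  cat(sprintf("<home_range> %s%s: %d ring(s), %.2f km^2 (%.0f%% KUD)\n",
              x$id %||% "?", if (!is.null(x$year)) paste0(" ", x$year) else "",
              length(x$rings), x$area / 1e6, 100 * x$isopleth))
  invisible(x)
}

home_range_bbox <- function(home_range) {
  all <- do.call(rbind, home_range$rings)
  c(min(all[, 1]), max(all[, 1]), min(all[, 2]), max(all[, 2]))
}

#' Sample available points within a home range
#'
#' Draws `ratio * n_used` points uniformly within the home-range polygon by
#' rejection sampling from its bounding box; deterministic under the seed.
#'
#' @param home_range A [home_range][estimate_kud()] (or any object with
#'   `rings`).
#' @param n_used Number of used points the sample is matched to.
#' @param ratio Available : used ratio (default 50, the 1:50 design).
#' @param seed Integer RNG seed.
#' @param clip_bbox Optional `c(xmin, xmax, ymin, ymax)` study-area extent;
#'   when given, availability is the home range intersected with it (home
#'   ranges of edge animals can spill past the covariate rasters).
#' @return Data frame with `x`, `y` (`ratio * n_used` rows).
#' @export
sample_available <- function(home_range, n_used, ratio = 50, seed = 1,
                             clip_bbox = NULL) {
  if (polygon_area(home_range$rings) <= 0) stop("home range has zero area")
  n <- as.integer(ratio * n_used)
  bb <- home_range_bbox(home_range)
  if (!is.null(clip_bbox)) {
    bb <- c(max(bb[1], clip_bbox[1]), min(bb[2], clip_bbox[2]),
            max(bb[3], clip_bbox[3]), min(bb[4], clip_bbox[4]))
    if (bb[1] >= bb[2] || bb[3] >= bb[4])
      stop("home range does not overlap the clip extent")
  }
  with_seed(seed, {
    xs <- numeric(0); ys <- numeric(0)
    tries <- 0L
    while (length(xs) < n) {
      m <- max(1000L, 2L * (n - length(xs)))
      cx <- stats::runif(m, bb[1], bb[2])
      cy <- stats::runif(m, bb[3], bb[4])
      ok <- points_in_polygon(cbind(cx, cy), home_range$rings,
                              boundary_tol = 0)
      xs <- c(xs, cx[ok]); ys <- c(ys, cy[ok])
      tries <- tries + 1L
      if (tries > 1000L)
        stop("rejection sampling failed: home range barely overlaps the ",
             "clip extent")
    }
    data.frame(x = xs[seq_len(n)], y = ys[seq_len(n)])
  })
}

#' Land-cover distance transform
#'
#' The exponential decay `exp(-distance / 750)` applied to raw
#' distance-to-land-cover values: it drops steeply over the first 500 m and
#' reaches 5% of its initial value at 2.25 km.
#'
#' @param distance_m Non-negative distances (m).
#' @return Transformed values in `[0, 1]`.
#' @export
transform_landcover_distance <- function(distance_m) {
  distance_decay(distance_m, 750)
}

#' Centre and scale values within populations
#'
#' Scales to mean 0 and standard deviation 1 within each population, using
#' the n-divisor (population) standard deviation. The per-population
#' transform parameters are returned for reuse on new values.
#'
#' @param values Numeric vector.
#' @param group Population labels, same length as `values`.
#' @param covariate Name used in error messages.
#' @return List: `scaled` (vector) and `params` (data.frame `group`, `mean`,
#'   `sd`).
#' @export
center_scale <- function(values, group = rep("all", length(values)),
                         covariate = "covariate") {
  group <- as.character(group)
  out <- numeric(length(values))
  params <- list()
  for (g in unique(group)) {
    idx <- group == g
    if (sum(idx) < 2)
      stop("need >= 2 values to scale ", covariate, " in population ", g)
    m <- mean(values[idx])
    s <- sqrt(mean((values[idx] - m)^2))
    if (s == 0)
      stop("zero variance scaling ", covariate, " in population ", g)
    out[idx] <- (values[idx] - m) / s
    params[[g]] <- data.frame(group = g, mean = m, sd = s)
  }
  list(scaled = out, params = do.call(rbind, params))
}

#' Apply stored centre/scale parameters
#'
#' @param values Numeric vector.
#' @param group Population labels.
#' @param params The `params` table from [center_scale()].
#' @return Scaled vector.
#' @export
apply_center_scale <- function(values, group, params) {
  group <- as.character(group)
  i <- match(group, params$group)
  if (anyNA(i)) stop("unknown population in apply_center_scale")
  (values - params$mean[i]) / params$sd[i]
}

#' Land-cover presence flags for a home range
#'
#' A class is present iff at least one raster cell of that class has its
#' centre inside the home-range polygon (boundary counts as inside).
#'
#' @param home_range A [home_range][estimate_kud()].
#' @param landcover [fp_raster()] of class codes indexing
#'   [landcover_classes()].
#' @return Named integer vector of 0/1 flags per class.
#' @export
landcover_presence <- function(home_range, landcover) {
  g <- landcover$grid
  ctr <- grid_centers(g)
  pts <- cbind(rep(ctr$x, each = g$nrow), rep(ctr$y, times = g$ncol))
  bb <- home_range_bbox(home_range)
  cand <- which(pts[, 1] >= bb[1] - g$res & pts[, 1] <= bb[2] + g$res &
                pts[, 2] >= bb[3] - g$res & pts[, 2] <= bb[4] + g$res)
  flags <- stats::setNames(integer(5), landcover_classes())
  if (length(cand) == 0) return(flags)
  inside <- points_in_polygon(pts[cand, , drop = FALSE], home_range$rings)
  codes <- as.numeric(landcover$values)[cand[inside]]
  for (ci in seq_along(landcover_classes()))
    flags[ci] <- as.integer(any(codes == ci))
  flags
}

#' Names of the RSF covariate columns
#' @export
ua_covariate_names <- function() {
  c("footprint", "elevation", "slope", landcover_classes())
}

#' Screen covariates for collinearity
#'
#' Pearson correlation of every unordered covariate pair within each
#' population, computed on available rows (characterising the habitat
#' domain). Pairs with `|r|` above the threshold are flagged but never
#' dropped automatically.
#'
#' @param ua_table A used/available table from [build_ua_table()].
#' @param threshold Absolute-correlation flag threshold (default 0.7).
#' @param rows `"available"` (default) or `"all"`.
#' @return List: `flagged` (data.frame `population`, `var1`, `var2`, `r`)
#'   and `n_comparisons` (total pairs examined across populations).
#' @export
correlation_screen <- function(ua_table, threshold = 0.7,
                               rows = c("available", "all")) {
  rows <- match.arg(rows)
  vars <- ua_covariate_names()
  if (!all(vars %in% names(ua_table)))
    stop("ua_table is missing covariate columns")
  pairs <- utils::combn(vars, 2)
  flagged <- list()
  n_comp <- 0L
  for (pop in unique(ua_table$population)) {
    sub <- ua_table[ua_table$population == pop, , drop = FALSE]
    if (rows == "available") sub <- sub[sub$used == 0, , drop = FALSE]
    for (k in seq_len(ncol(pairs))) {
      n_comp <- n_comp + 1L
      r <- suppressWarnings(stats::cor(sub[[pairs[1, k]]],
                                       sub[[pairs[2, k]]]))
      if (!is.na(r) && abs(r) > threshold)
        flagged[[length(flagged) + 1]] <-
          data.frame(population = pop, var1 = pairs[1, k],
                     var2 = pairs[2, k], r = r)
    }
  }
  list(flagged = if (length(flagged)) do.call(rbind, flagged)
       else data.frame(population = character(), var1 = character(),
                       var2 = character(), r = numeric()),
       n_comparisons = n_comp)
}

#' Assemble the used/available design table
#'
#' One row per used or available point with the extracted covariates
#' (transform order: land-cover distance decay first, then per-population
#' centring/scaling of elevation, slope and the five land-cover covariates,
#' pooled over used + available rows of both years; the footprint stays on
#' its raw `[0, 1]` scale), land-cover presence indicators, and keys.
#'
#' @param groups List of per-individual-year entries, each
#'   `list(id, year, population, used = <data.frame x,y>,
#'   available = <data.frame x,y>, home_range = <home_range>)`.
#' @param stack A [covariate_stack()].
#' @return Data frame of class `ua_table` with columns `used`,
#'   [ua_covariate_names()], `ind_<class>` indicators, `individual_year_id`,
#'   `animal_id`, `year`, `population`; scale parameters in
#'   `attr(, "scale_params")`.
#' @export
build_ua_table <- function(groups, stack) {
  rows <- list()
  for (g in groups) {
    pts <- rbind(cbind(g$used$x, g$used$y),
                 cbind(g$available$x, g$available$y))
    n_u <- nrow(g$used); n_a <- nrow(g$available)
    iy <- paste(g$id, g$year, sep = "_")
    ids <- paste0(iy, ":", seq_len(n_u + n_a))
    df <- data.frame(used = c(rep(1L, n_u), rep(0L, n_a)))
    df$footprint <- raster_extract(stack$footprint, pts, ids)
    df$elevation <- raster_extract(stack$elevation, pts, ids)
    df$slope <- raster_extract(stack$slope, pts, ids)
    for (cl in landcover_classes())
      df[[cl]] <- transform_landcover_distance(
        raster_extract(stack$lc_dist[[cl]], pts, ids))
    flags <- landcover_presence(g$home_range, stack$landcover)
    for (cl in landcover_classes())
      df[[paste0("ind_", cl)]] <- flags[[cl]]
    df$individual_year_id <- iy
    df$animal_id <- g$id
    df$year <- as.character(g$year)
    df$population <- g$population
    rows[[length(rows) + 1]] <- df
  }
  ua <- do.call(rbind, rows)
  rownames(ua) <- NULL
  sp <- list()
  for (v in c("elevation", "slope", landcover_classes())) {
    cs <- center_scale(ua[[v]], ua$population, covariate = v)
    ua[[v]] <- cs$scaled
    cs$params$covariate <- v
    sp[[v]] <- cs$params
  }
  attr(ua, "scale_params") <- do.call(rbind, sp)
  class(ua) <- c("ua_table", "data.frame")
  ua
}
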