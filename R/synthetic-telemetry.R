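#' Simulation ground truth
#'
#' The population-level parameters from which individual selection
#' coefficients are drawn. The footprint coefficient of each individual-year
#' has an exposure-dependent mean, `fr_intercept[t] + fr_slope[t] * exposure`,
#' which is the generative counterpart of a functional response in habitat
#' selection; all other coefficients are drawn around fixed year means.
#'
#' @param mu_beta Named list per year (e.g. `"2019"`, `"2020"`), each a named
#'   numeric vector of population means for `intercept`, `elevation`,
#'   `slope`, and the five land-cover coefficients.
#' @param sd_beta Named numeric vector of population standard deviations per
#'   coefficient (including `footprint`); all must be `>= 0`.
#' @param fr_intercept,fr_slope Named numeric per year: the
#'   exposure-dependent mean of the footprint coefficient.
#' @param individual_betas,individual_exposures Realised per-individual-year
#'   values; filled in by [simulate_individuals()].
#' @return Object of class `truth_record`.
#' @export
truth_record <- function(mu_beta, sd_beta, fr_intercept, fr_slope,
                         individual_betas = NULL,
                         individual_exposures = NULL) {
  if (any(sd_beta < 0)) stop("sd_beta must be >= 0")
  need <- c("intercept", "elevation", "slope", landcover_classes())
  for (y in names(mu_beta)) {
    if (!all(need %in% names(mu_beta[[y]])))
      stop("mu_beta[['", y, "']] missing coefficients")
  }
  if (!setequal(names(fr_intercept), names(mu_beta)) ||
      !setequal(names(fr_slope), names(mu_beta)))
    stop("fr_intercept / fr_slope must cover the same years as mu_beta")
  structure(list(mu_beta = mu_beta, sd_beta = sd_beta,
                 fr_intercept = fr_intercept, fr_slope = fr_slope,
                 individual_betas = individual_betas,
                 individual_exposures = individual_exposures),
            class = "truth_record")
}

#' Default simulation truth
#'
#' Emulates the study conditions of a park that is open in 2019 and closed in
#' 2020: a weakly negative functional-response slope in the open year and a
#' strongly positive slope in the closure year, with overall avoidance of the
#' footprint; moderate selection for forest, mild avoidance of steep slopes
#' and high elevation; between-individual spread of 0.5 on the footprint
#' coefficient and 0.3 elsewhere.
#'
#' @param fr_intercept,fr_slope Optional overrides of the exposure-dependent
#'   footprint-coefficient mean per year.
#' @return A [truth_record()].
#' @export
default_truth <- function(fr_intercept = c("2019" = -1.5, "2020" = -2.6),
                          fr_slope = c("2019" = -1, "2020" = 4)) {
  mu <- c(intercept = 0, elevation = -0.4, slope = -0.3,
          barren = -0.2, forest = 0.3, herbaceous = 0.1, scrub = 0,
          water = -0.1)
  truth_record(
    mu_beta = stats::setNames(rep(list(mu), length(fr_intercept)),
                              names(fr_intercept)),
    sd_beta = c(intercept = 1, footprint = 0.5, elevation = 0.3,
                slope = 0.3, barren = 0.3, forest = 0.3, herbaceous = 0.3,
                scrub = 0.3, water = 0.3),
    fr_intercept = fr_intercept, fr_slope = fr_slope)
}

#' Covariates on the model scale for a whole landscape
#'
#' Returns the per-cell covariate matrix the generator samples from:
#' raw footprint, landscape-standardised elevation and slope, and the five
#' decay-transformed, landscape-standardised land-cover distances. Cells are
#' in column-major order of the raster value matrix.
#'
#' @param landscape An `fp_landscape`.
#' @return Numeric matrix with one row per cell and columns `footprint`,
#'   `elevation`, `slope`, and [landcover_classes()].
#' @export
model_fields <- function(landscape) {
  st <- landscape$stack
  std <- function(v) (v - mean(v)) / stats::sd(v)
  cols <- list(footprint = as.numeric(st$footprint$values),
               elevation = std(as.numeric(st$elevation$values)),
               slope = std(as.numeric(st$slope$values)))
  for (cl in landcover_classes()) {
    tv <- transform_landcover_distance(as.numeric(st$lc_dist[[cl]]$values))
    cols[[cl]] <- std(tv)
  }
  do.call(cbind, cols)
}

# Indices (into column-major cell order) and centres of cells whose centres
# lie within radius of (cx, cy).
disc_cells <- function(grid, cx, cy, radius) {
  ctr <- grid_centers(grid)
  xs <- rep(ctr$x, each = grid$nrow)
  ys <- rep(ctr$y, times = grid$ncol)
  idx <- which((xs - cx)^2 + (ys - cy)^2 <= radius^2)
  list(idx = idx, x = xs[idx], y = ys[idx])
}

#' Simulate telemetry for a population with known truth
#'
#' For each individual-year a circular home-range disc is placed in the
#' landscape (same centre in both years for an individual); its exposure is
#' the mean footprint over the disc cells; its footprint coefficient is drawn
#' from `Normal(fr_intercept[t] + fr_slope[t] * exposure, sd)`, other
#' coefficients from their year means. Used locations are then drawn by exact
#' categorical sampling over the disc's cells with probability proportional
#' to `exp(linear predictor)` (uniform jitter within the chosen cell), and
#' time-stamped on an even grid within the year's study window.
#'
#' @param truth A [truth_record()].
#' @param landscape An `fp_landscape` from [generate_landscape()]; it must
#'   cover every home-range disc.
#' @param design List: `n_individuals`, `n_used_per_individual`,
#'   `home_range_radius_m` (default 900), `years` (default the years of
#'   `truth`), `fix_interval_h` (default 4), `window` (a [study_window()]).
#' @param seed Integer RNG seed.
#' @return List with `fixes` (data.frame `animal_id`, `timestamp`, `x`, `y`),
#'   `truth` (the input truth completed with realised `individual_betas` and
#'   `individual_exposures`), and `centers` (the true home-range disc centre
#'   and radius per individual).
#' @export
simulate_individuals <- function(truth, landscape, design, seed) {
  stopifnot(inherits(truth, "truth_record"),
            inherits(landscape, "fp_landscape"))
  n_ind <- design$n_individuals
  n_used <- design$n_used_per_individual
  radius <- design$home_range_radius_m %||% 900
  years <- as.character(design$years %||% names(truth$mu_beta))
  interval_h <- design$fix_interval_h %||% 4
  window <- design$window %||% study_window()
  grid <- landscape$stack$grid
  if (2 * radius > min(grid$xmax - grid$xmin, grid$ymax - grid$ymin))
    stop("home-range discs do not fit in the landscape")
  M <- model_fields(landscape)
  fpv <- M[, "footprint"]
  coef_names <- c("intercept", "footprint", "elevation", "slope",
                  landcover_classes())
  with_seed(seed, {
    ids <- sprintf("A%02d", seq_len(n_ind))
    cx <- stats::runif(n_ind, grid$xmin + radius, grid$xmax - radius)
    cy <- stats::runif(n_ind, grid$ymin + radius, grid$ymax - radius)
    fixes <- list(); betas <- list(); expo <- list()
    for (i in seq_len(n_ind)) {
      disc <- disc_cells(grid, cx[i], cy[i], radius)
      if (length(disc$idx) == 0) stop("home-range disc contains no cells")
      exposure <- mean(fpv[disc$idx])
      for (y in years) {
        b <- c(intercept = stats::rnorm(
                 1, unname(truth$mu_beta[[y]]["intercept"]),
                 unname(truth$sd_beta["intercept"])),
               footprint = stats::rnorm(
                 1, unname(truth$fr_intercept[y] +
                             truth$fr_slope[y] * exposure),
                 unname(truth$sd_beta["footprint"])))
        for (cn in c("elevation", "slope", landcover_classes()))
          b[cn] <- stats::rnorm(1, unname(truth$mu_beta[[y]][cn]),
                                unname(truth$sd_beta[cn]))
        eta <- as.numeric(M[disc$idx, , drop = FALSE] %*% b[colnames(M)])
        if (any(!is.finite(eta)))
          stop("non-finite linear predictor in simulation")
        w <- exp(eta - max(eta))
        pick <- sample.int(length(disc$idx), n_used, replace = TRUE,
                           prob = w)
        px <- disc$x[pick] + stats::runif(n_used, -grid$res / 2,
                                          grid$res / 2)
        py <- disc$y[pick] + stats::runif(n_used, -grid$res / 2,
                                          grid$res / 2)
        win <- window_for_year(window, y)
        step <- interval_h * 3600
        tmax <- as.numeric(win$end) - as.numeric(win$start)
        if ((n_used - 1) * step > tmax)
          step <- tmax / max(1, n_used - 1)
        ts <- win$start + (seq_len(n_used) - 1) * step
        fixes[[length(fixes) + 1]] <-
          data.frame(animal_id = ids[i], timestamp = ts, x = px, y = py)
        betas[[length(betas) + 1]] <-
          cbind(data.frame(animal_id = ids[i], year = y),
                as.data.frame(as.list(stats::setNames(b, coef_names))))
        expo[[length(expo) + 1]] <-
          data.frame(animal_id = ids[i], year = y, exposure = exposure)
      }
    }
    truth$individual_betas <- do.call(rbind, betas)
    truth$individual_exposures <- do.call(rbind, expo)
    list(fixes = do.call(rbind, fixes), truth = truth,
         centers = data.frame(animal_id = ids, x = cx, y = cy,
                              radius = radius))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
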