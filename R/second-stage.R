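#' Footprint exposure of an individual-year
#'
#' Exposure is the arithmetic mean footprint value over the available
#' locations of the individual-year's home range: the availability axis of
#' the functional response.
#'
#' @param available Data frame of available points (`x`, `y`).
#' @param footprint Footprint [fp_raster()].
#' @param id Optional individual-year id for error messages.
#' @return Mean footprint (scalar in `[0, 1]`).
#' @export
compute_exposure <- function(available, footprint, id = NULL) {
  if (is.null(available) || nrow(available) == 0)
    stop("no available points for exposure", if (!is.null(id))
      paste0(" (", id, ")"))
  mean(raster_extract(footprint, cbind(available$x, available$y), id))
}

# Exact conjugate Gaussian linear model with known observation variances:
# y_i ~ N(x_i' b, sd_i^2), b ~ N(0, prior_precision^-1 I). Returns the
# closed-form posterior and independent draws from it.
bayes_lm_known_var <- function(X, y, obs_sd, prior_precision = 0.01,
                               n_draws = 4000, seed = 1, extra_sd = 0) {
  if (any(obs_sd <= 0)) stop("observation sds must be positive")
  tau <- 1 / (obs_sd^2 + extra_sd^2)
  A <- crossprod(X, X * tau) + diag(prior_precision, ncol(X))
  cA <- chol(A)
  mu <- backsolve(cA, forwardsolve(t(cA), crossprod(X, y * tau)))
  draws <- with_seed(seed, {
    Z <- matrix(stats::rnorm(n_draws * ncol(X)), ncol(X), n_draws)
    t(as.numeric(mu) + backsolve(cA, Z))
  })
  colnames(draws) <- colnames(X)
  list(mean = stats::setNames(as.numeric(mu), colnames(X)),
       cov = chol2inv(cA), draws = draws)
}

fr_summary_table <- function(fit_core) {
  ci <- apply(fit_core$draws, 2, ci95)
  data.frame(parameter = colnames(fit_core$draws),
             mean = fit_core$mean,
             sd = sqrt(diag(fit_core$cov)),
             ci_low = ci[1, ], ci_high = ci[2, ],
             row.names = NULL)
}

#' Individual change-in-selection model
#'
#' For animals tracked in both years, regresses the change in the footprint
#' coefficient (2020 - 2019) on the mean footprint in the animal's 2019 home
#' range: `delta_j = intercept[k] + slope * exposure2019_j`, with a separate
#' intercept per population and one common slope, Normal(0, precision 0.01)
#' priors on both, and each observed change treated as measured with known
#' precision `1 / delta_sd_j^2`. The posterior is conjugate and sampled
#' exactly.
#'
#' @param observations Either a [change_observations()] table
#'   (`animal_id`, `population`, `delta_mean`, `delta_sd`) or a
#'   [coefficient_observations()] table containing both years per animal
#'   (differenced internally with quadrature-combined sds); an animal with
#'   only one year is an error.
#' @param exposures2019 Data frame `animal_id`, `exposure` (2019 exposure).
#' @param prior_precision,n_draws,seed,extra_sd Model settings; `extra_sd`
#'   adds an optional residual sd beyond measurement error (default 0, the
#'   stated likelihood).
#' @return Object of class `change_fit`: `summary`, `mean`, `cov`, `draws`,
#'   `slope` (named draw vector), `data`.
#' @export
fit_change_model <- function(observations, exposures2019,
                             prior_precision = 0.01, n_draws = 4000,
                             seed = 1, extra_sd = 0) {
  if (!"delta_mean" %in% names(observations)) {
    obs <- observations
    cnt <- table(obs$animal_id)
    if (any(cnt != 2))
      stop("unpaired individual(s): ",
           paste(names(cnt)[cnt != 2], collapse = ", "))
    ids <- names(cnt)
    observations <- do.call(rbind, lapply(ids, function(id) {
      a <- obs[obs$animal_id == id & obs$year == "2019", ]
      b <- obs[obs$animal_id == id & obs$year == "2020", ]
      if (nrow(a) != 1 || nrow(b) != 1)
        stop("unpaired individual(s): ", id)
      data.frame(animal_id = id, population = a$population,
                 delta_mean = b$beta_mean - a$beta_mean,
                 delta_sd = sqrt(a$beta_sd^2 + b$beta_sd^2))
    }))
  }
  i <- match(observations$animal_id, exposures2019$animal_id)
  if (anyNA(i)) stop("missing 2019 exposure for some animals")
  expo <- exposures2019$exposure[i]
  pops <- sort(unique(observations$population))
  X <- sapply(pops, function(p)
    as.numeric(observations$population == p))
  X <- matrix(X, nrow = nrow(observations))
  colnames(X) <- paste0("int_", pops)
  X <- cbind(X, slope = expo)
  core <- bayes_lm_known_var(X, observations$delta_mean,
                             observations$delta_sd, prior_precision,
                             n_draws, seed, extra_sd)
  structure(list(summary = fr_summary_table(core), mean = core$mean,
                 cov = core$cov, draws = core$draws,
                 slope = core$draws[, "slope"],
                 data = cbind(observations, exposure2019 = expo)),
            class = "change_fit")
}

#' @export
print.change_fit <- function(x, ...) {
  cat("<change_fit> individual change in footprint selection vs 2019 exposure\n")
  print(x$summary, digits = 3)
  invisible(x)
}

fr_guilds <- function() c("large carnivore", "ungulate")

#' Functional-response measurement-error model
#'
#' Relates individual-year footprint selection coefficients to footprint
#' exposure: `beta_j = intercept[group, t] + slope[grouping, t] * exposure_j`
#' with the observed posterior mean of each coefficient treated as measured
#' with known precision `1 / beta_sd_j^2` and Normal(0, precision 0.01)
#' priors throughout. Three structures: `"global"` (one slope per year;
#' intercepts by population-year), `"guild"` (slopes by guild and year,
#' large carnivores vs ungulates, the small-carnivore red fox excluded;
#' intercepts by population-year) and `"species"` (separate slope and
#' intercept per species-year). The conjugate posterior is sampled exactly.
#'
#' @param observations A [coefficient_observations()]-style table
#'   (`individual_year_id`, `year`, `population`, `species`, `guild`,
#'   `beta_mean`, `beta_sd`).
#' @param exposures Data frame `individual_year_id`, `exposure` (each
#'   individual-year's own home-range exposure).
#' @param structure `"global"`, `"guild"` or `"species"`.
#' @param prior_precision,n_draws,seed,extra_sd As in [fit_change_model()].
#' @return Object of class `fr_fit`: `structure`, `summary`, `mean`, `cov`,
#'   `draws`, `slopes` (slope column names), `unidentifiable` (flagged slope
#'   groups with < 2 observations or constant exposure), `data`.
#' @export
fit_functional_response <- function(observations, exposures,
                                    structure = c("global", "guild",
                                                  "species"),
                                    prior_precision = 0.01, n_draws = 4000,
                                    seed = 1, extra_sd = 0) {
  structure_ <- match.arg(structure)
  obs <- observations
  i <- match(obs$individual_year_id, exposures$individual_year_id)
  if (anyNA(i)) stop("missing exposure for some individual-years")
  obs$exposure <- exposures$exposure[i]
  if (structure_ == "guild") {
    keep <- obs$guild %in% fr_guilds()
    obs <- obs[keep, , drop = FALSE]
    if (nrow(obs) == 0) stop("no observations in a modelled guild")
  }
  obs$year <- as.character(obs$year)
  int_group <- switch(structure_,
    global = paste0(obs$population, "_", obs$year),
    guild = paste0(obs$population, "_", obs$year),
    species = paste0(obs$species, "_", obs$year))
  slope_group <- switch(structure_,
    global = obs$year,
    guild = paste0(obs$guild, "_", obs$year),
    species = paste0(obs$species, "_", obs$year))
  ig <- sort(unique(int_group)); sg <- sort(unique(slope_group))
  X <- matrix(0, nrow(obs), length(ig) + length(sg),
              dimnames = list(NULL, c(paste0("int_", ig),
                                      paste0("slope_", sg))))
  for (k in seq_along(ig))
    X[int_group == ig[k], k] <- 1
  for (k in seq_along(sg))
    X[slope_group == sg[k], length(ig) + k] <-
      obs$exposure[slope_group == sg[k]]
  unident <- character(0)
  for (g in sg) {
    e <- obs$exposure[slope_group == g]
    if (length(e) < 2 || stats::sd(e) == 0)
      unident <- c(unident, g)
  }
  core <- bayes_lm_known_var(X, obs$beta_mean, obs$beta_sd,
                             prior_precision, n_draws, seed, extra_sd)
  structure(list(structure = structure_,
                 summary = fr_summary_table(core),
                 mean = core$mean, cov = core$cov, draws = core$draws,
                 slopes = paste0("slope_", sg),
                 unidentifiable = unident, data = obs),
            class = "fr_fit")
}

#' @export
print.fr_fit <- function(x, ...) {
  cat(sprintf("<fr_fit> %s functional-response model, %d observations\n",
              x$structure, nrow(x$data)))
  if (length(x$unidentifiable))
    cat("  unidentifiable slope group(s): ",
        paste(x$unidentifiable, collapse = ", "), "\n")
  print(x$summary[grepl("^slope_", x$summary$parameter), ], digits = 3)
  invisible(x)
}

#' Predicted functional-response curve
#'
#' Draw-wise `intercept + slope * exposure` over a grid, summarised to the
#' posterior mean and 95% credible band. Grid points outside the observed
#' exposure range are flagged as extrapolation.
#'
#' @param fit An [fit_functional_response()] result.
#' @param exposure_grid Numeric exposure values.
#' @param year Year label.
#' @param population Population (intercept group for the global and guild
#'   structures).
#' @param guild Guild (slope group for the guild structure).
#' @param species Species (intercept and slope group for the species
#'   structure).
#' @return Data frame `exposure`, `mean`, `ci_low`, `ci_high`,
#'   `extrapolated`.
#' @export
predict_functional_response <- function(fit, exposure_grid, year,
                                        population = NULL, guild = NULL,
                                        species = NULL) {
  year <- as.character(year)
  int_col <- switch(fit$structure,
    global = paste0("int_", population, "_", year),
    guild = paste0("int_", population, "_", year),
    species = paste0("int_", species, "_", year))
  slope_col <- switch(fit$structure,
    global = paste0("slope_", year),
    guild = paste0("slope_", guild, "_", year),
    species = paste0("slope_", species, "_", year))
  if (!int_col %in% colnames(fit$draws) ||
      !slope_col %in% colnames(fit$draws))
    stop("unknown group/year: ", int_col, " / ", slope_col)
  a <- fit$draws[, int_col]; b <- fit$draws[, slope_col]
  pred <- outer(a, rep(1, length(exposure_grid))) + outer(b, exposure_grid)
  ci <- apply(pred, 2, ci95)
  rng <- range(fit$data$exposure)
  data.frame(exposure = exposure_grid, mean = colMeans(pred),
             ci_low = ci[1, ], ci_high = ci[2, ],
             extrapolated = exposure_grid < rng[1] |
               exposure_grid > rng[2])
}
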