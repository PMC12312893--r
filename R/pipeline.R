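#' Run the full analysis pipeline on one population
#'
#' Chains every stage on raw telemetry: GPS-error screening, 4 h interval
#' harmonisation, clipping to the closure window and its 2019 twin, 95% KUD
#' home ranges, individual-year inclusion filters, used/available sampling,
#' covariate extraction, the hierarchical RSF, exposure computation and the
#' second-stage models (global functional response; individual change model
#' when animals are tracked in both years).
#'
#' @param fixes Raw telemetry data.frame (`animal_id`, `timestamp`, `x`,
#'   `y`).
#' @param stack A [covariate_stack()].
#' @param park Park boundary ring matrix.
#' @param window A [study_window()].
#' @param population_id Population label.
#' @param ratio Available : used ratio (default 50).
#' @param thresholds An [inclusion_thresholds()].
#' @param mcmc An [mcmc_config()].
#' @param seed Seed for availability sampling.
#' @param species,guild Labels forwarded to the coefficient table.
#' @return List: `groups`, `home_ranges`, `exclusions`, `ua`, `posterior`,
#'   `summaries`, `exposures`, `coefficients`, `fr_global`, `change`
#'   (NULL when no animal is paired across years).
#' @export
run_rsf_study <- function(fixes, stack, park, window = study_window(),
                          population_id = "P1", ratio = 50,
                          thresholds = inclusion_thresholds(),
                          mcmc = mcmc_config(), seed = 1,
                          species = NA_character_, guild = NA_character_) {
  prep <- prep_tracks(fixes, window)
  hrs <- list()
  for (g in names(prep$groups)) {
    tr <- prep$groups[[g]]
    if (nrow(tr) >= max(5, thresholds$min_fixes))
      hrs[[g]] <- estimate_kud(tr, res_m = stack$grid$res,
                               id = tr$animal_id[1], year = tr$year[1])
  }
  incl <- apply_inclusion_filters(prep$groups, park, stack$footprint,
                                  thresholds, hrs)
  if (length(incl$kept) < 2)
    stop("fewer than 2 individual-years pass the inclusion filters")
  groups <- list()
  k <- 0L
  for (g in names(incl$kept)) {
    k <- k + 1L
    tr <- incl$kept[[g]]
    avail <- sample_available(hrs[[g]], nrow(tr), ratio, seed + k,
                              clip_bbox = c(stack$grid$xmin,
                                            stack$grid$xmax,
                                            stack$grid$ymin,
                                            stack$grid$ymax))
    groups[[g]] <- list(id = tr$animal_id[1], year = tr$year[1],
                        population = population_id,
                        used = data.frame(x = tr$x, y = tr$y),
                        available = avail, home_range = hrs[[g]])
  }
  ua <- build_ua_table(groups, stack)
  post <- fit_hierarchical_rsf(ua, mcmc = mcmc)
  summaries <- derive_population_summaries(post)
  expo <- data.frame(
    individual_year_id = names(groups),
    animal_id = vapply(groups, function(g) g$id, ""),
    year = vapply(groups, function(g) as.character(g$year), ""),
    exposure = vapply(groups, function(g)
      compute_exposure(g$available, stack$footprint), numeric(1)),
    row.names = NULL)
  coefs <- coefficient_observations(post, species = species, guild = guild)
  fr <- fit_functional_response(coefs, expo, "global", seed = seed)
  change <- NULL
  if (all(c("2019", "2020") %in% post$years)) {
    ch_obs <- tryCatch(change_observations(post), error = function(e) NULL)
    if (!is.null(ch_obs) && nrow(ch_obs) >= 2) {
      e19 <- expo[expo$year == "2019", c("animal_id", "exposure")]
      change <- fit_change_model(ch_obs, e19, seed = seed)
    }
  }
  list(groups = groups, home_ranges = hrs, exclusions = incl$report,
       error_log = prep$error_log, ua = ua, posterior = post,
       summaries = summaries, exposures = expo, coefficients = coefs,
       fr_global = fr, change = change)
}

#' Simulate an exact-likelihood used/available dataset
#'
#' The parameter-recovery companion of [simulate_individuals()]: home ranges
#' are the true discs, used cells are drawn by exact categorical sampling
#' proportional to `exp(linear predictor)` and available cells uniformly
#' over the same disc cells, and the covariates entering the table are the
#' generator's own model-scale fields. The fitted model is then exactly the
#' generating model, which isolates estimator behaviour from home-range
#' estimation error.
#'
#' @param truth A [truth_record()].
#' @param landscape An `fp_landscape`.
#' @param design As in [simulate_individuals()] (`n_individuals`,
#'   `n_used_per_individual`, `home_range_radius_m`, `years`).
#' @param ratio Available : used ratio.
#' @param seed Integer RNG seed.
#' @return List: `ua` (a table accepted by [fit_hierarchical_rsf()]),
#'   `truth` (with realised individuals), `exposures`.
#' @export
simulate_rsf_dataset <- function(truth, landscape, design, ratio = 20,
                                 seed = 1) {
  n_ind <- design$n_individuals
  n_used <- design$n_used_per_individual
  radius <- design$home_range_radius_m %||% 900
  years <- as.character(design$years %||% names(truth$mu_beta))
  grid <- landscape$stack$grid
  M <- model_fields(landscape)
  coef_names <- rsf_coef_names()
  with_seed(seed, {
    ids <- sprintf("A%02d", seq_len(n_ind))
    cx <- stats::runif(n_ind, grid$xmin + radius, grid$xmax - radius)
    cy <- stats::runif(n_ind, grid$ymin + radius, grid$ymax - radius)
    rows <- list(); betas <- list(); expo <- list()
    for (i in seq_len(n_ind)) {
      disc <- disc_cells(grid, cx[i], cy[i], radius)
      Md <- M[disc$idx, , drop = FALSE]
      exposure <- mean(Md[, "footprint"])
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
        eta <- as.numeric(Md %*% b[colnames(M)])
        if (any(!is.finite(eta))) stop("non-finite linear predictor")
        used_i <- sample.int(nrow(Md), n_used, replace = TRUE,
                             prob = exp(eta - max(eta)))
        avail_i <- sample.int(nrow(Md), ratio * n_used, replace = TRUE)
        pick <- c(used_i, avail_i)
        df <- as.data.frame(Md[pick, , drop = FALSE])
        df <- cbind(used = c(rep(1L, n_used),
                             rep(0L, ratio * n_used)), df)
        for (cl in landcover_classes()) df[[paste0("ind_", cl)]] <- 1L
        iy <- paste(ids[i], y, sep = "_")
        df$individual_year_id <- iy
        df$animal_id <- ids[i]
        df$year <- y
        df$population <- "SIM"
        rows[[length(rows) + 1]] <- df
        betas[[length(betas) + 1]] <-
          cbind(data.frame(animal_id = ids[i], year = y),
                as.data.frame(as.list(b[coef_names])))
        expo[[length(expo) + 1]] <-
          data.frame(individual_year_id = iy, animal_id = ids[i],
                     year = y, exposure = exposure)
      }
    }
    truth$individual_betas <- do.call(rbind, betas)
    truth$individual_exposures <- do.call(rbind, expo)[,
      c("animal_id", "year", "exposure")]
    list(ua = do.call(rbind, rows), truth = truth,
         exposures = do.call(rbind, expo))
  })
}

#' One parameter-recovery replicate
#'
#' Simulates an exact-likelihood dataset with the given population mean of
#' the footprint coefficient as truth (no functional-response slope), fits
#' the hierarchical RSF and reports whether the 95% credible interval of the
#' year's population mean covers the truth.
#'
#' @param seed Replicate seed.
#' @param landscape An `fp_landscape` (shared across replicates).
#' @param mu_footprint True population mean of the footprint coefficient.
#' @param design Simulation design (single year by default).
#' @param ratio Available : used ratio.
#' @param mcmc An [mcmc_config()].
#' @return List: `mean`, `ci`, `covered`, `max_rhat`.
#' @export
run_recovery_replicate <- function(seed, landscape, mu_footprint = -1.88,
                                   design = list(n_individuals = 8,
                                                 n_used_per_individual = 100,
                                                 home_range_radius_m = 900,
                                                 years = "2019"),
                                   ratio = 10,
                                   mcmc = mcmc_config(n_chains = 2,
                                                      n_iterations = 1500,
                                                      burn_in = 300,
                                                      thin = 3)) {
  truth <- default_truth(
    fr_intercept = stats::setNames(rep(mu_footprint,
                                       length(design$years %||% "2019")),
                                   as.character(design$years %||% "2019")),
    fr_slope = stats::setNames(rep(0, length(design$years %||% "2019")),
                               as.character(design$years %||% "2019")))
  sim <- simulate_rsf_dataset(truth, landscape, design, ratio, seed)
  mcmc$seed <- seed
  post <- suppressWarnings(fit_hierarchical_rsf(sim$ua, mcmc = mcmc))
  y <- as.character((design$years %||% "2019")[1])
  dr <- pooled_draws(post, paste0("mu_footprint_", y))
  ci <- ci95(dr)
  list(mean = mean(dr), ci = ci,
       covered = ci[1] <= mu_footprint && mu_footprint <= ci[2],
       max_rhat = post$convergence$max_rhat)
}
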