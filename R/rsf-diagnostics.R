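#' Gelman-Rubin potential scale reduction factor
#'
#' The classic R-hat: with m chains of n draws, `W` the mean within-chain
#' variance and `B/n` the between-chain variance of chain means,
#' `R-hat = sqrt(((n-1)/n * W + B/n) / W)`. With `split = TRUE` (the
#' default) each chain is first split in half, so within-chain
#' non-stationarity also inflates the statistic. A parameter with zero
#' within-chain variance in every chain returns 1 when the chains agree and
#' `Inf` when they do not.
#'
#' @param chains List of numeric vectors, one per chain (equal lengths).
#' @param split Split each chain in half before computing (default TRUE).
#' @return The R-hat value.
#' @export
gelman_rubin <- function(chains, split = TRUE) {
  if (!is.list(chains) || length(chains) < 2)
    stop("need >= 2 chains to compute R-hat")
  n0 <- min(lengths(chains))
  chains <- lapply(chains, function(x) x[seq_len(n0)])
  if (split) {
    h <- n0 %/% 2
    chains <- c(lapply(chains, function(x) x[seq_len(h)]),
                lapply(chains, function(x) x[(n0 - h + 1):n0]))
  }
  m <- length(chains)
  n <- length(chains[[1]])
  means <- vapply(chains, mean, numeric(1))
  vars <- vapply(chains, stats::var, numeric(1))
  W <- mean(vars)
  B_over_n <- stats::var(means)  # = B/n in the usual notation
  if (W == 0) return(if (B_over_n == 0) 1 else Inf)
  sqrt(((n - 1) / n * W + B_over_n) / W)
}

#' Convergence report for an RSF posterior
#'
#' Split-chain Gelman-Rubin statistic for every monitored parameter; the fit
#' passes iff the maximum is at most 1.1.
#'
#' @param posterior An `rsf_posterior` (or any list with per-chain draw
#'   matrices under `$draws`).
#' @return List: `rhat` (named vector), `max_rhat`, `pass`, `flagged`
#'   (parameters above 1.1).
#' @export
check_convergence <- function(posterior) {
  chains <- posterior$draws
  if (length(chains) < 2)
    stop("convergence diagnosis requires >= 2 chains")
  pars <- colnames(chains[[1]])
  rhat <- vapply(pars, function(p)
    gelman_rubin(lapply(chains, function(ch) ch[, p]), split = TRUE),
    numeric(1))
  list(rhat = rhat, max_rhat = max(rhat),
       pass = max(rhat) <= 1.1,
       flagged = names(rhat)[rhat > 1.1])
}

#' Classify selection from a credible interval
#'
#' `"avoid"` when the interval lies entirely below zero, `"select"` when
#' entirely above, `"neutral"` when it overlaps zero.
#'
#' @param mean Posterior mean (unused in the rule; carried for reporting).
#' @param ci_low,ci_high Equal-tailed 95% credible bounds,
#'   `ci_low <= ci_high`.
#' @return One of `"avoid"`, `"select"`, `"neutral"`.
#' @export
classify_selection <- function(mean, ci_low, ci_high) {
  if (ci_low > ci_high) stop("ci_low must be <= ci_high")
  if (ci_high < 0) "avoid" else if (ci_low > 0) "select" else "neutral"
}

# pooled draws of one parameter across chains
pooled_draws <- function(posterior, par) {
  unlist(lapply(posterior$draws, function(ch) ch[, par]), use.names = FALSE)
}

#' Population summaries of footprint selection
#'
#' Per-year population mean footprint coefficient (posterior mean, 95%
#' equal-tailed CI, selection class) and, when both years are present, the
#' interannual difference computed draw-wise (2020 - 2019) before
#' summarising. Two aggregations are available: `"hypermean"` summarises the
#' year-indexed population hyper-mean itself; `"individual"` averages the
#' individual coefficient draws within each year first (the two aggregations
#' answer slightly different questions and need not agree numerically).
#'
#' @param posterior An `rsf_posterior`.
#' @param aggregation `"hypermean"` (default) or `"individual"`.
#' @return List: `summary` (data.frame `quantity`, `mean`, `ci_low`,
#'   `ci_high`, `class`) and `draws` (named list of the pooled draw
#'   vectors).
#' @export
derive_population_summaries <- function(posterior,
                                        aggregation = c("hypermean",
                                                        "individual")) {
  aggregation <- match.arg(aggregation)
  years <- posterior$years
  dr <- list()
  for (y in years) {
    if (aggregation == "hypermean") {
      dr[[y]] <- pooled_draws(posterior, paste0("mu_footprint_", y))
    } else {
      cols <- paste0("beta[", posterior$individual_years[
        posterior$year_index == match(y, years)], "].footprint")
      dr[[y]] <- unlist(lapply(posterior$draws, function(ch)
        rowMeans(ch[, cols, drop = FALSE])), use.names = FALSE)
    }
  }
  rows <- list()
  for (y in years) {
    ci <- ci95(dr[[y]])
    rows[[y]] <- data.frame(quantity = paste0("mean_footprint_", y),
                            mean = mean(dr[[y]]), ci_low = ci[1],
                            ci_high = ci[2],
                            class = classify_selection(mean(dr[[y]]),
                                                       ci[1], ci[2]))
  }
  if (all(c("2019", "2020") %in% years)) {
    dd <- dr[["2020"]] - dr[["2019"]]
    ci <- ci95(dd)
    dr$difference <- dd
    rows$difference <- data.frame(quantity = "difference_2020_2019",
                                  mean = mean(dd), ci_low = ci[1],
                                  ci_high = ci[2],
                                  class = classify_selection(mean(dd),
                                                             ci[1], ci[2]))
  }
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  list(summary = summary, draws = dr)
}

#' Per-individual footprint coefficient observations for the second stage
#'
#' Extracts the posterior mean and sd of every individual-year footprint
#' coefficient, the inputs of the measurement-error models.
#'
#' @param posterior An `rsf_posterior`.
#' @param species,guild Optional labels (single values or named by
#'   animal id) attached for the guild/species functional-response models.
#' @return Data frame `individual_year_id`, `animal_id`, `year`,
#'   `population`, `species`, `guild`, `beta_mean`, `beta_sd`.
#' @export
coefficient_observations <- function(posterior, species = NA_character_,
                                     guild = NA_character_) {
  iys <- posterior$individual_years
  label_for <- function(lab) {
    if (length(lab) == 1 && is.null(names(lab)))
      return(rep(lab, length(iys)))
    out <- lab[posterior$animal_ids]
    unname(out)
  }
  means <- sds <- numeric(length(iys))
  for (k in seq_along(iys)) {
    d <- pooled_draws(posterior, paste0("beta[", iys[k], "].footprint"))
    means[k] <- mean(d); sds[k] <- stats::sd(d)
  }
  data.frame(individual_year_id = iys,
             animal_id = posterior$animal_ids,
             year = posterior$years[posterior$year_index],
             population = posterior$population,
             species = label_for(species),
             guild = label_for(guild),
             beta_mean = means, beta_sd = sds)
}

#' Draw-wise change observations for the individual change model
#'
#' For animals tracked in both years, the 2020 - 2019 difference of the
#' footprint coefficient. With `method = "draws"` (preferred) the difference
#' is formed draw-wise from the joint posterior; with `"quadrature"` the
#' per-year posterior sds are combined as `sqrt(sd2019^2 + sd2020^2)` under
#' an independence assumption.
#'
#' @param posterior An `rsf_posterior` containing both years.
#' @param method `"draws"` (default) or `"quadrature"`.
#' @return Data frame `animal_id`, `population`, `delta_mean`, `delta_sd`.
#' @export
change_observations <- function(posterior,
                                method = c("draws", "quadrature")) {
  method <- match.arg(method)
  if (!all(c("2019", "2020") %in% posterior$years))
    stop("both years are required for change observations")
  ids <- unique(posterior$animal_ids)
  both <- ids[vapply(ids, function(id)
    all(paste0(id, c("_2019", "_2020")) %in% posterior$individual_years),
    logical(1))]
  out <- lapply(both, function(id) {
    d19 <- pooled_draws(posterior, paste0("beta[", id, "_2019].footprint"))
    d20 <- pooled_draws(posterior, paste0("beta[", id, "_2020].footprint"))
    if (method == "draws") {
      dd <- d20 - d19
      data.frame(animal_id = id, population = posterior$population,
                 delta_mean = mean(dd), delta_sd = stats::sd(dd))
    } else {
      data.frame(animal_id = id, population = posterior$population,
                 delta_mean = mean(d20) - mean(d19),
                 delta_sd = sqrt(stats::var(d19) + stats::var(d20)))
    }
  })
  do.call(rbind, out)
}
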