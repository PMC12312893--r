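beta0 <- c(intercept = -0.5, footprint = -1.2, elevation = 0.4,
           slope = -0.3, barren = 0.2, forest = 0.5, herbaceous = -0.1,
           scrub = 0, water = -0.4)

test_that("RSF log likelihood matches brute-force evaluation", {
  rows <- make_ua_direct(beta0, n_rows = 10, seed = 71)
  ll <- rsf_log_likelihood(beta0, rows)
  # independent term-by-term oracle
  oracle <- 0
  for (i in seq_len(10)) {
    eta <- beta0["intercept"] + beta0["footprint"] * rows$footprint[i] +
      beta0["elevation"] * rows$elevation[i] +
      beta0["slope"] * rows$slope[i]
    for (cl in landcover_classes())
      eta <- eta + rows[[paste0("ind_", cl)]][i] * beta0[cl] * rows[[cl]][i]
    p <- 1 / (1 + exp(-eta))
    oracle <- oracle + rows$used[i] * log(p) +
      (1 - rows$used[i]) * log(1 - p)
  }
  expect_equal(ll, unname(oracle), tolerance = 1e-12)
  # all-zero coefficients: N * log(0.5)
  z <- setNames(rep(0, 9), names(beta0))
  expect_equal(rsf_log_likelihood(z, rows), 10 * log(0.5))
})

test_that("absent cover types are masked out of the likelihood", {
  rows <- make_ua_direct(beta0, n_rows = 50, seed = 72,
                         indicators = c(1L, 1L, 1L, 1L, 0L))  # water absent
  b1 <- beta0; b2 <- beta0
  b2["water"] <- 42
  expect_equal(rsf_log_likelihood(b1, rows), rsf_log_likelihood(b2, rows))
  # but a present class does change the likelihood
  b3 <- beta0; b3["forest"] <- 42
  expect_false(rsf_log_likelihood(b1, rows) ==
                 rsf_log_likelihood(b3, rows))
})

test_that("likelihood is stable at extreme linear predictors", {
  rows <- make_ua_direct(beta0, n_rows = 20, seed = 73)
  big <- beta0; big["intercept"] <- 700
  expect_true(is.finite(rsf_log_likelihood(big, rows)))
  big["intercept"] <- -700
  expect_true(is.finite(rsf_log_likelihood(big, rows)))
})

test_that("Gelman-Rubin statistic matches the direct formula", {
  set.seed(81)
  c1 <- rnorm(100); c2 <- rnorm(100)
  # direct-formula oracle, no splitting
  m <- 2; n <- 100
  W <- mean(c(var(c1), var(c2)))
  B_n <- var(c(mean(c1), mean(c2)))
  oracle <- sqrt(((n - 1) / n * W + B_n) / W)
  expect_equal(gelman_rubin(list(c1, c2), split = FALSE), oracle,
               tolerance = 1e-10)
  # iid chains converge to ~1; an offset chain blows up
  expect_lt(gelman_rubin(list(rnorm(2000), rnorm(2000), rnorm(2000))),
            1.05)
  expect_gt(gelman_rubin(list(rnorm(200), rnorm(200) + 10)), 1.1)
  expect_error(gelman_rubin(list(rnorm(10))), "2 chains")
})

test_that("split R-hat detects within-chain drift", {
  drift <- seq(0, 5, length.out = 400) + rnorm(400, 0, 0.1)
  stat <- rnorm(400)
  expect_gt(gelman_rubin(list(drift, drift + rnorm(400, 0, 0.1))), 1.1)
  expect_lt(gelman_rubin(list(stat, rnorm(400))), 1.05)
})

test_that("selection classification follows the CI rule", {
  expect_equal(classify_selection(-1.88, -2.26, -1.50), "avoid")
  expect_equal(classify_selection(0.483, -0.003, 0.971), "neutral")
  expect_equal(classify_selection(0.5, 0.2, 0.9), "select")
  expect_error(classify_selection(0, 1, -1), "ci_low")
})

# a minimal hand-built posterior for summary arithmetic
fake_posterior <- function(d19, d20) {
  half <- function(x) list(x[seq_len(length(x) / 2)],
                           x[(length(x) / 2 + 1):length(x)])
  mk <- function(a, b) cbind("mu_footprint_2019" = a,
                             "mu_footprint_2020" = b,
                             "beta[A_2019].footprint" = a,
                             "beta[A_2020].footprint" = b)
  ch <- Map(mk, half(d19), half(d20))
  structure(list(draws = ch, years = c("2019", "2020"),
                 individual_years = c("A_2019", "A_2020"),
                 animal_ids = c("A", "A"), year_index = c(1, 2),
                 population = "P"), class = "rsf_posterior")
}

test_that("population summaries difference the years draw-wise", {
  set.seed(91)
  d <- rnorm(1000)
  ps <- fake_posterior(d, d)  # identical years
  s <- derive_population_summaries(ps)
  diff_row <- s$summary[s$summary$quantity == "difference_2020_2019", ]
  expect_equal(diff_row$mean, 0)
  expect_equal(diff_row$class, "neutral")
  # linearity of the mean
  d20 <- rnorm(1000, 1.5)
  ps2 <- fake_posterior(d, d20)
  s2 <- derive_population_summaries(ps2)
  expect_equal(s2$summary$mean[3],
               mean(d20) - mean(d), tolerance = 1e-12)
  # equal-tailed CI matches the order-statistic interpolation oracle
  dd <- sort(d20 - d)
  n <- length(dd)
  qint <- function(p) {
    h <- (n - 1) * p + 1
    lo <- floor(h)
    dd[lo] + (h - lo) * (dd[min(lo + 1, n)] - dd[lo])
  }
  expect_equal(s2$summary$ci_low[3], qint(0.025), tolerance = 1e-12)
  expect_equal(s2$summary$ci_high[3], qint(0.975), tolerance = 1e-12)
})

test_that("single-individual posterior matches the numerical MLE", {
  rows <- make_ua_direct(beta0, n_rows = 3000, seed = 74)
  fit <- fit_single_rsf(rows, prior_precision = 1e-4,
                        mcmc = mcmc_config(n_chains = 1,
                                           n_iterations = 3000,
                                           burn_in = 500, thin = 1,
                                           seed = 2))
  mle <- rsf_mle(rows)
  expect_lt(max(abs(fit$mean - mle)), 0.1)
  expect_gt(min(fit$accept), 0.3)
})

test_that("hierarchical fit recovers parameters and keeps draw counts", {
  land <- test_landscape()
  truth <- default_truth(fr_intercept = c("2019" = -1.6),
                         fr_slope = c("2019" = 0))
  sim <- simulate_rsf_dataset(truth, land,
                              design = list(n_individuals = 6,
                                            n_used_per_individual = 80,
                                            home_range_radius_m = 800,
                                            years = "2019"),
                              ratio = 10, seed = 21)
  mc <- mcmc_config(n_chains = 3, n_iterations = 2400, burn_in = 600,
                    thin = 3, seed = 7)
  post <- suppressWarnings(fit_hierarchical_rsf(sim$ua, mcmc = mc))
  # draw bookkeeping: chains x (iterations - burn_in) / thin
  expect_length(post$draws, 3)
  expect_equal(nrow(post$draws[[1]]), (2400 - 600) / 3)
  expect_true(all(c("mu_footprint_2019", "tau_footprint",
                    "sigma_intercept") %in% colnames(post$draws[[1]])))
  # posterior of the population mean near the realised individual mean
  s <- derive_population_summaries(post)
  realised <- mean(sim$truth$individual_betas$footprint)
  expect_gt(s$summary$ci_high[1], realised - 0.5)
  expect_lt(s$summary$ci_low[1], realised + 0.5)
  # individual aggregation is also available and close in this design
  s2 <- derive_population_summaries(post, aggregation = "individual")
  expect_lt(abs(s2$summary$mean[1] - s$summary$mean[1]), 0.5)
  # determinism under identical config
  post2 <- suppressWarnings(fit_hierarchical_rsf(sim$ua, mcmc = mc))
  expect_identical(post$draws[[1]], post2$draws[[1]])
  expect_error(fit_hierarchical_rsf(sim$ua[sim$ua$individual_year_id ==
                                             sim$ua$individual_year_id[1], ]),
               ">= 2")
})

test_that("near-zero hyper-variance shrinks individuals together", {
  land <- test_landscape()
  truth <- default_truth(fr_intercept = c("2019" = -1.5),
                         fr_slope = c("2019" = 0))
  truth$sd_beta[] <- 0.02  # essentially identical individuals
  sim <- simulate_rsf_dataset(truth, land,
                              design = list(n_individuals = 5,
                                            n_used_per_individual = 60,
                                            home_range_radius_m = 800,
                                            years = "2019"),
                              ratio = 8, seed = 22)
  post <- suppressWarnings(
    fit_hierarchical_rsf(sim$ua,
                         mcmc = mcmc_config(n_chains = 2,
                                            n_iterations = 1200,
                                            burn_in = 300, thin = 3,
                                            seed = 3)))
  # hierarchical posterior means of individual footprint coefficients are
  # less spread than the separate single-animal MLEs
  iys <- post$individual_years
  post_means <- vapply(iys, function(iy)
    mean(footprintRSF:::pooled_draws(post,
                                     paste0("beta[", iy, "].footprint"))),
    numeric(1))
  mles <- vapply(iys, function(iy)
    rsf_mle(sim$ua[sim$ua$individual_year_id == iy, ])["footprint"],
    numeric(1))
  expect_lt(sd(post_means), sd(mles))
})

test_that("the sampler agrees with an independent JAGS implementation", {
  library(rjags)
  land <- test_landscape()
  truth <- default_truth(fr_intercept = c("2019" = -1.5),
                         fr_slope = c("2019" = 0))
  sim <- simulate_rsf_dataset(truth, land,
                              design = list(n_individuals = 4,
                                            n_used_per_individual = 60,
                                            home_range_radius_m = 800,
                                            years = "2019"),
                              ratio = 6, seed = 23)
  ua <- sim$ua
  post <- fit_hierarchical_rsf(ua,
                               mcmc = mcmc_config(n_chains = 2,
                                                  n_iterations = 3000,
                                                  burn_in = 500, thin = 2,
                                                  seed = 11))
  blocks <- footprintRSF:::build_rsf_blocks(ua)
  X <- do.call(rbind, lapply(blocks, `[[`, "X"))
  yv <- unlist(lapply(blocks, `[[`, "y"))
  grp <- rep(seq_along(blocks),
             vapply(blocks, function(b) length(b$y), integer(1)))
  model <- "
  model {
    for (i in 1:N) {
      used[i] ~ dbern(ilogit(inprod(beta[grp[i], 1:9], X[i, 1:9])))
    }
    for (j in 1:J) {
      beta[j, 1] ~ dnorm(mu_int, tau_int)
      beta[j, 2] ~ dnorm(mu_fp, tau_fp)
      beta[j, 3] ~ dnorm(mu_el, tau_el)
      beta[j, 4] ~ dnorm(mu_sl, tau_sl)
      beta[j, 5:9] ~ dmnorm(mu_lc[1:5], Omega[1:5, 1:5])
    }
    mu_int ~ dnorm(0, 0.01); mu_fp ~ dnorm(0, 0.01)
    mu_el ~ dnorm(0, 0.01); mu_sl ~ dnorm(0, 0.01)
    for (c in 1:5) { mu_lc[c] ~ dnorm(0, 0.01) }
    sigma_int ~ dunif(0, 100); tau_int <- pow(sigma_int, -2)
    tau_fp ~ dunif(0, 25); tau_el ~ dunif(0, 25); tau_sl ~ dunif(0, 25)
    Omega ~ dwish(R5[1:5, 1:5], 6)
  }"
  jm <- jags.model(textConnection(model),
                   data = list(N = nrow(X), J = length(blocks), X = X,
                               used = yv, grp = grp, R5 = diag(5)),
                   n.chains = 2, quiet = TRUE,
                   inits = list(.RNG.name = "base::Mersenne-Twister",
                                .RNG.seed = 4))
  update(jm, 500, progress.bar = "none")
  js <- coda.samples(jm, c("mu_fp", "beta"), n.iter = 2500, thin = 2,
                     progress.bar = "none")
  jdraw <- do.call(rbind, lapply(js, as.matrix))
  mu_fp_jags <- mean(jdraw[, "mu_fp"])
  mu_fp_ours <- mean(footprintRSF:::pooled_draws(post, "mu_footprint_2019"))
  expect_lt(abs(mu_fp_ours - mu_fp_jags), 0.3)
  for (j in seq_along(blocks)) {
    ours <- mean(footprintRSF:::pooled_draws(
      post, paste0("beta[", blocks[[j]]$iy, "].footprint")))
    jags <- mean(jdraw[, sprintf("beta[%d,2]", j)])
    expect_lt(abs(ours - jags), 0.3)
  }
})
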