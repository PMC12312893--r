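# Shared fixtures, built in code. The landscape is generated once per test
# run and cached; everything below is deterministic under fixed seeds.

.fixture_env <- new.env(parent = emptyenv())

test_landscape <- function() {
  if (is.null(.fixture_env$land)) {
    .fixture_env$land <- generate_landscape(
      landscape_config(extent_m = c(4800, 4800)), seed = 42)
  }
  .fixture_env$land
}

# A small used/available table built directly from a known logistic model:
# covariates iid standard normal (footprint uniform on [0,1]), response
# drawn from the Bernoulli-logit with the supplied coefficients.
make_ua_direct <- function(beta, n_rows = 2000, seed = 1, id = "T01",
                           year = "2019", population = "SIM",
                           indicators = rep(1L, 5)) {
  cn <- c("intercept", "footprint", "elevation", "slope",
          landcover_classes())
  stopifnot(all(names(beta) == cn))
  withr_seed <- function(code) { set.seed(seed); code }
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  df <- data.frame(footprint = runif(n_rows),
                   elevation = rnorm(n_rows), slope = rnorm(n_rows))
  for (cl in landcover_classes()) df[[cl]] <- rnorm(n_rows)
  names(indicators) <- landcover_classes()
  for (cl in landcover_classes())
    df[[paste0("ind_", cl)]] <- indicators[[cl]]
  eta <- beta["intercept"] +
    beta["footprint"] * df$footprint +
    beta["elevation"] * df$elevation + beta["slope"] * df$slope
  for (cl in landcover_classes())
    eta <- eta + indicators[[cl]] * beta[cl] * df[[cl]]
  df$used <- rbinom(n_rows, 1, plogis(eta))
  df$individual_year_id <- paste(id, year, sep = "_")
  df$animal_id <- id
  df$year <- year
  df$population <- population
  df
}

# Regular fix track for one animal: n fixes at interval_h hours starting at
# `start`, positions a slow random walk.
make_track <- function(n, interval_h = 4, start = "2019-04-01 00:00:00",
                       id = "A01", seed = 1, x0 = 2000, y0 = 2000,
                       step_sd = 60) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  t0 <- as.POSIXct(start, tz = "UTC")
  data.frame(animal_id = id,
             timestamp = t0 + (seq_len(n) - 1) * interval_h * 3600,
             x = x0 + cumsum(rnorm(n, 0, step_sd)),
             y = y0 + cumsum(rnorm(n, 0, step_sd)))
}

# Independent numerical MLE of the Bernoulli-logit RSF likelihood
# (general-purpose optimiser over rsf_log_likelihood; no prior).
rsf_mle <- function(rows) {
  cn <- c("intercept", "footprint", "elevation", "slope",
          landcover_classes())
  fn <- function(b) -rsf_log_likelihood(setNames(b, cn), rows)
  opt <- optim(rep(0, 9), fn, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-12))
  setNames(opt$par, cn)
}
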