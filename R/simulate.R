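#' Simulation configuration for synthetic Brent goose datasets
#'
#' Builds and validates the parameter set for [simulate_dataset()]. Defaults
#' emulate the field system: ~213 females caught over 6 springs during
#' Icelandic staging, skull-length allometry around a 89.6 mm reference,
#' a quadratic within-season mass trajectory, a quadratically trending June
#' NAO series, and Poisson offspring counts driven by standardized mass,
#' standardized NAO residuals, their quadratic interaction, and a year-level
#' random intercept on the log scale.
#'
#' Day-of-annual-cycle convention: day 1 = 1 July (the post-breeding moult),
#' so the April–May staging window spans days ~275–335.
#'
#' @param n_years Number of study breeding cycles (>= 2).
#' @param n_birds_per_year Females captured per year; scalar or vector of
#'   length `n_years`. The field sample of 213 birds over 6 years is obtained
#'   with `c(36, 36, 36, 35, 35, 35)`.
#' @param skull_mean_mm,skull_sd_mm Skull-length distribution (mm). The mean
#'   defaults to the 89.6 mm reference length used for mass standardisation.
#' @param allometric_exponent Power-law exponent linking mass to skull
#'   length (the SMA slope used in the scaled mass index), default 3.4.
#' @param baseline_mass_g Structural mass (g) of a bird at the reference
#'   skull length, default 1464.2 g (the sample mean mass of staging females).
#' @param seasonal_coeffs Length-2 numeric `(linear, quadratic)` for the
#'   within-season mass trajectory in grams per day (per day squared),
#'   centred on the middle of the staging window.
#' @param staging_window Integer range of capture days within the cycle.
#' @param mass_noise_sd_g SD (g) of the individual condition component of
#'   mass — the carry-over signal the model standardizes and fits.
#' @param nao_trend_coeffs Length-3 `(intercept, linear, quadratic)` of the
#'   long-term June NAO trend over the year index.
#' @param nao_n_years Length of the simulated NAO series; the study years are
#'   its final `n_years` entries (detrending uses the full series).
#' @param nao_resid_sd SD of yearly NAO deviations from the trend.
#' @param beta Named numeric vector of log-link fixed effects on the
#'   standardized scale, in the order `(intercept, mass, nao, mass2,
#'   mass2_nao, mass_nao)`.
#' @param year_intercept_sd SD of the year random intercept (log scale).
#' @param resight_rate Expected post-capture resighting records per bird.
#' @param prop_with_associate Probability a bird is recorded with an adult
#'   associate (pair bond) in the capture year.
#' @param offspring_cap Optional integer cap on offspring counts (the
#'   biological clutch range is 2–6 eggs); `NA` (default) leaves counts as
#'   plain Poisson draws, matching the fitted model family.
#' @param start_year First calendar year of the study window.
#' @param seed Master seed; all component substreams derive from it.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_years = 6,
                       n_birds_per_year = c(36, 36, 36, 35, 35, 35),
                       skull_mean_mm = 89.6,
                       skull_sd_mm = 2.6,
                       allometric_exponent = 3.4,
                       baseline_mass_g = 1464.2,
                       seasonal_coeffs = c(4, -0.05),
                       staging_window = c(275, 335),
                       mass_noise_sd_g = 95,
                       nao_trend_coeffs = c(0.4, -0.055, 0.0011),
                       nao_n_years = 60,
                       nao_resid_sd = 1,
                       beta = c(intercept = -0.09, mass = 0.11, nao = -0.58,
                                mass2 = -0.14, mass2_nao = -0.27,
                                mass_nao = 0),
                       year_intercept_sd = 0.3,
                       resight_rate = 5,
                       prop_with_associate = 0.9,
                       offspring_cap = NA,
                       start_year = 2004,
                       seed = 1L) {
  cfg <- list(
    n_years = as.integer(n_years),
    n_birds_per_year = as.integer(n_birds_per_year),
    skull_mean_mm = skull_mean_mm, skull_sd_mm = skull_sd_mm,
    allometric_exponent = allometric_exponent,
    baseline_mass_g = baseline_mass_g,
    seasonal_coeffs = seasonal_coeffs,
    staging_window = as.integer(staging_window),
    mass_noise_sd_g = mass_noise_sd_g,
    nao_trend_coeffs = nao_trend_coeffs,
    nao_n_years = as.integer(nao_n_years),
    nao_resid_sd = nao_resid_sd,
    beta = .complete_beta(beta),
    year_intercept_sd = year_intercept_sd,
    resight_rate = resight_rate,
    prop_with_associate = prop_with_associate,
    offspring_cap = offspring_cap,
    start_year = as.integer(start_year),
    seed = as.integer(seed)
  )
  .validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

.beta_names <- c("intercept", "mass", "nao", "mass2", "mass2_nao", "mass_nao")

.complete_beta <- function(beta) {
  if (is.null(names(beta))) {
    if (length(beta) < 5 || length(beta) > 6)
      stop("config error in field 'beta': unnamed beta must have length 5 or 6",
           call. = FALSE)
    beta <- setNames(c(beta, rep(0, 6 - length(beta))), .beta_names)
  } else {
    bad <- setdiff(names(beta), .beta_names)
    if (length(bad))
      stop("config error in field 'beta': unknown term(s) ",
           paste(bad, collapse = ", "), call. = FALSE)
    full <- setNames(numeric(6), .beta_names)
    full[names(beta)] <- beta
    beta <- full
  }
  beta
}

.validate_sim_config <- function(cfg) {
  fail <- function(field, why)
    stop(sprintf("config error in field '%s': %s", field, why), call. = FALSE)
  if (cfg$n_years < 2) fail("n_years", "must be >= 2")
  if (!length(cfg$n_birds_per_year) %in% c(1L, cfg$n_years))
    fail("n_birds_per_year", "must be scalar or length n_years")
  if (any(cfg$n_birds_per_year < 2)) fail("n_birds_per_year", "must be >= 2")
  for (f in c("skull_sd_mm", "mass_noise_sd_g", "nao_resid_sd"))
    if (!is.finite(cfg[[f]]) || cfg[[f]] <= 0) fail(f, "must be > 0")
  if (cfg$allometric_exponent <= 0) fail("allometric_exponent", "must be > 0")
  if (cfg$year_intercept_sd < 0) fail("year_intercept_sd", "must be >= 0")
  if (length(cfg$seasonal_coeffs) != 2) fail("seasonal_coeffs", "needs (linear, quadratic)")
  if (length(cfg$nao_trend_coeffs) != 3)
    fail("nao_trend_coeffs", "needs (intercept, linear, quadratic)")
  if (cfg$nao_n_years < cfg$n_years) fail("nao_n_years", "must cover the study years")
  if (diff(cfg$staging_window) < 0 || cfg$staging_window[1] < 1 ||
      cfg$staging_window[2] > 366)
    fail("staging_window", "must be an increasing range within 1-366")
  if (cfg$resight_rate < 0) fail("resight_rate", "must be >= 0")
  invisible(cfg)
}

# Independent substream seeds derived from the master seed, so changing the
# draw count of one component never perturbs the others.
.substream_seeds <- function(seed, n = 6L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Generate a synthetic dataset of captures, NAO series and truth
#'
#' Draws one capture per bird (the single-measurement design of the field
#' study): skull length is Normal, capture day uniform over the staging
#' window, raw mass is allometric structural mass plus the seasonal
#' trajectory plus a Gaussian condition component, and next-winter offspring
#' counts are Poisson with a log-linear predictor in standardized condition
#' and standardized NAO residuals plus a year random intercept.
#' Deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A `goose_sim` list with elements `birds` (data frame: bird_id,
#'   year, day_of_cycle, mass_g, skull_mm, n_offspring_next_winter,
#'   adult_associate_flag), `nao` (year, june_nao), and `truth` (the config
#'   plus realized year effects, condition z-scores and NAO residuals).
#' @export
simulate_dataset <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  cfg <- config
  seeds <- .substream_seeds(cfg$seed)
  nb <- if (length(cfg$n_birds_per_year) == 1L)
    rep(cfg$n_birds_per_year, cfg$n_years) else cfg$n_birds_per_year
  n <- sum(nb)
  study_years <- seq(cfg$start_year, length.out = cfg$n_years)
  year_of <- rep(study_years, nb)

  set.seed(seeds[1])
  skull <- rnorm(n, cfg$skull_mean_mm, cfg$skull_sd_mm)
  set.seed(seeds[2])
  day <- sample(seq(cfg$staging_window[1], cfg$staging_window[2]), n,
                replace = TRUE)
  set.seed(seeds[3])
  condition <- rnorm(n, 0, cfg$mass_noise_sd_g)

  mid <- mean(cfg$staging_window)
  seasonal <- cfg$seasonal_coeffs[1] * (day - mid) +
    cfg$seasonal_coeffs[2] * (day - mid)^2
  mass <- cfg$baseline_mass_g * (skull / cfg$skull_mean_mm)^cfg$allometric_exponent +
    seasonal + condition

  # NAO series spans nao_n_years ending at the last study year
  nao_years <- seq(cfg$start_year + cfg$n_years - cfg$nao_n_years,
                   length.out = cfg$nao_n_years)
  yr_idx <- seq_along(nao_years)
  set.seed(seeds[4])
  nao_resid <- rnorm(cfg$nao_n_years, 0, cfg$nao_resid_sd)
  june_nao <- cfg$nao_trend_coeffs[1] + cfg$nao_trend_coeffs[2] * yr_idx +
    cfg$nao_trend_coeffs[3] * yr_idx^2 + nao_resid

  # Standardized covariates as the analysis sees them: condition z-scored
  # across birds, NAO residual z-scored at the observation level
  mass_z <- if (sd(condition) > 0) (condition - mean(condition)) / sd(condition)
            else condition
  study_resid <- nao_resid[match(study_years, nao_years)]
  obs_resid <- study_resid[match(year_of, study_years)]
  nao_z <- if (sd(obs_resid) > 0) (obs_resid - mean(obs_resid)) / sd(obs_resid)
           else obs_resid

  set.seed(seeds[5])
  u_year <- rnorm(cfg$n_years, 0, cfg$year_intercept_sd)
  b <- cfg$beta
  lp <- b["intercept"] + b["mass"] * mass_z + b["nao"] * nao_z +
    b["mass2"] * mass_z^2 + b["mass2_nao"] * mass_z^2 * nao_z +
    b["mass_nao"] * mass_z * nao_z + u_year[match(year_of, study_years)]
  offspring <- rpois(n, exp(lp))
  if (!is.na(cfg$offspring_cap))
    offspring <- pmin(offspring, as.integer(cfg$offspring_cap))
  associate <- runif(n) < cfg$prop_with_associate

  birds <- data.frame(
    bird_id = sprintf("B%04d", seq_len(n)),
    year = year_of,
    day_of_cycle = day,
    mass_g = mass,
    skull_mm = skull,
    n_offspring_next_winter = offspring,
    adult_associate_flag = associate,
    stringsAsFactors = FALSE
  )
  out <- list(
    birds = birds,
    nao = data.frame(year = nao_years, june_nao = june_nao),
    truth = c(unclass(cfg), list(
      study_years = study_years, u_year = u_year, mass_z = mass_z,
      nao_resid_true = study_resid, nao_z = nao_z,
      expected_offspring = exp(lp), resight_seed = seeds[6]
    ))
  )
  class(out) <- "goose_sim"
  out
}

#' Generate a resighting table for the breeder-assignment filter
#'
#' For each simulated bird, draws counts of post-capture winter resighting
#' records with and without accompanying juveniles. Birds that returned with
#' offspring are conspicuous family groups: whenever resighting effort is
#' non-zero they carry at least one juvenile record. Unsuccessful birds
#' accumulate only juvenile-free records at the effort rate.
#'
#' @param dataset A `goose_sim` from [simulate_dataset()].
#' @param config The [sim_config()] used (for `resight_rate`).
#' @return Data frame: bird_id, year, n_records_no_juv, n_records_with_juv.
#' @export
simulate_resightings <- function(dataset, config = NULL) {
  stopifnot(inherits(dataset, "goose_sim"))
  rate <- if (is.null(config)) dataset$truth$resight_rate else config$resight_rate
  birds <- dataset$birds
  if (nrow(birds) == 0) stop("dataset is empty", call. = FALSE)
  set.seed(dataset$truth$resight_seed)
  n <- nrow(birds)
  breeder <- birds$n_offspring_next_winter > 0
  with_juv <- integer(n)
  no_juv <- integer(n)
  if (rate > 0) {
    with_juv[breeder] <- 1L + rpois(sum(breeder), 0.7 * rate)
    no_juv[breeder] <- rpois(sum(breeder), 0.3 * rate)
    no_juv[!breeder] <- rpois(sum(!breeder), rate)
  }
  data.frame(bird_id = birds$bird_id, year = birds$year,
             n_records_no_juv = no_juv, n_records_with_juv = with_juv,
             stringsAsFactors = FALSE)
}

#' Write a simulated dataset to CSV files
#'
#' Emits `birds.csv`, `nao.csv` and `resightings.csv` with the documented
#' column schemas into `dir`.
#'
#' @param dataset A `goose_sim`.
#' @param dir Output directory (created if absent).
#' @param config Optional [sim_config()] for the resighting stage.
#' @return Invisibly, the paths written.
#' @export
write_dataset <- function(dataset, dir, config = NULL) {
  stopifnot(inherits(dataset, "goose_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("birds.csv", "nao.csv", "resightings.csv"))
  write.csv(dataset$birds, paths[1], row.names = FALSE)
  write.csv(dataset$nao, paths[2], row.names = FALSE)
  write.csv(simulate_resightings(dataset, config), paths[3], row.names = FALSE)
  invisible(paths)
}

#' Simulate data under the bivariate latent-variable model
#'
#' Testbed for [mcmc_bivariate()]: draws correlated observation-level
#' residuals `(e_mass, e_juv)` from a 2x2 covariance with the given latent
#' correlation, builds raw mass from a day polynomial and skull length plus
#' `e_mass`, and offspring counts as Poisson with `exp(b0 + b1 * nao +
#' e_juv)` (log-normal Poisson). Parameter recovery on this generator
#' checks the carry-over statistic directly.
#'
#' @param n Number of birds.
#' @param latent_cor True residual correlation between mass and offspring.
#' @param v_mass,v_juv Residual variances (g^2 and log-scale).
#' @param mass_coefs Coefficients `(intercept, day_linear_g_per_day,
#'   day_quad, skull_g_per_mm)` on raw day/skull scales.
#' @param juv_coefs Coefficients `(intercept, nao)` on the log scale.
#' @param n_years Years over which birds and NAO values spread.
#' @param seed Integer seed.
#' @return Data frame with `mass_g`, `skull_mm`, `day_of_cycle`,
#'   `n_offspring`, `nao_z`, `year`, plus attribute `truth`.
#' @export
simulate_bivariate <- function(n, latent_cor = 0.5, v_mass = 9038,
                               v_juv = 0.84,
                               mass_coefs = c(-130, 4, -0.05, 22),
                               juv_coefs = c(-0.6, -0.9),
                               n_years = 6, seed = 1L) {
  stopifnot(abs(latent_cor) < 1, v_mass > 0, v_juv > 0)
  set.seed(as.integer(seed))
  day <- sample(275:335, n, replace = TRUE)
  skull <- rnorm(n, 89.6, 2.6)
  year <- sample(seq_len(n_years), n, replace = TRUE) + 2003L
  nao_year <- rnorm(n_years)
  nao <- (nao_year - mean(nao_year)) / sd(nao_year)
  nao <- nao[year - 2003L]
  C <- latent_cor * sqrt(v_mass * v_juv)
  Sigma <- matrix(c(v_mass, C, C, v_juv), 2)
  L <- chol(Sigma)
  E <- matrix(rnorm(2 * n), n, 2) %*% L
  mid <- 305
  mass <- mass_coefs[1] + mass_coefs[2] * (day - mid) +
    mass_coefs[3] * (day - mid)^2 + mass_coefs[4] * skull + E[, 1]
  y <- rpois(n, exp(pmin(juv_coefs[1] + juv_coefs[2] * nao + E[, 2], 30)))
  out <- data.frame(mass_g = mass, skull_mm = skull, day_of_cycle = day,
                    n_offspring = y, nao_z = nao, year = year)
  attr(out, "truth") <- list(latent_cor = latent_cor, Sigma = Sigma,
                             mass_coefs = mass_coefs, juv_coefs = juv_coefs)
  out
}

#' @export
print.goose_sim <- function(x, ...) {
  cat(sprintf("Synthetic Brent goose dataset: %d females over %d years (%s-%s)\n",
              nrow(x$birds), x$truth$n_years, min(x$birds$year),
              max(x$birds$year)))
  cat(sprintf("  NAO series: %d years; offspring range %d-%d\n",
              nrow(x$nao), min(x$birds$n_offspring_next_winter),
              max(x$birds$n_offspring_next_winter)))
  invisible(x)
}
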