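test_that("SMA slope is the OLS slope / correlation quotient", {
  # field-study inputs: printed OLS slope 1.003, correlation 0.29
  expect_equal(sma_slope(1.003, 0.29), 3.45862068966, tolerance = 1e-10)
  expect_equal(sma_slope(2.0, 0.5), 4.0)
  for (b in c(-2, 0.5, 3.4)) expect_equal(sma_slope(b, 1.0), b)
  expect_error(sma_slope(1.003, 0), "degenerate")
})

test_that("scaled mass index has the closed power-law form", {
  expect_equal(scaled_mass_index(1500, 89.6, 89.6, 3.4), 1500)
  for (L in c(10, 50, 200))
    expect_equal(scaled_mass_index(1000, 2 * L, L, 1.0), 500)
  expect_equal(scaled_mass_index(1464.2, 95.0, 89.6, 3.4), 1200.01694164,
               tolerance = 1e-9)
  expect_error(scaled_mass_index(-1, 90), "positive")
})

test_that("SMI is monotone in mass and exceeds raw mass below reference size", {
  masses <- seq(1200, 1700, by = 100)
  smi <- scaled_mass_index(masses, 85, 89.6, 3.4)
  expect_true(all(diff(smi) > 0))
  expect_true(all(smi > masses))  # L < L0, b > 0
})

test_that("allometry fit recovers a noiseless power law exactly", {
  skull <- seq(80, 100, length.out = 50)
  rec <- data.frame(mass_g = 2e-3 * skull^3.4, skull_mm = skull)
  fit <- fit_allometry(rec)
  expect_equal(fit$ols_slope, 3.4, tolerance = 1e-10)
  expect_equal(fit$pearson_r, 1, tolerance = 1e-10)
  expect_equal(fit$sma_slope, 3.4, tolerance = 1e-9)
})

test_that("SMA estimator recovers the exponent under symmetric errors", {
  # errors-in-variables data with error-variance ratio b^2 — the regime the
  # standardised major axis is designed for
  set.seed(42)
  n <- 1e4
  b <- 3.4
  s <- rnorm(n, 0, 0.03)
  log_skull <- log(89.6) + s + rnorm(n, 0, 0.01)
  log_mass <- log(1464.2) + b * s + rnorm(n, 0, b * 0.01)
  fit <- fit_allometry(data.frame(mass_g = exp(log_mass),
                                  skull_mm = exp(log_skull)))
  expect_lt(abs(fit$sma_slope - b), 0.05)
  expect_error(fit_allometry(data.frame(mass_g = c(1, 2, 3),
                                        skull_mm = rep(90, 3))),
               "zero variance")
})

test_that("seasonal correction returns residual + mean and is idempotent", {
  set.seed(1)
  days <- sample(275:335, 200, replace = TRUE)
  smi <- 1400 + 3 * (days - 305) - 0.04 * (days - 305)^2 + rnorm(200, 0, 50)
  out <- seasonal_correct(smi, days)
  expect_equal(mean(out$corrected), mean(smi), tolerance = 1e-9)
  again <- seasonal_correct(out$corrected, days)
  expect_equal(again$corrected, out$corrected, tolerance = 1e-8)

  # constant input: zero residuals (perfect-fit summary warnings expected)
  cst <- suppressWarnings(seasonal_correct(rep(7, 10), c(275:284)))
  expect_equal(cst$corrected, rep(7, 10))
  # exactly quadratic input: all corrected values equal the sample mean
  quad <- 2 + 0.5 * days - 0.001 * days^2
  qc <- suppressWarnings(seasonal_correct(quad, days))
  expect_equal(qc$corrected, rep(mean(quad), length(quad)), tolerance = 1e-8)
  expect_error(seasonal_correct(smi[1:5], rep(300, 5)), "collinear")
})

test_that("seasonal polynomial coefficients are recovered from the generator", {
  cfg <- sim_config(n_years = 40, n_birds_per_year = 250, seed = 12)
  ds <- simulate_dataset(cfg)
  # fixed true exponent isolates the seasonal signal
  smi <- scaled_mass_index(ds$birds$mass_g, ds$birds$skull_mm, 89.6, 3.4)
  out <- seasonal_correct(smi, ds$birds$day_of_cycle)
  # true raw-basis quadratic coefficient: c2; linear at centred 0: c1 - 2*c2*mid
  mid <- mean(c(275, 335))
  true_c2 <- cfg$seasonal_coeffs[2]
  true_c1 <- cfg$seasonal_coeffs[1] - 2 * cfg$seasonal_coeffs[2] * mid
  expect_lt(abs(out$fit$poly_coeffs[3] - true_c2), 3 * out$fit$coef_se[3])
  expect_lt(abs(out$fit$poly_coeffs[2] - true_c1), 3 * out$fit$coef_se[2])
})

test_that("NAO detrending is an orthogonal quadratic projection", {
  years <- 1950:2009
  quad <- 0.5 - 0.03 * (years - 1950) + 5e-4 * (years - 1950)^2
  nao <- data.frame(year = years, june_nao = quad)
  out <- suppressWarnings(detrend_nao(nao))  # perfect fit
  expect_equal(out$resid, rep(0, 60), tolerance = 1e-9)

  # outlier response equals the explicit hat-matrix projection
  d <- 2.5
  k <- 17
  y2 <- quad
  y2[k] <- y2[k] + d
  out2 <- detrend_nao(data.frame(year = years, june_nao = y2))
  yc <- years - mean(years)   # centred basis, same column space
  X <- cbind(1, yc, yc^2)
  H <- X %*% solve(crossprod(X)) %*% t(X)
  expected <- d * (diag(60) - H)[, k]
  expect_equal(out2$resid, expected, tolerance = 1e-6)

  # orthogonality to the design, residual sum zero
  set.seed(2)
  nao3 <- data.frame(year = years, june_nao = quad + rnorm(60))
  r <- detrend_nao(nao3)$resid
  expect_lt(abs(sum(r)), 1e-8)
  expect_lt(abs(sum(r * years)), 1e-5)
  # invariance to recentring the year covariate
  r2 <- detrend_nao(data.frame(year = years - 1980,
                               june_nao = nao3$june_nao))$resid
  expect_equal(r, r2, tolerance = 1e-8)
  expect_error(detrend_nao(data.frame(year = 1:3, june_nao = 1:3)),
               "4 distinct years")
})

test_that("detrending recovers the residual spread of the generator", {
  cfg <- sim_config(nao_n_years = 60, nao_resid_sd = 1, seed = 13)
  ds <- simulate_dataset(cfg)
  r <- detrend_nao(ds$nao)$resid
  se_sd <- 1 / sqrt(2 * (60 - 3))
  expect_lt(abs(sd(r) - 1), 3 * se_sd)
})

test_that("breeder assignment follows the 3-record + associate rule", {
  expect_equal(assign_breeder_status(2, 0, TRUE), "excluded")
  expect_equal(assign_breeder_status(3, 0, FALSE), "excluded")
  expect_equal(assign_breeder_status(5, 0, TRUE), "non_breeder")
  expect_equal(assign_breeder_status(3, 0, TRUE), "non_breeder")
  expect_equal(assign_breeder_status(0, 1, FALSE), "breeder")
  # any juvenile sighting precludes non-breeder status
  grid <- expand.grid(no = 0:5, with = 1:3, assoc = c(TRUE, FALSE))
  expect_true(all(assign_breeder_status(grid$no, grid$with, grid$assoc)
                  == "breeder"))
})

test_that("z-transform standardises, is shift-invariant and invertible", {
  zt <- z_transform(c(1, 2, 3))
  expect_equal(zt$z, c(-1, 0, 1))
  x <- rnorm(50, 100, 7)
  a <- z_transform(x)
  b <- z_transform(x + 42)
  expect_equal(a$z, b$z, tolerance = 1e-10)
  expect_equal(z_inverse(a$z, a), x, tolerance = 1e-12)
  expect_lt(abs(mean(a$z)), 1e-12)
  expect_equal(sd(a$z), 1, tolerance = 1e-12)
  expect_error(z_transform(rep(3, 5)), "zero variance")
})

test_that("preprocess builds a standardized analysis table", {
  cfg <- sim_config(seed = 14)
  ds <- simulate_dataset(cfg)
  rs <- simulate_resightings(ds, cfg)
  prep <- preprocess(ds$birds, ds$nao, rs)
  d <- prep$data
  expect_true(all(c("smi_g", "corrected_mass_g", "mass_z", "nao_resid",
                    "nao_z", "status", "n_offspring") %in% names(d)))
  expect_lt(abs(mean(d$mass_z)), 1e-10)
  expect_equal(sd(d$mass_z), 1, tolerance = 1e-10)
  expect_equal(sd(d$nao_z), 1, tolerance = 1e-10)
  expect_true(all(d$status != "excluded"))
  expect_true(all(d$n_offspring[d$status == "non_breeder"] == 0))
  expect_true(all(d$n_offspring[d$status == "breeder"] >= 1))
  # rows with missing morphometrics are dropped and logged
  birds2 <- ds$birds
  birds2$mass_g[1:3] <- NA
  prep2 <- preprocess(birds2, ds$nao)
  expect_equal(prep2$log$n_dropped_morphometrics, 3)
})
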