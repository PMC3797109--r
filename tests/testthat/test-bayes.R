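test_that("chain bookkeeping stores (n_iter - burn_in)/thin samples", {
  expect_identical(n_stored(mcmc_control(250000, 50000, 50)), 4000L)
  expect_identical(n_stored(mcmc_control(1000, 200, 8)), 100L)
  ds <- simulate_dataset(sim_config(n_years = 3, n_birds_per_year = 10,
                                    nao_n_years = 10, seed = 30))
  prep <- preprocess(ds$birds, ds$nao)
  ch <- mcmc_top_model(prep$data, model_spec("NAO", "nao"),
                       mcmc_control(600, 100, 5), seed = 1)
  expect_identical(nrow(ch$samples), 100L)
})

test_that("chains are reproducible given seed and control", {
  ds <- simulate_dataset(sim_config(n_years = 3, n_birds_per_year = 10,
                                    nao_n_years = 10, seed = 31))
  prep <- preprocess(ds$birds, ds$nao)
  ctl <- mcmc_control(500, 100, 4)
  a <- mcmc_top_model(prep$data, model_spec("NAO", "nao"), ctl, seed = 11)
  b <- mcmc_top_model(prep$data, model_spec("NAO", "nao"), ctl, seed = 11)
  expect_identical(a$samples, b$samples)
  c <- mcmc_top_model(prep$data, model_spec("NAO", "nao"), ctl, seed = 12)
  expect_false(identical(a$samples, c$samples))
})

test_that("degenerate design columns raise an explicit rank error", {
  ds <- simulate_dataset(sim_config(n_years = 3, n_birds_per_year = 10,
                                    nao_n_years = 10, seed = 32))
  prep <- preprocess(ds$birds, ds$nao)
  d <- prep$data
  d$nao_z <- d$mass_z
  expect_error(mcmc_top_model(d, model_spec("Mass + NAO", c("mass", "nao")),
                              mcmc_control(300, 100, 2), seed = 1),
               "rank")
})

test_that("posterior means agree with the Laplace MLE on the same data", {
  ds <- simulate_dataset(sim_config(seed = 33))
  prep <- preprocess(ds$birds, ds$nao)
  sp <- top_model_spec()
  lap <- fit_poisson_glmm(prep$data, sp)
  ch <- mcmc_top_model(prep$data, sp, mcmc_control(8000, 2000, 5), seed = 2)
  post_mean <- colMeans(ch$samples)
  post_sd <- apply(ch$samples, 2, sd)
  for (p in names(lap$beta))
    expect_lt(abs(post_mean[p] - lap$beta[p]), 2 * post_sd[p])
})

test_that("prediction grid orders bounds and handles degenerate chains", {
  sp <- top_model_spec()
  zero_chain <- structure(
    list(samples = matrix(0, 50, 6,
                          dimnames = list(NULL, c("intercept", "mass", "nao",
                                                  "mass2", "mass2_nao",
                                                  "sigma_u"))),
         spec = sp, control = mcmc_control(500, 0, 10), model = "top"),
    class = "posterior_chain")
  g <- predict_grid(zero_chain, mass_z = c(-1, 0, 1),
                    nao_values = c(good = -1, poor = 1))
  expect_true(all(g$mean == 1 & g$lo95 == 1 & g$hi95 == 1))

  one_chain <- zero_chain
  one_chain$samples <- matrix(rep(c(field_beta, 0.3), each = 1), 1, 6,
                              dimnames = dimnames(zero_chain$samples))
  g1 <- predict_grid(one_chain, mass_z = 0, nao_values = c(mean = 0))
  expect_equal(g1$mean, exp(-0.09), tolerance = 1e-12)
  # interaction structure: good years reward high mass
  g2 <- predict_grid(one_chain, mass_z = 1, nao_values = c(good = -1, poor = 1))
  expect_gt(g2$mean[g2$scenario == "good"], g2$mean[g2$scenario == "poor"])
})

test_that("prediction intervals bracket the mean on a real chain", {
  ds <- simulate_dataset(sim_config(seed = 34))
  prep <- preprocess(ds$birds, ds$nao)
  ch <- mcmc_top_model(prep$data, top_model_spec(),
                       mcmc_control(3000, 1000, 4), seed = 3)
  g <- predict_grid(ch, nao_values = nao_scenarios(prep))
  expect_true(all(g$lo95 <= g$mean + 1e-12 & g$mean <= g$hi95 + 1e-12))
  expect_true(all(g$lo95 >= 0))
})

test_that("scenario values are signed means of the detrended residuals", {
  ds <- simulate_dataset(sim_config(seed = 35))
  prep <- preprocess(ds$birds, ds$nao)
  sc <- nao_scenarios(prep)
  expect_lt(sc["good"], 0)
  expect_gt(sc["poor"], 0)
  z <- unique(prep$data[c("year", "nao_z")])$nao_z
  expect_equal(unname(sc["good"]), mean(z[z < 0]))
  expect_equal(unname(sc["poor"]), mean(z[z > 0]))
})

test_that("posterior correlation is exact on constant chains", {
  ch <- constant_sigma_chain(4, 1, 1)
  pc <- posterior_correlation(ch)
  expect_equal(pc$mode, 0.5)
  expect_equal(pc$lower95, 0.5)
  expect_equal(pc$upper95, 0.5)
  ch0 <- constant_sigma_chain(4, 0, 1)
  expect_equal(posterior_correlation(ch0)$mode, 0)
  bad <- constant_sigma_chain(1, 2, 1)
  expect_error(posterior_correlation(bad), "positive definite")
})

test_that("posterior correlation is invariant to rescaling mass", {
  d <- simulate_bivariate(400, latent_cor = 0.4, seed = 36)
  ctl <- mcmc_control(4000, 1000, 5)
  r1 <- posterior_correlation(mcmc_bivariate(d, ctl, seed = 4))
  d_kg <- d
  d_kg$mass_g <- d$mass_g / 1000
  r2 <- posterior_correlation(mcmc_bivariate(d_kg, ctl, seed = 4))
  expect_equal(r1$samples, r2$samples, tolerance = 1e-6)
})

test_that("null latent correlation yields an interval containing zero", {
  d <- simulate_bivariate(600, latent_cor = 0, seed = 37)
  pc <- posterior_correlation(mcmc_bivariate(d, mcmc_control(6000, 2000, 4),
                                             seed = 5))
  expect_lt(pc$lower95, 0)
  expect_gt(pc$upper95, 0)
})

test_that("bivariate mass equation recovers the skull slope", {
  d <- simulate_bivariate(800, latent_cor = 0.3, seed = 38)
  ch <- mcmc_bivariate(d, mcmc_control(6000, 2000, 4), seed = 6)
  sk <- ch$samples[, "mass_skull"]
  expect_lt(abs(mean(sk) - 22), 3 * sd(sk))
})
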