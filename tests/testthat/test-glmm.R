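test_that("candidate set has the eight models with the right complexity", {
  cand <- candidate_models()
  expect_length(cand, 8)
  expect_equal(vapply(cand, `[[`, 0L, "k"), c(3L, 3L, 4L, 5L, 4L, 5L, 6L, 2L))
  byname <- setNames(cand, vapply(cand, `[[`, "", "name"))
  expect_setequal(byname[["Mass^2 * NAO"]]$terms,
                  c("mass", "nao", "mass2", "mass2_nao"))
  expect_equal(byname[["Null"]]$terms, character())
  expect_setequal(byname[["Mass * NAO"]]$terms, c("mass", "nao", "mass_nao"))
})

test_that("marginality of interaction terms is enforced", {
  expect_error(model_spec("bad", c("mass_nao")), "marginality")
  expect_error(model_spec("bad", c("mass", "nao", "mass2_nao")), "marginality")
  expect_silent(model_spec("ok", c("mass", "nao", "mass2", "mass2_nao")))
})

test_that("likelihood evaluator reproduces the closed-form Poisson case", {
  # counts 1,2,3 at lambda = 2: ll = 6 ln 2 - 6 - ln 12
  X <- matrix(1, 3, 1)
  ll <- glmm_loglik_laplace(log(2), 0, X, c(1, 2, 3), rep(1, 3))
  expect_equal(as.numeric(ll), 6 * log(2) - 6 - log(12), tolerance = 1e-12)
})

test_that("boundary data give a sigma = 0 fit at the sample-mean rate", {
  d <- data.frame(n_offspring = rep(c(1, 2, 3), 2), mass_z = 0, nao_z = 0,
                  year = rep(1:2, each = 3))
  f <- fit_poisson_glmm(d, model_spec("Null"))
  expect_true(f$converged)
  expect_equal(f$sigma_u, 0)
  expect_equal(unname(exp(f$beta)), 2, tolerance = 1e-8)
  expect_equal(f$loglik, 2 * (6 * log(2) - 6 - log(12)), tolerance = 1e-8)
})

test_that("at sigma = 0 the Laplace likelihood equals an independent GLM", {
  for (s in 1:3) {
    d <- tiny_glmm_data(s)
    sp <- model_spec("Mass", "mass")
    X <- design_matrix(sp, d$mass_z, d$nao_z)
    g <- glm(n_offspring ~ mass_z, data = d, family = poisson)
    ll <- glmm_loglik_laplace(coef(g), 0, X, d$n_offspring, d$year)
    expect_equal(as.numeric(ll), as.numeric(logLik(g)), tolerance = 1e-8)
  }
})

test_that("Laplace likelihood tracks 64-node adaptive quadrature", {
  # documented tolerance on small fixtures: 0.05 loglik units
  for (s in 1:5) {
    d <- tiny_glmm_data(s)
    f <- fit_poisson_glmm(d, model_spec("Mass", "mass"))
    X <- design_matrix(f$spec, d$mass_z, d$nao_z)
    agq <- glmm_loglik_agq(f$beta, f$sigma_u, X, d$n_offspring, d$year, 64)
    expect_lt(abs(f$loglik - agq), 0.05)
  }
})

test_that("the engine matches lme4 on a field-scale dataset", {
  ds <- simulate_dataset(sim_config(seed = 7))
  prep <- preprocess(ds$birds, ds$nao)
  f <- fit_poisson_glmm(prep$data, top_model_spec())
  m <- lme4::glmer(
    n_offspring ~ mass_z + nao_z + I(mass_z^2) + I(mass_z^2 * nao_z) +
      (1 | year),
    data = prep$data, family = poisson)
  expect_equal(f$loglik, as.numeric(logLik(m)), tolerance = 1e-4)
  expect_equal(unname(f$beta), unname(lme4::fixef(m)), tolerance = 1e-3)
  expect_equal(f$sigma_u,
               unname(attr(lme4::VarCorr(m)$year, "stddev")),
               tolerance = 1e-3)
})

test_that("optimum beats the zero vector and refits are stable", {
  d <- tiny_glmm_data(4, n_groups = 5, per_group = 8)
  sp <- model_spec("Mass", "mass")
  f <- fit_poisson_glmm(d, sp)
  X <- design_matrix(sp, d$mass_z, d$nao_z)
  ll0 <- glmm_loglik_laplace(rep(0, 2), 0.3, X, d$n_offspring, d$year)
  expect_gte(f$loglik, as.numeric(ll0))
  # perturbed restart reproduces the optimum
  f2 <- fit_poisson_glmm(d, sp, glmm_control(sigma_start = 1.5))
  expect_equal(f$loglik, f2$loglik, tolerance = 1e-6)
  expect_lte(f$grad_norm, 1e-6)
})

test_that("adding a term never decreases the maximized loglik", {
  ds <- simulate_dataset(sim_config(seed = 15))
  prep <- preprocess(ds$birds, ds$nao)
  fits <- fit_candidate_set(prep)
  ll <- vapply(fits, `[[`, 0, "loglik")
  chains <- list(c("Null", "Mass", "Mass + NAO", "Mass * NAO"),
                 c("Null", "NAO", "Mass + NAO"),
                 c("Null", "Mass", "Mass^2", "Mass^2 + NAO"))
  for (ch in chains) expect_true(all(diff(ll[ch]) >= -1e-6))
})

test_that("rank-deficient designs are rejected, not silently fitted", {
  d <- tiny_glmm_data(5)
  d$nao_z <- d$mass_z  # perfectly collinear
  expect_error(fit_poisson_glmm(d, model_spec("Mass + NAO", c("mass", "nao"))),
               "rank-deficient")
})

test_that("population-level predictions are exp of the linear predictor", {
  d <- tiny_glmm_data(6, n_groups = 4, per_group = 10)
  f <- fit_poisson_glmm(d, model_spec("Null"))
  f0 <- f
  f0$beta[] <- 0
  expect_equal(predict_response(f0, 1.3, -0.7), 1)
  # reference top-model coefficients
  ft <- f
  ft$spec <- top_model_spec()
  ft$beta <- field_beta
  expect_equal(predict_response(ft, 0, 0), exp(-0.09), tolerance = 1e-12)
  expect_equal(predict_response(ft, 1, -1), exp(0.73), tolerance = 1e-12)
  # favourable weather at high mass beats poor weather
  expect_gt(predict_response(ft, 1, -1), predict_response(ft, 1, 1))
})
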