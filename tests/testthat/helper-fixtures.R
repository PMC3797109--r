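# Shared fixtures built in code at test time.

# the interaction model best supported in the field study
top_model_spec <- function() {
  model_spec("Mass^2 * NAO", c("mass", "nao", "mass2", "mass2_nao"))
}

field_beta <- c(intercept = -0.09, mass = 0.11, nao = -0.58,
                mass2 = -0.14, mass2_nao = -0.27)

# analysis table using the generator's own standardized covariates (the
# scale on which the generative coefficients are defined)
truth_table <- function(ds) {
  data.frame(n_offspring = ds$birds$n_offspring_next_winter,
             mass_z = ds$truth$mass_z, nao_z = ds$truth$nao_z,
             year = ds$birds$year)
}

# small multi-group Poisson fixture for engine tests
tiny_glmm_data <- function(seed, n_groups = 3, per_group = 4, sigma_u = 0.6) {
  set.seed(seed)
  g <- rep(seq_len(n_groups), each = per_group)
  n <- n_groups * per_group
  u <- rnorm(n_groups, 0, sigma_u)
  d <- data.frame(mass_z = rnorm(n), nao_z = rnorm(n), year = g)
  d$n_offspring <- rpois(n, exp(0.3 + 0.2 * d$mass_z + u[g]))
  d
}

# constant-covariance chain for the correlation statistic
constant_sigma_chain <- function(v_mass, c_, v_juv, n = 200) {
  s <- cbind(V_mass = rep(v_mass, n), C = rep(c_, n), V_juv = rep(v_juv, n))
  structure(list(samples = s, control = mcmc_control(1000, 0, 5),
                 model = "bivariate"), class = "posterior_chain")
}
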