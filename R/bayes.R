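#' MCMC control settings
#'
#' Defaults follow the field analysis protocol: 250000 iterations, 50000
#' burn-in, thinning interval 50, storing exactly 4000 samples.
#'
#' @param n_iter Total iterations.
#' @param burn_in Burn-in iterations discarded (adaptation of proposal
#'   scales happens only here, so detailed balance holds afterwards).
#' @param thin Thinning interval.
#' @return An `mcmc_control` list.
#' @export
mcmc_control <- function(n_iter = 250000, burn_in = 50000, thin = 50) {
  stopifnot(n_iter > burn_in, burn_in >= 0, thin >= 1)
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin)), class = "mcmc_control")
}

#' Number of samples a control setting stores
#' @param control An [mcmc_control()].
#' @return Integer stored-sample count, `floor((n_iter - burn_in)/thin)`.
#' @export
n_stored <- function(control) {
  as.integer((control$n_iter - control$burn_in) %/% control$thin)
}

# Effective sample size via Geyer's initial positive sequence on paired
# autocorrelations.
.ess <- function(x) {
  n <- length(x)
  if (n < 10 || var(x) == 0) return(n)
  rho <- as.numeric(stats::acf(x, lag.max = min(n - 1, 2000),
                               plot = FALSE)$acf)
  tau <- 0
  m <- 1
  while (m + 1 <= length(rho)) {
    pair <- rho[m] + rho[m + 1]
    if (pair < 0) break
    tau <- tau + pair
    m <- m + 2
  }
  max(1, min(n, n / max(2 * tau - 1, 1)))
}

.adapt <- function(scale, acc_count, window, target) {
  rate <- acc_count / window
  min(max(scale * exp(0.5 * (rate - target)), 1e-3), 10)
}

#' Bayesian refit of a candidate Poisson GLMM by MCMC
#'
#' Metropolis-within-Gibbs sampler for the same model family as
#' [fit_poisson_glmm()]: a block random-walk update of the fixed effects
#' (proposal shaped by the Laplace vcov), vectorised independent
#' random-walk updates of the year intercepts, and a log-scale random-walk
#' update of the intercept SD. Priors: Normal(0, 1e8) on fixed effects,
#' half-Cauchy(scale 5) on the intercept SD. Proposal scales adapt during
#' burn-in only.
#'
#' @param data Analysis table (columns `n_offspring`, `mass_z`, `nao_z`,
#'   `year`).
#' @param spec A [model_spec()]; typically the retained top model.
#' @param control An [mcmc_control()].
#' @param seed Integer seed (chains are reproducible given it).
#' @param prior_sd_beta,prior_scale_sigma Prior hyperparameters.
#' @return A `posterior_chain` list: `samples` (matrix, columns = fixed
#'   effects and `sigma_u`), `spec`, `control`, `accept` rates, `ess` per
#'   parameter, `model = "top"`.
#' @export
mcmc_top_model <- function(data, spec, control = mcmc_control(), seed = 1L,
                           prior_sd_beta = 1e4, prior_scale_sigma = 5) {
  set.seed(as.integer(seed))
  y <- data$n_offspring
  X <- design_matrix(spec, data$mass_z, data$nao_z)
  if (qr(X)$rank < ncol(X))
    stop("rank-deficient design matrix: remove degenerate column(s)",
         call. = FALSE)
  g <- as.integer(factor(data$year))
  J <- max(g)
  p <- ncol(X)

  lap <- fit_poisson_glmm(data, spec)
  beta <- lap$beta
  V <- lap$vcov
  if (!all(is.finite(V))) V <- diag(p) * 0.01
  prop_chol <- tryCatch(chol((2.4^2 / p) * (V + diag(1e-8, p))),
                        error = function(e) diag(0.05, p))
  # start at the Laplace solution: conditional modes keep the sampler out
  # of the sigma -> 0 funnel while u is still unadapted
  u <- if (length(lap$modes) == J) lap$modes else numeric(J)
  sigma <- max(lap$sigma_u, 0.1)

  loglik_obs <- function(beta, u) {
    eta <- pmin(as.numeric(X %*% beta) + u[g], 30)
    sum(y * eta - exp(eta))
  }
  grp_ll <- function(beta, u) {
    eta <- pmin(as.numeric(X %*% beta) + u[g], 30)
    as.numeric(rowsum(y * eta - exp(eta), g))
  }
  log_prior_sigma <- function(s) dcauchy_half(s, prior_scale_sigma)

  scale_u <- 0.5
  scale_s <- 0.5
  scale_b <- 1
  acc <- c(beta = 0, u = 0, sigma = 0)
  win <- c(beta = 0, u = 0, sigma = 0)
  n_keep <- n_stored(control)
  samples <- matrix(NA_real_, n_keep, p + 1,
                    dimnames = list(NULL, c(colnames(X), "sigma_u")))
  kept <- 0L
  ll_cur <- loglik_obs(beta, u)

  for (iter in seq_len(control$n_iter)) {
    # fixed-effect block
    prop <- beta + scale_b * as.numeric(rnorm(p) %*% prop_chol)
    ll_prop <- loglik_obs(prop, u)
    lr <- ll_prop - ll_cur +
      sum(dnorm(prop, 0, prior_sd_beta, log = TRUE)) -
      sum(dnorm(beta, 0, prior_sd_beta, log = TRUE))
    if (is.finite(lr) && log(runif(1)) < lr) {
      beta <- prop; ll_cur <- ll_prop
      acc["beta"] <- acc["beta"] + 1; win["beta"] <- win["beta"] + 1
    }
    # year intercepts, independent across groups
    gl <- grp_ll(beta, u)
    u_prop <- u + rnorm(J, 0, scale_u)
    eta_p <- pmin(as.numeric(X %*% beta) + u_prop[g], 30)
    gl_p <- as.numeric(rowsum(y * eta_p - exp(eta_p), g))
    lr_u <- gl_p - gl + (u^2 - u_prop^2) / (2 * sigma^2)
    lr_u[!is.finite(lr_u)] <- -Inf
    take <- log(runif(J)) < lr_u
    u[take] <- u_prop[take]
    acc["u"] <- acc["u"] + mean(take); win["u"] <- win["u"] + mean(take)
    ll_cur <- loglik_obs(beta, u)
    # intercept SD on the log scale (Jacobian term included)
    ls_prop <- log(sigma) + rnorm(1, 0, scale_s)
    s_prop <- exp(ls_prop)
    lr_s <- sum(dnorm(u, 0, s_prop, log = TRUE)) -
      sum(dnorm(u, 0, sigma, log = TRUE)) +
      log_prior_sigma(s_prop) - log_prior_sigma(sigma) +
      ls_prop - log(sigma)
    # support truncated to sigma > 1e-8 (numerically degenerate below)
    if (is.finite(s_prop) && s_prop > 1e-8 && is.finite(lr_s) &&
        log(runif(1)) < lr_s) {
      sigma <- s_prop
      acc["sigma"] <- acc["sigma"] + 1; win["sigma"] <- win["sigma"] + 1
    }
    # burn-in-only adaptation
    if (iter <= control$burn_in && iter %% 50 == 0) {
      scale_b <- .adapt(scale_b, win["beta"], 50, 0.234)
      scale_u <- .adapt(scale_u, win["u"], 50, 0.44)
      scale_s <- .adapt(scale_s, win["sigma"], 50, 0.44)
      win[] <- 0
    }
    if (iter > control$burn_in &&
        (iter - control$burn_in) %% control$thin == 0) {
      kept <- kept + 1L
      samples[kept, ] <- c(beta, sigma)
    }
  }
  if (!all(is.finite(samples))) stop("divergent chain: non-finite samples",
                                     call. = FALSE)
  structure(list(samples = samples, spec = spec, control = control,
                 model = "top", seed = as.integer(seed),
                 accept = acc / control$n_iter,
                 ess = apply(samples, 2, .ess)),
            class = "posterior_chain")
}

dcauchy_half <- function(x, scale) {
  ifelse(x <= 0, -Inf, log(2) + stats::dcauchy(x, 0, scale, log = TRUE))
}

#' Good/poor June NAO scenarios from the detrended residuals
#'
#' Scenario values on the standardized scale, per the prediction protocol:
#' "good" breeding conditions are the mean of study years with negative NAO
#' residuals, "poor" the mean of years with positive residuals.
#'
#' @param prep A `preprocessed` object (or a data frame with `year` and
#'   `nao_z` columns).
#' @return Named numeric `c(good = ..., poor = ...)`.
#' @export
nao_scenarios <- function(prep) {
  d <- if (inherits(prep, "preprocessed")) prep$data else prep
  yr <- !duplicated(d$year)
  z <- d$nao_z[yr]
  c(good = mean(z[z < 0]), poor = mean(z[z > 0]))
}

#' Posterior prediction grid for offspring counts
#'
#' For each grid cell (standardized mass value x NAO scenario) computes the
#' posterior of the population-level expected count `exp(X beta)` over the
#' stored samples and summarises it by the mean and equal-tailed 95%
#' interval.
#'
#' @param chain A `posterior_chain` from [mcmc_top_model()].
#' @param mass_z Grid of standardized mass values (default +/- 1.5 SD).
#' @param nao_values Named vector of scenario NAO values (e.g. from
#'   [nao_scenarios()]).
#' @return Data frame: `mass_z`, `scenario`, `nao_z`, `mean`, `lo95`,
#'   `hi95`, with `lo95 <= mean <= hi95` in every row.
#' @export
predict_grid <- function(chain, mass_z = seq(-1.5, 1.5, by = 0.25),
                         nao_values = c(good = -1, poor = 1)) {
  stopifnot(inherits(chain, "posterior_chain"), nrow(chain$samples) >= 1)
  B <- chain$samples[, colnames(design_matrix(chain$spec, 0, 0)), drop = FALSE]
  out <- list()
  for (s in names(nao_values)) {
    X <- design_matrix(chain$spec, mass_z, rep(nao_values[[s]], length(mass_z)))
    lam <- exp(B %*% t(X))                     # samples x cells
    qs <- apply(lam, 2, quantile, c(0.025, 0.975), names = FALSE)
    out[[s]] <- data.frame(mass_z = mass_z, scenario = s,
                           nao_z = nao_values[[s]],
                           mean = colMeans(lam), lo95 = qs[1, ], hi95 = qs[2, ],
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Bivariate mass/offspring latent-variable model by MCMC
#'
#' Joint model validating the derived-variable analysis without BLUP-style
#' two-stage fitting: raw capture mass is Gaussian in a second-order day
#' polynomial and skull length; the offspring count is Poisson with a
#' log-link linear predictor in June NAO plus a latent observation-level
#' residual (log-normal Poisson). The two observation-level residuals share
#' an unstructured 2x2 covariance whose correlation is the carry-over
#' statistic.
#'
#' Updates: Gaussian-equation coefficients are conjugate given the latent
#' Poisson residual; the latent residuals are updated by vectorised
#' random-walk Metropolis against their conditional Gaussian prior; the
#' Poisson coefficients by block random-walk; the covariance by its
#' conjugate inverse-Wishart draw (identity prior scale, minimal proper
#' degrees of freedom), which is symmetric positive definite by
#' construction.
#'
#' @param data Data frame with columns `mass_g`, `skull_mm`, `day_of_cycle`,
#'   `n_offspring` and an NAO covariate (`nao_z` if present, else
#'   `june_nao`).
#' @param control An [mcmc_control()].
#' @param seed Integer seed.
#' @param prior_nu,prior_scale Inverse-Wishart prior degrees of freedom and
#'   scale matrix for the residual covariance. The default (`NULL`) is the
#'   identity on the internally standardized mass scale, which keeps the
#'   posterior correlation invariant to the units mass is recorded in; a
#'   user-supplied matrix is interpreted on the raw data scale.
#' @return A `posterior_chain` with samples of the mass-equation
#'   coefficients, offspring-equation coefficients, and `V_mass`, `C`,
#'   `V_juv`; `model = "bivariate"`.
#' @export
mcmc_bivariate <- function(data, control = mcmc_control(), seed = 1L,
                           prior_nu = 3, prior_scale = NULL) {
  set.seed(as.integer(seed))
  need <- c("mass_g", "skull_mm", "day_of_cycle", "n_offspring")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("data missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  nao <- if ("nao_z" %in% names(data)) data$nao_z else data$june_nao
  n <- nrow(data)
  pd <- poly(data$day_of_cycle, 2)
  Xm <- cbind(intercept = 1, day1 = pd[, 1], day2 = pd[, 2],
              skull = data$skull_mm)
  Xj <- cbind(intercept = 1, nao = nao)
  y <- data$n_offspring
  # sample on a unit mass scale for conditioning; results are mapped back,
  # and the correlation is invariant to the rescaling
  s_m <- sd(data$mass_g)
  if (!is.finite(s_m) || s_m == 0) s_m <- 1
  mass <- data$mass_g / s_m
  if (is.null(prior_scale)) {
    prior_scale <- diag(2)          # on the standardized scale
  } else {
    Dscl <- diag(c(1 / s_m, 1))
    prior_scale <- Dscl %*% prior_scale %*% Dscl
  }

  # init from independent fits
  am <- coef(lm(mass ~ Xm - 1))
  em <- mass - as.numeric(Xm %*% am)
  bj <- coef(glm(y ~ Xj - 1, family = poisson()))
  ej <- numeric(n)
  Sigma <- matrix(c(var(em), 0, 0, 0.5), 2)

  XtXm_inv <- solve(crossprod(Xm))
  scale_ej <- 0.5
  scale_bj <- 0.1
  win <- c(ej = 0, bj = 0)
  n_keep <- n_stored(control)
  par_names <- c(paste0("mass_", colnames(Xm)), paste0("juv_", colnames(Xj)),
                 "V_mass", "C", "V_juv")
  samples <- matrix(NA_real_, n_keep, length(par_names),
                    dimnames = list(NULL, par_names))
  kept <- 0L
  acc <- c(ej = 0, bj = 0)

  for (iter in seq_len(control$n_iter)) {
    Vm <- Sigma[1, 1]; C <- Sigma[1, 2]; Vj <- Sigma[2, 2]
    # mass-equation coefficients: conjugate given e_juv
    cond_var <- max(Vm - C^2 / Vj, 1e-12)
    ystar <- mass - (C / Vj) * ej
    mhat <- XtXm_inv %*% crossprod(Xm, ystar)
    am <- as.numeric(mhat + crossprod(chol(cond_var * XtXm_inv),
                                      rnorm(ncol(Xm))))
    em <- mass - as.numeric(Xm %*% am)
    # latent Poisson residuals: vectorised MH
    prior_mean <- (C / Vm) * em
    prior_var <- max(Vj - C^2 / Vm, 1e-12)
    eta0 <- pmin(as.numeric(Xj %*% bj) + ej, 30)
    ej_prop <- ej + rnorm(n, 0, scale_ej)
    eta1 <- pmin(as.numeric(Xj %*% bj) + ej_prop, 30)
    lr <- (y * eta1 - exp(eta1)) - (y * eta0 - exp(eta0)) +
      ((ej - prior_mean)^2 - (ej_prop - prior_mean)^2) / (2 * prior_var)
    lr[!is.finite(lr)] <- -Inf
    take <- log(runif(n)) < lr
    ej[take] <- ej_prop[take]
    acc["ej"] <- acc["ej"] + mean(take); win["ej"] <- win["ej"] + mean(take)
    # Poisson coefficients: block MH
    bp <- bj + rnorm(length(bj), 0, scale_bj)
    eta0 <- pmin(as.numeric(Xj %*% bj) + ej, 30)
    eta1 <- pmin(as.numeric(Xj %*% bp) + ej, 30)
    lr_b <- sum(y * eta1 - exp(eta1)) - sum(y * eta0 - exp(eta0))
    if (is.finite(lr_b) && log(runif(1)) < lr_b) {
      bj <- bp
      acc["bj"] <- acc["bj"] + 1; win["bj"] <- win["bj"] + 1
    }
    # residual covariance: conjugate inverse-Wishart
    E <- cbind(em, ej)
    S <- prior_scale + crossprod(E)
    Sinv <- tryCatch(solve(S), error = function(e)
      solve(S + diag(1e-10 * max(diag(S)), 2)))
    W <- rWishart(1, prior_nu + n, Sinv)[, , 1]
    Sigma <- solve(W)
    Sigma <- (Sigma + t(Sigma)) / 2
    if (iter <= control$burn_in && iter %% 50 == 0) {
      scale_ej <- .adapt(scale_ej, win["ej"], 50, 0.44)
      scale_bj <- .adapt(scale_bj, win["bj"], 50, 0.234)
      win[] <- 0
    }
    if (iter > control$burn_in &&
        (iter - control$burn_in) %% control$thin == 0) {
      kept <- kept + 1L
      samples[kept, ] <- c(am * s_m, bj, Sigma[1, 1] * s_m^2,
                           Sigma[1, 2] * s_m, Sigma[2, 2])
    }
  }
  if (!all(is.finite(samples))) stop("divergent chain: non-finite samples",
                                     call. = FALSE)
  structure(list(samples = samples, control = control, model = "bivariate",
                 seed = as.integer(seed), accept = acc / control$n_iter,
                 ess = apply(samples, 2, .ess)),
            class = "posterior_chain")
}

#' Posterior mass-offspring correlation (the carry-over statistic)
#'
#' Per stored sample computes `r_t = C_t / sqrt(V_mass,t * V_juv,t)` from
#' the residual covariance of the bivariate model and summarises `{r_t}` by
#' its kernel-density posterior mode (Gaussian kernel, Silverman bandwidth)
#' and equal-tailed 95% interval. Scale-free: invariant to rescaling mass.
#'
#' @param chain A `posterior_chain` from [mcmc_bivariate()], or any chain
#'   with `V_mass`, `C`, `V_juv` columns (>= 100 stored samples for the
#'   density mode; constant chains are summarised exactly).
#' @return List: `mode`, `lower95`, `upper95`, `samples` (the r_t draws).
#' @export
posterior_correlation <- function(chain) {
  s <- chain$samples
  need <- c("V_mass", "C", "V_juv")
  if (!all(need %in% colnames(s)))
    stop("chain lacks covariance columns V_mass, C, V_juv", call. = FALSE)
  Vm <- s[, "V_mass"]; C <- s[, "C"]; Vj <- s[, "V_juv"]
  if (any(Vm <= 0) || any(Vj <= 0) || any(C^2 > Vm * Vj))
    stop("invariant violation: stored covariance not positive definite",
         call. = FALSE)
  r <- C / sqrt(Vm * Vj)
  mode <- if (var(r) == 0) r[1] else {
    if (length(r) < 100)
      stop("need >= 100 stored samples for the posterior mode", call. = FALSE)
    d <- density(r, bw = "nrd0")
    d$x[which.max(d$y)]
  }
  q <- quantile(r, c(0.025, 0.975), names = FALSE)
  list(mode = mode, lower95 = q[1], upper95 = q[2], samples = r)
}

#' @export
print.posterior_chain <- function(x, ...) {
  cat(sprintf("Posterior chain (%s model): %d stored samples (%d iterations, %d burn-in, thin %d)\n",
              x$model, nrow(x$samples), x$control$n_iter, x$control$burn_in,
              x$control$thin))
  sm <- rbind(mean = colMeans(x$samples),
              sd = apply(x$samples, 2, sd), ess = round(x$ess))
  print(round(sm, 3))
  invisible(x)
}
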