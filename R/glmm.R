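#' Candidate model specification
#'
#' A candidate Poisson GLMM for the offspring-count analysis: an intercept,
#' an ordered subset of the five fixed-effect terms built from standardized
#' mass and standardized NAO residuals, and a year random intercept (always
#' present). `k` counts the intercept, each fixed term, and the
#' random-intercept variance.
#'
#' Marginality is enforced: `mass2_nao` requires `mass`, `nao` and `mass2`;
#' `mass_nao` requires `mass` and `nao`.
#'
#' @param name Model label.
#' @param terms Character subset of
#'   `c("mass", "nao", "mass_nao", "mass2", "mass2_nao")`.
#' @return A `model_spec` list with `name`, `terms`, `k`.
#' @export
model_spec <- function(name, terms = character()) {
  all_terms <- c("mass", "nao", "mass_nao", "mass2", "mass2_nao")
  bad <- setdiff(terms, all_terms)
  if (length(bad)) stop("unknown term(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  terms <- all_terms[all_terms %in% terms]
  if ("mass2_nao" %in% terms && !all(c("mass", "nao", "mass2") %in% terms))
    stop("marginality: mass2_nao requires mass, nao and mass2", call. = FALSE)
  if ("mass_nao" %in% terms && !all(c("mass", "nao") %in% terms))
    stop("marginality: mass_nao requires mass and nao", call. = FALSE)
  structure(list(name = name, terms = terms, k = 2L + length(terms)),
            class = "model_spec")
}

#' The eight-model candidate set
#'
#' Competing hypotheses for offspring counts: a linear or quadratic
#' carry-over effect of pre-migration mass, an effect of June NAO during
#' breeding, additive combinations, interactions in which weather modifies
#' the (linear or quadratic) mass slope, and an intercept-only null. Every
#' model carries the year random intercept.
#'
#' @return List of 8 [model_spec()] objects with k = 3, 3, 4, 5, 4, 5, 6, 2.
#' @export
candidate_models <- function() {
  list(
    model_spec("Mass", "mass"),
    model_spec("NAO", "nao"),
    model_spec("Mass + NAO", c("mass", "nao")),
    model_spec("Mass * NAO", c("mass", "nao", "mass_nao")),
    model_spec("Mass^2", c("mass", "mass2")),
    model_spec("Mass^2 + NAO", c("mass", "nao", "mass2")),
    model_spec("Mass^2 * NAO", c("mass", "nao", "mass2", "mass2_nao")),
    model_spec("Null", character())
  )
}

#' Fixed-effect design matrix for a candidate model
#'
#' @param spec A [model_spec()].
#' @param mass_z,nao_z Standardized covariate vectors.
#' @return Numeric matrix with an intercept column; squared and interaction
#'   columns are formed from the standardized main effects
#'   (standardize-then-square), keeping main effects interpretable in the
#'   presence of interactions.
#' @export
design_matrix <- function(spec, mass_z, nao_z) {
  cols <- list(intercept = rep(1, length(mass_z)),
               mass = mass_z, nao = nao_z, mass_nao = mass_z * nao_z,
               mass2 = mass_z^2, mass2_nao = mass_z^2 * nao_z)
  X <- do.call(cbind, cols[c("intercept", spec$terms)])
  colnames(X) <- c("intercept", spec$terms)
  X
}

#' Control settings for the Laplace GLMM optimiser
#'
#' @param inner_tol Convergence tolerance for the inner Newton solve of the
#'   random-intercept modes.
#' @param inner_maxit Maximum inner Newton iterations.
#' @param grad_tol Gradient-norm tolerance certified at the outer optimum.
#' @param maxit Maximum outer quasi-Newton iterations.
#' @param sigma_start Starting value for the random-intercept SD.
#' @param boundary_tol sigma below this is treated as a boundary fit and
#'   reported as exactly 0.
#' @return A list of control parameters.
#' @export
glmm_control <- function(inner_tol = 1e-10, inner_maxit = 100,
                         grad_tol = 1e-8, maxit = 500,
                         sigma_start = 0.3, boundary_tol = 1e-4) {
  list(inner_tol = inner_tol, inner_maxit = inner_maxit, grad_tol = grad_tol,
       maxit = maxit, sigma_start = sigma_start, boundary_tol = boundary_tol)
}

# Poisson log-likelihood constant term
.pois_const <- function(y) -sum(lgamma(y + 1))

# Inner Newton solve for the random-intercept modes, vectorized over groups.
# g is an integer group index 1..J; returns list(u, W) with W_j = sum_j mu.
.solve_modes <- function(eta_fix, y, g, J, sigma2, u0, tol, maxit) {
  u <- u0
  sum_y <- as.numeric(rowsum(y, g))
  for (it in seq_len(maxit)) {
    eta <- pmin(eta_fix + u[g], 30)
    W <- as.numeric(rowsum(exp(eta), g))
    grad <- sum_y - W - u / sigma2
    step <- grad / (W + 1 / sigma2)
    step <- pmin(pmax(step, -5), 5)
    u <- u + step
    if (max(abs(step)) < tol) break
  }
  eta <- pmin(eta_fix + u[g], 30)
  list(u = u, W = as.numeric(rowsum(exp(eta), g)))
}

#' Laplace-approximate marginal log-likelihood of the Poisson GLMM
#'
#' Profiles the year-intercept modes by Newton iteration and applies the
#' Laplace correction per group. At `sigma = 0` this reduces exactly to the
#' ordinary Poisson GLM log-likelihood.
#'
#' @param beta Fixed-effect vector (matching `ncol(X)`).
#' @param sigma Random-intercept SD (>= 0).
#' @param X Design matrix.
#' @param y Counts.
#' @param group Grouping factor/vector (year).
#' @param control A [glmm_control()].
#' @return Log-likelihood (scalar), with attribute `modes` (the conditional
#'   modes of the year intercepts).
#' @export
glmm_loglik_laplace <- function(beta, sigma, X, y, group,
                                control = glmm_control()) {
  g <- as.integer(factor(group))
  J <- max(g)
  eta_fix <- as.numeric(X %*% beta)
  if (sigma <= 0) {
    eta <- pmin(eta_fix, 30)
    ll <- sum(y * eta - exp(eta)) + .pois_const(y)
    attr(ll, "modes") <- numeric(J)
    return(ll)
  }
  s2 <- sigma^2
  m <- .solve_modes(eta_fix, y, g, J, s2, numeric(J),
                    control$inner_tol, control$inner_maxit)
  eta <- pmin(eta_fix + m$u[g], 30)
  ll <- sum(y * eta - exp(eta)) + .pois_const(y) -
    sum(m$u^2) / (2 * s2) - 0.5 * sum(log1p(s2 * m$W))
  attr(ll, "modes") <- m$u
  ll
}

# Analytic gradient of the Laplace log-likelihood wrt (beta, log sigma).
# Uses the implicit derivative of the profiled modes.
.laplace_grad <- function(beta, theta, X, y, group, control) {
  g <- as.integer(factor(group))
  J <- max(g)
  sigma2 <- exp(2 * theta)
  eta_fix <- as.numeric(X %*% beta)
  m <- .solve_modes(eta_fix, y, g, J, sigma2, numeric(J),
                    control$inner_tol, control$inner_maxit)
  u <- m$u
  mu <- exp(pmin(eta_fix + u[g], 30))
  W <- m$W                      # sum of mu per group
  D <- W + 1 / sigma2
  res <- y - mu
  # W_p per group: sum of mu * x_p
  Wp <- rowsum(mu * X, g)                        # J x p
  gb <- colSums(res * X) - colSums(Wp / D) / 2 +
    colSums(Wp * (W / D^2)) / 2
  gt <- sum(u^2) / sigma2 - sum(W / D) - sum(u * W / (sigma2 * D^2))
  c(gb, gt)
}

#' Fit a Poisson random-intercept GLMM by Laplace maximum likelihood
#'
#' Maximises the Laplace-approximate marginal likelihood over the fixed
#' effects and the log random-intercept SD: inner Newton iterations profile
#' the year-intercept modes; the outer problem is solved by BFGS with
#' analytic gradients and polished by Newton steps until the gradient norm
#' is below `control$grad_tol`. Boundary fits (`sigma -> 0`) are reported as
#' converged with `sigma_u = 0` and the corresponding Poisson GLM solution.
#'
#' @param data Data frame with columns `n_offspring`, `mass_z`, `nao_z`,
#'   `year` (or supply `y`, `X`, `group` directly via `...` is not
#'   supported; use the data-frame interface).
#' @param spec A [model_spec()].
#' @param control A [glmm_control()].
#' @return A `glmm_fit` list: `spec`, `beta` (named), `se`, `vcov`,
#'   `sigma_u`, `loglik`, `converged`, `grad_norm`, `n_obs`, `n_groups`,
#'   `k`, `modes`.
#' @export
fit_poisson_glmm <- function(data, spec, control = glmm_control()) {
  y <- data$n_offspring
  if (any(y < 0) || any(y != floor(y))) stop("counts must be non-negative integers",
                                             call. = FALSE)
  X <- design_matrix(spec, data$mass_z, data$nao_z)
  group <- data$year
  J <- length(unique(group))
  if (J < 2) stop("need >= 2 grouping levels", call. = FALSE)
  if (qr(X)$rank < ncol(X))
    stop("rank-deficient design matrix for model '", spec$name, "'",
         call. = FALSE)

  glm0 <- suppressWarnings(glm.fit(X, y, family = poisson()))
  ll_glm <- sum(y * pmin(glm0$linear.predictors, 30)) -
    sum(exp(pmin(glm0$linear.predictors, 30))) + .pois_const(y)
  p <- ncol(X)

  negll <- function(par)
    -as.numeric(glmm_loglik_laplace(par[1:p], max(exp(par[p + 1]), 1e-8),
                                    X, y, group, control))
  neggr <- function(par)
    -.laplace_grad(par[1:p], max(par[p + 1], log(1e-8)), X, y, group, control)

  start <- c(glm0$coefficients, log(control$sigma_start))
  opt <- optim(start, negll, neggr, method = "BFGS",
               control = list(maxit = control$maxit, reltol = 1e-14))
  par <- opt$par

  # Newton polish to certify the gradient tolerance
  fd_hess <- function(par) {
    h <- 1e-5 * pmax(abs(par), 1)
    H <- matrix(0, length(par), length(par))
    for (j in seq_along(par)) {
      up <- par; up[j] <- up[j] + h[j]
      dn <- par; dn[j] <- dn[j] - h[j]
      H[, j] <- (neggr(up) - neggr(dn)) / (2 * h[j])
    }
    (H + t(H)) / 2
  }
  for (it in 1:25) {
    gr <- neggr(par)
    if (max(abs(gr)) <= control$grad_tol) break
    H <- fd_hess(par)
    step <- tryCatch(solve(H, gr), error = function(e) NULL)
    if (is.null(step) || !all(is.finite(step))) break
    step <- pmin(pmax(step, -1), 1)
    cand <- par - step
    if (negll(cand) <= negll(par) + 1e-9) par <- cand else {
      cand <- par - 0.25 * step
      if (negll(cand) <= negll(par)) par <- cand else break
    }
  }
  grad_norm <- max(abs(neggr(par)))
  sigma <- unname(exp(par[p + 1]))
  ll <- -negll(par)

  boundary <- sigma < control$boundary_tol || ll_glm >= ll - 1e-8
  if (boundary && ll_glm >= ll - 1e-6) {
    beta <- glm0$coefficients
    sigma <- 0
    ll <- ll_glm
    V <- tryCatch(solve(crossprod(X * sqrt(glm0$weights))),
                  error = function(e) matrix(NA, p, p))
    grad_norm <- 0
    conv <- glm0$converged
  } else {
    beta <- unname(par[1:p])
    H <- fd_hess(par)
    V <- tryCatch(solve(H)[1:p, 1:p, drop = FALSE],
                  error = function(e) matrix(NA, p, p))
    conv <- opt$convergence == 0 && grad_norm <= max(control$grad_tol, 1e-6)
  }
  names(beta) <- colnames(X)
  se <- sqrt(pmax(diag(V), 0))
  names(se) <- colnames(X)
  ll_final <- glmm_loglik_laplace(beta, sigma, X, y, group, control)

  structure(list(spec = spec, beta = beta, se = se, vcov = V,
                 sigma_u = sigma, loglik = as.numeric(ll_final),
                 converged = conv, grad_norm = grad_norm,
                 n_obs = length(y), n_groups = J, k = spec$k,
                 modes = attr(ll_final, "modes")),
            class = "glmm_fit")
}

#' @export
print.glmm_fit <- function(x, ...) {
  cat(sprintf("Poisson GLMM (Laplace): %s | logLik %.3f | sigma_u %.3f | k %d%s\n",
              x$spec$name, x$loglik, x$sigma_u, x$k,
              if (!x$converged) " [NOT CONVERGED]" else ""))
  print(round(rbind(estimate = x$beta, se = x$se), 4))
  invisible(x)
}

#' Marginal log-likelihood by adaptive Gauss-Hermite quadrature
#'
#' Independent oracle for [glmm_loglik_laplace()]: integrates each group's
#' likelihood over the random intercept with Gauss-Hermite nodes centred at
#' the conditional mode and scaled by the local curvature. At one node this
#' reproduces the Laplace value; at many nodes it converges to the exact
#' marginal likelihood.
#'
#' @inheritParams glmm_loglik_laplace
#' @param n_nodes Number of quadrature nodes (default 64).
#' @return Log-likelihood (scalar).
#' @export
glmm_loglik_agq <- function(beta, sigma, X, y, group, n_nodes = 64,
                            control = glmm_control()) {
  if (sigma <= 0)
    return(as.numeric(glmm_loglik_laplace(beta, 0, X, y, group, control)))
  gh <- pracma::gaussHermite(n_nodes)
  g <- as.integer(factor(group))
  J <- max(g)
  s2 <- sigma^2
  eta_fix <- as.numeric(X %*% beta)
  m <- .solve_modes(eta_fix, y, g, J, s2, numeric(J),
                    control$inner_tol, control$inner_maxit)
  scale <- 1 / sqrt(m$W + 1 / s2)
  ll <- .pois_const(y)
  for (j in seq_len(J)) {
    idx <- g == j
    yj <- y[idx]; ej <- eta_fix[idx]
    uk <- m$u[j] + sqrt(2) * scale[j] * gh$x
    contrib <- vapply(uk, function(u) {
      eta <- pmin(ej + u, 30)
      sum(yj * eta - exp(eta)) - u^2 / (2 * s2)
    }, numeric(1))
    logterms <- log(gh$w) + gh$x^2 + contrib +
      log(sqrt(2) * scale[j]) - 0.5 * log(2 * pi * s2)
    mx <- max(logterms)
    ll <- ll + mx + log(sum(exp(logterms - mx)))
  }
  ll
}

#' Population-level predicted offspring count
#'
#' Expected count at given standardized mass and NAO, with the year random
#' intercept set to zero (population level).
#'
#' @param fit A `glmm_fit`.
#' @param mass_z,nao_z Standardized covariate values (vectorised).
#' @return `exp(linear predictor)`.
#' @export
predict_response <- function(fit, mass_z, nao_z) {
  if (!isTRUE(fit$converged)) stop("fit did not converge", call. = FALSE)
  X <- design_matrix(fit$spec, mass_z, nao_z)
  as.numeric(exp(X %*% fit$beta))
}

#' Fit the full candidate set
#'
#' @param data Preprocessed analysis table (or a `preprocessed` object).
#' @param specs List of [model_spec()]s; defaults to [candidate_models()].
#' @param control A [glmm_control()].
#' @return Named list of `glmm_fit` objects.
#' @export
fit_candidate_set <- function(data, specs = candidate_models(),
                              control = glmm_control()) {
  if (inherits(data, "preprocessed")) data <- data$data
  fits <- lapply(specs, function(s) fit_poisson_glmm(data, s, control))
  names(fits) <- vapply(specs, `[[`, "", "name")
  fits
}
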