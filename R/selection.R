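#' Small-sample corrected Akaike information criterion
#'
#' `AICc = -2*loglik + 2k + 2k(k+1)/(n - k - 1)`, with `n` the number of
#' observations (birds, not years — the convention validated against the
#' reference candidate set).
#'
#' @param loglik Maximised log-likelihood.
#' @param k Number of estimated parameters (intercept + fixed terms +
#'   random-intercept variance).
#' @param n Number of observations; must exceed `k + 1`.
#' @return AICc (vectorised over its arguments).
#' @export
aicc <- function(loglik, k, n) {
  if (any(n <= k + 1))
    stop("AICc undefined: n must exceed k + 1", call. = FALSE)
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

.spec_lookup <- function(name) {
  cand <- candidate_models()
  idx <- match(name, vapply(cand, `[[`, "", "name"))
  if (anyNA(idx)) stop("unknown model name(s): ",
                       paste(name[is.na(idx)], collapse = ", "), call. = FALSE)
  cand[idx]
}

#' Rank candidate fits by AICc and attach Akaike weights
#'
#' @param fits Either a list of `glmm_fit` objects or a data frame with
#'   columns `name`, `loglik`, `k` (model specs are then looked up in
#'   [candidate_models()] by name).
#' @param n Sample size for AICc (number of birds).
#' @param delta_threshold Delta-AICc cut for the candidate retention set
#'   (default 6).
#' @return A `selection_table` data frame ordered by AICc (ties broken by
#'   smaller k, then name) with columns `name`, `k`, `loglik`, `aicc`,
#'   `delta`, `weight`, `in_delta_set`, and a `specs` attribute holding the
#'   ordered [model_spec()]s. Weights sum to 1 over all rows.
#' @export
rank_models <- function(fits, n, delta_threshold = 6) {
  if (is.data.frame(fits)) {
    tab <- data.frame(name = fits$name, k = fits$k, loglik = fits$loglik,
                      stringsAsFactors = FALSE)
    specs <- .spec_lookup(fits$name)
  } else {
    tab <- data.frame(name = vapply(fits, function(f) f$spec$name, ""),
                      k = vapply(fits, `[[`, 0L, "k"),
                      loglik = vapply(fits, `[[`, 0, "loglik"),
                      stringsAsFactors = FALSE)
    specs <- lapply(fits, `[[`, "spec")
  }
  tab$aicc <- aicc(tab$loglik, tab$k, n)
  ord <- order(tab$aicc, tab$k, tab$name)
  tab <- tab[ord, , drop = FALSE]
  specs <- specs[ord]
  tab$delta <- tab$aicc - tab$aicc[1]
  w <- exp(-tab$delta / 2)
  tab$weight <- w / sum(w)
  tab$in_delta_set <- tab$delta <= delta_threshold
  rownames(tab) <- NULL
  attr(tab, "specs") <- specs
  attr(tab, "n") <- n
  attr(tab, "delta_threshold") <- delta_threshold
  class(tab) <- c("selection_table", "data.frame")
  tab
}

#' Is model `a` nested within model `b`?
#'
#' True iff `a`'s fixed-term set is a strict subset of `b`'s. A model is not
#' nested in itself.
#'
#' @param a,b [model_spec()] objects.
#' @return Logical.
#' @export
is_nested <- function(a, b) {
  all(a$terms %in% b$terms) && length(a$terms) < length(b$terms)
}

#' Apply the nesting rule to a ranked selection table
#'
#' A model inside the delta set is dropped when a model with better AICc
#' support (ranked above it) is nested within it: retaining such more
#' complex supersets would reward parameters that add little fit. The
#' top-ranked model can never be dropped.
#'
#' @param table A `selection_table` from [rank_models()].
#' @param delta_threshold Delta cut (defaults to the table's own).
#' @return The table with a logical `retained` column
#'   (`retained` implies `in_delta_set`).
#' @export
apply_nesting_rule <- function(table, delta_threshold = NULL) {
  stopifnot(inherits(table, "selection_table"))
  if (is.null(delta_threshold)) delta_threshold <- attr(table, "delta_threshold")
  specs <- attr(table, "specs")
  in_set <- table$delta <= delta_threshold
  retained <- logical(nrow(table))
  for (i in seq_len(nrow(table))) {
    if (!in_set[i]) next
    dominated <- FALSE
    for (j in seq_len(i - 1L)) {
      if (is_nested(specs[[j]], specs[[i]])) { dominated <- TRUE; break }
    }
    retained[i] <- !dominated
  }
  table$in_delta_set <- in_set
  table$retained <- retained
  table
}

#' Model-averaged estimates over the retained set
#'
#' Akaike weights are renormalized over the retained (post-nesting-rule)
#' models; for each fixed-effect term the function reports the
#' natural-average estimate (weights renormalized over the models containing
#' the term), the shrinkage ("zeroes") estimate (absent terms contribute 0),
#' the relative importance (summed renormalized weight of models containing
#' the term), and — when per-model standard errors are available — the
#' unconditional SE combining within-model variance and between-model
#' spread.
#'
#' @param table A `selection_table` with a `retained` column.
#' @param fits List of `glmm_fit`s named by model (provides coefficients and
#'   SEs), or `NULL` if `coefs` is given.
#' @param coefs Optional data frame / matrix of coefficients with rows
#'   named by model and columns `intercept`, `mass`, `nao`, `mass_nao`,
#'   `mass2`, `mass2_nao` (`NA` when absent from the model), e.g. printed
#'   reference values.
#' @param ses Optional matrix of standard errors shaped like `coefs`.
#' @return An `averaged_estimates` data frame: `term`, `natural_avg`,
#'   `unconditional_se`, `shrinkage_avg`, `importance`.
#' @export
model_average <- function(table, fits = NULL, coefs = NULL, ses = NULL) {
  stopifnot(inherits(table, "selection_table"), !is.null(table$retained))
  keep <- which(table$retained)
  if (!length(keep)) stop("empty retained set", call. = FALSE)
  w <- table$weight[keep]
  w <- w / sum(w)
  models <- table$name[keep]

  term_order <- c("intercept", "mass", "nao", "mass_nao", "mass2", "mass2_nao")
  if (is.null(coefs)) {
    if (is.null(fits)) stop("need fits or coefs", call. = FALSE)
    fits <- fits[models]
    coefs <- matrix(NA_real_, length(models), length(term_order),
                    dimnames = list(models, term_order))
    ses <- coefs
    for (m in models) {
      coefs[m, names(fits[[m]]$beta)] <- fits[[m]]$beta
      ses[m, names(fits[[m]]$se)] <- fits[[m]]$se
    }
  } else {
    coefs <- as.data.frame(coefs)
    if ("name" %in% names(coefs)) rownames(coefs) <- coefs$name
    absent <- setdiff(models, rownames(coefs))
    if (length(absent))
      stop("coefs lacks retained model(s): ", paste(absent, collapse = ", "),
           call. = FALSE)
    coefs <- as.matrix(coefs[models, term_order, drop = FALSE])
    if (!is.null(ses)) {
      ses <- as.data.frame(ses)
      if ("name" %in% names(ses)) rownames(ses) <- ses$name
      ses <- as.matrix(ses[models, term_order, drop = FALSE])
    }
  }

  present <- !is.na(coefs)
  terms <- term_order[colSums(present) > 0]
  out <- lapply(terms, function(t) {
    has <- present[, t]
    wt <- w[has] / sum(w[has])
    nat <- sum(wt * coefs[has, t])
    shrink <- sum(w[has] * coefs[has, t])
    imp <- sum(w[has])
    use <- if (!is.null(ses) && all(is.finite(ses[has, t])))
      sqrt(sum(wt * (ses[has, t]^2 + (coefs[has, t] - nat)^2))) else NA_real_
    data.frame(term = t, natural_avg = nat, unconditional_se = use,
               shrinkage_avg = shrink, importance = imp,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  class(out) <- c("averaged_estimates", "data.frame")
  out
}

#' Marginal R-squared of a Poisson log-link mixed model
#'
#' Fraction of latent-scale variance explained by the fixed effects:
#' `R2m = var_f / (var_f + var_u + var_d)`, where `var_f` is the variance of
#' the fixed-effect linear predictor over the data, `var_u` the
#' year-intercept variance, and `var_d = log(1 + 1/lambda_bar)` the
#' log-link Poisson distribution-specific variance (lognormal
#' approximation), with `lambda_bar` the mean fixed-effect expected count.
#'
#' @param fit A converged `glmm_fit`.
#' @param data The analysis table the model was fitted to.
#' @return Marginal R-squared in `[0, 1)`.
#' @export
marginal_r2 <- function(fit, data) {
  if (!isTRUE(fit$converged)) stop("fit did not converge", call. = FALSE)
  X <- design_matrix(fit$spec, data$mass_z, data$nao_z)
  eta <- as.numeric(X %*% fit$beta)
  var_f <- if (length(unique(eta)) > 1) var(eta) else 0
  lambda_bar <- mean(exp(eta))
  var_d <- log1p(1 / lambda_bar)
  total <- var_f + fit$sigma_u^2 + var_d
  if (total <= 0) stop("degenerate variance decomposition", call. = FALSE)
  var_f / total
}

#' Reference candidate-set summaries from the original field study
#'
#' Published per-model log-likelihoods, parameter counts and coefficient
#' estimates for the eight-model candidate set fitted to the original 213
#' female Brent geese (raw field data not deposited). Used to validate the
#' selection arithmetic and to parameterise simulations at field scale.
#'
#' @return Data frame: `name`, `k`, `loglik`, and per-term coefficients
#'   (`NA` where a term is absent from a model).
#' @export
reference_model_set <- function() {
  path <- system.file("extdata", "reference_model_set.csv",
                      package = "carrygoose", mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE)
}

#' @export
print.selection_table <- function(x, ...) {
  df <- as.data.frame(x)
  df$loglik <- round(df$loglik, 3)
  df$aicc <- round(df$aicc, 1)
  df$delta <- round(df$delta, 2)
  df$weight <- round(df$weight, 3)
  print(df)
  invisible(x)
}
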