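#' Validate pipeline input tables
#'
#' Schema checks for the CSV inputs: required columns and types, row
#' counts, duplicate bird ids, offspring integrality, NAO coverage of the
#' study years. A NAO series covering extra years is tolerated (it is used
#' for detrending); study years absent from the NAO series are an error.
#'
#' @param birds,nao Data frames (or file paths) with the `birds.csv` /
#'   `nao.csv` schemas.
#' @param resightings Optional resighting table or path.
#' @return A `validation_report` list: `ok`, `errors`, `warnings`,
#'   `counts`.
#' @export
validate_inputs <- function(birds, nao, resightings = NULL) {
  read_maybe <- function(x) if (is.character(x)) read.csv(x) else x
  birds <- read_maybe(birds); nao <- read_maybe(nao)
  resightings <- if (!is.null(resightings)) read_maybe(resightings)
  errors <- character(); warnings <- character()

  need_birds <- c("bird_id", "year", "day_of_cycle", "mass_g", "skull_mm",
                  "n_offspring_next_winter")
  miss <- setdiff(need_birds, names(birds))
  if (length(miss))
    errors <- c(errors, paste("birds: missing column(s):",
                              paste(miss, collapse = ", ")))
  if (!length(miss)) {
    if (any(duplicated(birds[c("bird_id", "year")])))
      errors <- c(errors, "birds: duplicate bird_id/year rows")
    if (any(birds$day_of_cycle < 1 | birds$day_of_cycle > 366, na.rm = TRUE))
      errors <- c(errors, "birds: day_of_cycle outside 1-366")
    off <- birds$n_offspring_next_winter
    if (any(off < 0 | off != floor(off), na.rm = TRUE))
      errors <- c(errors, "birds: offspring counts must be non-negative integers")
    n_bad <- sum(!(is.finite(birds$mass_g) & is.finite(birds$skull_mm) &
                     birds$mass_g > 0 & birds$skull_mm > 0))
    if (n_bad) warnings <- c(warnings, sprintf(
      "birds: %d row(s) with missing/non-positive morphometrics will be dropped",
      n_bad))
  }
  miss_nao <- setdiff(c("year", "june_nao"), names(nao))
  if (length(miss_nao))
    errors <- c(errors, paste("nao: missing column(s):",
                              paste(miss_nao, collapse = ", ")))
  if (!length(miss) && !length(miss_nao)) {
    absent <- setdiff(unique(birds$year), nao$year)
    if (length(absent))
      errors <- c(errors, paste("nao: study year(s) absent from series:",
                                paste(absent, collapse = ", ")))
    extra <- setdiff(nao$year, unique(birds$year))
    if (length(extra))
      warnings <- c(warnings, sprintf(
        "nao: %d year(s) without captures (used for detrending only)",
        length(extra)))
  }
  if (!is.null(resightings)) {
    miss_rs <- setdiff(c("bird_id", "n_records_no_juv", "n_records_with_juv"),
                       names(resightings))
    if (length(miss_rs))
      errors <- c(errors, paste("resightings: missing column(s):",
                                paste(miss_rs, collapse = ", ")))
  }
  structure(list(ok = length(errors) == 0, errors = errors,
                 warnings = warnings,
                 counts = list(birds = nrow(birds), nao = nrow(nao),
                               resightings = if (!is.null(resightings))
                                 nrow(resightings))),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("Input validation: %s (birds %d, nao %d)\n",
              if (x$ok) "PASS" else "FAIL", x$counts$birds, x$counts$nao))
  for (e in x$errors) cat("  error:", e, "\n")
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' Pipeline configuration
#'
#' @param out_dir Output directory for all artifacts.
#' @param seed Master seed (mandatory; drives every stochastic stage).
#' @param simulate A [sim_config()] to generate inputs, or `NULL` to read
#'   them from `paths`.
#' @param paths Named list with `birds`, `nao` and optionally `resightings`
#'   CSV paths (ignored when `simulate` is given).
#' @param delta_threshold Delta-AICc cut for the retention set.
#' @param mcmc An [mcmc_control()] for the Bayesian stage.
#' @param run_bivariate Whether to run the bivariate carry-over model.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, seed, simulate = NULL, paths = NULL,
                            delta_threshold = 6, mcmc = mcmc_control(),
                            run_bivariate = FALSE) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  if (is.null(simulate) && is.null(paths))
    stop("either a simulate block or input paths are required", call. = FALSE)
  if (!is.null(paths)) {
    for (p in unlist(paths))
      if (!file.exists(p)) stop("input file not found: ", p, call. = FALSE)
  }
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 simulate = simulate, paths = paths,
                 delta_threshold = delta_threshold, mcmc = mcmc,
                 run_bivariate = run_bivariate),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file with `out_dir`, `seed`, and optionally `simulate`
#'   (sim_config fields), `paths`, `delta_threshold`, `mcmc`
#'   (n_iter/burn_in/thin), `run_bivariate`.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  sim <- if (!is.null(cfg$simulate)) do.call(sim_config, cfg$simulate)
  mc <- if (!is.null(cfg$mcmc)) do.call(mcmc_control, cfg$mcmc) else mcmc_control()
  pipeline_config(out_dir = cfg$out_dir, seed = cfg$seed, simulate = sim,
                  paths = cfg$paths,
                  delta_threshold = cfg$delta_threshold %||% 6, mcmc = mc,
                  run_bivariate = isTRUE(cfg$run_bivariate))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis pipeline
#'
#' Simulate (or load) inputs, validate, preprocess, fit the candidate set,
#' rank with AICc and the nesting rule, model-average, refit the retained
#' top model by MCMC, and write all artifacts plus a manifest with input
#' digests. Deterministic stages are bit-identical across reruns with the
#' same config; stochastic stages are reproducible given the seed.
#'
#' @param config A [pipeline_config()] (or path to a YAML config).
#' @return Invisibly, a list with the in-memory results (`prep`, `fits`,
#'   `selection`, `averaged`, `chain`, `grid`, `manifest`).
#' @export
run_all <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  if (!is.null(config$simulate)) {
    sim <- config$simulate
    sim$seed <- config$seed
    cfg <- do.call(sim_config, sim[setdiff(names(sim), "n_total")])
    ds <- stage("simulate", simulate_dataset(cfg))
    stage("simulate", write_dataset(ds, config$out_dir, cfg))
    birds <- ds$birds; nao <- ds$nao
    resightings <- read.csv(out("resightings.csv"))
  } else {
    birds <- read.csv(config$paths$birds)
    nao <- read.csv(config$paths$nao)
    resightings <- if (!is.null(config$paths$resightings))
      read.csv(config$paths$resightings)
  }

  vr <- stage("validate", validate_inputs(birds, nao, resightings))
  if (!vr$ok)
    stop("pipeline stage 'validate' failed:\n  ",
         paste(vr$errors, collapse = "\n  "), call. = FALSE)

  prep <- stage("preprocess", preprocess(birds, nao, resightings))
  write.csv(prep$data, out("preprocessed.csv"), row.names = FALSE)

  fits <- stage("fit", fit_candidate_set(prep))
  fits_json <- lapply(fits, function(f)
    list(name = f$spec$name, terms = f$spec$terms, k = f$k,
         beta = as.list(f$beta), se = as.list(f$se), sigma_u = f$sigma_u,
         loglik = f$loglik, converged = f$converged))
  jsonlite::write_json(fits_json, out("fits.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  tab <- stage("select", apply_nesting_rule(
    rank_models(fits, n = nrow(prep$data),
                delta_threshold = config$delta_threshold)))
  avg <- stage("select", model_average(tab, fits))
  write.csv(as.data.frame(tab), out("selection_table.csv"), row.names = FALSE)
  write.csv(avg, out("averaged_estimates.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(n = nrow(prep$data), delta_threshold = config$delta_threshold,
         table = as.data.frame(tab), averaged = avg),
    out("selection.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)

  top_spec <- attr(tab, "specs")[[which(tab$retained)[1]]]
  chain <- stage("bayes", mcmc_top_model(prep$data, top_spec,
                                         control = config$mcmc,
                                         seed = config$seed))
  write_chain(chain, out("chain.csv"))
  grid <- stage("bayes", predict_grid(chain, nao_values = nao_scenarios(prep)))
  write.csv(grid, out("prediction_grid.csv"), row.names = FALSE)

  biv <- NULL
  if (isTRUE(config$run_bivariate)) {
    biv <- stage("bayes", mcmc_bivariate(prep$data, control = config$mcmc,
                                         seed = config$seed + 1L))
    write_chain(biv, out("chain_bivariate.csv"))
    pc <- posterior_correlation(biv)
    jsonlite::write_json(pc[c("mode", "lower95", "upper95")],
                         out("posterior_correlation.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  artifacts <- c("preprocessed.csv", "fits.json", "selection_table.csv",
                 "averaged_estimates.csv", "selection.json", "chain.csv",
                 "prediction_grid.csv")
  manifest <- list(
    package_version = as.character(packageVersion("carrygoose")),
    seed = config$seed,
    delta_threshold = config$delta_threshold,
    mcmc = unclass(config$mcmc),
    n_birds = nrow(prep$data),
    dropped_rows = prep$log$n_dropped_morphometrics,
    excluded_birds = prep$log$n_excluded_status,
    top_model = top_spec$name,
    digests = as.list(tools::md5sum(file.path(config$out_dir,
                                              artifacts[file.exists(out(artifacts))])))
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(prep = prep, fits = fits, selection = tab, averaged = avg,
                 chain = chain, bivariate = biv, grid = grid,
                 manifest = manifest))
}

#' Write a posterior chain in long CSV form
#'
#' Columns: `iteration` (stored-sample index), `parameter`, `value`.
#' @param chain A `posterior_chain`.
#' @param path Output CSV path.
#' @return Invisibly, the path.
#' @export
write_chain <- function(chain, path) {
  s <- chain$samples
  long <- data.frame(iteration = rep(seq_len(nrow(s)), ncol(s)),
                     parameter = rep(colnames(s), each = nrow(s)),
                     value = as.vector(s), stringsAsFactors = FALSE)
  write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' Read a posterior chain written by [write_chain()]
#' @param path CSV path.
#' @return Matrix of samples (columns = parameters).
#' @export
read_chain <- function(path) {
  long <- read.csv(path, stringsAsFactors = FALSE)
  pars <- unique(long$parameter)
  s <- sapply(pars, function(p) long$value[long$parameter == p])
  colnames(s) <- pars
  s
}
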