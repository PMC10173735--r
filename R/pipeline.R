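pipeline_stages <- function() {
  c("synth", "calibrate", "gridsearch", "fit", "compare", "mcmc", "report")
}

config_schema <- function() {
  list(
    out_dir = NULL, seed = NULL,
    design = names(study_design()),
    synth = c("volume_sd", "dispersion", "expression_noise", "truth"),
    fit = c("variants", "n_starts", "n_polish"),
    grid = c("ke_max", "ki_max", "step"),
    mcmc = c("n_steps", "n_aux", "n_retain"),
    posterior = c("n_draws")
  )
}

#' Build and validate a pipeline configuration
#'
#' Unknown keys (at top level or inside a section) are rejected by name;
#' the seed is mandatory because every stochastic stage derives its seed
#' from it.  The fixed parameters kA and kex cannot be freed through the
#' configuration.
#'
#' @param config a named list (e.g. from \code{yaml::read_yaml}).
#' @return the validated config, with defaults filled in.
#' @export
validate_config <- function(config) {
  schema <- config_schema()
  bad <- setdiff(names(config), names(schema))
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  for (sec in names(schema)) {
    if (is.null(schema[[sec]]) || is.null(config[[sec]])) next
    bad <- setdiff(names(config[[sec]]), schema[[sec]])
    if (length(bad))
      stop("unknown config key(s) in '", sec, "': ",
           paste(bad, collapse = ", "))
  }
  if (is.null(config$seed)) stop("config must set a seed")
  if (is.null(config$out_dir)) stop("config must set out_dir")
  if (!is.null(config$synth$truth)) {
    if (any(c("kA", "kex") %in% names(config$synth$truth)))
      stop("kA and kex are fixed at 1 and cannot be overridden")
  }
  defaults <- list(
    synth = list(volume_sd = 0.2, dispersion = 0.15, expression_noise = TRUE),
    fit = list(variants = c("none", "all"), n_starts = 24, n_polish = 3),
    grid = list(ke_max = 20, ki_max = 20, step = 1),
    mcmc = list(n_steps = 600, n_aux = 3, n_retain = 300),
    posterior = list(n_draws = 10)
  )
  for (sec in names(defaults)) {
    for (k in names(defaults[[sec]]))
      if (is.null(config[[sec]][[k]])) config[[sec]][[k]] <- defaults[[sec]][[k]]
  }
  config
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file.
#' @return validated config list.
#' @export
read_config <- function(path) {
  validate_config(yaml::read_yaml(path))
}

#' Run the full analysis pipeline
#'
#' Synthetic data generation, basal-growth calibration, the two-parameter
#' grid search on the input-driven model, multistart variant fits, AIC
#' comparison, posterior sampling with credible intervals and
#' posterior-predictive simulation, and a machine-readable run manifest.
#' Each stage logs its seed; outputs are written under
#' \code{config$out_dir}.  A stage failure halts the run after writing a
#' manifest that records the completed stages.
#'
#' @param config validated configuration (see \code{\link{validate_config}}).
#' @return the manifest list, invisibly.
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = config$seed, stages = list(), files = list())
  seed <- config$seed

  log_stage <- function(name, ...) {
    message(sprintf("[%s] %s", name, sprintf(...)))
  }
  finish_stage <- function(name, stage_seed = NA) {
    manifest$stages[[name]] <<- list(status = "complete", seed = stage_seed)
  }
  fail <- function(name, e) {
    manifest$stages[[name]] <- list(status = "failed",
                                    error = conditionMessage(e))
    write_manifest(manifest, out)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e))
  }

  design <- do.call(study_design, config$design %||% list())
  truth <- do.call(ctl_params, config$synth$truth %||% list())

  ## synth
  ds <- tryCatch({
    log_stage("synth", "generating dataset (seed %d)", seed)
    ds <- generate_full_dataset(truth, design, seed = seed,
                                volume_sd = config$synth$volume_sd,
                                dispersion = config$synth$dispersion,
                                expression_noise = config$synth$expression_noise)
    utils::write.csv(ds$volumes, file.path(out, "volumes.csv"),
                     row.names = FALSE)
    utils::write.csv(ds$cryosections, file.path(out, "cryosections.csv"),
                     row.names = FALSE)
    write_expression_table(ds$expression, file.path(out, "expression.tsv"))
    write_observations(ds$observations, file.path(out, "observations.csv"))
    finish_stage("synth", seed)
    ds
  }, error = function(e) fail("synth", e))

  ## calibrate
  template <- tryCatch({
    gfit <- fit_exponential_growth(ds$volumes[ds$volumes$cohort == "untreated", ])
    un <- ds$cryosections[ds$cryosections$condition == "untreated", ]
    ratio <- mean(un$sgm_count / un$g1_count)
    k <- cycle_rates_from_growth(gfit$g, ratio)
    log_stage("calibrate", "g = %.3f, ratio = %.3f -> kgs = %.3f, ksg = %.3f",
              gfit$g, ratio, k["kgs"], k["ksg"])
    jsonlite::write_json(list(g = gfit$g, ratio = ratio,
                              kgs = unname(k["kgs"]), ksg = unname(k["ksg"])),
                         file.path(out, "calibration.json"),
                         auto_unbox = TRUE, digits = NA)
    finish_stage("calibrate")
    ctl_params(kgs = unname(k["kgs"]), ksg = unname(k["ksg"]))
  }, error = function(e) fail("calibrate", e))

  ## gridsearch (input-driven model on growth-rate + ratio data)
  tryCatch({
    obs <- as.data.frame(ds$observations)
    knE <- obs[obs$observable == "ctl_density", c("day", "mean")]
    knI <- obs[obs$observable == "ifng", c("day", "mean")]
    names(knE) <- names(knI) <- c("day", "value")
    knI$value <- pmax(knI$value, 0)
    inputs <- input_signals(knE, knI)
    gr_obs <- observation_set(
      obs[obs$observable %in% c("growth_rate", "ratio_sgm_g1"), ])
    gs <- grid_search_basic(
      gr_obs, inputs,
      ke_values = seq(0, config$grid$ke_max, by = config$grid$step),
      ki_values = seq(0, config$grid$ki_max, by = config$grid$step),
      params_template = template, V0 = design$V0)
    log_stage("gridsearch", "best ke = %.2f, ki = %.2f (logL %.2f)",
              gs$best["ke"], gs$best["ki"], gs$logL)
    utils::write.csv(gs$surface, file.path(out, "grid_surface.csv"),
                     row.names = FALSE)
    finish_stage("gridsearch")
  }, error = function(e) fail("gridsearch", e))

  ## variant fits
  fits <- tryCatch({
    fits <- lapply(config$fit$variants, function(v) {
      log_stage("fit", "variant %s (%d starts, seed %d)", v,
                config$fit$n_starts, seed + 10)
      f <- multistart_fit(ds$observations, variant = v,
                          n_starts = config$fit$n_starts, seed = seed + 10,
                          params_template = template, V0 = design$V0,
                          n_polish = config$fit$n_polish,
                          top_k = config$mcmc$n_aux + 1)
      write_fit_json(f, file.path(out, paste0("fit_", v, ".json")))
      f
    })
    finish_stage("fit", seed + 10)
    fits
  }, error = function(e) fail("fit", e))

  ## compare
  best <- tryCatch({
    tab <- compare_variants(fits)
    utils::write.csv(tab, file.path(out, "aic_table.csv"), row.names = FALSE)
    log_stage("compare", "best variant: %s (AIC %.2f)",
              tab$variant[1], tab$AIC[1])
    finish_stage("compare")
    fits[[match(tab$variant[1], vapply(fits, `[[`, "", "variant"))]]
  }, error = function(e) fail("compare", e))

  ## mcmc + posterior predictive
  tryCatch({
    post <- sample_posterior(best, ds$observations,
                             n_steps = config$mcmc$n_steps,
                             n_aux = config$mcmc$n_aux,
                             n_retain = config$mcmc$n_retain,
                             seed = seed + 20)
    write_posterior(post, file.path(out, "posterior_draws.csv"),
                    file.path(out, "posterior_meta.json"))
    ci <- credible_intervals(post)
    utils::write.csv(ci, file.path(out, "credible_intervals.csv"),
                     row.names = FALSE)
    pp <- posterior_predictive(post, n_draws = config$posterior$n_draws,
                               seed = seed + 30)
    if (!is.null(pp$trajectories))
      utils::write.csv(pp$trajectories,
                       file.path(out, "posterior_predictive.csv"),
                       row.names = FALSE)
    log_stage("mcmc", "main-chain acceptance %.2f", post$accept_rate[1])
    finish_stage("mcmc", seed + 20)
  }, error = function(e) fail("mcmc", e))

  ## report
  manifest <- tryCatch({
    finish_stage("report")
    m <- write_manifest(manifest, out, config)
    m
  }, error = function(e) fail("report", e))

  invisible(manifest)
}

write_manifest <- function(manifest, out, config = NULL) {
  files <- setdiff(list.files(out, full.names = TRUE),
                   file.path(out, "manifest.json"))
  manifest$files <- lapply(stats::setNames(files, basename(files)),
                           function(f) unname(tools::md5sum(f)))
  if (!is.null(config)) manifest$config <- config
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest
}

`%||%` <- function(a, b) if (is.null(a)) b else a
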