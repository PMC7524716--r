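#' Configuration for the end-to-end modeling pipeline
#'
#' Collects everything [run_pipeline()] needs: synthetic-data settings (or
#' file paths to pre-generated inputs), the model and objective mode,
#' calibration budget and bounds settings, significance level, and seeds.
#' Unknown keys are rejected so configuration typos fail before any
#' simulation.
#'
#' @param years simulated years.
#' @param seed master seed; stage seeds are derived from it.
#' @param model `"MEND"` or `"TECO"`.
#' @param mode objective mode (`"gMEND"`, `"tMEND"`, `"TECO"`).
#' @param q10_true named list/vector with `control` and `warming` generating
#'   Q10 values for the synthetic truth.
#' @param n_rh Rh observations per treatment.
#' @param sigma_rh,sigma_mbc,sigma_gene observation noise scales.
#' @param max_evals SCE evaluation budget per treatment.
#' @param region_iter,region_chains COFI region-chain settings per
#'   treatment (see [calibrate_model()]).
#' @param dt_calibration,dt_truth integration steps (days).
#' @param alpha COFI significance level.
#' @param spinup_cycles climatology passes before the truth run.
#' @param n_draws Monte-Carlo draws for the adaptation uncertainty.
#' @param forcing_path,observations_dir optional paths to pre-generated
#'   inputs; when `NULL` the synthetic module generates them.
#' @param out_dir output directory; `NULL` for a temporary directory.
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(years = 7, seed = 1, model = "MEND",
                            mode = "gMEND",
                            q10_true = list(control = 1.77, warming = 1.39),
                            n_rh = 74, sigma_rh = 0.2, sigma_mbc = 0.15,
                            sigma_gene = 0.1, max_evals = 3000,
                            region_iter = 2500, region_chains = 4,
                            dt_calibration = 0.5, dt_truth = 0.25,
                            alpha = 0.05, spinup_cycles = 8,
                            n_draws = 10000,
                            forcing_path = NULL, observations_dir = NULL,
                            out_dir = NULL) {
  cfg <- as.list(environment())
  validate_pipeline_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_pipeline_config <- function(cfg) {
  if (!cfg$model %in% c("MEND", "TECO")) abort("unknown model.")
  if (!cfg$mode %in% c("gMEND", "tMEND", "TECO")) abort("unknown mode.")
  if (cfg$model == "TECO" && cfg$mode != "TECO")
    abort("model TECO requires mode TECO.")
  if (cfg$years < 1) abort("`years` must be >= 1.")
  for (fld in c("forcing_path", "observations_dir")) {
    if (!is.null(cfg[[fld]]) && !file.exists(cfg[[fld]]))
      abort(paste0(fld, " does not exist: ", cfg[[fld]]))
  }
  invisible(cfg)
}

#' Read a pipeline configuration from a YAML file
#'
#' Strict: keys not understood by [pipeline_config()] are rejected.
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(raw), known)
  if (length(bad) > 0)
    abort(paste0("unknown configuration key(s): ", toString(bad)))
  do.call(pipeline_config, raw)
}

#' Run the full generate - simulate - calibrate - adapt pipeline
#'
#' Generates (or loads) paired control/warming forcing and observations,
#' spins the model up, calibrates each treatment independently with SCE,
#' filters COFI ensembles, extracts model-derived Q10 with percentile
#' intervals, and quantifies the thermal-adaptation effect with Monte-Carlo
#' uncertainty. All stage outputs are written under `out_dir` together with
#' a machine-readable `summary.yml` and a run log recording seeds.
#'
#' @param config a [pipeline_config()].
#' @return list of class `pipeline_result`: `calibrations` (per treatment),
#'   `q10` (tibble per treatment), `adaptation` ([adaptation_uncertainty()]
#'   output), `summary` (named list as written to `summary.yml`),
#'   `out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$out_dir %||% tempfile("gimend_run_")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  logline <- function(...) cat(..., "\n", file = log_path, append = TRUE,
                               sep = "")
  logline("gimend pipeline, seed = ", config$seed,
          ", model = ", config$model, ", mode = ", config$mode)

  if (config$mode == "gMEND" && !is.null(config$observations_dir)) {
    for (tr in c("control", "warming")) {
      gt <- file.path(config$observations_dir, tr, "genes.csv")
      if (!file.exists(gt))
        abort(paste0("mode gMEND requires a gene table; missing: ", gt))
    }
  }

  seed <- config$seed
  if (is.null(config$forcing_path)) {
    forcing <- gen_forcing(years = config$years, seed = seed)
    write_forcing(forcing, file.path(out_dir, "forcing.csv"))
  } else {
    forcing <- read_forcing(config$forcing_path)
  }
  f_ctl <- forcing_treatment(forcing, "control")
  f_wrm <- forcing_treatment(forcing, "warming")
  logline("forcing: ", nrow(f_ctl), " days per treatment")

  truth <- list(
    control = mend_params(q10 = config$q10_true$control),
    warming = mend_params(q10 = config$q10_true$warming)
  )
  obs <- list()
  init <- list()
  for (tr in c("control", "warming")) {
    f <- if (tr == "control") f_ctl else f_wrm
    init[[tr]] <- spinup_mend(f, truth[[tr]], cycles = config$spinup_cycles,
                              dt = config$dt_truth)
    if (is.null(config$observations_dir)) {
      obs[[tr]] <- gen_observations(
        f, truth[[tr]], init = init[[tr]], n_rh = config$n_rh,
        sigma_rh = config$sigma_rh, sigma_mbc = config$sigma_mbc,
        sigma_gene = config$sigma_gene, seed = seed + match(tr, c("control", "warming")),
        dt = config$dt_truth)
      write_observations(obs[[tr]], file.path(out_dir, "observations", tr))
    } else {
      obs[[tr]] <- read_observations(file.path(config$observations_dir, tr))
    }
  }
  logline("observations: ", nrow(obs$control$rh_obs), " Rh per treatment")

  ctl_seed <- seed + 11L
  wrm_seed <- seed + 12L
  control <- sce_control(max_evals = config$max_evals)
  cal <- list()
  cal$control <- calibrate_model(
    f_ctl, obs$control, model = config$model, mode = config$mode,
    init = init$control, control = control, dt = config$dt_calibration,
    alpha = config$alpha, region_iter = config$region_iter,
    region_chains = config$region_chains, seed = ctl_seed)
  logline("control calibration: J_min = ", signif(cal$control$j_min, 5),
          ", ensemble n = ", cal$control$ensemble$n_accepted)

  ce <- cg <- NULL
  if (config$mode == "gMEND") {
    ce <- cal$control$best_sim$annual_enzymes
    cg <- obs$control$genes
  }
  cal$warming <- calibrate_model(
    f_wrm, obs$warming, model = config$model, mode = config$mode,
    init = init$warming, control = control, dt = config$dt_calibration,
    alpha = config$alpha, region_iter = config$region_iter,
    region_chains = config$region_chains, seed = wrm_seed,
    control_enzymes = ce, control_genes = cg)
  logline("warming calibration: J_min = ", signif(cal$warming$j_min, 5),
          ", ensemble n = ", cal$warming$ensemble$n_accepted)

  for (tr in c("control", "warming")) {
    readr::write_csv(cal[[tr]]$fit$archive,
                     file.path(out_dir, paste0("archive_", tr, ".csv")))
    readr::write_csv(cal[[tr]]$ensemble$summary,
                     file.path(out_dir, paste0("ensemble_", tr, ".csv")))
  }

  q10 <- dplyr::bind_rows(
    control = model_derived_q10(cal$control),
    warming = model_derived_q10(cal$warming),
    .id = "treatment")

  t_ctl <- mean(f_ctl$soil_temp)
  t_warm <- mean(f_wrm$soil_temp)
  rh_baseline <- mean(obs$control$rh_obs$value)
  adapt <- adaptation_uncertainty(
    cal$control$ensemble$sets$q10, cal$warming$ensemble$sets$q10,
    t_ctl, t_warm, rh_baseline, n_draws = config$n_draws,
    seed = seed + 21L)

  summary <- list(
    seed = seed,
    model = config$model, mode = config$mode,
    best_params = lapply(cal, function(x) as.list(x$best_theta)),
    j_components = lapply(cal, function(x) as.list(x$j_components)),
    j_min = lapply(cal, function(x) x$j_min),
    j_critical = lapply(cal, function(x) x$j_critical),
    aic = lapply(cal, function(x) x$aic),
    mean_cv = lapply(cal, function(x) mean(x$ensemble$summary$cv)),
    q10 = lapply(split(q10, q10$treatment), as.list),
    adaptation = as.list(adapt$summary),
    t_ctl = t_ctl, t_warm = t_warm, rh_baseline = rh_baseline
  )
  yaml::write_yaml(summary, file.path(out_dir, "summary.yml"))
  logline("done; summary written")

  structure(list(calibrations = cal, q10 = q10, adaptation = adapt,
                 observations = obs, forcing = forcing,
                 summary = summary, out_dir = out_dir),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result> ", x$summary$model, "/", x$summary$mode, "\n",
      sep = "")
  print(x$q10)
  cat("adaptation %dRh: ", signif(x$adaptation$summary$mean_pct, 3),
      " +/- ", signif(x$adaptation$summary$sd_pct, 3), "\n", sep = "")
  invisible(x)
}
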