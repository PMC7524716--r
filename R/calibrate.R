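#' Default calibration bounds for the MEND model
#'
#' The default calibrated set has 11 parameters: `q10`, `cue`, the three
#' maximum decomposition rates, the DOM uptake kinetics (`v_uptake`,
#' `k_uptake`), a shared enzyme-production scale `p_enz_scale` (multiplies
#' both POM enzyme production rates), enzyme turnover `r_enz`, mortality
#' `k_mortality` and maintenance `k_maint`. The Q10 prior range defaults to
#' \[1.2, 2.5\] (the range of apparent Q10 estimates); `cue` to
#' \[0.2, 0.7\]; rate parameters to one third to three times their defaults.
#' Priors are uniform on these ranges.
#'
#' @param params base [mend_params()] around which rate bounds are placed.
#' @param calibrate character vector of parameters to calibrate.
#' @param q10_range,cue_range explicit ranges for `q10` and `cue`.
#' @param rate_spread multiplicative half-width for rate parameters
#'   (default 10: bounds are default/10 to default*10).
#' @return tibble with columns `parameter`, `lower`, `upper`.
#' @export
mend_calib_bounds <- function(params = mend_params(),
                              calibrate = c("q10", "cue", "vmax_ox",
                                            "vmax_hyd", "vmax_mom",
                                            "v_uptake", "k_uptake",
                                            "p_enz_scale", "r_enz",
                                            "k_mortality", "k_maint"),
                              q10_range = c(1.2, 2.5),
                              cue_range = c(0.2, 0.7),
                              rate_spread = 10) {
  purrr::map_dfr(calibrate, function(pn) {
    if (pn == "q10")
      return(tibble::tibble(parameter = pn, lower = q10_range[1],
                            upper = q10_range[2]))
    if (pn == "cue")
      return(tibble::tibble(parameter = pn, lower = cue_range[1],
                            upper = cue_range[2]))
    if (pn == "p_enz_scale")
      return(tibble::tibble(parameter = pn, lower = 1 / rate_spread,
                            upper = rate_spread))
    if (!pn %in% names(params))
      abort(paste0("unknown MEND parameter: ", pn))
    v <- unname(params[pn])
    tibble::tibble(parameter = pn, lower = v / rate_spread,
                   upper = v * rate_spread)
  })
}

#' Default calibration bounds for the TECO model
#'
#' The default calibrated set has 10 parameters: `q10`, the 7 pool turnover
#' rates and the 2 moisture-response shape parameters (`w_fc`, `w_exp`).
#'
#' @param params base [teco_params()].
#' @param q10_range Q10 prior range.
#' @param rate_spread multiplicative half-width for turnover rates.
#' @return tibble with columns `parameter`, `lower`, `upper`.
#' @export
teco_calib_bounds <- function(params = teco_params(),
                              q10_range = c(1.2, 2.5), rate_spread = 3) {
  dplyr::bind_rows(
    tibble::tibble(parameter = "q10", lower = q10_range[1],
                   upper = q10_range[2]),
    tibble::tibble(parameter = paste0("turnover.", params$pools),
                   lower = as.numeric(params$turnover) / rate_spread,
                   upper = as.numeric(params$turnover) * rate_spread),
    tibble::tibble(parameter = c("w_fc", "w_exp"),
                   lower = c(0.15, 0.5), upper = c(0.6, 2))
  )
}

apply_mend_theta <- function(base, theta) {
  th <- theta
  if ("p_enz_scale" %in% names(th)) {
    s <- th[["p_enz_scale"]]
    base <- set_params(base, c(p_enz_ox = unname(base["p_enz_ox"]) * s,
                               p_enz_hyd = unname(base["p_enz_hyd"]) * s))
    th <- th[names(th) != "p_enz_scale"]
  }
  if (length(th) > 0) base <- set_params(base, th)
  base
}

apply_teco_theta <- function(base, theta) {
  for (nmv in names(theta)) {
    v <- theta[[nmv]]
    if (startsWith(nmv, "turnover.")) {
      base$turnover[sub("^turnover\\.", "", nmv)] <- v
    } else if (nmv %in% c("q10", "t_ref", "w_fc", "w_exp")) {
      base[[nmv]] <- v
    } else {
      abort(paste0("unknown TECO parameter: ", nmv))
    }
  }
  base
}

#' Calibrate MEND or TECO against an observation set
#'
#' Assembles the weighted multi-objective function for the chosen mode
#' (tMEND, gMEND, or TECO), minimizes it with [sce_optimize()], and filters
#' the full evaluation archive through the COFI threshold into a parameter
#' uncertainty ensemble. The observation count `n` used by the COFI
#' criterion defaults to the number of Rh observations, which dominate the
#' objective.
#'
#' @param forcing single-treatment forcing tibble.
#' @param obs observation set for the same treatment.
#' @param model `"MEND"` or `"TECO"`.
#' @param mode objective mode; defaults to `"gMEND"` for MEND and `"TECO"`
#'   for TECO.
#' @param base_params full parameter object supplying the non-calibrated
#'   values; default [mend_params()] / [teco_params()].
#' @param init initial pool state (e.g. from [spinup_mend()]); `NULL` uses
#'   the model default.
#' @param bounds bounds tibble ([mend_calib_bounds()] /
#'   [teco_calib_bounds()]).
#' @param control [sce_control()] settings.
#' @param dt integration step used inside the objective (0.5 d is a good
#'   calibration compromise; verify the optimum at a finer step).
#' @param alpha COFI significance level.
#' @param n_obs observation count for the COFI threshold.
#' @param region_iter length of the [cofi_region_sample()] chain used to
#'   build the uncertainty ensemble; the optimizer's archive concentrates
#'   around the optimum and would understate the confidence region, so the
#'   ensemble is taken from uniform-over-region chains. Set to 0 to
#'   filter the raw archive instead (default 2500, split across chains).
#' @param region_chains number of region chains, started from mutually
#'   distant archive points inside the region (default 4).
#' @param seed integer seed.
#' @param control_enzymes,control_genes forwarded to
#'   [objective_components()] for warming-mode gMEND.
#' @param penalty finite objective value substituted when a parameter set
#'   makes the simulation fail.
#' @return object of class `calibration_result`: `fit` ([sce_optimize()]
#'   result), `ensemble` ([cofi_ensemble()]), `best_params` (full parameter
#'   object), `best_sim`, `j_components`, `spec`, `j_critical`, `aic`.
#' @export
calibrate_model <- function(forcing, obs, model = c("MEND", "TECO"),
                            mode = NULL, base_params = NULL, init = NULL,
                            bounds = NULL, control = sce_control(),
                            dt = 0.5, alpha = 0.05, n_obs = NULL,
                            region_iter = 2500, region_chains = 4,
                            seed = 1,
                            control_enzymes = NULL,
                            control_genes = NULL, penalty = 1e6) {
  model <- match.arg(model)
  treatment <- forcing$treatment[1]
  if (is.null(mode)) mode <- if (model == "MEND") "gMEND" else "TECO"
  spec <- objective_spec(mode, treatment)
  if (model == "TECO" && mode != "TECO")
    abort("TECO supports only the respiration objective.")

  if (is.null(base_params))
    base_params <- if (model == "MEND") mend_params() else teco_params()
  if (is.null(bounds))
    bounds <- if (model == "MEND") mend_calib_bounds(base_params)
              else teco_calib_bounds(base_params)

  simulate_theta <- function(theta) {
    if (model == "MEND") {
      pars <- apply_mend_theta(base_params, theta)
      simulate_mend(forcing, pars, init = init, dt = dt)
    } else {
      pars <- apply_teco_theta(base_params, theta)
      simulate_teco(forcing, pars, init = init, dt = dt)
    }
  }
  objective <- function(x) {
    theta <- stats::setNames(as.numeric(x), bounds$parameter)
    sim <- tryCatch(simulate_theta(theta), error = function(e) NULL)
    if (is.null(sim)) return(penalty)
    jc <- tryCatch(
      objective_components(sim, obs, spec,
                           control_enzymes = control_enzymes,
                           control_genes = control_genes),
      error = function(e) NULL)
    if (is.null(jc)) return(penalty)
    overall_objective(jc, spec$weights)
  }

  lower <- stats::setNames(bounds$lower, bounds$parameter)
  upper <- stats::setNames(bounds$upper, bounds$parameter)
  fit <- sce_optimize(objective, lower, upper, control = control,
                      seed = seed)

  if (is.null(n_obs)) n_obs <- nrow(obs$rh_obs)
  p_cal <- sum(upper > lower)
  j_cr <- cofi_threshold(fit$j_min, p_cal, n_obs, alpha)
  if (region_iter > 0) {
    # The archive over-represents the optimum's neighbourhood, so the
    # ensemble comes from uniform-over-region chains instead. Multiple
    # chains are started from mutually distant archive points inside the
    # region: the region can be a curved ridge in 11 dimensions that a
    # single random walk traverses too slowly.
    starts <- region_chain_starts(fit$archive, bounds$parameter, j_cr,
                                  lower, upper, region_chains,
                                  fit$best_par)
    per <- ceiling(region_iter / length(starts))
    pool <- purrr::map_dfr(seq_along(starts), function(k) {
      cofi_region_sample(objective, lower, upper, j_cr,
                         start = starts[[k]], n_iter = per,
                         seed = seed + k)
    })
  } else {
    pool <- fit$archive[, c(bounds$parameter, "j")]
  }
  ens <- cofi_ensemble(pool, j_cr, params = bounds$parameter)

  best_theta <- fit$best_par
  best_sim <- simulate_theta(best_theta)
  j_comp <- objective_components(best_sim, obs, spec,
                                 control_enzymes = control_enzymes,
                                 control_genes = control_genes)
  best_full <- if (model == "MEND") apply_mend_theta(base_params, best_theta)
               else apply_teco_theta(base_params, best_theta)

  idx <- match(obs$rh_obs$date, best_sim$daily$date)
  sse <- sum((best_sim$daily$rh_area[idx] - obs$rh_obs$value)^2)
  aic <- aic_sse(nrow(obs$rh_obs), sse, p_cal)

  structure(list(
    fit = fit,
    ensemble = ens,
    best_params = best_full,
    best_theta = best_theta,
    best_sim = best_sim,
    j_components = j_comp,
    j_min = fit$j_min,
    j_critical = j_cr,
    aic = aic,
    spec = spec,
    model = model,
    treatment = treatment,
    n_obs = n_obs,
    alpha = alpha,
    seed = seed,
    dt = dt
  ), class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("<calibration_result> ", x$model, " / ", x$spec$mode, " / ",
      x$treatment, "\n", sep = "")
  cat("  J_min = ", signif(x$j_min, 4), ", J_cr = ", signif(x$j_critical, 4),
      ", ensemble n = ", x$ensemble$n_accepted, ", AIC = ",
      signif(x$aic, 5), "\n", sep = "")
  cat("  components: ",
      paste(names(x$j_components), signif(x$j_components, 3),
            sep = " = ", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Model-derived Q10 point estimate and confidence interval
#'
#' Extracts the temperature-sensitivity parameter from a calibration: the
#' best-fit value plus a confidence interval over the COFI (or MCMC)
#' accepted parameter sets. The default interval is the projection of the
#' confidence region onto the Q10 axis (the min-max of accepted sets):
#' the projection of a joint 95% region is a valid, conservative interval
#' for a single parameter, and unlike draw percentiles it does not depend
#' on how the region's volume happens to be distributed across the other
#' parameters. Percentile intervals of the draws are also available.
#'
#' @param x a `calibration_result`, `parameter_ensemble`, or numeric vector
#'   of Q10 draws.
#' @param parameter name of the Q10 column (default `"q10"`).
#' @param level interval coverage for `ci_method = "percentile"`.
#' @param ci_method `"projection"` (region extent, default) or
#'   `"percentile"` (draw quantiles).
#' @return tibble with `estimate`, `mean`, `sd`, `lower`, `upper`, `n`.
#' @export
model_derived_q10 <- function(x, parameter = "q10", level = 0.95,
                              ci_method = c("projection", "percentile")) {
  ci_method <- match.arg(ci_method)
  if (inherits(x, "calibration_result")) {
    draws <- x$ensemble$sets[[parameter]]
    est <- unname(x$best_theta[parameter])
  } else if (inherits(x, "parameter_ensemble")) {
    draws <- x$sets[[parameter]]
    est <- mean(draws)
  } else {
    draws <- as.numeric(x)
    est <- mean(draws)
  }
  if (is.null(draws) || length(draws) == 0) abort("no Q10 draws available.")
  if (ci_method == "projection") {
    lo <- min(draws); hi <- max(draws)
  } else {
    a <- (1 - level) / 2
    lo <- quantile(draws, a, names = FALSE)
    hi <- quantile(draws, 1 - a, names = FALSE)
  }
  tibble::tibble(
    estimate = est, mean = mean(draws), sd = sd(draws),
    lower = lo, upper = hi,
    n = length(draws)
  )
}

# pick `n` mutually distant archive points inside the confidence region
# (greedy maximin on box-normalised coordinates, seeded with the best fit)
region_chain_starts <- function(archive, par_names, j_cr, lower, upper,
                                n, best_par) {
  inside <- archive[archive$j < j_cr, par_names, drop = FALSE]
  starts <- list(best_par)
  if (nrow(inside) == 0 || n <= 1) return(starts)
  width <- pmax(upper - lower, .Machine$double.eps)
  norm <- sweep(sweep(as.matrix(inside), 2, lower[par_names]), 2,
                width[par_names], "/")
  chosen <- matrix((best_par[par_names] - lower[par_names]) /
                     width[par_names], nrow = 1)
  for (k in seq_len(n - 1)) {
    d2 <- apply(norm, 1, function(r) min(colSums((t(chosen) - r)^2)))
    pick <- which.max(d2)
    chosen <- rbind(chosen, norm[pick, ])
    full <- lower
    full[par_names] <- as.numeric(inside[pick, ])
    starts <- c(starts, list(full))
  }
  starts
}
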