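#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a model simulation
#'
#' Returns the daily trajectory in long form: one row per date, variable
#' and value.
#'
#' @param x a `mend_sim` or `teco_sim`.
#' @param ... unused.
#' @return tibble with `date`, `variable`, `value`.
#' @export
tidy.mend_sim <- function(x, ...) {
  tidyr::pivot_longer(x$daily, -"date", names_to = "variable",
                      values_to = "value")
}

#' Glance at a model simulation
#'
#' @param x a `mend_sim` or `teco_sim`.
#' @param ... unused.
#' @return one-row tibble: `n_days`, `mean_rh_area`, `cum_rh`,
#'   `balance_residual`, `relative_balance_error`, `model`, `dt`.
#' @export
glance.mend_sim <- function(x, ...) {
  tibble::tibble(
    n_days = nrow(x$daily),
    mean_rh_area = mean(x$daily$rh_area),
    cum_rh = sum(x$daily$rh),
    balance_residual = x$balance_residual,
    relative_balance_error = x$relative_balance_error,
    model = x$model,
    dt = x$dt
  )
}

#' Tidy an SCE optimization
#'
#' @param x an `sce_fit`.
#' @param ... unused.
#' @return the evaluation archive tibble (parameters, `j`, `eval`).
#' @export
tidy.sce_fit <- function(x, ...) x$archive

#' @export
glance.sce_fit <- function(x, ...) {
  tibble::tibble(j_min = x$j_min, n_evals = x$n_evals,
                 converged = x$converged, seed = x$seed)
}

#' Tidy a COFI parameter ensemble
#'
#' @param x a `parameter_ensemble`.
#' @param ... unused.
#' @return the per-parameter summary tibble (`parameter`, `mean`, `sd`,
#'   `cv`, `q2.5`, `q97.5`).
#' @export
tidy.parameter_ensemble <- function(x, ...) x$summary

#' @export
glance.parameter_ensemble <- function(x, ...) {
  tibble::tibble(n_accepted = x$n_accepted, j_critical = x$j_critical,
                 mean_cv = mean(x$summary$cv))
}

#' Tidy a calibration result
#'
#' @param x a `calibration_result`.
#' @param ... unused.
#' @return per-parameter tibble joining the best-fit value with the COFI
#'   ensemble summary.
#' @export
tidy.calibration_result <- function(x, ...) {
  dplyr::left_join(
    tibble::tibble(parameter = names(x$best_theta),
                   estimate = as.numeric(x$best_theta)),
    x$ensemble$summary, by = "parameter")
}

#' @export
glance.calibration_result <- function(x, ...) {
  tibble::tibble(
    model = x$model, mode = x$spec$mode, treatment = x$treatment,
    j_min = x$j_min, j_critical = x$j_critical,
    n_ensemble = x$ensemble$n_accepted,
    mean_cv = mean(x$ensemble$summary$cv),
    aic = x$aic, n_obs = x$n_obs, n_evals = x$fit$n_evals
  )
}

#' Tidy an apparent-Q10 fit
#'
#' @param x a `q10_fit`.
#' @param ... unused.
#' @return one-row tibble: `q10_hat`, `r_tref`, `se`, `p_value`, `n`,
#'   `method`.
#' @export
tidy.q10_fit <- function(x, ...) {
  tibble::tibble(q10_hat = x$q10_hat, r_tref = x$r_tref, se = x$se,
                 p_value = x$p_value, t_ref = x$t_ref, n = x$n,
                 method = x$method)
}

#' Tidy a Monte-Carlo adaptation analysis
#'
#' @param x an `adaptation_mc`.
#' @param ... unused.
#' @return the per-draw tibble of fluxes and percentage effects.
#' @export
tidy.adaptation_mc <- function(x, ...) x$draws

#' @export
glance.adaptation_mc <- function(x, ...) x$summary

#' @export
tidy.mcmc_fit <- function(x, ...) x$draws

#' @export
glance.mcmc_fit <- function(x, ...) {
  tibble::tibble(n_draws = nrow(x$draws),
                 acceptance_rate = x$acceptance_rate,
                 temperature = x$temperature,
                 max_split_diag = max(x$converged_diag))
}
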