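#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_col
#'   geom_hline geom_errorbar geom_histogram facet_wrap labs theme_minimal
NULL

#' @export
ggplot2::autoplot

#' Plot a daily simulation
#'
#' Daily heterotrophic respiration (area units) over time.
#'
#' @param object a `mend_sim` or `teco_sim`.
#' @param variables columns of `object$daily` to draw.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.mend_sim <- function(object, variables = "rh_area", ...) {
  d <- tidy(object) |>
    dplyr::filter(.data$variable %in% variables)
  ggplot(d, aes(x = .data$date, y = .data$value)) +
    geom_line(colour = "steelblue") +
    facet_wrap(~variable, scales = "free_y", ncol = 1) +
    labs(x = NULL, y = NULL,
         title = paste(object$model, "daily simulation")) +
    theme_minimal()
}

#' Plot SCE convergence
#'
#' Running best objective value against evaluation count.
#'
#' @param object an `sce_fit`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.sce_fit <- function(object, ...) {
  d <- object$archive |>
    dplyr::mutate(best = cummin(.data$j))
  ggplot(d, aes(x = .data$eval, y = .data$best)) +
    geom_line() +
    labs(x = "objective evaluations", y = "best J",
         title = "SCE-UA convergence") +
    theme_minimal()
}

#' Plot a COFI parameter ensemble
#'
#' Coefficient of variation per calibrated parameter.
#'
#' @param object a `parameter_ensemble`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.parameter_ensemble <- function(object, ...) {
  ggplot(object$summary,
         aes(x = stats::reorder(.data$parameter, .data$cv), y = .data$cv)) +
    geom_col(fill = "grey40") +
    labs(x = NULL, y = "coefficient of variation",
         title = "Parameter uncertainty (COFI ensemble)") +
    theme_minimal()
}

#' Plot the Monte-Carlo adaptation distribution
#'
#' Histogram of the percentage reduction in heterotrophic respiration due
#' to thermal adaptation, with the ensemble mean marked.
#'
#' @param object an `adaptation_mc`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.adaptation_mc <- function(object, ...) {
  ggplot(object$draws, aes(x = .data$pct_delta_rh)) +
    geom_histogram(bins = 60, fill = "grey40") +
    ggplot2::geom_vline(xintercept = object$summary$mean_pct,
                        colour = "firebrick") +
    labs(x = "%dRh (reduction due to thermal adaptation)", y = "draws",
         title = "Thermal-adaptation effect") +
    theme_minimal()
}

#' Observed versus simulated respiration
#'
#' Scatter of simulated against observed Rh at the observation dates, with
#' the 1:1 line.
#'
#' @param result a `calibration_result`.
#' @param obs the observation set used in the calibration.
#' @return a ggplot.
#' @export
plot_fit <- function(result, obs) {
  daily <- result$best_sim$daily
  idx <- match(obs$rh_obs$date, daily$date)
  d <- tibble::tibble(observed = obs$rh_obs$value,
                      simulated = daily$rh_area[idx])
  ggplot(d, aes(x = .data$observed, y = .data$simulated)) +
    geom_point(alpha = 0.7) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    labs(x = "observed Rh (g C m-2 d-1)", y = "simulated Rh (g C m-2 d-1)",
         title = paste0(result$spec$mode, " fit, ", result$treatment,
                        " (R2 = ",
                        signif(1 - unname(result$j_components["rh"]), 3),
                        ")")) +
    theme_minimal()
}
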