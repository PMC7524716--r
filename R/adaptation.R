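#' Q10-type respiration at a given temperature
#'
#' `R(T) = R(t_anchor) * q10^((T - t_anchor) / 10)`. The anchor is explicit:
#' the same exponential curve can be anchored at the model reference
#' temperature (10 degrees C) or at the mean annual control soil temperature
#' (17 degrees C), and re-anchoring along the curve leaves predictions
#' unchanged.
#'
#' @param r_ref respiration at the anchor temperature, g C m-2 d-1 (> 0).
#' @param q10 temperature sensitivity (> 0).
#' @param temp evaluation temperature, degrees C.
#' @param t_anchor anchor temperature, degrees C.
#' @return respiration at `temp`, g C m-2 d-1.
#' @examples
#' q10_respiration(1.84, 1.39, 20, 17)  # about 2.03
#' @export
q10_respiration <- function(r_ref, q10, temp, t_anchor = 10) {
  if (any(r_ref <= 0)) abort("`r_ref` must be > 0.")
  if (any(q10 <= 0)) abort("`q10` must be > 0.")
  r_ref * q10^((temp - t_anchor) / 10)
}

#' Fit apparent Q10 to respiration-temperature observations
#'
#' Fits `R(T) = R(t_ref) * q10^((T - t_ref)/10)` by nonlinear least squares
#' (Levenberg-Marquardt), initialised from a log-linear regression of
#' `log(R)` on `(T - t_ref)/10`. The log-linear slope test supplies the
#' p-value for temperature dependence. Non-positive respiration values are
#' rejected with a count.
#'
#' @param data data frame with the observation columns.
#' @param rh,temp column names of respiration and soil temperature.
#' @param t_ref reference temperature, degrees C.
#' @return object of class `q10_fit`: list with `q10_hat`, `r_tref`, `se`,
#'   `p_value`, `t_ref`, `n`, `method`.
#' @examples
#' d <- data.frame(temp = seq(5, 30, 2),
#'                 rh = 1.5 * 1.5^((seq(5, 30, 2) - 10) / 10))
#' fit_apparent_q10(d, rh = "rh", temp = "temp")$q10_hat  # 1.5
#' @export
fit_apparent_q10 <- function(data, rh = "rh", temp = "soil_temp",
                             t_ref = 10) {
  r <- data[[rh]]
  tt <- data[[temp]]
  if (is.null(r) || is.null(tt)) abort("columns not found in `data`.")
  bad <- sum(r <= 0, na.rm = TRUE) + sum(is.na(r) | is.na(tt))
  keep <- !is.na(r) & !is.na(tt) & r > 0
  if (bad > 0)
    warn(paste0(bad, " non-positive or missing observation(s) dropped."))
  r <- r[keep]; tt <- tt[keep]
  if (length(r) < 3) abort("need at least 3 usable paired points.")
  if (diff(range(tt)) == 0) abort("temperature range is zero.")

  z <- (tt - t_ref) / 10
  ll <- lm(log(r) ~ z)
  q10_0 <- exp(coef(ll)[["z"]])
  r0 <- exp(coef(ll)[["(Intercept)"]])
  # noiseless inputs are legitimate; silence the perfect-fit notice
  sll <- suppressWarnings(summary(ll))
  p_value <- sll$coefficients["z", "Pr(>|t|)"]

  fit <- tryCatch(
    minpack.lm::nlsLM(r ~ a * q10^z, start = list(a = r0, q10 = q10_0),
                      lower = c(1e-12, 1e-6)),
    error = function(e) NULL)
  if (is.null(fit)) {
    out <- list(q10_hat = q10_0, r_tref = r0,
                se = q10_0 * sll$coefficients["z", "Std. Error"],
                method = "log-linear")
  } else {
    s <- summary(fit)$coefficients
    out <- list(q10_hat = s["q10", "Estimate"], r_tref = s["a", "Estimate"],
                se = s["q10", "Std. Error"], method = "nls")
  }
  structure(c(out, list(p_value = p_value, t_ref = t_ref, n = length(r))),
            class = "q10_fit")
}

#' @export
print.q10_fit <- function(x, ...) {
  cat("<q10_fit> Q10 = ", signif(x$q10_hat, 4), " +/- ", signif(x$se, 3),
      " (", x$method, ", n = ", x$n, ", p = ", format(signif(x$p_value, 3)),
      ")\n", sep = "")
  invisible(x)
}

#' Thermal-adaptation effect on heterotrophic respiration
#'
#' Quantifies how much heterotrophic respiration is reduced by thermal
#' adaptation. Both warming fluxes are anchored at the baseline control
#' flux and temperature: with adaptation, warming Rh uses the
#' warming-calibrated Q10; without adaptation it keeps the control Q10.
#' The effect is `delta = Rh_woA - Rh_wA` and the percentage effect is
#' `100 * delta / Rh_baseline`.
#'
#' @param q10_ctl,q10_warm model-derived Q10 under control and warming.
#' @param t_ctl,t_warm mean annual soil temperature, degrees C.
#' @param rh_baseline mean control Rh at `t_ctl`, g C m-2 d-1.
#' @return tibble of class `adaptation_result` with `rh_ct`, `rh_wa`,
#'   `rh_woa`, `delta_rh`, `pct_delta_rh`, `q10_ctl`, `q10_warm`, `t_ctl`,
#'   `t_warm`.
#' @examples
#' adaptation_effect(1.77, 1.39, 17, 20, 1.84)
#' @export
adaptation_effect <- function(q10_ctl, q10_warm, t_ctl, t_warm,
                              rh_baseline) {
  if (any(c(q10_ctl, q10_warm, rh_baseline) <= 0))
    abort("Q10 values and the baseline flux must be > 0.")
  rh_wa <- q10_respiration(rh_baseline, q10_warm, t_warm, t_ctl)
  rh_woa <- q10_respiration(rh_baseline, q10_ctl, t_warm, t_ctl)
  delta <- rh_woa - rh_wa
  out <- tibble::tibble(
    rh_ct = rh_baseline, rh_wa = rh_wa, rh_woa = rh_woa,
    delta_rh = delta, pct_delta_rh = 100 * delta / rh_baseline,
    q10_ctl = q10_ctl, q10_warm = q10_warm, t_ctl = t_ctl, t_warm = t_warm
  )
  class(out) <- c("adaptation_result", class(out))
  out
}

#' Thermal-adaptation effect with Monte-Carlo uncertainty
#'
#' Propagates Q10 parameter uncertainty through [adaptation_effect()] by
#' independently drawing from the control and warming Q10 ensembles,
#' reporting the mean, SD and a 95% percentile interval of the percentage
#' effect, and a Kruskal-Wallis test comparing the with- and
#' without-adaptation flux draws.
#'
#' @param q10_ctl_draws,q10_warm_draws numeric ensembles of Q10 values
#'   (e.g. the COFI-accepted sets).
#' @inheritParams adaptation_effect
#' @param n_draws Monte-Carlo sample size (default 10000).
#' @param seed integer seed.
#' @return list of class `adaptation_mc`: `summary` tibble (`mean_pct`,
#'   `sd_pct`, `lower_pct`, `upper_pct`, `mean_rh_wa`, `mean_rh_woa`,
#'   `kw_p`), `draws` tibble, plus the point-estimate `effect` at the
#'   ensemble means.
#' @export
adaptation_uncertainty <- function(q10_ctl_draws, q10_warm_draws,
                                   t_ctl, t_warm, rh_baseline,
                                   n_draws = 10000, seed = 1) {
  if (length(q10_ctl_draws) == 0 || length(q10_warm_draws) == 0)
    abort("ensembles must be non-empty.")
  old <- .Random.seed_exists()
  set.seed(seed)
  on.exit(old(), add = TRUE)
  qc <- sample(q10_ctl_draws, n_draws, replace = TRUE)
  qw <- sample(q10_warm_draws, n_draws, replace = TRUE)
  eff <- adaptation_effect(qc, qw, t_ctl, t_warm, rh_baseline)

  kw_p <- NA_real_
  if (length(unique(eff$rh_wa)) > 1 || length(unique(eff$rh_woa)) > 1) {
    kw <- kruskal.test(list(eff$rh_wa, eff$rh_woa))
    kw_p <- kw$p.value
  }
  summ <- tibble::tibble(
    mean_pct = mean(eff$pct_delta_rh),
    sd_pct = sd(eff$pct_delta_rh),
    lower_pct = quantile(eff$pct_delta_rh, 0.025, names = FALSE),
    upper_pct = quantile(eff$pct_delta_rh, 0.975, names = FALSE),
    mean_rh_wa = mean(eff$rh_wa),
    mean_rh_woa = mean(eff$rh_woa),
    kw_p = kw_p,
    n_draws = n_draws
  )
  point <- adaptation_effect(mean(q10_ctl_draws), mean(q10_warm_draws),
                             t_ctl, t_warm, rh_baseline)
  structure(list(summary = summ, draws = eff, effect = point, seed = seed),
            class = "adaptation_mc")
}

#' @export
print.adaptation_mc <- function(x, ...) {
  s <- x$summary
  cat("<adaptation_mc> %dRh = ", signif(s$mean_pct, 3), " +/- ",
      signif(s$sd_pct, 3), " [", signif(s$lower_pct, 3), ", ",
      signif(s$upper_pct, 3), "]  (", s$n_draws, " draws)\n", sep = "")
  invisible(x)
}

#' Single-factor temperature / moisture attribution scenarios
#'
#' Runs the calibrated MEND model under four forcing scenarios: control,
#' control with the warming temperature only, control with the warming
#' moisture only, and full warming; reports the mean Rh of each scenario
#' and its percentage change relative to control. With Q10 > 1 and a
#' warming temperature offset, the temperature-only change is positive; a
#' warming-reduced moisture gives a negative moisture-only change.
#'
#' @param params calibrated [mend_params()].
#' @param forcing_ctl,forcing_warm day-aligned single-treatment forcing
#'   tibbles.
#' @param init initial state (e.g. spun up under control).
#' @param dt integration step.
#' @return tibble of class `scenario_table`: `scenario`, `mean_rh`
#'   (g C m-2 d-1), `pct_change`.
#' @export
single_factor_scenarios <- function(params, forcing_ctl, forcing_warm,
                                    init = NULL, dt = 0.5) {
  if (nrow(forcing_ctl) != nrow(forcing_warm) ||
      any(forcing_ctl$date != forcing_warm$date))
    abort("control and warming forcing must be day-aligned.")
  t_only <- forcing_ctl
  t_only$soil_temp <- forcing_warm$soil_temp
  w_only <- forcing_ctl
  w_only$moisture <- forcing_warm$moisture
  run <- function(f) {
    mean(simulate_mend(f, params, init = init, dt = dt)$daily$rh_area)
  }
  means <- c(control = run(forcing_ctl), `T-only` = run(t_only),
             `W-only` = run(w_only), warming = run(forcing_warm))
  out <- tibble::tibble(
    scenario = names(means),
    mean_rh = as.numeric(means),
    pct_change = 100 * (as.numeric(means) / means[["control"]] - 1)
  )
  class(out) <- c("scenario_table", class(out))
  out
}

#' Partition soil respiration fluxes
#'
#' `partition_respiration()` computes autotrophic respiration as the
#' difference between total and heterotrophic soil respiration
#' (`ra = rt - rh`); negative values are permitted but flagged with a
#' warning. `derive_gpp()` derives gross primary productivity from net
#' ecosystem exchange and ecosystem respiration under the sink-positive
#' sign convention (positive NEE = net carbon sink), i.e. `gpp = nee + er`.
#'
#' @param rt,rh total and heterotrophic respiration (same units, `rt >= 0`).
#' @return numeric vector (`ra` or `gpp`).
#' @examples
#' partition_respiration(3.2, 1.84)
#' derive_gpp(2, 5)  # 7
#' @export
partition_respiration <- function(rt, rh) {
  if (any(rt < 0)) abort("`rt` must be >= 0.")
  ra <- rt - rh
  if (any(ra < 0)) warn("negative autotrophic respiration (rh > rt).")
  ra
}

#' @rdname partition_respiration
#' @param nee net ecosystem exchange (positive = sink).
#' @param er ecosystem respiration (positive).
#' @export
derive_gpp <- function(nee, er) {
  nee + er
}

#' Warming response ratio with delta-method confidence interval
#'
#' `RR = ln(mean(warming) / mean(control))`, the standard warming-effect
#' statistic for gene-abundance data, with a 95% confidence interval from
#' the delta-method standard error
#' `sqrt(sd_w^2 / (n_w mean_w^2) + sd_c^2 / (n_c mean_c^2))`. The effect is
#' significant when the interval excludes zero.
#'
#' @param warming_vals,control_vals numeric vectors (positive means; >= 2
#'   values each for the interval).
#' @param level interval coverage (default 0.95).
#' @return tibble: `rr`, `se`, `lower`, `upper`, `significant`.
#' @examples
#' response_ratio(c(2, 2.2, 1.9), c(1, 1.1, 0.9))
#' @export
response_ratio <- function(warming_vals, control_vals, level = 0.95) {
  mw <- mean(warming_vals); mc <- mean(control_vals)
  if (mw <= 0 || mc <= 0) abort("group means must be positive.")
  if (length(warming_vals) < 2 || length(control_vals) < 2)
    abort("need >= 2 values per group for a confidence interval.")
  rr <- log(mw / mc)
  se <- sqrt(sd(warming_vals)^2 / (length(warming_vals) * mw^2) +
               sd(control_vals)^2 / (length(control_vals) * mc^2))
  zq <- stats::qnorm(1 - (1 - level) / 2)
  tibble::tibble(rr = rr, se = se, lower = rr - zq * se,
                 upper = rr + zq * se,
                 significant = (rr - zq * se) > 0 | (rr + zq * se) < 0)
}
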