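#' MEND model parameters
#'
#' Constructs the full parameter set of the microbial-enzyme decomposition
#' model. Carbon pools: two particulate organic matter pools decomposed by
#' oxidative and hydrolytic enzymes respectively, a mineral-associated pool
#' decomposed by a generic enzyme group, adsorbed and dissolved organic
#' matter exchanging through Langmuir sorption, and active/dormant microbial
#' biomass with explicit enzyme production. All rates are per day; pools are
#' mg C per g dry soil.
#'
#' Decomposition is Michaelis-Menten in substrate and linear in the enzyme
#' pool, scaled by temperature (Q10 form), moisture and pH response
#' functions. Microbial uptake of dissolved OM is partitioned by the carbon
#' use efficiency `cue` into growth and growth respiration; maintenance of
#' active and dormant biomass is respired. Moisture stress drives the
#' active-to-dormant transition and wet conditions drive resuscitation.
#'
#' @param q10 temperature sensitivity of decomposition/uptake/maintenance.
#' @param t_ref reference temperature, degrees C (default 10).
#' @param vmax_ox,k_ox,vmax_hyd,k_hyd maximum specific decomposition rates
#'   (mg C per mg enzyme C per day) and half-saturation constants
#'   (mg C g-1) for the oxidative and hydrolytic POM pools.
#' @param vmax_mom,k_mom same for the mineral-associated pool.
#' @param v_uptake,k_uptake DOM uptake kinetics of active biomass.
#' @param cue carbon use efficiency in (0, 1).
#' @param cue_slope optional linear temperature dependence of CUE per
#'   degree C (effective CUE = `cue + cue_slope * (T - t_ref)`, clipped to
#'   (0.01, 0.99)); 0 (constant CUE) by default.
#' @param frac_to_dom fraction of POM decomposition routed to DOM (the
#'   remainder becomes mineral-associated OM).
#' @param k_ads,k_des,q_max Langmuir adsorption/desorption rates and
#'   sorption capacity.
#' @param p_enz_ox,p_enz_hyd,p_enz_mom specific enzyme production rates
#'   (d-1 of active biomass).
#' @param r_enz enzyme turnover rate, d-1 (turned-over enzyme joins DOM).
#' @param k_mortality microbial mortality, d-1.
#' @param mort_to_dom fraction of dead biomass routed to DOM (remainder to
#'   hydrolytic POM).
#' @param k_maint specific maintenance rate, d-1.
#' @param dormancy_beta dormant:active maintenance ratio.
#' @param k_dorm,k_resusc dormancy/resuscitation rate scales, d-1.
#' @param w_fc,w_exp moisture response: scalar = min(1, (W/w_fc)^w_exp).
#' @param ph_opt,ph_sigma Gaussian pH response (max 1 at `ph_opt`).
#' @param in_pox,in_phyd input allocation fractions to the two POM pools
#'   (remainder enters DOM).
#' @param ... ignored; forces full naming of arguments.
#'
#' @return a named numeric vector of class `mend_params`.
#' @examples
#' p <- mend_params(q10 = 1.77)
#' p["q10"]
#' @export
mend_params <- function(q10 = 1.8, t_ref = 10,
                        vmax_ox = 1.2, k_ox = 10, vmax_hyd = 1.8, k_hyd = 10,
                        vmax_mom = 1, k_mom = 15,
                        v_uptake = 0.6, k_uptake = 0.4,
                        cue = 0.4, cue_slope = 0, frac_to_dom = 0.5,
                        k_ads = 0.5, k_des = 0.01, q_max = 2,
                        p_enz_ox = 0.004, p_enz_hyd = 0.006,
                        p_enz_mom = 0.002, r_enz = 0.02,
                        k_mortality = 0.012, mort_to_dom = 0.5,
                        k_maint = 0.008, dormancy_beta = 0.02,
                        k_dorm = 0.02, k_resusc = 0.05,
                        w_fc = 0.37, w_exp = 1,
                        ph_opt = 7, ph_sigma = 1.5,
                        in_pox = 0.2, in_phyd = 0.6, ...) {
  p <- c(q10 = q10, t_ref = t_ref,
         vmax_ox = vmax_ox, k_ox = k_ox, vmax_hyd = vmax_hyd, k_hyd = k_hyd,
         vmax_mom = vmax_mom, k_mom = k_mom,
         v_uptake = v_uptake, k_uptake = k_uptake,
         cue = cue, cue_slope = cue_slope, frac_to_dom = frac_to_dom,
         k_ads = k_ads, k_des = k_des, q_max = q_max,
         p_enz_ox = p_enz_ox, p_enz_hyd = p_enz_hyd, p_enz_mom = p_enz_mom,
         r_enz = r_enz, k_mortality = k_mortality, mort_to_dom = mort_to_dom,
         k_maint = k_maint, dormancy_beta = dormancy_beta,
         k_dorm = k_dorm, k_resusc = k_resusc,
         w_fc = w_fc, w_exp = w_exp, ph_opt = ph_opt, ph_sigma = ph_sigma,
         in_pox = in_pox, in_phyd = in_phyd)
  validate_mend_params(p)
  structure(p, class = c("mend_params", "numeric"))
}

validate_mend_params <- function(p) {
  if (any(!is.finite(p))) abort("all MEND parameters must be finite.")
  rates <- setdiff(names(p), c("t_ref", "ph_opt", "cue_slope"))
  if (any(p[rates] < 0)) abort("MEND rates and fractions must be >= 0.")
  if (p["q10"] <= 0) abort("`q10` must be > 0.")
  if (p["cue"] <= 0 || p["cue"] >= 1) abort("`cue` must lie in (0, 1).")
  for (fr in c("frac_to_dom", "mort_to_dom"))
    if (p[fr] < 0 || p[fr] > 1) abort(paste0("`", fr, "` must lie in [0, 1]."))
  if (p["in_pox"] + p["in_phyd"] > 1)
    abort("`in_pox` + `in_phyd` must be <= 1.")
  if (p["q_max"] <= 0) abort("`q_max` must be > 0.")
  invisible(p)
}

#' Update a parameter vector
#'
#' @param params a `mend_params` (or TECO parameter list) object.
#' @param values named numeric vector of replacements.
#' @return updated parameters of the same class.
#' @export
set_params <- function(params, values) {
  stopifnot(!is.null(names(values)))
  bad <- setdiff(names(values), names(params))
  if (length(bad) > 0) abort(paste0("unknown parameter(s): ", toString(bad)))
  params[names(values)] <- values
  if (inherits(params, "mend_params")) validate_mend_params(params)
  params
}

mend_pool_names <- c("p_ox", "p_hyd", "mom", "qom", "dom",
                     "b_active", "b_dormant", "enz_ox", "enz_hyd", "enz_mom")

#' Initial MEND carbon-pool state
#'
#' @param p_ox,p_hyd,mom,qom,dom,b_active,b_dormant,enz_ox,enz_hyd,enz_mom
#'   pool sizes, mg C per g soil. Defaults are a plausible grassland topsoil
#'   partition of roughly 11 mg C g-1 total organic carbon.
#' @return named numeric vector of class `mend_state`.
#' @export
mend_state <- function(p_ox = 0.67, p_hyd = 1.1, mom = 6.7, qom = 1.6,
                       dom = 0.07, b_active = 0.18, b_dormant = 0.015,
                       enz_ox = 0.032, enz_hyd = 0.048, enz_mom = 0.016) {
  x <- c(p_ox = p_ox, p_hyd = p_hyd, mom = mom, qom = qom, dom = dom,
         b_active = b_active, b_dormant = b_dormant,
         enz_ox = enz_ox, enz_hyd = enz_hyd, enz_mom = enz_mom)
  if (any(x < 0)) abort("all pools must be >= 0.")
  structure(x, class = c("mend_state", "numeric"))
}

#' Environmental response scalars
#'
#' `temperature_scalar()` is the Q10 multiplier `q10^((T - t_ref)/10)`;
#' `moisture_scalar()` is `min(1, (W / w_fc)^w_exp)`, equal to 1 at field
#' capacity and monotone below it; `ph_scalar()` is a Gaussian in pH with
#' maximum 1 at the optimum.
#'
#' @param temp soil temperature, degrees C.
#' @param q10 temperature sensitivity (> 0).
#' @param t_ref reference temperature, degrees C.
#' @return unitless multiplier.
#' @examples
#' temperature_scalar(20, q10 = 2, t_ref = 10)  # 2
#' moisture_scalar(0.37)                        # 1 at field capacity
#' ph_scalar(7)                                 # 1 at the optimum
#' @export
temperature_scalar <- function(temp, q10, t_ref = 10) {
  if (any(q10 <= 0)) abort("`q10` must be > 0.")
  q10^((temp - t_ref) / 10)
}

#' @rdname temperature_scalar
#' @param moisture volumetric water content, fraction in (0, 1).
#' @param w_fc field-capacity (reference) moisture.
#' @param w_exp shape exponent.
#' @export
moisture_scalar <- function(moisture, w_fc = 0.37, w_exp = 1) {
  if (any(moisture <= 0 | moisture >= 1))
    abort("`moisture` must lie strictly in (0, 1).")
  pmin(1, (moisture / w_fc)^w_exp)
}

#' @rdname temperature_scalar
#' @param ph soil pH in \[3, 10\].
#' @param ph_opt optimum pH.
#' @param ph_sigma Gaussian width.
#' @export
ph_scalar <- function(ph, ph_opt = 7, ph_sigma = 1.5) {
  if (any(ph < 3 | ph > 10)) abort("`ph` must lie in [3, 10].")
  exp(-0.5 * ((ph - ph_opt) / ph_sigma)^2)
}

#' Component fluxes of the MEND model at one state
#'
#' Evaluates every component flux (decomposition of the three OM pools,
#' sorption exchange, DOM uptake, growth and maintenance respiration, enzyme
#' production and turnover, mortality, dormancy and resuscitation) for a
#' single day of forcing. Mostly useful for inspection and testing; the
#' integrator applies the same kernel internally.
#'
#' @param state a [mend_state()] vector.
#' @param params a [mend_params()] vector.
#' @param soil_temp,moisture,ph scalar forcing for the day.
#' @return a tibble with columns `flux` and `value` (mg C g-1 d-1).
#' @export
mend_fluxes <- function(state, params, soil_temp, moisture, ph) {
  validate_mend_params(params)
  f <- mend_flux_cpp(as.numeric(state), param_vec(params),
                     soil_temp, moisture, ph)
  if (any(!is.finite(f)) || any(f < -1e-12))
    abort("non-finite or negative component flux computed.")
  tibble::tibble(flux = names(f), value = as.numeric(f))
}

#' Simulate the MEND model over a daily forcing series
#'
#' Fixed-step explicit integration (default dt = 0.1 d) with adaptive
#' sub-stepping and conservative flux limiting so pools never go negative
#' and the per-step carbon budget closes exactly: inputs - Rh = change in
#' storage. Heterotrophic respiration is the sum of growth respiration and
#' active/dormant maintenance respiration.
#'
#' @param forcing single-treatment forcing tibble (see [gen_forcing()],
#'   [forcing_treatment()]).
#' @param params [mend_params()].
#' @param init [mend_state()]; if `NULL`, the default state.
#' @param dt integration step in days (<= 1).
#' @param soil_mass_per_m2 unit conversion for area-based respiration.
#' @return an object of class `mend_sim`: list with `daily` (tibble: `date`,
#'   `rh` mg C g-1 d-1, `rh_area` g C m-2 d-1, `mbc`, and all pools),
#'   `annual_enzymes` (tibble: `year`, `enz_ox`, `enz_hyd` annual means),
#'   `balance_residual`, `final_state`, `params`.
#' @examples
#' f <- gen_forcing(years = 1, seed = 1)
#' sim <- simulate_mend(forcing_treatment(f, "control"), mend_params())
#' head(sim$daily)
#' @export
simulate_mend <- function(forcing, params, init = NULL, dt = 0.1,
                          soil_mass_per_m2 = 1.8e5) {
  stopifnot(dt <= 1, dt > 0)
  validate_forcing(forcing)
  if (length(unique(forcing$treatment)) != 1)
    abort("`forcing` must contain a single treatment; see forcing_treatment().")
  validate_mend_params(params)
  if (is.null(init)) init <- mend_state()

  res <- mend_core_cpp(as.numeric(init), param_vec(params),
                       forcing$soil_temp, forcing$moisture, forcing$ph,
                       forcing$c_input, dt, TRUE)

  pools <- tibble::as_tibble(as.data.frame(res$pools))
  names(pools) <- mend_pool_names
  daily <- dplyr::bind_cols(
    tibble::tibble(
      date = forcing$date,
      rh = as.numeric(res$daily_rh),
      rh_area = soil_to_area(as.numeric(res$daily_rh), soil_mass_per_m2),
      mbc = pools$b_active + pools$b_dormant
    ),
    pools
  )
  throughput <- max(res$cum_input, res$cum_rh, sum(init))
  if (any(daily$rh < 0)) abort("negative daily Rh encountered.")

  annual <- daily |>
    dplyr::mutate(year = as.integer(format(.data$date, "%Y"))) |>
    dplyr::group_by(.data$year) |>
    dplyr::summarise(
      enz_ox = mean(.data$enz_ox),
      enz_hyd = mean(.data$enz_hyd),
      n_days = dplyr::n(),
      .groups = "drop"
    )

  structure(list(
    daily = daily,
    annual_enzymes = annual,
    balance_residual = res$balance_residual,
    relative_balance_error =
      res$balance_residual / max(throughput, .Machine$double.eps),
    limited_steps = res$limited_steps,
    final_state = structure(stats::setNames(as.numeric(daily[nrow(daily), mend_pool_names]),
                                            mend_pool_names),
                            class = c("mend_state", "numeric")),
    params = params,
    dt = dt,
    model = "MEND"
  ), class = "mend_sim")
}

#' @export
print.mend_sim <- function(x, ...) {
  cat("<mend_sim> ", nrow(x$daily), " days, dt = ", x$dt, " d\n", sep = "")
  cat("  mean Rh: ", signif(mean(x$daily$rh_area), 4), " g C m-2 d-1\n", sep = "")
  cat("  max |C-balance residual|: ", format(x$balance_residual, digits = 3),
      " mg C g-1\n", sep = "")
  invisible(x)
}

#' Spin the MEND model up to a quasi-steady annual cycle
#'
#' Repeats the forcing climatology until the relative year-over-year change
#' of every pool falls below `tol`, or `cycles` is exhausted (the state is
#' still returned, flagged unconverged).
#'
#' @inheritParams simulate_mend
#' @param cycles maximum number of climatology passes (>= 1).
#' @param tol relative change tolerance (default 1e-3).
#' @return a `mend_state` with attributes `converged` and `cycles_used`.
#' @export
spinup_mend <- function(forcing, params, init = NULL, cycles = 20,
                        tol = 1e-3, dt = 0.1) {
  if (cycles < 1) abort("`cycles` must be >= 1.")
  validate_forcing(forcing)
  validate_mend_params(params)
  state <- if (is.null(init)) mend_state() else init
  converged <- FALSE
  used <- 0L
  for (i in seq_len(cycles)) {
    res <- mend_core_cpp(as.numeric(state), param_vec(params),
                         forcing$soil_temp, forcing$moisture, forcing$ph,
                         forcing$c_input, dt, FALSE)
    new <- stats::setNames(as.numeric(res$pools[1, ]), mend_pool_names)
    rel <- abs(new - as.numeric(state)) /
      pmax(abs(as.numeric(state)), 1e-6)
    state <- structure(new, class = c("mend_state", "numeric"))
    used <- i
    if (max(rel) < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warn(paste0("spin-up not converged after ", cycles, " cycle(s); ",
                "max relative change ", signif(max(rel), 3)))
  attr(state, "converged") <- converged
  attr(state, "cycles_used") <- used
  state
}

# plain named numeric (the C++ kernel indexes parameters by name)
param_vec <- function(params) {
  stats::setNames(as.numeric(params), names(params))
}
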