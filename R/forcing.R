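#' Generate paired control/warming daily forcing series
#'
#' Builds a synthetic daily environmental driver table for a temperate
#' grassland warming experiment: a sinusoidal annual soil-temperature cycle
#' with AR(1) day-to-day weather noise, a seasonal volumetric soil-moisture
#' series, constant near-neutral pH, and a carbon input series that is
#' piecewise-constant over 8-day blocks (emulating an 8-day GPP product
#' scaled by a belowground-allocation fraction). The warming series applies a
#' constant soil-temperature offset and a relative moisture reduction to the
#' *same* weather realisation, so the treatment contrast is exact by
#' construction.
#'
#' @param years number of simulated years (>= 1).
#' @param seed integer seed; identical seeds give bit-identical output.
#' @param warming_delta_t soil warming offset, degrees C (default 2.8).
#' @param moisture_reduction relative moisture reduction under warming
#'   (default 0.064, i.e. warming moisture = control x 0.936). Must be < 1.
#' @param t_mean,t_amp mean and seasonal amplitude of control soil
#'   temperature, degrees C (defaults 17 and 10).
#' @param t_ar1,t_sd AR(1) coefficient and innovation SD of the temperature
#'   weather noise.
#' @param w_mean,w_amp mean and seasonal amplitude of volumetric moisture.
#' @param w_sd innovation SD of the AR(1) moisture noise.
#' @param ph constant soil pH.
#' @param gpp_mean mean GPP, g C m-2 d-1.
#' @param gpp_amp_rel relative seasonal amplitude of GPP in (0, 1).
#' @param gpp_block_sd lognormal SD of the 8-day GPP block noise.
#' @param alloc_frac fraction of GPP entering the soil as C input.
#' @param soil_mass_per_m2 unit-conversion constant, see [soil_to_area()].
#' @param start_date first simulated day (a `Date`).
#'
#' @return A tibble with one row per day and treatment: `treatment`
#'   ("control"/"warming"), `day_index`, `date`, `soil_temp` (degrees C),
#'   `moisture` (volumetric fraction), `ph`, `c_input`
#'   (mg C per g soil per day).
#' @examples
#' f <- gen_forcing(years = 1, seed = 1)
#' dplyr::count(f, treatment)
#' @export
gen_forcing <- function(years = 7, seed = 1,
                        warming_delta_t = 2.8, moisture_reduction = 0.064,
                        t_mean = 17, t_amp = 10, t_ar1 = 0.8, t_sd = 1.5,
                        w_mean = 0.25, w_amp = 0.07, w_sd = 0.015,
                        ph = 6.8,
                        gpp_mean = 5, gpp_amp_rel = 0.8, gpp_block_sd = 0.3,
                        alloc_frac = 0.4,
                        soil_mass_per_m2 = 1.8e5,
                        start_date = as.Date("2010-01-01")) {
  if (years < 1) abort("`years` must be a positive whole number.")
  if (moisture_reduction >= 1) abort("`moisture_reduction` must be < 1.")

  n <- round(years * 365)
  day <- seq_len(n)
  date <- start_date + day - 1L
  doy <- as.numeric(format(date, "%j"))
  season <- sin(2 * pi * (doy - 110) / 365.25) # peak around late July

  old <- .Random.seed_exists()
  set.seed(seed)
  on.exit(old(), add = TRUE)

  ar1 <- function(n, rho, sd) {
    e <- rnorm(n, 0, sd)
    stats::filter(e, rho, method = "recursive") |> as.numeric()
  }

  soil_temp <- t_mean + t_amp * season + ar1(n, t_ar1, t_sd)
  moisture <- w_mean - w_amp * season + ar1(n, 0.9, w_sd)
  moisture <- pmin(pmax(moisture, 0.03), 0.6)

  # 8-day-blocked GPP product: seasonal curve x lognormal block noise
  block <- (day - 1) %/% 8
  nblock <- max(block) + 1
  block_noise <- rlnorm(nblock, -gpp_block_sd^2 / 2, gpp_block_sd)
  gpp_season <- gpp_mean * (1 + gpp_amp_rel * season)
  gpp_block <- vapply(split(gpp_season, block), mean, numeric(1))
  gpp <- pmax(gpp_block[block + 1] * block_noise[block + 1], 0)
  c_input <- area_to_soil(gpp * alloc_frac, soil_mass_per_m2)

  ctl <- tibble::tibble(
    treatment = "control", day_index = day, date = date,
    soil_temp = soil_temp, moisture = moisture, ph = ph, c_input = c_input
  )
  wrm <- ctl
  wrm$treatment <- "warming"
  wrm$soil_temp <- ctl$soil_temp + warming_delta_t
  wrm$moisture <- ctl$moisture * (1 - moisture_reduction)
  out <- dplyr::bind_rows(ctl, wrm)
  validate_forcing(out)
  out
}

# restore-RNG helper: returns a function that restores the pre-call state
.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    saved <- get(".Random.seed", envir = globalenv())
    function() assign(".Random.seed", saved, envir = globalenv())
  } else {
    function() invisible(NULL)
  }
}

#' Validate a daily forcing table
#'
#' Checks the invariants the simulators rely on: the required columns, one
#' contiguous daily record per treatment, moisture in (0, 1), pH in
#' \[3, 10\] and non-negative carbon input.
#'
#' @param forcing a forcing tibble as produced by [gen_forcing()].
#' @return the input, invisibly, if valid; otherwise an error.
#' @export
validate_forcing <- function(forcing) {
  need <- c("treatment", "day_index", "date", "soil_temp", "moisture",
            "ph", "c_input")
  miss <- setdiff(need, names(forcing))
  if (length(miss) > 0)
    abort(paste0("forcing is missing column(s): ", toString(miss)))
  for (tr in unique(forcing$treatment)) {
    d <- forcing$date[forcing$treatment == tr]
    gaps <- which(diff(as.integer(d)) != 1L)
    if (length(gaps) > 0)
      abort(paste0("forcing for treatment '", tr, "' is not contiguous; ",
                   "first gap after ", d[gaps[1]]))
  }
  if (any(forcing$moisture <= 0 | forcing$moisture >= 1))
    abort("moisture must lie strictly in (0, 1).")
  if (any(forcing$ph < 3 | forcing$ph > 10))
    abort("ph must lie in [3, 10].")
  if (any(forcing$c_input < 0))
    abort("c_input must be non-negative.")
  invisible(forcing)
}

#' Extract one treatment from a forcing table
#'
#' @param forcing forcing tibble (both treatments).
#' @param treatment `"control"` or `"warming"`.
#' @return single-treatment forcing tibble ordered by day.
#' @export
forcing_treatment <- function(forcing, treatment = c("control", "warming")) {
  treatment <- match.arg(treatment)
  out <- dplyr::arrange(
    dplyr::filter(forcing, .data$treatment == !!treatment),
    .data$day_index
  )
  if (nrow(out) == 0)
    abort(paste0("no rows for treatment '", treatment, "'."))
  out
}
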