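#' Generate noisy synthetic observations from a known MEND truth
#'
#' Runs the MEND forward model with known ("true") parameters over a
#' single-treatment forcing series and samples from it the observation
#' structure the calibration assumes: dated heterotrophic-respiration values
#' (~monthly, area units), sparse microbial-biomass-carbon values (annual),
#' and annual oxidative/hydrolytic gene-abundance indices proportional to
#' the annual mean simulated enzyme pools. Noise is multiplicative
#' lognormal on every variable (mean-one, so zero sigma recovers the truth
#' exactly); the gene-enzyme correlation the gene-informed objective assumes
#' therefore holds by construction.
#'
#' @param forcing single-treatment forcing tibble (>= 1 year).
#' @param true_params [mend_params()] used as the generating truth.
#' @param init initial state; default [spinup_mend()] from the default state
#'   is recommended, or pass `NULL` to use the default state directly.
#' @param n_rh number of Rh observations (default 74); sampled monthly on
#'   day 15 and truncated to `n_rh`.
#' @param mbc_dates number of MBC observations (default one per year,
#'   mid-September, emulating annual soil sampling).
#' @param sigma_rh,sigma_mbc,sigma_gene lognormal noise scales.
#' @param gene_scale multiplicative factor from enzyme pool (mg C g-1) to
#'   gene-abundance index (arbitrary units).
#' @param seed integer seed; identical seed and configuration give
#'   identical observations.
#' @param dt integration step for the truth run.
#' @param soil_mass_per_m2 unit conversion, see [soil_to_area()].
#' @return list of class `observation_set`: `rh_obs` (tibble `date`,
#'   `value` g C m-2 d-1), `mbc_obs` (tibble `date`, `value` mg C g-1),
#'   `genes` (tibble `year`, `gene_ox`, `gene_hyd`), `treatment`, `truth`
#'   (the generating simulation), `seed`.
#' @export
gen_observations <- function(forcing, true_params, init = NULL,
                             n_rh = 74, mbc_dates = NULL,
                             sigma_rh = 0.2, sigma_mbc = 0.15,
                             sigma_gene = 0.1, gene_scale = 100,
                             seed = 1, dt = 0.1, soil_mass_per_m2 = 1.8e5) {
  validate_forcing(forcing)
  sim <- simulate_mend(forcing, true_params, init = init, dt = dt,
                       soil_mass_per_m2 = soil_mass_per_m2)
  daily <- sim$daily
  if (n_rh > nrow(daily))
    abort("`n_rh` exceeds the number of simulated days.")

  # monthly Rh sampling on a fixed day-of-month, truncated to n_rh
  rh_dates <- daily$date[format(daily$date, "%d") == "15"]
  if (length(rh_dates) < n_rh)
    abort("forcing too short for the requested number of Rh observations.")
  rh_dates <- rh_dates[seq_len(n_rh)]

  if (is.null(mbc_dates)) {
    mbc_sel <- daily$date[format(daily$date, "%m-%d") == "09-15"]
  } else {
    mbc_sel <- daily$date[format(daily$date, "%d") == "15"]
    mbc_sel <- mbc_sel[seq(1, length(mbc_sel),
                           length.out = min(mbc_dates, length(mbc_sel)))]
  }

  old <- .Random.seed_exists()
  set.seed(seed)
  on.exit(old(), add = TRUE)
  lnoise <- function(n, sigma) rlnorm(n, -sigma^2 / 2, sigma)

  rh_true <- daily$rh_area[match(rh_dates, daily$date)]
  rh_obs <- tibble::tibble(date = rh_dates,
                           value = rh_true * lnoise(n_rh, sigma_rh))

  mbc_true <- daily$mbc[match(mbc_sel, daily$date)]
  mbc_obs <- tibble::tibble(date = mbc_sel,
                            value = mbc_true * lnoise(length(mbc_sel),
                                                      sigma_mbc))

  ann <- sim$annual_enzymes
  genes <- tibble::tibble(
    year = ann$year,
    gene_ox = ann$enz_ox * gene_scale * lnoise(nrow(ann), sigma_gene),
    gene_hyd = ann$enz_hyd * gene_scale * lnoise(nrow(ann), sigma_gene)
  )

  structure(list(
    rh_obs = rh_obs,
    mbc_obs = mbc_obs,
    genes = genes,
    treatment = forcing$treatment[1],
    truth = sim,
    seed = seed
  ), class = "observation_set")
}

#' @export
print.observation_set <- function(x, ...) {
  cat("<observation_set> treatment:", x$treatment, "\n")
  cat("  Rh:", nrow(x$rh_obs), "dated values;  MBC:", nrow(x$mbc_obs),
      "dated values;  gene years:", nrow(x$genes), "\n")
  invisible(x)
}

validate_observations <- function(obs) {
  for (part in c("rh_obs", "mbc_obs")) {
    if (any(obs[[part]]$value <= 0))
      abort(paste0(part, " must contain positive values only."))
  }
  if (any(obs$genes$gene_ox <= 0) || any(obs$genes$gene_hyd <= 0))
    abort("gene indices must be positive.")
  if (anyDuplicated(obs$genes$year))
    abort("duplicate year in gene table.")
  invisible(obs)
}
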