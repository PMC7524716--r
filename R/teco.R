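#' TECO model parameters
#'
#' First-order multi-pool terrestrial ecosystem carbon model (a CENTURY
#' variant) used as the non-microbial baseline. Carbon dynamics follow
#' `dX/dt = A xi(T, W) K X + B I(t)` where `K` is the diagonal of base
#' turnover rates, `A` the donor-to-receiver transfer matrix (the complement
#' of each donor's transfers is respired), `B` the allocation of carbon
#' input to entry pools, and `xi` a Q10-by-moisture scalar applied to the
#' environment-sensitive (litter and SOM) pools.
#'
#' The default topology has 7 pools: foliage and root (plant pools feeding
#' the litter pools, transfers summing to 1 so they respire nothing),
#' metabolic and structural litter, and fast/slow/passive SOM.
#'
#' @param turnover named base turnover rates, d-1.
#' @param transfer donor-to-receiver transfer matrix; `transfer[i, j]` is the
#'   fraction of the flux out of pool `j` entering pool `i`. Column sums must
#'   be <= 1; the complement is respired.
#' @param alloc allocation fractions of C input to each pool (sums to 1).
#' @param env_sensitive logical; which pools respond to temperature/moisture.
#' @param q10,t_ref Q10 temperature response of the sensitive pools.
#' @param w_fc,w_exp moisture response, as in [moisture_scalar()].
#' @return a list of class `teco_params`.
#' @export
teco_params <- function(turnover = NULL, transfer = NULL, alloc = NULL,
                        env_sensitive = NULL, q10 = 1.8, t_ref = 10,
                        w_fc = 0.37, w_exp = 1) {
  pools <- c("foliage", "root", "lit_metabolic", "lit_structural",
             "som_fast", "som_slow", "som_passive")
  np <- length(pools)
  if (is.null(turnover))
    turnover <- c(foliage = 1 / 365, root = 1 / 730,
                  lit_metabolic = 1 / 30, lit_structural = 1 / 365,
                  som_fast = 1 / 365, som_slow = 1 / 3650,
                  som_passive = 1 / 36500)
  if (is.null(transfer)) {
    transfer <- matrix(0, np, np, dimnames = list(pools, pools))
    transfer["lit_metabolic", "foliage"] <- 0.6
    transfer["lit_structural", "foliage"] <- 0.4
    transfer["lit_metabolic", "root"] <- 0.5
    transfer["lit_structural", "root"] <- 0.5
    transfer["som_fast", "lit_metabolic"] <- 0.45
    transfer["som_fast", "lit_structural"] <- 0.35
    transfer["som_slow", "lit_structural"] <- 0.15
    transfer["som_slow", "som_fast"] <- 0.25
    transfer["som_passive", "som_slow"] <- 0.05
    transfer["som_fast", "som_slow"] <- 0.20
    transfer["som_fast", "som_passive"] <- 0.45
  }
  if (is.null(alloc))
    alloc <- c(foliage = 0.6, root = 0.4, lit_metabolic = 0,
               lit_structural = 0, som_fast = 0, som_slow = 0,
               som_passive = 0)
  if (is.null(env_sensitive))
    env_sensitive <- c(foliage = FALSE, root = FALSE, lit_metabolic = TRUE,
                       lit_structural = TRUE, som_fast = TRUE,
                       som_slow = TRUE, som_passive = TRUE)
  p <- list(pools = names(turnover), turnover = turnover,
            transfer = transfer, alloc = alloc,
            env_sensitive = env_sensitive, q10 = q10, t_ref = t_ref,
            w_fc = w_fc, w_exp = w_exp)
  validate_teco_params(p)
  structure(p, class = "teco_params")
}

validate_teco_params <- function(p) {
  np <- length(p$turnover)
  if (any(p$turnover < 0)) abort("turnover rates must be >= 0.")
  if (!all(dim(p$transfer) == c(np, np)))
    abort("transfer matrix dimensions must match the pool count.")
  cs <- colSums(p$transfer)
  if (any(cs > 1 + 1e-12))
    abort("transfer fractions out of a donor pool must sum to <= 1.")
  if (abs(sum(p$alloc) - 1) > 1e-12)
    abort("allocation fractions must sum to 1.")
  if (p$q10 <= 0) abort("`q10` must be > 0.")
  invisible(p)
}

#' Simulate the TECO model over a daily forcing series
#'
#' Same integration, conservation and non-negativity contract as
#' [simulate_mend()]. Heterotrophic respiration is the respired complement
#' of the transfers out of the litter/SOM pools; the plant pools' transfers
#' sum to 1 by default so Rh is purely heterotrophic.
#'
#' @inheritParams simulate_mend
#' @param params a [teco_params()] list.
#' @param init named pool vector, mg C g-1; default a small grassland stock.
#' @return an object of class `teco_sim` (same shape as `mend_sim`, without
#'   enzyme columns; `annual_enzymes` is `NULL`).
#' @export
simulate_teco <- function(forcing, params, init = NULL, dt = 0.1,
                          soil_mass_per_m2 = 1.8e5) {
  stopifnot(dt <= 1, dt > 0)
  validate_forcing(forcing)
  if (length(unique(forcing$treatment)) != 1)
    abort("`forcing` must contain a single treatment; see forcing_treatment().")
  validate_teco_params(params)
  np <- length(params$turnover)
  if (is.null(init))
    init <- stats::setNames(
      c(0.5, 0.8, 0.3, 1, 2.5, 5, 2)[seq_len(np)], params$pools)
  if (any(init < 0)) abort("all pools must be >= 0.")

  res <- teco_core_cpp(as.numeric(init), params$transfer,
                       as.numeric(params$turnover),
                       as.logical(params$env_sensitive),
                       as.numeric(params$alloc),
                       params$q10, params$t_ref, params$w_fc, params$w_exp,
                       forcing$soil_temp, forcing$moisture, forcing$c_input,
                       dt, TRUE)

  pools <- tibble::as_tibble(as.data.frame(res$pools))
  names(pools) <- params$pools
  daily <- dplyr::bind_cols(
    tibble::tibble(
      date = forcing$date,
      rh = as.numeric(res$daily_rh),
      rh_area = soil_to_area(as.numeric(res$daily_rh), soil_mass_per_m2)
    ),
    pools
  )
  throughput <- max(res$cum_input, res$cum_rh, sum(init))
  structure(list(
    daily = daily,
    annual_enzymes = NULL,
    balance_residual = res$balance_residual,
    relative_balance_error =
      res$balance_residual / max(throughput, .Machine$double.eps),
    final_state = stats::setNames(as.numeric(daily[nrow(daily), params$pools]),
                                  params$pools),
    params = params,
    dt = dt,
    model = "TECO"
  ), class = c("teco_sim", "mend_sim"))
}

#' Spin the TECO model up to a quasi-steady annual cycle
#'
#' @inheritParams simulate_teco
#' @param cycles maximum climatology passes.
#' @param tol relative year-over-year change tolerance.
#' @return named pool vector with attributes `converged`, `cycles_used`.
#' @export
spinup_teco <- function(forcing, params, init = NULL, cycles = 20,
                        tol = 1e-3, dt = 0.1) {
  if (cycles < 1) abort("`cycles` must be >= 1.")
  state <- NULL
  converged <- FALSE
  used <- 0L
  for (i in seq_len(cycles)) {
    sim <- simulate_teco(forcing, params, init = state, dt = dt)
    new <- sim$final_state
    if (!is.null(state)) {
      rel <- abs(new - state) / pmax(abs(state), 1e-6)
      if (max(rel) < tol) { state <- new; used <- i; converged <- TRUE; break }
    }
    state <- new
    used <- i
  }
  if (!converged)
    warn(paste0("TECO spin-up not converged after ", cycles, " cycle(s)."))
  attr(state, "converged") <- converged
  attr(state, "cycles_used") <- used
  state
}
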