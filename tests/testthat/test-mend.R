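test_that("environmental scalars match their closed forms", {
  expect_equal(temperature_scalar(10, q10 = 1.7, t_ref = 10), 1)
  expect_equal(temperature_scalar(20, q10 = 2, t_ref = 10), 2)
  # independent log-space evaluation
  expect_equal(temperature_scalar(20, q10 = 1.39, t_ref = 17),
               exp(0.3 * log(1.39)))
  expect_error(temperature_scalar(15, q10 = 0), "q10")

  expect_equal(moisture_scalar(0.37, w_fc = 0.37), 1)
  w <- seq(0.05, 0.36, by = 0.01)
  expect_true(all(diff(moisture_scalar(w)) >= 0))
  expect_equal(moisture_scalar(0.2, w_fc = 0.4, w_exp = 1.5),
               (0.2 / 0.4)^1.5)
  expect_error(moisture_scalar(0), "moisture")

  expect_equal(ph_scalar(7), 1)
  expect_equal(ph_scalar(7 + 1.5, ph_sigma = 1.5), exp(-1 / 2))
  expect_equal(ph_scalar(6.2), ph_scalar(7.8))
  expect_error(ph_scalar(11), "ph")
})

test_that("all-zero pools give all-zero fluxes", {
  zero <- mend_state(0, 0, 0, 0, 0, 0, 0, 0, 0, 0)
  fl <- mend_fluxes(zero, mend_params(), soil_temp = 15, moisture = 0.25,
                    ph = 7)
  expect_true(all(fl$value == 0))
})

test_that("POM decomposition saturates at vmax * enzyme * scalars", {
  p <- mend_params()
  big <- mend_state(p_ox = 1e9)
  fl <- mend_fluxes(big, p, soil_temp = 22, moisture = 0.3, ph = 6.5)
  env <- temperature_scalar(22, p["q10"], p["t_ref"]) *
    moisture_scalar(0.3, p["w_fc"], p["w_exp"]) *
    ph_scalar(6.5, p["ph_opt"], p["ph_sigma"])
  expect_equal(fl$value[fl$flux == "dec_ox"],
               unname(p["vmax_ox"] * mend_state()["enz_ox"] * env),
               tolerance = 1e-6)
})

test_that("flux kernel matches an independently scripted evaluation", {
  p <- mend_params(q10 = 1.6, cue = 0.45)
  x <- fix_rich_state()
  Tq <- 18; W <- 0.22; pH <- 6.4
  fl <- mend_fluxes(x, p, Tq, W, pH)
  got <- setNames(fl$value, fl$flux)

  # oracle: direct formula evaluation, written independently of the kernel
  ft <- p[["q10"]]^((Tq - p[["t_ref"]]) / 10)
  fw <- min(1, (W / p[["w_fc"]])^p[["w_exp"]])
  fp <- exp(-0.5 * ((pH - p[["ph_opt"]]) / p[["ph_sigma"]])^2)
  env <- ft * fw * fp
  upt <- p[["v_uptake"]] * x[["b_active"]] * x[["dom"]] /
    (p[["k_uptake"]] + x[["dom"]]) * env
  exp_flux <- c(
    dec_ox = p[["vmax_ox"]] * x[["enz_ox"]] * x[["p_ox"]] /
      (p[["k_ox"]] + x[["p_ox"]]) * env,
    dec_hyd = p[["vmax_hyd"]] * x[["enz_hyd"]] * x[["p_hyd"]] /
      (p[["k_hyd"]] + x[["p_hyd"]]) * env,
    dec_mom = p[["vmax_mom"]] * x[["enz_mom"]] * x[["mom"]] /
      (p[["k_mom"]] + x[["mom"]]) * env,
    ads = p[["k_ads"]] * x[["dom"]] * (1 - x[["qom"]] / p[["q_max"]]),
    des = p[["k_des"]] * x[["qom"]] / p[["q_max"]],
    uptake = upt,
    growth_resp = (1 - p[["cue"]]) * upt,
    maint_active = p[["k_maint"]] * ft * x[["b_active"]],
    maint_dormant = p[["dormancy_beta"]] * p[["k_maint"]] * ft *
      x[["b_dormant"]],
    enz_prod_ox = p[["p_enz_ox"]] * x[["b_active"]],
    enz_prod_hyd = p[["p_enz_hyd"]] * x[["b_active"]],
    enz_prod_mom = p[["p_enz_mom"]] * x[["b_active"]],
    enz_turn_ox = p[["r_enz"]] * x[["enz_ox"]],
    enz_turn_hyd = p[["r_enz"]] * x[["enz_hyd"]],
    enz_turn_mom = p[["r_enz"]] * x[["enz_mom"]],
    mortality = p[["k_mortality"]] * x[["b_active"]],
    to_dormant = p[["k_dorm"]] * (1 - fw) * x[["b_active"]],
    resuscitation = p[["k_resusc"]] * fw * x[["b_dormant"]]
  )
  expect_equal(got[names(exp_flux)], exp_flux, tolerance = 1e-12)
})

test_that("CUE temperature dependence rescales growth respiration", {
  x <- fix_rich_state()
  const <- mend_fluxes(x, mend_params(cue = 0.4), 20, 0.3, 7)
  slope <- mend_fluxes(x, mend_params(cue = 0.4, cue_slope = -0.01),
                       20, 0.3, 7)
  upt <- const$value[const$flux == "uptake"]
  expect_equal(slope$value[slope$flux == "uptake"], upt)
  # effective CUE at 20 C is 0.4 - 0.01 * (20 - 10) = 0.3
  expect_equal(slope$value[slope$flux == "growth_resp"], 0.7 * upt)
  expect_equal(const$value[const$flux == "growth_resp"], 0.6 * upt)
})

test_that("zero input and zero pools stay an absorbing state", {
  f <- fix_forcing(years = 1, seed = 9)
  ctl <- forcing_treatment(f, "control")
  ctl$c_input <- 0
  zero <- mend_state(0, 0, 0, 0, 0, 0, 0, 0, 0, 0)
  sim <- simulate_mend(ctl, mend_params(), init = zero, dt = 0.5)
  expect_true(all(sim$daily$rh == 0))
  expect_true(all(as.matrix(sim$daily[, c("p_ox", "dom", "b_active")]) == 0))
})

test_that("carbon balance closes and pools stay non-negative over 7 years", {
  f <- fix_forcing(years = 7, seed = 1)
  ctl <- forcing_treatment(f, "control")
  sim <- simulate_mend(ctl, mend_params(q10 = 1.77), dt = 0.25)
  expect_lt(sim$relative_balance_error, 1e-8)
  pools <- as.matrix(sim$daily[, gimend:::mend_pool_names])
  expect_true(all(pools >= 0))
  expect_true(all(sim$daily$rh >= 0))
})

test_that("halving the step changes daily Rh by less than 0.1%", {
  f <- fix_forcing(years = 2, seed = 4)
  ctl <- forcing_treatment(f, "control")
  p <- mend_params()
  coarse <- simulate_mend(ctl, p, dt = 0.1)
  half <- simulate_mend(ctl, p, dt = 0.05)
  rel <- abs(coarse$daily$rh - half$daily$rh) / pmax(half$daily$rh, 1e-12)
  expect_lt(max(rel), 1e-3)
  # and both agree with a 10x finer reference
  fine <- simulate_mend(ctl, p, dt = 0.01)
  rel_ref <- abs(half$daily$rh - fine$daily$rh) / pmax(fine$daily$rh, 1e-12)
  expect_lt(max(rel_ref), 1e-3)
})

test_that("warmer forcing raises cumulative Rh; drier forcing lowers it", {
  f <- fix_forcing(years = 2, seed = 6)
  ctl <- forcing_treatment(f, "control")
  p <- mend_params(q10 = 1.8)
  init <- mend_state()
  base <- simulate_mend(ctl, p, init = init, dt = 0.25)
  warm <- ctl; warm$soil_temp <- warm$soil_temp + 2.8
  dry <- ctl; dry$moisture <- dry$moisture * 0.8
  expect_gt(sum(simulate_mend(warm, p, init = init, dt = 0.25)$daily$rh),
            sum(base$daily$rh))
  expect_lt(sum(simulate_mend(dry, p, init = init, dt = 0.25)$daily$rh),
            sum(base$daily$rh))
})

test_that("spin-up reaches a quasi-steady cycle and stays there", {
  f <- fix_forcing(years = 1, seed = 8)
  ctl <- forcing_treatment(f, "control")
  p <- mend_params()
  st <- spinup_mend(ctl, p, cycles = 40, dt = 0.25)
  expect_true(attr(st, "converged"))
  # one more pass changes every pool by less than the tolerance
  more <- spinup_mend(ctl, p, init = st, cycles = 2, dt = 0.25)
  rel <- abs(as.numeric(more) - as.numeric(st)) /
    pmax(abs(as.numeric(st)), 1e-6)
  expect_lt(max(rel), 1e-3)
  expect_warning(spinup_mend(ctl, mend_params(),
                             init = mend_state(mom = 60), cycles = 1,
                             dt = 0.5),
                 "not converged")
})

test_that("parameter constructors validate their domains", {
  expect_error(mend_params(cue = 1.2), "cue")
  expect_error(mend_params(q10 = -1), ">= 0")
  expect_error(mend_params(in_pox = 0.8, in_phyd = 0.4), "in_pox")
  expect_error(mend_state(p_ox = -1), ">= 0")
  expect_error(set_params(mend_params(), c(nope = 1)), "unknown parameter")
  p2 <- set_params(mend_params(), c(q10 = 2.2))
  expect_equal(unname(p2["q10"]), 2.2)
})
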