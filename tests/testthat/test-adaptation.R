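test_that("Q10 respiration follows Eq-type scaling and re-anchoring", {
  expect_equal(q10_respiration(1.84, 1.39, 17, 17), 1.84)
  expect_equal(round(q10_respiration(1.84, 1.39, 20, 17), 2), 2.03)
  expect_equal(round(q10_respiration(1.84, 1.77, 20, 17), 2), 2.18)
  # anchor invariance: re-anchor along the same exponential curve
  r20 <- q10_respiration(1.84, 1.5, 20, 17)
  expect_equal(q10_respiration(r20, 1.5, 25, 20),
               q10_respiration(1.84, 1.5, 25, 17))
  expect_error(q10_respiration(-1, 1.5, 20, 17), "r_ref")
})

test_that("apparent Q10 is exact on noiseless data", {
  tt <- seq(4, 30, length.out = 40)
  d <- data.frame(soil_temp = tt, rh = 1.3 * 1.5^((tt - 10) / 10))
  fit <- fit_apparent_q10(d, t_ref = 10)
  expect_equal(fit$q10_hat, 1.5, tolerance = 1e-9)
  expect_equal(fit$r_tref, 1.3, tolerance = 1e-9)
  expect_lt(fit$p_value, 1e-10)
})

test_that("apparent Q10 on noisy data matches the log-linear oracle", {
  set.seed(31)
  tt <- runif(74, 2, 32)
  rh <- 1.8 * 1.6^((tt - 10) / 10) * rlnorm(74, -0.02, 0.2)
  d <- data.frame(soil_temp = tt, rh = rh)
  fit <- fit_apparent_q10(d, t_ref = 10)
  # oracle: regression of ln Rh on (T - t_ref)/10
  ll <- lm(log(rh) ~ I((tt - 10) / 10))
  q_ll <- exp(coef(ll)[[2]])
  se_ll <- q_ll * summary(ll)$coefficients[2, "Std. Error"]
  # the absolute-space and log-space estimators weight the heteroscedastic
  # noise differently; they agree within their combined standard errors
  expect_lt(abs(fit$q10_hat - q_ll), 2 * sqrt(fit$se^2 + se_ll^2))
  # estimator bias below its standard error at n = 74
  expect_lt(abs(fit$q10_hat - 1.6), 2 * fit$se)
})

test_that("apparent Q10 guards degenerate inputs", {
  d <- data.frame(soil_temp = rep(15, 5), rh = rexp(5) + 0.1)
  expect_error(fit_apparent_q10(d), "range")
  d2 <- data.frame(soil_temp = c(10, 20), rh = c(1, 2))
  expect_error(fit_apparent_q10(d2), "3 usable")
  d3 <- data.frame(soil_temp = seq(5, 25, 5), rh = c(-1, 1, 2, 3, 4))
  expect_warning(fit_apparent_q10(d3), "dropped")
})

test_that("the adaptation effect reproduces the worked demonstration", {
  eff <- adaptation_effect(1.77, 1.39, 17, 20, 1.84)
  expect_equal(round(eff$rh_wa, 2), 2.03)
  expect_equal(round(eff$rh_woa, 2), 2.18)
  # the printed-precision arithmetic: (2.18 - 2.03) / 1.84 = 8.2%
  expect_equal(round(100 * (round(eff$rh_woa, 2) - round(eff$rh_wa, 2)) /
                       eff$rh_ct, 1), 8.2)
  # the exact equations give 8.3% at full precision
  expect_equal(round(eff$pct_delta_rh, 1), 8.3)
  expect_equal(eff$delta_rh, eff$rh_woa - eff$rh_wa)

  # hand evaluation of the closed form at other inputs
  eff2 <- adaptation_effect(2, 1.5, 15, 20, 1)
  expect_equal(eff2$rh_wa, 1.5^0.5)
  expect_equal(eff2$rh_woa, 2^0.5)
  expect_equal(eff2$pct_delta_rh, 100 * (sqrt(2) - sqrt(1.5)))

  # no adaptation, no effect; swapping Q10s flips the sign
  expect_equal(adaptation_effect(1.6, 1.6, 17, 20, 1.84)$pct_delta_rh, 0)
  expect_equal(adaptation_effect(1.39, 1.77, 17, 20, 1.84)$pct_delta_rh,
               -adaptation_effect(1.77, 1.39, 17, 20, 1.84)$pct_delta_rh)
  # positive iff the control Q10 exceeds the warming Q10 under warming
  expect_gt(adaptation_effect(1.8, 1.4, 17, 20, 1.84)$pct_delta_rh, 0)
  expect_lt(adaptation_effect(1.4, 1.8, 17, 20, 1.84)$pct_delta_rh, 0)
})

test_that("Monte-Carlo adaptation matches degenerate and exhaustive cases", {
  # degenerate ensembles collapse to the point estimate
  mc <- adaptation_uncertainty(rep(1.77, 5), rep(1.39, 5), 17, 20, 1.84,
                               n_draws = 100, seed = 1)
  expect_equal(mc$summary$mean_pct, mc$effect$pct_delta_rh)
  expect_equal(mc$summary$sd_pct, 0)

  # identical ensembles: mean effect ~ 0 by symmetry
  ens <- c(1.4, 1.5, 1.6, 1.7, 1.8)
  sym <- adaptation_uncertainty(ens, ens, 17, 20, 1.84, n_draws = 20000,
                                seed = 2)
  expect_lt(abs(sym$summary$mean_pct), 0.5)

  # small ensembles: mean matches the exhaustive cross-product oracle
  qc <- c(1.6, 1.7, 1.8, 1.9)
  qw <- c(1.3, 1.4, 1.5)
  mc2 <- adaptation_uncertainty(qc, qw, 17, 20, 1.84, n_draws = 50000,
                                seed = 3)
  grid <- expand.grid(qc = qc, qw = qw)
  exact <- mean(adaptation_effect(grid$qc, grid$qw, 17, 20,
                                  1.84)$pct_delta_rh)
  expect_equal(mc2$summary$mean_pct, exact, tolerance = 0.02)
  expect_lt(mc2$summary$kw_p, 0.05)  # distinct ensembles differ
  expect_error(adaptation_uncertainty(numeric(0), 1.4, 17, 20, 1.84),
               "non-empty")
})

test_that("flux partitioning and GPP derivation follow their identities", {
  expect_equal(partition_respiration(3, 3), 0)
  expect_equal(partition_respiration(3.17, 1.84), 1.33)
  # a heterotrophic fraction fixture: rh / rt = 0.58
  rt <- 2.5; rh <- 0.58 * rt
  expect_equal(rh / rt, 0.58)
  expect_equal(partition_respiration(rt, rh), rt * 0.42)
  expect_warning(partition_respiration(1, 2), "negative")
  expect_equal(derive_gpp(2, 5), 7)  # sink-positive convention
  expect_equal(derive_gpp(-1, 5), 4)
})

test_that("response ratios and their delta-method intervals are exact", {
  expect_equal(response_ratio(c(1, 2, 3), c(1, 2, 3))$rr, 0)
  w <- c(2, 2.2, 1.8); c0 <- c(1, 1.1, 0.9)
  rr <- response_ratio(w, c0)
  expect_equal(rr$rr, log(2))
  # hand-computed delta-method interval
  se <- sqrt(sd(w)^2 / (3 * mean(w)^2) + sd(c0)^2 / (3 * mean(c0)^2))
  expect_equal(rr$se, se)
  expect_equal(rr$lower, log(2) - qnorm(0.975) * se)
  expect_true(rr$significant)
  same <- response_ratio(c(1, 1.2, 0.8), c(1.1, 0.9, 1.05))
  expect_false(same$significant)
  expect_error(response_ratio(c(-2, 1), c(1, 1)), "positive")
})

test_that("single-factor scenarios reproduce the expected signs", {
  f <- fix_forcing(years = 2, seed = 10)
  ctl <- forcing_treatment(f, "control")
  wrm <- forcing_treatment(f, "warming")
  p <- mend_params(q10 = 1.8)
  tab <- single_factor_scenarios(p, ctl, wrm, dt = 0.5)
  expect_equal(tab$pct_change[tab$scenario == "control"], 0)
  expect_gt(tab$pct_change[tab$scenario == "T-only"], 0)
  expect_lt(tab$pct_change[tab$scenario == "W-only"], 0)

  # identical forcings give identically zero changes
  tab0 <- single_factor_scenarios(p, ctl, ctl, dt = 0.5)
  expect_true(all(tab0$pct_change == 0))
  expect_error(single_factor_scenarios(p, ctl[1:100, ], wrm), "aligned")
})
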