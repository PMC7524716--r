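test_that("zero-noise observations recover the truth simulation exactly", {
  f <- fix_forcing(years = 2, seed = 2)
  ctl <- forcing_treatment(f, "control")
  pt <- mend_params(q10 = 1.6)
  obs <- gen_observations(ctl, pt, n_rh = 20, sigma_rh = 0, sigma_mbc = 0,
                          sigma_gene = 0, seed = 1, dt = 0.25)
  sim <- obs$truth
  idx <- match(obs$rh_obs$date, sim$daily$date)
  expect_equal(obs$rh_obs$value, sim$daily$rh_area[idx], tolerance = 1e-12)
  mi <- match(obs$mbc_obs$date, sim$daily$date)
  expect_equal(obs$mbc_obs$value, sim$daily$mbc[mi], tolerance = 1e-12)
  # gene indices correlate perfectly with the annual enzyme pools
  expect_equal(cor(obs$genes$gene_ox, sim$annual_enzymes$enz_ox), 1)
  expect_equal(cor(obs$genes$gene_hyd, sim$annual_enzymes$enz_hyd), 1)
})

test_that("noisy observations match an independent re-generation recipe", {
  f <- fix_forcing(years = 2, seed = 2)
  ctl <- forcing_treatment(f, "control")
  pt <- mend_params(q10 = 1.6)
  obs <- gen_observations(ctl, pt, n_rh = 20, sigma_rh = 0.2,
                          sigma_mbc = 0.15, sigma_gene = 0.1,
                          gene_scale = 100, seed = 77, dt = 0.25)

  # oracle: re-apply the documented noise recipe to the truth run
  sim <- simulate_mend(ctl, pt, dt = 0.25)
  set.seed(77)
  ln <- function(n, s) rlnorm(n, -s^2 / 2, s)
  rh_dates <- sim$daily$date[format(sim$daily$date, "%d") == "15"][1:20]
  rh <- sim$daily$rh_area[match(rh_dates, sim$daily$date)] * ln(20, 0.2)
  mbc_dates <- sim$daily$date[format(sim$daily$date, "%m-%d") == "09-15"]
  mbc <- sim$daily$mbc[match(mbc_dates, sim$daily$date)] *
    ln(length(mbc_dates), 0.15)
  gox <- sim$annual_enzymes$enz_ox * 100 * ln(2, 0.1)
  ghy <- sim$annual_enzymes$enz_hyd * 100 * ln(2, 0.1)

  expect_equal(obs$rh_obs$value, rh, tolerance = 1e-12)
  expect_equal(obs$rh_obs$date, rh_dates)
  expect_equal(obs$mbc_obs$value, mbc, tolerance = 1e-12)
  expect_equal(obs$genes$gene_ox, gox, tolerance = 1e-12)
  expect_equal(obs$genes$gene_hyd, ghy, tolerance = 1e-12)
})

test_that("observation generation is deterministic and validated", {
  f <- fix_forcing(years = 2, seed = 2)
  ctl <- forcing_treatment(f, "control")
  pt <- mend_params()
  a <- gen_observations(ctl, pt, n_rh = 12, seed = 5, dt = 0.5)
  b <- gen_observations(ctl, pt, n_rh = 12, seed = 5, dt = 0.5)
  expect_equal(a$rh_obs, b$rh_obs)
  expect_equal(a$genes, b$genes)
  expect_error(gen_observations(ctl, pt, n_rh = 1e5, dt = 0.5),
               "exceeds|too short")
  expect_true(all(a$rh_obs$value > 0))
  expect_true(all(a$genes$gene_ox > 0))
})
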