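test_that("expected warming enzymes are the elementwise product", {
  expect_equal(expected_warming_enzymes(c(1, 2, 3), c(1, 1, 1)), c(1, 2, 3))
  expect_equal(expected_warming_enzymes(c(1, 2, 3), c(2, 2, 2)), c(2, 4, 6))
  expect_equal(expected_warming_enzymes(c(0.5, 1.2), c(1.3, 0.7)),
               c(0.65, 0.84))
  expect_error(expected_warming_enzymes(1:3, 1:2), "coverage")
  expect_error(expected_warming_enzymes(1:2, c(1, -1)), "> 0")
})

test_that("objective weights follow the 5/8 + 3x1/8 scheme and are checked", {
  s <- objective_spec("gMEND", "control")
  expect_equal(s$weights, c(5, 1, 1, 1) / 8)
  expect_equal(objective_spec("tMEND")$weights, c(5, 1) / 6)
  expect_error(objective_spec("gMEND", weights = c(0.5, 0.2, 0.1, 0.1)),
               "sum to 1")
  expect_equal(overall_objective(c(0, 0, 0, 0), c(5, 1, 1, 1) / 8), 0)
  expect_equal(overall_objective(c(0.4, 0.8, 0.8, 0.8), c(5, 1, 1, 1) / 8),
               0.55)  # 0.25 + 0.3
  expect_error(overall_objective(c(0.1, 0.2), c(0.5, 0.4)), "sum to 1")
  # permutation invariance
  j <- c(0.3, 0.1, 0.7, 0.2); w <- c(5, 1, 1, 1) / 8
  perm <- c(3, 1, 4, 2)
  expect_equal(overall_objective(j, w), overall_objective(j[perm], w[perm]))
})

test_that("objective components reproduce the per-variable metrics", {
  f <- fix_forcing(years = 2, seed = 2)
  ctl <- forcing_treatment(f, "control")
  pt <- mend_params(q10 = 1.6)
  obs <- gen_observations(ctl, pt, n_rh = 20, sigma_rh = 0.1,
                          sigma_mbc = 0.1, sigma_gene = 0.05, seed = 4,
                          dt = 0.25)
  sim <- simulate_mend(ctl, pt, dt = 0.25)

  jc <- objective_components(sim, obs, objective_spec("gMEND", "control"))
  expect_named(jc, c("rh", "mbc", "enz_ox", "enz_hyd"))
  # oracle: metrics applied outside the pipeline
  idx <- match(obs$rh_obs$date, sim$daily$date)
  expect_equal(unname(jc["rh"]),
               1 - r_squared(obs$rh_obs$value, sim$daily$rh_area[idx]))
  mi <- match(obs$mbc_obs$date, sim$daily$date)
  expect_equal(unname(jc["mbc"]),
               mare(obs$mbc_obs$value, sim$daily$mbc[mi]))
  expect_equal(unname(jc["enz_ox"]),
               1 - pearson_r(obs$genes$gene_ox, sim$annual_enzymes$enz_ox))

  # tMEND drops the gene components
  jt <- objective_components(sim, obs, objective_spec("tMEND", "control"))
  expect_named(jt, c("rh", "mbc"))

  # zero noise makes every component (numerically) zero
  obs0 <- gen_observations(ctl, pt, n_rh = 20, sigma_rh = 0, sigma_mbc = 0,
                           sigma_gene = 0, seed = 4, dt = 0.25)
  j0 <- objective_components(sim, obs0, objective_spec("gMEND", "control"))
  expect_true(all(abs(j0) < 1e-10))
})

test_that("warming-mode gene components use the expected-enzyme MARE", {
  f <- fix_forcing(years = 2, seed = 2)
  wrm <- forcing_treatment(f, "warming")
  pt <- mend_params(q10 = 1.4)
  obs <- gen_observations(wrm, pt, n_rh = 20, sigma_rh = 0.1,
                          sigma_gene = 0.05, seed = 9, dt = 0.25)
  sim <- simulate_mend(wrm, pt, dt = 0.25)
  ctl_enz <- sim$annual_enzymes
  ctl_enz$enz_ox <- ctl_enz$enz_ox * 0.9   # stand-in control simulation
  ctl_genes <- obs$genes
  ctl_genes$gene_ox <- ctl_genes$gene_ox * 0.8

  spec <- objective_spec("gMEND", "warming")
  expect_error(objective_components(sim, obs, spec), "control_enzymes")
  jc <- objective_components(sim, obs, spec, control_enzymes = ctl_enz,
                             control_genes = ctl_genes)
  exp_ox <- ctl_enz$enz_ox * (obs$genes$gene_ox / ctl_genes$gene_ox)
  expect_equal(unname(jc["enz_ox"]),
               mare(exp_ox, sim$annual_enzymes$enz_ox))
})
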