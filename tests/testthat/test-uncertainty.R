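test_that("COFI threshold matches its F-based closed form and limits", {
  # hand evaluation with the published F quantile
  expect_equal(cofi_threshold(0.5, p = 11, n = 74, alpha = 0.05),
               0.5 * (1 + 11 / 63 * qf(0.95, 11, 63)))
  # J_cr -> J_min as n grows
  expect_gt(cofi_threshold(0.5, 11, 74), cofi_threshold(0.5, 11, 740))
  expect_equal(cofi_threshold(0.5, 11, 1e7), 0.5, tolerance = 1e-4)
  # ordering holds for any valid input
  for (n in c(15, 74, 300)) expect_gt(cofi_threshold(0.3, 11, n), 0.3)
  expect_error(cofi_threshold(0.5, 11, 11), "exceed")
  expect_error(cofi_threshold(-1, 2, 10), "j_min")
})

test_that("COFI filtering and summaries match a direct recomputation", {
  arch <- tibble::tibble(
    a = c(1, 2, 3, 4, 5), b = c(10, 9, 8, 7, 6),
    j = c(0.2, 0.5, 0.3, 0.9, 0.25), eval = 1:5
  )
  ens <- cofi_ensemble(arch, j_critical = 0.4)
  expect_equal(ens$n_accepted, 3)
  expect_true(all(ens$sets$j < 0.4))
  kept <- arch$a[arch$j < 0.4]
  row <- ens$summary[ens$summary$parameter == "a", ]
  expect_equal(row$mean, mean(kept))
  expect_equal(row$sd, sd(kept))
  expect_equal(row$cv, sd(kept) / mean(kept))
  expect_equal(row$q2.5, quantile(kept, 0.025, names = FALSE))

  full <- cofi_ensemble(arch, j_critical = Inf)
  expect_equal(full$n_accepted, 5)
  expect_error(cofi_ensemble(arch, j_critical = 0.1), "enlarge")
  # ensemble size shrinks monotonically as the threshold tightens
  sizes <- vapply(c(1, 0.6, 0.35, 0.26),
                  function(jc) cofi_ensemble(arch, jc)$n_accepted,
                  numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("the region sampler stays inside the confidence region", {
  fn <- function(x) sum(x^2)
  draws <- cofi_region_sample(fn, c(-2, -2), c(2, 2), j_critical = 0.5,
                              start = c(0, 0), n_iter = 500, seed = 1)
  expect_true(all(draws$j < 0.5))
  expect_true(all(abs(as.matrix(draws[, 1:2])) <= 2))
  expect_error(cofi_region_sample(fn, c(-2, -2), c(2, 2), j_critical = 0.5,
                                  start = c(2, 2), n_iter = 10, seed = 1),
               "inside")
})

test_that("Metropolis sampling reproduces known targets", {
  # flat objective: acceptance ~ 1, uniform marginal on the box
  flat <- suppressWarnings(
    mcmc_sample(function(x) 0.5, c(x = 0), c(x = 1), n_iter = 3000,
                burn_in = 200, proposal_scale = 0.3, temperature = 1,
                seed = 3))
  expect_gt(flat$acceptance_rate, 0.95)
  expect_gt(stats::ks.test(flat$draws$x, "punif")$p.value, 0.01)

  # 1-D quadratic: stationary density exp(-x^2 / T), SD = sqrt(T / 2)
  quad <- mcmc_sample(function(x) x[1]^2, c(x = -3), c(x = 3),
                      n_iter = 4000, burn_in = 500, proposal_scale = 0.15,
                      temperature = 0.5, seed = 2)
  expect_equal(sd(quad$draws$x), sqrt(0.25), tolerance = 0.1)
  expect_true(quad$acceptance_rate > 0.05 && quad$acceptance_rate < 0.7)

  # determinism
  again <- mcmc_sample(function(x) x[1]^2, c(x = -3), c(x = 3),
                       n_iter = 4000, burn_in = 500, proposal_scale = 0.15,
                       temperature = 0.5, seed = 2)
  expect_identical(quad$draws, again$draws)

  # poor acceptance is flagged
  expect_warning(
    mcmc_sample(function(x) 1e3 * x[1]^2, c(x = -3), c(x = 3),
                n_iter = 200, burn_in = 50, proposal_scale = 0.5,
                temperature = 0.01, seed = 1),
    "acceptance rate")
})
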