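# single-pool TECO configuration with constant environmental scalars
one_pool <- function(k = 0.01) {
  teco_params(
    turnover = c(pool = k),
    transfer = matrix(0, 1, 1, dimnames = list("pool", "pool")),
    alloc = c(pool = 1),
    env_sensitive = c(pool = FALSE)
  )
}

test_that("a single pool with zero input decays exponentially", {
  f <- fix_forcing(years = 1, seed = 3)
  ctl <- forcing_treatment(f, "control")
  ctl$c_input <- 0
  k <- 0.01
  sim <- simulate_teco(ctl, one_pool(k), init = c(pool = 5), dt = 0.02)
  t_end <- nrow(ctl)
  expect_equal(sim$daily$pool[t_end], 5 * exp(-k * t_end),
               tolerance = 1e-3)
  # cumulative Rh equals the carbon that left the pool (no transfers)
  expect_equal(sum(sim$daily$rh), 5 - sim$daily$pool[t_end],
               tolerance = 1e-6)
})

test_that("a two-pool chain matches its closed-form solution", {
  f <- fix_forcing(years = 1, seed = 3)
  ctl <- forcing_treatment(f, "control")[1:200, ]
  ctl$c_input <- 0
  k1 <- 0.05; k2 <- 0.01; a21 <- 0.6
  tr <- matrix(0, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  tr["b", "a"] <- a21
  pars <- teco_params(turnover = c(a = k1, b = k2), transfer = tr,
                      alloc = c(a = 1, b = 0),
                      env_sensitive = c(a = FALSE, b = FALSE))
  x0 <- c(a = 3, b = 1)
  sim <- simulate_teco(ctl, pars, init = x0, dt = 0.02)
  # analytic solution of the linear chain (matrix exponential by hand)
  tt <- 200
  a_t <- x0[["a"]] * exp(-k1 * tt)
  b_t <- x0[["b"]] * exp(-k2 * tt) +
    a21 * k1 * x0[["a"]] * (exp(-k2 * tt) - exp(-k1 * tt)) / (k1 - k2)
  expect_equal(sim$daily$a[tt], a_t, tolerance = 1e-2)
  expect_equal(sim$daily$b[tt], b_t, tolerance = 1e-2)
})

test_that("the default 7-pool model conserves carbon and is linear", {
  f <- fix_forcing(years = 3, seed = 5)
  ctl <- forcing_treatment(f, "control")
  sim <- simulate_teco(ctl, teco_params(), dt = 0.25)
  expect_lt(sim$relative_balance_error, 1e-8)
  expect_true(all(sim$daily$rh >= 0))

  # doubling initial pools and inputs doubles the Rh trajectory
  init <- setNames(c(0.5, 0.8, 0.3, 1, 2.5, 5, 2), teco_params()$pools)
  base <- simulate_teco(ctl, teco_params(), init = init, dt = 0.25)
  ctl2 <- ctl; ctl2$c_input <- 2 * ctl2$c_input
  dbl <- simulate_teco(ctl2, teco_params(), init = 2 * init, dt = 0.25)
  expect_equal(dbl$daily$rh, 2 * base$daily$rh, tolerance = 1e-10)
})

test_that("TECO parameter validation catches malformed topologies", {
  p <- teco_params()
  p$transfer[, "som_slow"] <- 0.6
  expect_error(validate_teco_params(p), "sum to <= 1")
  p2 <- teco_params()
  p2$alloc <- p2$alloc * 2
  expect_error(validate_teco_params(p2), "sum to 1")
})
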