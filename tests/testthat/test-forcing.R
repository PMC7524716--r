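test_that("warming contrast is exact: +2.8 degrees and -6.4% moisture", {
  f <- fix_forcing(years = 7, seed = 1)
  ctl <- forcing_treatment(f, "control")
  wrm <- forcing_treatment(f, "warming")
  expect_equal(mean(wrm$soil_temp) - mean(ctl$soil_temp), 2.8,
               tolerance = 1e-12)
  expect_equal(wrm$soil_temp - ctl$soil_temp, rep(2.8, nrow(ctl)),
               tolerance = 1e-12)
  expect_equal(wrm$moisture / ctl$moisture, rep(1 - 0.064, nrow(ctl)),
               tolerance = 1e-12)
})

test_that("zero warming offsets give an identical warming series", {
  f <- gen_forcing(years = 1, seed = 3, warming_delta_t = 0,
                   moisture_reduction = 0)
  ctl <- forcing_treatment(f, "control")
  wrm <- forcing_treatment(f, "warming")
  expect_identical(ctl$soil_temp, wrm$soil_temp)
  expect_identical(ctl$moisture, wrm$moisture)
  expect_identical(ctl$c_input, wrm$c_input)
})

test_that("forcing generation is deterministic in the seed", {
  a <- fix_forcing(years = 2, seed = 11)
  b <- fix_forcing(years = 2, seed = 11)
  c <- fix_forcing(years = 2, seed = 12)
  expect_identical(a, b)
  expect_false(identical(a$soil_temp, c$soil_temp))
})

test_that("forcing satisfies its invariants", {
  f <- fix_forcing(years = 3, seed = 5)
  expect_true(all(f$moisture > 0 & f$moisture < 1))
  expect_true(all(f$ph >= 3 & f$ph <= 10))
  expect_true(all(f$c_input >= 0))
  ctl <- forcing_treatment(f, "control")
  expect_equal(as.integer(diff(ctl$date)), rep(1L, nrow(ctl) - 1))
  # carbon input is blocked in 8-day segments
  runs <- rle(ctl$c_input)
  expect_true(all(head(runs$lengths, -1) == 8))
})

test_that("invalid generator arguments are rejected", {
  expect_error(gen_forcing(years = 0), "years")
  expect_error(gen_forcing(years = 1, moisture_reduction = 1),
               "moisture_reduction")
})

test_that("forcing validation reports gaps and bad columns", {
  f <- fix_forcing(years = 1, seed = 2)
  broken <- f[-5, ]
  expect_error(validate_forcing(broken), "not contiguous")
  expect_error(validate_forcing(f[, -3]), "missing column")
})
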