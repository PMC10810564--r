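test_that("a zero-step noiseless spec gives constant channels", {
  spec <- challenge_spec(dETCO2 = 0, dMABP = 0)
  inp <- make_inputs(spec)
  expect_equal(length(unique(inp$MABP)), 1L)
  expect_equal(length(unique(inp$ETCO2)), 1L)
  expect_equal(length(unique(inp$SpO2)), 1L)
})

test_that("the default challenge raises ETCO2 by ~2 kPa inside the window", {
  inp <- make_inputs(challenge_spec())
  plateau <- mean(inp$ETCO2[inp$t >= 300 & inp$t <= 400]) - inp$ETCO2[1]
  expect_equal(plateau, 2, tolerance = 0.05)
  expect_true(all(abs(inp$SpO2 - 0.98) < 1e-12))
})

test_that("seeded generation is reproducible", {
  spec <- challenge_spec()
  a <- make_inputs(spec, seed = 42)
  b <- make_inputs(spec, seed = 42)
  expect_identical(a, b)
  oa <- make_observations(a, mode = "descriptive", spec = spec, seed = 43)
  ob <- make_observations(b, mode = "descriptive", spec = spec, seed = 43)
  expect_identical(oa, ob)
})

test_that("descriptive observations hit the stated plateaus with a delayed oxCCO rise", {
  obs <- desc_obs()
  spec <- challenge_spec()
  at_offset <- obs[obs$t == spec$offset, ]
  expect_equal(at_offset$oxCCO, 0.58, tolerance = 1e-9)
  win <- obs$t >= 300 & obs$t <= 400
  expect_gt(mean(obs$dCBF_pct[win]), 30)
  expect_gt(mean(obs$TOI[win]) - spec$toi_baseline, 5)

  half_time <- function(v) {
    target <- v[obs$t == spec$offset] / 2
    obs$t[which(v >= target)[1]]
  }
  expect_gt(half_time(obs$oxCCO), half_time(obs$dCBF_pct))
})

test_that("forward mode without noise reproduces the simulation exactly", {
  obs <- fwd_supply_obs()
  sim <- bc_simulate(std_inputs(), true_gen_params())
  expect_equal(obs$dCBF_pct, sim$dCBF_pct, tolerance = 1e-12)
  expect_equal(obs$TOI, sim$TOI, tolerance = 1e-12)
  expect_equal(obs$oxCCO, sim$oxCCO, tolerance = 1e-12)
})

test_that("forward-mode noise has the configured standard deviation", {
  spec <- challenge_spec(noise_obs = c(oxCCO = 0.05))
  noiseless <- fwd_supply_obs()
  noisy <- make_observations(std_inputs(), mode = "forward",
                             params = true_gen_params(), spec = spec,
                             seed = 99)
  resid <- noisy$oxCCO - noiseless$oxCCO
  expect_equal(sd(resid), 0.05, tolerance = 0.15)
  expect_gt(length(resid), 500)
})

test_that("invalid challenge specs are rejected", {
  expect_error(challenge_spec(onset = 500, offset = 400), "onset")
  expect_error(challenge_spec(noise_obs = c(oxCCO = -1)), "noise")
  expect_error(make_observations(std_inputs(), mode = "forward"), "params")
})
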