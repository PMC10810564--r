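tiny_ga <- ga_control(pop_size = 8, generations = 3)

test_that("fits are deterministic given the seed", {
  obs <- fwd_supply_obs()
  f1 <- fit_regime(obs, std_inputs(), "supply", ga = tiny_ga, seed = 5,
                   polish = FALSE)
  f2 <- fit_regime(obs, std_inputs(), "supply", ga = tiny_ga, seed = 5,
                   polish = FALSE)
  expect_identical(f1$par, f2$par)
  expect_identical(cost_total(f1$cost), cost_total(f2$cost))
})

test_that("a warm-started fit is never worse than the generating parameters", {
  obs <- fwd_supply_obs()
  p_true <- true_gen_params()
  truth <- c(p_true$supps, p_true$R_autc, p_true$tau_c, p_true$tau_c2,
             p_true$P_an, p_true$CBF_n)
  f <- fit_regime(obs, std_inputs(), "supply", ga = tiny_ga, seed = 5,
                  init = truth, polish = FALSE)
  sim_true <- bc_simulate(std_inputs(), p_true)
  true_cost <- cost_total(evaluate_cost(obs, sim_true,
                                        weights = cost_weights(obs)))
  expect_lte(cost_total(f$cost), true_cost + 1e-6)
})

test_that("bounds must cover exactly the regime's six free parameters", {
  obs <- fwd_supply_obs()
  b <- default_bounds("supply")
  expect_error(fit_regime(obs, std_inputs(), "supply", bounds = b[-1]),
               "free parameters")
  b2 <- c(b, list(extra = c(0, 1)))
  expect_error(fit_regime(obs, std_inputs(), "supply", bounds = b2),
               "free parameters")
  expect_error(fit_regime(obs, std_inputs(), "demand", bounds = b),
               "free parameters")
})

test_that("noiseless supply-regime data are recovered with tight repeat spread", {
  rf <- recovery_repeats()
  p_true <- true_gen_params()
  expect_identical(nrow(rf$table), 6L)
  expect_true(all(is.finite(rf$stats$sd)))

  best <- rf$best
  expect_equal(best$par[["supps"]], p_true$supps, tolerance = 0.2)
  expect_equal(best$par[["tau_c2"]], p_true$tau_c2, tolerance = 0.3)
  expect_equal(best$par[["tau_c"]], p_true$tau_c, tolerance = 0.3)
  expect_equal(best$par[["R_autc"]], p_true$R_autc, tolerance = 0.3)

  stats <- rf$stats
  expect_lt(stats$sd[stats$term == "supps"] /
            abs(stats$mean[stats$term == "supps"]), 0.1)
})

test_that("repeat tables are reproducible and well formed", {
  obs <- fwd_supply_obs()
  r1 <- repeat_fits(obs, std_inputs(), "supply", ga = tiny_ga, seed = 9,
                    repeats = 3, polish = FALSE)
  r2 <- repeat_fits(obs, std_inputs(), "supply", ga = tiny_ga, seed = 9,
                    repeats = 3, polish = FALSE)
  expect_identical(r1$table, r2$table)
  expect_identical(nrow(r1$table), 3L)
  expect_true(all(r1$stats$sd >= 0))
  expect_error(repeat_fits(obs, std_inputs(), "supply", repeats = 1),
               "repeats")
})

test_that("tidy and glance expose the fit in broom conventions", {
  f <- disc_supply_fit()
  td <- tidy(f)
  expect_named(td, c("term", "estimate", "lower", "upper"))
  expect_identical(td$term[1], "supps")
  g <- glance(f)
  expect_true(all(c("regime", "total_cost", "oxCCO_plateau",
                    "dCMRO2_pct") %in% names(g)))
  rg <- glance(recovery_repeats())
  expect_identical(rg$repeats, 6L)
})

test_that("supply-generated data are fitted better by the supply regime", {
  cs <- cost_total(disc_supply_fit()$cost)
  cd <- cost_total(disc_demand_fit()$cost)
  expect_lt(cs, cd)
})
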