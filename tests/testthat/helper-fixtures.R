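# Shared fixtures, computed once per test run and cached so that the
# expensive objects (GA fits, repeat tables) are reused across test files.

.bc_test_cache <- new.env(parent = emptyenv())

bc_cached <- function(key, expr) {
  if (!exists(key, envir = .bc_test_cache, inherits = FALSE)) {
    assign(key, force(expr), envir = .bc_test_cache)
  }
  get(key, envir = .bc_test_cache, inherits = FALSE)
}

default_params <- function() bc_cached("params", bc_params())

# noiseless standard challenge (2 kPa ETCO2 step, 100-400 s)
std_inputs <- function() bc_cached("inputs", make_inputs(challenge_spec()))

# noiseless descriptive group-mean observations
desc_obs <- function() bc_cached(
  "desc_obs", make_observations(std_inputs(), mode = "descriptive"))

# simulations for the supps/uf sweeps (gain value 0 shared)
sweep_sim <- function(gain, value) {
  key <- paste0("sweep.", gain, ".", value)
  bc_cached(key, {
    p <- if (value == 0) default_params() else {
      do.call(bc_params, setNames(list(value), gain))
    }
    bc_simulate(std_inputs(), p)
  })
}

# desk-scale GA settings used by the heavier fitting tests
test_ga <- function() ga_control(pop_size = 32, generations = 30)

# supply-regime all-signal fit of the descriptive challenge (study question)
supply_fit_desc <- function() bc_cached("supply_fit_desc", {
  fit_regime(desc_obs(), std_inputs(), "supply",
             ga = ga_control(pop_size = 40, generations = 40), seed = 1)
})

# forward-mode data from known supply-regime parameters (recovery problems)
true_gen_params <- function() bc_cached(
  "p_true", bc_params(supps = 0.1, tau_c2 = 180))
fwd_supply_obs <- function() bc_cached(
  "fwd_obs",
  make_observations(std_inputs(), mode = "forward",
                    params = true_gen_params()))

# supply vs demand all-signal fits on the supply-generated data
disc_supply_fit <- function() bc_cached("disc_supply", {
  fit_regime(fwd_supply_obs(), std_inputs(), "supply", ga = test_ga(),
             seed = 7)
})
disc_demand_fit <- function() bc_cached("disc_demand", {
  fit_regime(fwd_supply_obs(), std_inputs(), "demand", ga = test_ga(),
             seed = 7)
})

# repeated recovery fits (parameter-spread statistics)
recovery_repeats <- function() bc_cached("recovery", {
  repeat_fits(fwd_supply_obs(), std_inputs(), "supply", ga = test_ga(),
              seed = 100, repeats = 6)
})

# fixed-step RK4 oracle for the ODE solver, using the pure-R reference
# right-hand side and linear interpolation of the input channels. The step
# must resolve the fast cytochrome pool (|lambda| ~ 5e2 /s), so dt = 2 ms.

# cached adaptive-solver vs RK4-oracle state trajectories on a short
# challenge (shared between the solver and acceptance tests)
oracle_trajectories <- function() bc_cached("oracle", {
  p <- default_params()
  inputs <- make_inputs(challenge_spec(duration = 120, onset = 20,
                                       offset = 100))
  y0 <- bc_steady_state(p, list(MABP = inputs$MABP[1],
                                SpO2 = inputs$SpO2[1],
                                PaCO2 = inputs$PaCO2[1]))
  lsoda <- brainco2:::bc_integrate(
    p, inputs$t,
    list(cbind(inputs$t, inputs$MABP), cbind(inputs$t, inputs$SpO2),
         cbind(inputs$t, inputs$PaCO2)), y0)
  list(lsoda = lsoda, rk4 = rk4_states(inputs, p))
})

rk4_states <- function(inputs, params, dt = 0.002) {
  t_grid <- inputs$t
  interp <- function(ch, tt) approx(inputs$t, inputs[[ch]], xout = tt,
                                    rule = 2)$y
  in_at <- function(tt) list(MABP = interp("MABP", tt),
                             SpO2 = interp("SpO2", tt),
                             PaCO2 = interp("PaCO2", tt))
  y <- bc_steady_state(params, in_at(t_grid[1]))
  out <- matrix(NA_real_, length(t_grid), length(y),
                dimnames = list(NULL, names(y)))
  out[1, ] <- y
  tt <- t_grid[1]
  for (k in 2:length(t_grid)) {
    n_step <- round((t_grid[k] - t_grid[k - 1]) / dt)
    for (j in seq_len(n_step)) {
      k1 <- bc_derivs(y, in_at(tt), params)
      k2 <- bc_derivs(y + dt / 2 * k1, in_at(tt + dt / 2), params)
      k3 <- bc_derivs(y + dt / 2 * k2, in_at(tt + dt / 2), params)
      k4 <- bc_derivs(y + dt * k3, in_at(tt + dt), params)
      y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      tt <- tt + dt
    }
    out[k, ] <- y
  }
  out
}
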