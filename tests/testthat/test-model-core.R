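test_that("derivatives vanish at the calibrated baseline steady state", {
  p <- default_params()
  s <- bc_steady_state(p)
  expect_lt(max(abs(bc_derivs(s, baseline_inputs_at(p), p))), 1e-9)
})

test_that("CO2 filter derivative follows the first-order closed form after a step", {
  p <- default_params()
  s <- bc_steady_state(p)
  for (dP in c(2, 7.5, 15)) {
    i <- baseline_inputs_at(p)
    i$PaCO2 <- p$PaCO2_n + dP
    d <- bc_derivs(s, i, p)
    expect_equal(d[["c1"]], (dP / p$dPaCO2_ref) / p$tau_c, tolerance = 1e-12)
    expect_equal(d[["c2"]], (dP / p$dPaCO2_ref) / p$tau_c2, tolerance = 1e-12)
  }
})

test_that("uf scales the ATP-synthase proton flux linearly via u_eff", {
  p0 <- bc_params()
  p1 <- bc_params(uf = -0.05)
  s <- bc_steady_state(p0)
  s[["c2"]] <- 1   # metabolic CO2 stimulus at its reference level
  i <- baseline_inputs_at(p0)
  a0 <- bc_derivs(s, i, p0, aux = TRUE)$aux
  a1 <- bc_derivs(s, i, p1, aux = TRUE)$aux
  expect_equal(a1[["L_CV"]], 0.95 * a0[["L_CV"]], tolerance = 1e-12)
})

test_that("non-finite states are rejected naming the offending variable", {
  p <- default_params()
  s <- bc_steady_state(p)
  s[["Dp"]] <- NaN
  expect_error(bc_derivs(s, baseline_inputs_at(p), p), "Dp")
})

test_that("steady state at raised PaCO2 raises CBF and TOI and conserves fluxes", {
  p <- default_params()
  s0 <- bc_steady_state(p)
  i1 <- baseline_inputs_at(p)
  i1$PaCO2 <- p$PaCO2_n + 3.75
  s1 <- bc_steady_state(p, i1)
  o0 <- bc_observables(s0, baseline_inputs_at(p), p)
  o1 <- bc_observables(s1, i1, p)
  expect_gt(o1$CBF, o0$CBF)
  expect_gt(o1$TOI, o0$TOI)

  # conservation at any converged steady state
  for (o in list(o0, o1)) {
    expect_lt(abs(o$J_O2 - o$CMRO2), 1e-8)
    balance <- p$p1 * o$f1 + p$p2 * o$f2 + p$p3 * o$f3 - o$L_CV - o$L_leak
    expect_lt(abs(balance), 1e-8)
  }
})

test_that("redox pools stay complementary and bounded along a challenge", {
  sim <- sweep_sim("supps", 0.05)
  # CuA_ox is reported through oxCCO; reconstruct both pool halves
  p <- attr(sim, "params")
  y0 <- attr(sim, "y0")
  cua_ox <- sim$oxCCO / p$cytox_tot + (1 - y0[["CuA_red"]])
  expect_true(all(cua_ox >= 0 & cua_ox <= 1))
  expect_true(all(sim$NADNADHrat > 0))
  expect_true(all(sim$O2_mito >= 0))
  expect_true(all(sim$Dp >= 0))
  expect_true(all(sim$SvO2 >= 0 & sim$SvO2 <= 1))
})

test_that("constant baseline inputs give a flat simulation for 600 s", {
  p <- default_params()
  inputs <- tibble::tibble(t = 0:600, MABP = p$P_an, SpO2 = p$SaO2_n,
                           PaCO2 = p$PaCO2_n)
  sim <- bc_simulate(inputs, p)
  expect_lt(max(abs(sim$CBF / p$CBF_n - 1)), 1e-6)
  expect_lt(max(abs(sim$CMRO2 / p$CMRO2_n - 1)), 1e-6)
  expect_lt(max(abs(sim$Dp / p$Dp_n - 1)), 1e-6)
  expect_lt(max(abs(sim$oxCCO)), 1e-6 * p$cytox_tot)
})

test_that("filtered CO2 stimulus reaches 1 - 1/e of its plateau at t = tau_c", {
  p <- default_params()
  i0 <- baseline_inputs_at(p)
  i1 <- i0; i1$PaCO2 <- p$PaCO2_n + 15
  t_grid <- seq(0, 120, by = 0.25)
  forc <- list(cbind(c(-1, 121), rep(i1$MABP, 2)),
               cbind(c(-1, 121), rep(i1$SpO2, 2)),
               cbind(c(-1, 121), rep(i1$PaCO2, 2)))
  y0 <- bc_steady_state(p, i0)   # step applied at t = 0
  traj <- bc_integrate(p, t_grid, forc, y0)
  c1 <- traj[, "c1"]
  target <- (1 - exp(-1)) * 1.0  # plateau is exactly 1 for a 15 mmHg step
  t_hit <- approx(c1, t_grid, xout = target)$y
  expect_equal(t_hit, p$tau_c, tolerance = 0.01)
})

test_that("adaptive solver matches a fixed-step RK4 oracle on a challenge trajectory", {
  tr <- oracle_trajectories()
  for (nm in bc_state_names()) {
    scale <- max(abs(tr$rk4[, nm]))
    expect_lt(max(abs(tr$lsoda[, nm] - tr$rk4[, nm])) / scale, 1e-4)
  }
})

test_that("solver tolerance changes do not move the outputs materially", {
  inputs <- std_inputs()
  p <- default_params()
  s1 <- bc_simulate(inputs, p)
  s2 <- bc_simulate(inputs, p, rtol = 1e-8, atol = 1e-11)
  for (ch in c("CBF", "TOI", "CMRO2", "Dp")) {
    scale <- max(abs(s2[[ch]]))
    expect_lt(max(abs(s1[[ch]] - s2[[ch]])) / scale, 1e-4)
  }
})

test_that("observables follow their defining algebra", {
  p <- default_params()
  s <- bc_steady_state(p)
  i <- baseline_inputs_at(p)

  # fully oxidised CuA pool
  s2 <- s; s2[["CuA_red"]] <- 0
  o2 <- bc_observables(s2, i, p)
  expect_equal(o2$oxCCO, p$cytox_tot * (1 - p$CuA_ox_n), tolerance = 1e-12)

  # AVR -> 0 limit: TOI reads the venous compartment only
  p0 <- bc_params(AVR_n = 1e-9)
  s0 <- bc_steady_state(p0)
  o0 <- bc_observables(s0, baseline_inputs_at(p0), p0)
  expect_equal(o0$TOI, 100 * o0$SvO2, tolerance = 1e-6)

  # unphysical extraction errors: shrink the vessel radius drastically
  s3 <- s; s3[["r"]] <- 0.3
  expect_error(bc_observables(s3, i, p), "SvO2")
})
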