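test_that("calibration puts the baseline steady state exactly on the nominal targets", {
  p <- default_params()
  s <- bc_steady_state(p)
  o <- bc_observables(s, baseline_inputs_at(p), p)

  expect_equal(o$CBF, p$CBF_n, tolerance = 1e-6)
  expect_equal(s[["Dp"]], p$Dp_n, tolerance = 1e-6)
  expect_equal(o$CMRO2, p$CMRO2_n, tolerance = 1e-6)
  expect_equal(o$TOI, p$TOI_n, tolerance = 1e-6)
  expect_equal(o$oxCCO, 0, tolerance = 1e-9)
  expect_equal(s[["NADH"]], p$NADH_frac_n, tolerance = 1e-6)
  expect_equal(s[["a3_red"]], p$a3_red_n, tolerance = 1e-6)
  expect_equal(s[["O2"]], p$O2_mito_n, tolerance = 1e-6)
})

test_that("unmodified defaults: u = 1, supps = uf = 0, demand decoupled from CBF", {
  p <- default_params()
  expect_identical(p$u, 1)
  expect_identical(p$supps, 0)
  expect_identical(p$uf, 0)
  expect_identical(p$R_u, 0)
})

test_that("derived rate constants are positive and overrides recalibrate them", {
  p <- default_params()
  for (nm in c("k1", "k2", "k3", "k_prod", "D_O2", "k_leak", "r_CV", "C_buf")) {
    expect_gt(p[[nm]], 0)
  }
  p2 <- bc_params(CBF_n = 0.01)
  expect_false(isTRUE(all.equal(p2$D_O2, p$D_O2)))
  s2 <- bc_steady_state(p2)
  o2 <- bc_observables(s2, baseline_inputs_at(p2), p2)
  expect_equal(o2$CBF, 0.01, tolerance = 1e-6)
})

test_that("parameter validation rejects bad inputs with informative errors", {
  expect_error(bc_params(nonsense = 1), "unknown parameter")
  expect_error(bc_params(k1 = 5), "derived parameter")
  expect_error(bc_params(gamma1 = 20), "gamma2 > gamma1")
  expect_error(bc_params(tau_c = -1), "tau_c")
  # calibration failure: capillary O2 scale below the mitochondrial target
  expect_error(bc_params(K_O2cap = 0.01), "O2_mito_n|capillary")
})

test_that("parameter sets round-trip through flat YAML", {
  p <- bc_params(supps = 0.07, tau_c2 = 120)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_params(p, path)
  p2 <- read_params(path)
  expect_equal(p2$supps, 0.07)
  expect_equal(p2$tau_c2, 120)
  expect_equal(p2$k1, p$k1, tolerance = 1e-12)
})

test_that("default CO2 vasoreactivity is ~4 percent CBF per mmHg at small signal", {
  p <- default_params()
  s0 <- bc_steady_state(p)
  i1 <- baseline_inputs_at(p)
  i1$PaCO2 <- p$PaCO2_n + 1
  s1 <- bc_steady_state(p, i1)
  o0 <- bc_observables(s0, baseline_inputs_at(p), p)
  o1 <- bc_observables(s1, i1, p)
  react <- 100 * (o1$CBF / o0$CBF - 1)
  expect_equal(react, 4, tolerance = 0.05)
})
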