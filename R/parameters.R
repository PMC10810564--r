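#' Build a calibrated model parameter set
#'
#' Returns the full parameter set of the circulation + mitochondria model,
#' calibrated so that with baseline inputs (MABP = `P_an`, SpO2 = `SaO2_n`,
#' PaCO2 = `PaCO2_n`) the steady state sits exactly on the nominal targets
#' (`CBF_n`, `CMRO2_n`, `Dp_n`, `CuA_ox_n`, `a3_red_n`, `NADH_frac_n`,
#' `O2_mito_n` and the derived `TOI_n`). The rate constants `k1`, `k2`, `k3`,
#' `k_prod`, `D_O2`, `k_leak`, `r_CV` and the proton capacitance `C_buf` are
#' solved from those targets; `R_autc` defaults to the value giving a
#' small-signal CBF reactivity of `cbf_reactivity_n` percent per mmHg PaCO2.
#'
#' The two CO2-metabolism gains are `supps` (substrate supply: positive values
#' throttle NADH production, raising the NAD/NADH ratio) and `uf` (ATP
#' demand: the effective demand is `u * (1 + uf * c2)` inside the ATP-synthase
#' proton flux). Both default to 0, i.e. the unmodified model in which CO2
#' reaches metabolism only through blood flow and oxygen delivery. `R_u` is
#' fixed at 0: functional-activation demand is decoupled from CBF.
#'
#' @param ... Named parameter overrides (e.g. `supps = 0.05`, `tau_c = 25`).
#'   Unknown names are an error. Derived rate constants cannot be overridden;
#'   they are recomputed from the targets on every call.
#'
#' @return A named list of class `bc_params` with all constants of the model,
#'   including the derived rates and an attribute `calibrated = TRUE`.
#'
#' @examples
#' p <- bc_params()
#' p$R_autc                     # CO2 vasoreactivity gain (~0.3)
#' p2 <- bc_params(supps = 0.05, tau_c2 = 180)
#' @export
bc_params <- function(...) {
  overrides <- list(...)
  if (length(overrides) == 1L && is.list(overrides[[1]]) && is.null(names(overrides))) {
    overrides <- overrides[[1]]
  }
  defaults <- bc_param_defaults()
  if (length(overrides)) {
    nm <- names(overrides)
    if (is.null(nm) || any(nm == "")) {
      abort("all parameter overrides must be named")
    }
    unknown <- setdiff(nm, names(defaults))
    if (length(unknown)) {
      abort(paste0("unknown parameter(s): ", paste(unknown, collapse = ", ")))
    }
    derived <- intersect(nm, bc_derived_names())
    if (length(derived)) {
      abort(paste0(
        "derived parameter(s) cannot be overridden (recomputed by calibration): ",
        paste(derived, collapse = ", ")
      ))
    }
    defaults[nm] <- overrides
  }
  p <- bc_calibrate(defaults)
  bc_validate_params(p)
  structure(p, class = "bc_params", calibrated = TRUE)
}

# Nominal (non-derived) defaults. Units: pressures mmHg, times s,
# concentrations mM (cytox_tot in uM as reported by NIRS), Dp in mV,
# CBF in ml blood / ml tissue / s.
bc_param_defaults <- function() {
  list(
    # fit-able set
    supps  = 0,       # CO2 -> substrate-supply gain (positive = supply falls)
    uf     = 0,       # CO2 -> ATP-demand gain (positive = demand rises)
    R_autc = NA_real_, # CO2 vasoreactivity gain; derived unless overridden
    tau_c  = 30,      # s, vascular CO2 filter
    tau_c2 = 30,      # s, metabolic CO2 filter
    P_an   = 90,      # mmHg, normal MABP
    CBF_n  = 0.0083,  # s^-1 (~50 ml/100g/min)
    # circulation
    R_autp = 1.0,     # pressure autoregulation gain
    R_u    = 0,       # demand -> CBF coupling, fixed 0
    k_r    = 0.5,     # max fractional radius change
    t_r    = 5,       # s, radius relaxation
    tau_P  = 5,       # s, pressure filter
    r_n    = 1,       # normal vessel radius (arbitrary length unit)
    P_v    = 4,       # mmHg, venous pressure
    dPaCO2_ref = 15,  # mmHg, reference CO2 excursion (~2 kPa) normalizing c1/c2
    PaCO2_n    = 37.5, # mmHg (5 kPa)
    cbf_reactivity_n = 4, # % dCBF per mmHg PaCO2, small-signal target
    # oxygen transport & optics
    H_b      = 8.9,    # mM O2 carrying capacity of blood
    AVR_n    = 0.25,   # baseline arterial volume fraction of optical field
    K_O2cap  = 0.06,   # mM, capillary dissolved-O2 scale
    Km_O2    = 5e-4,   # mM, haem a3 oxygen affinity
    O2_mito_n = 0.024, # mM
    SaO2_n   = 0.98,   # baseline arterial saturation (fraction)
    avr_dynamic = 1,   # 1: TOI arterial weight follows vessel radius; 0: fixed AVR_n
    # mitochondria
    u          = 1,    # baseline demand (not varied)
    D_NADH     = 0.2,  # exponent of the legacy u^(2*D_NADH) supply coupling
    NADH_frac_n = 0.1, # baseline NADH/(NAD+NADH) (NAD/NADH = 9)
    NAD_tot    = 0.25, # mM, total NAD pool
    cytox_tot  = 2.2,  # uM, NIRS-visible CuA pool
    CuA_ox_n   = 0.67, # baseline oxidised CuA fraction
    a3_red_n   = 0.10, # baseline reduced haem a3 fraction
    K_N        = 0.1,  # NAD-dependence of substrate production
    Dp_n       = 145,  # mV, baseline proton motive force
    Dp_CV0     = 90,   # mV, Dp at which ATP-synthase flux vanishes
    Z          = 59.0, # mV, Nernstian slope
    p1 = 4, p2 = 1, p3 = 1, # H+ pumped per electron at f1/f2/f3
    gamma1 = 2, gamma2 = 15, gamma3 = 0.5, # Dp-sensitivities of f1/f2/f3
    leak_frac_n = 0.25, # fraction of baseline proton re-entry via leak
    tau_Dp     = 5,     # s, target relaxation time of Dp
    CMRO2_n    = 0.024, # mM O2 / s
    # derived by calibration (placeholders)
    k1 = NA_real_, k2 = NA_real_, k3 = NA_real_, k_prod = NA_real_,
    D_O2 = NA_real_, k_leak = NA_real_, r_CV = NA_real_, C_buf = NA_real_,
    SvO2_n = NA_real_, TOI_n = NA_real_
  )
}

bc_derived_names <- function() {
  c("k1", "k2", "k3", "k_prod", "D_O2", "k_leak", "r_CV", "C_buf",
    "SvO2_n", "TOI_n")
}

# Solve the rate constants so that the baseline steady state sits exactly on
# the nominal targets. All relations are closed-form.
bc_calibrate <- function(p) {
  f_n <- 4 * p$CMRO2_n               # electron flux through the chain, mM e-/s
  CuA_red_n <- 1 - p$CuA_ox_n
  a3_ox_n   <- 1 - p$a3_red_n
  NADfrac_n <- 1 - p$NADH_frac_n
  sat_n <- p$O2_mito_n / (p$O2_mito_n + p$Km_O2)

  if (CuA_red_n <= 0 || a3_ox_n <= 0 || NADfrac_n <= 0) {
    abort("calibration failure: baseline redox fractions leave no oxidised/reduced pool")
  }
  p$k1 <- f_n / (p$CuA_ox_n * p$NADH_frac_n)
  p$k2 <- f_n / (CuA_red_n * a3_ox_n)
  p$k3 <- f_n / (p$a3_red_n * sat_n)
  p$k_prod <- (f_n / 2) * (NADfrac_n + p$K_N) / (NADfrac_n * p$u^(2 * p$D_NADH))

  # Oxygen delivery: capillary dissolved O2 tracks mean capillary saturation.
  p$SvO2_n <- p$SaO2_n - p$CMRO2_n / (p$CBF_n * p$H_b)
  if (p$SvO2_n <= 0) {
    abort("calibration failure: baseline venous saturation (SvO2_n) is not positive; check CBF_n, CMRO2_n, H_b")
  }
  O2cap_n <- p$K_O2cap * (p$SaO2_n + p$SvO2_n) / 2
  if (O2cap_n <= p$O2_mito_n) {
    abort("calibration failure: capillary O2 does not exceed mitochondrial O2 (O2_mito_n target unreachable); check K_O2cap")
  }
  p$D_O2 <- p$CMRO2_n / (O2cap_n - p$O2_mito_n)

  # Proton balance at baseline: pumping = L_CV + L_leak, split by leak_frac_n.
  L_tot <- (p$p1 + p$p2 + p$p3) * f_n
  theta_n <- (p$Dp_n - p$Dp_CV0) / p$Z
  if (theta_n <= 0) {
    abort("calibration failure: Dp_n must exceed Dp_CV0 for forward ATP synthesis")
  }
  p$k_leak <- p$leak_frac_n * L_tot / p$Dp_n
  p$r_CV <- (1 - p$leak_frac_n) * L_tot / (p$u * (exp(theta_n) - 1))

  # Proton capacitance: set so Dp relaxes with ~tau_Dp at baseline
  # (|d(net flux)/dDp| evaluated analytically at the calibration point).
  dnet_dDp <- (p$p1 * f_n * p$gamma1 + p$p2 * f_n * p$gamma2 + p$p3 * f_n * p$gamma3) / p$Z +
    p$r_CV * p$u * exp(theta_n) / p$Z + p$k_leak
  p$C_buf <- p$tau_Dp * dnet_dDp

  # TOI at baseline (arterial weight = AVR_n since r = r_n).
  p$TOI_n <- 100 * (p$AVR_n * p$SaO2_n + (1 - p$AVR_n) * p$SvO2_n)

  # CO2 vasoreactivity gain from the small-signal reactivity target:
  # dCBF%/dPaCO2 at 0 = 400 * k_r * R_autc / dPaCO2_ref.
  if (is.na(p$R_autc)) {
    p$R_autc <- p$cbf_reactivity_n * p$dPaCO2_ref / (400 * p$k_r)
  }
  p
}

bc_validate_params <- function(p) {
  pos <- c("tau_c", "tau_c2", "P_an", "CBF_n", "k_r", "t_r", "tau_P", "r_n",
           "dPaCO2_ref", "PaCO2_n", "H_b", "K_O2cap", "Km_O2", "O2_mito_n",
           "u", "NAD_tot", "cytox_tot", "K_N", "Dp_n", "Z", "C_buf",
           "tau_Dp", "CMRO2_n", "k1", "k2", "k3", "k_prod", "D_O2",
           "k_leak", "r_CV", "R_autc")
  for (nm in pos) {
    if (!is.finite(p[[nm]]) || p[[nm]] <= 0) {
      abort(paste0("parameter '", nm, "' must be finite and > 0"))
    }
  }
  frac <- c("SaO2_n", "AVR_n", "NADH_frac_n", "CuA_ox_n", "a3_red_n",
            "leak_frac_n", "SvO2_n")
  for (nm in frac) {
    if (!is.finite(p[[nm]]) || p[[nm]] < 0 || p[[nm]] > 1) {
      abort(paste0("parameter '", nm, "' must lie in [0, 1]"))
    }
  }
  if (p$R_u != 0) {
    abort("R_u is fixed at 0 (demand is decoupled from CBF)")
  }
  if (!(p$gamma2 > p$gamma1 && p$gamma1 >= 0)) {
    abort("require gamma2 > gamma1 >= 0 (demand reduction must reduce CuA oxidation)")
  }
  if (p$P_an <= p$P_v) abort("P_an must exceed venous pressure P_v")
  invisible(p)
}

#' @export
print.bc_params <- function(x, ...) {
  cat("<bc_params> calibrated model parameter set\n")
  cat(sprintf("  regimes: supps = %g, uf = %g (u = %g, R_u = %g)\n",
              x$supps, x$uf, x$u, x$R_u))
  cat(sprintf("  circulation: R_autc = %.4g, tau_c = %g s, tau_c2 = %g s, P_an = %g mmHg, CBF_n = %g /s\n",
              x$R_autc, x$tau_c, x$tau_c2, x$P_an, x$CBF_n))
  cat(sprintf("  baseline: CMRO2_n = %g mM/s, Dp_n = %g mV, NAD/NADH = %.3g, TOI_n = %.3f %%\n",
              x$CMRO2_n, x$Dp_n, (1 - x$NADH_frac_n) / x$NADH_frac_n, x$TOI_n))
  cat(sprintf("  derived rates: k1 = %.4g, k2 = %.4g, k3 = %.4g, k_prod = %.4g, D_O2 = %.4g\n",
              x$k1, x$k2, x$k3, x$k_prod, x$D_O2))
  invisible(x)
}

# Parameter vector in the fixed order shared with the compiled RHS.
bc_param_vector <- function(p) {
  c(p$supps, p$uf, p$R_autc, p$tau_c, p$tau_c2, p$P_an, p$CBF_n,
    p$R_autp, p$k_r, p$t_r, p$tau_P, p$r_n, p$P_v, p$dPaCO2_ref, p$PaCO2_n,
    p$H_b, p$K_O2cap, p$Km_O2,
    p$u, p$D_NADH, p$K_N, p$NAD_tot, p$cytox_tot * 1e-3,
    p$Dp_n, p$Dp_CV0, p$Z, p$p1, p$p2, p$p3, p$gamma1, p$gamma2, p$gamma3,
    p$C_buf, p$k_leak, p$r_CV, p$k1, p$k2, p$k3, p$k_prod, p$D_O2)
}

#' Read or write a parameter set as flat YAML
#'
#' Only the nominal (non-derived) parameters are written; reading rebuilds the
#' calibrated set via [bc_params()].
#'
#' @param p A `bc_params` object.
#' @param path File path of the YAML file.
#' @return `read_params()` returns a `bc_params`; `write_params()` returns
#'   `path` invisibly.
#' @export
write_params <- function(p, path) {
  stopifnot(inherits(p, "bc_params"))
  nominal <- p[setdiff(names(p), bc_derived_names())]
  yaml::write_yaml(nominal, path)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  vals <- yaml::read_yaml(path)
  keep <- setdiff(names(vals), bc_derived_names())
  do.call(bc_params, vals[keep])
}
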