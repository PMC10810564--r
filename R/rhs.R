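#' Model state and derivative evaluation
#'
#' `bc_state_names()` gives the order of the nine ODE state variables.
#' `bc_derivs()` evaluates the right-hand side of the model at one instant;
#' it is the reference (pure R) implementation of the same equations compiled
#' in C for integration, and is exposed for inspection and testing.
#'
#' States: `P_filt` (filtered MABP, mmHg), `c1`/`c2` (filtered vascular and
#' metabolic CO2 stimuli, dimensionless fractional excursions), `r` (vessel
#' radius), `NADH` (NADH fraction of the NAD pool), `CuA_red` (reduced CuA
#' fraction), `a3_red` (reduced haem a3 fraction), `O2` (mitochondrial O2,
#' mM), `Dp` (proton motive force, mV).
#'
#' @param state Named numeric vector of the nine states (order of
#'   [bc_state_names()]).
#' @param inputs_t List or named vector with instantaneous `MABP` (mmHg),
#'   `SpO2` (fraction) and `PaCO2` (mmHg).
#' @param params A [bc_params()] object.
#' @param aux If `TRUE` return the auxiliary fluxes alongside the derivatives.
#' @return Named numeric vector of derivatives, or (with `aux = TRUE`) a list
#'   with elements `deriv` and `aux` (fluxes `f1`, `f2`, `f3`, `J_prod`,
#'   `J_O2`, `L_CV`, `L_leak`, plus `CBF`, `SvO2`).
#' @examples
#' p <- bc_params()
#' s <- bc_steady_state(p)
#' max(abs(bc_derivs(s, baseline_inputs_at(p), p)))  # ~0 at baseline
#' @export
bc_derivs <- function(state, inputs_t, params, aux = FALSE) {
  if (!all(is.finite(state))) {
    bad <- bc_state_names()[!is.finite(state)]
    abort(paste0("non-finite state variable(s): ", paste(bad, collapse = ", ")))
  }
  p <- params
  s <- as.list(setNames(as.numeric(state), bc_state_names()))
  MABP <- inputs_t[["MABP"]]; SpO2 <- inputs_t[["SpO2"]]; PaCO2 <- inputs_t[["PaCO2"]]

  x <- (PaCO2 - p$PaCO2_n) / p$dPaCO2_ref
  dP_filt <- (MABP - s$P_filt) / p$tau_P
  dc1 <- (x - s$c1) / p$tau_c
  dc2 <- (x - s$c2) / p$tau_c2

  r_inf <- p$r_n * (1 + p$k_r * tanh(p$R_autc * s$c1 - p$R_autp * (s$P_filt / p$P_an - 1)))
  dr <- (r_inf - s$r) / p$t_r

  CBF <- p$CBF_n * (s$r / p$r_n)^4 * (MABP - p$P_v) / (p$P_an - p$P_v)

  u_eff <- max(p$u * (1 + p$uf * s$c2), 0)
  NADf <- 1 - s$NADH
  J_prod <- max(p$k_prod * p$u^(2 * p$D_NADH) * (1 - p$supps * s$c2), 0) *
    NADf / (NADf + p$K_N)

  e1 <- exp(-p$gamma1 * (s$Dp - p$Dp_n) / p$Z)
  e2 <- exp(-p$gamma2 * (s$Dp - p$Dp_n) / p$Z)
  e3 <- exp(-p$gamma3 * (s$Dp - p$Dp_n) / p$Z)
  O2c <- max(s$O2, 0)
  f1 <- p$k1 * (1 - s$CuA_red) * s$NADH * e1
  f2 <- p$k2 * s$CuA_red * (1 - s$a3_red) * e2
  f3 <- p$k3 * s$a3_red * (O2c / (O2c + p$Km_O2)) * e3

  CMRO2 <- f3 / 4
  SvO2 <- min(max(SpO2 - CMRO2 / (CBF * p$H_b), 0), SpO2)
  O2cap <- p$K_O2cap * (SpO2 + SvO2) / 2
  J_O2 <- p$D_O2 * (O2cap - s$O2)

  theta <- (s$Dp - p$Dp_CV0) / p$Z
  L_CV <- if (s$Dp > p$Dp_CV0) p$r_CV * u_eff * (exp(theta) - 1) else 0
  L_leak <- p$k_leak * s$Dp

  cytox_mM <- p$cytox_tot * 1e-3
  deriv <- c(
    P_filt  = dP_filt,
    c1      = dc1,
    c2      = dc2,
    r       = dr,
    NADH    = (J_prod - f1 / 2) / p$NAD_tot,
    CuA_red = (f1 - f2) / cytox_mM,
    a3_red  = (f2 - f3) / cytox_mM,
    O2      = J_O2 - f3 / 4,
    Dp      = (p$p1 * f1 + p$p2 * f2 + p$p3 * f3 - L_CV - L_leak) / p$C_buf
  )
  if (!aux) return(deriv)
  list(deriv = deriv,
       aux = c(f1 = f1, f2 = f2, f3 = f3, J_prod = J_prod, J_O2 = J_O2,
               L_CV = L_CV, L_leak = L_leak, CBF = CBF, SvO2 = SvO2,
               CMRO2 = CMRO2))
}

#' @rdname bc_derivs
#' @export
bc_state_names <- function() {
  c("P_filt", "c1", "c2", "r", "NADH", "CuA_red", "a3_red", "O2", "Dp")
}

#' Baseline input triple for a parameter set
#'
#' The constant inputs at which the model was calibrated: `MABP = P_an`,
#' `SpO2 = SaO2_n`, `PaCO2 = PaCO2_n`.
#'
#' @param params A [bc_params()] object.
#' @return Named list with `MABP`, `SpO2`, `PaCO2`.
#' @export
baseline_inputs_at <- function(params) {
  list(MABP = params$P_an, SpO2 = params$SaO2_n, PaCO2 = params$PaCO2_n)
}
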