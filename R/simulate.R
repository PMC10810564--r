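#' Derived observables at a model state
#'
#' Maps an instantaneous state to the measurable quantities: CBF, middle
#' cerebral artery velocity change (identical to the CBF change in percent,
#' constant vessel cross-section), TOI (arterio-venous weighted haemoglobin
#' saturation of the optical field), the NIRS oxCCO change
#' `cytox_tot * (CuA_ox - ref)`, CMRO2 (`f3/4`), venous saturation and the
#' internal fluxes.
#'
#' @param state Named state vector (see [bc_state_names()]).
#' @param inputs_t Instantaneous inputs (`MABP`, `SpO2`, `PaCO2`).
#' @param params A [bc_params()] object.
#' @param cua_ox_ref Reference oxidised CuA fraction for the oxCCO change
#'   (default `CuA_ox_n`; [bc_simulate()] passes the run's initial value).
#' @param cbf_ref Reference CBF for percentage changes (default `CBF_n`).
#' @return A one-row tibble of observables.
#' @export
bc_observables <- function(state, inputs_t, params,
                           cua_ox_ref = params$CuA_ox_n,
                           cbf_ref = params$CBF_n) {
  d <- bc_derivs(state, inputs_t, params, aux = TRUE)
  a <- as.list(d$aux)
  p <- params
  s <- as.list(state)
  svo2_raw <- inputs_t[["SpO2"]] - a$CMRO2 / (a$CBF * p$H_b)
  if (svo2_raw < -1e-9 || svo2_raw > inputs_t[["SpO2"]] + 1e-9) {
    abort("unphysical oxygen extraction: SvO2 outside [0, SaO2]")
  }
  w_a <- if (p$avr_dynamic != 0) {
    rr2 <- (s$r / p$r_n)^2
    p$AVR_n * rr2 / (p$AVR_n * rr2 + (1 - p$AVR_n))
  } else {
    p$AVR_n
  }
  dcbf <- 100 * (a$CBF / cbf_ref - 1)
  tibble(
    CBF = a$CBF,
    dCBF_pct = dcbf,
    Vmca_pct = dcbf,
    TOI = 100 * (w_a * inputs_t[["SpO2"]] + (1 - w_a) * a$SvO2),
    oxCCO = p$cytox_tot * ((1 - s$CuA_red) - cua_ox_ref),
    CMRO2 = a$CMRO2,
    SvO2 = a$SvO2,
    Dp = s$Dp,
    NADNADHrat = (1 - s$NADH) / s$NADH,
    O2_mito = s$O2,
    f1 = a$f1, f2 = a$f2, f3 = a$f3,
    J_O2 = a$J_O2, L_CV = a$L_CV, L_leak = a$L_leak
  )
}

#' Simulate the model over an input trace
#'
#' Integrates the nine-state ODE system over the time grid of `inputs` with a
#' stiff-capable adaptive solver (lsoda, compiled right-hand side), starting
#' from the steady state at the first sample's inputs. Percentage CBF change
#' and the oxCCO change are reported relative to that initial steady state, so
#' all delta channels start at zero.
#'
#' @param inputs Input trace: a data frame with columns `t` (s, uniform),
#'   `MABP` (mmHg), `SpO2` (fraction) and `PaCO2` (mmHg), e.g. from
#'   [make_inputs()] or [read_trace()].
#' @param params A [bc_params()] object (default [bc_params()]).
#' @param rtol,atol Solver tolerances.
#' @return A tibble of class `bc_sim` with one row per input sample and
#'   columns `t`, `CBF`, `dCBF_pct`, `Vmca_pct`, `TOI`, `oxCCO`, `CMRO2`,
#'   `SvO2`, `Dp`, `NADNADHrat`, `O2_mito`, `f1`, `f2`, `f3`, `J_O2`, `L_CV`,
#'   `L_leak`. The parameter set and initial state are kept as attributes.
#' @examples
#' inp <- make_inputs(challenge_spec(duration = 300))
#' sim <- bc_simulate(inp, bc_params(supps = 0.05))
#' @export
bc_simulate <- function(inputs, params = bc_params(),
                        rtol = 1e-6, atol = 1e-9) {
  inputs <- validate_input_trace(inputs)
  p <- params
  inputs0 <- list(MABP = inputs$MABP[1], SpO2 = inputs$SpO2[1],
                  PaCO2 = inputs$PaCO2[1])
  y0 <- bc_steady_state(p, inputs0)
  forc <- list(cbind(inputs$t, inputs$MABP),
               cbind(inputs$t, inputs$SpO2),
               cbind(inputs$t, inputs$PaCO2))
  traj <- bc_integrate(p, times = inputs$t, forcings = forc, y0 = y0,
                       rtol = rtol, atol = atol)
  out <- bc_observe_trajectory(traj, inputs, p, y0)
  class(out) <- c("bc_sim", class(out))
  attr(out, "params") <- p
  attr(out, "y0") <- y0
  out
}

# Vectorized observables over an integrated trajectory (same formulas as
# bc_observables, applied columnwise).
bc_observe_trajectory <- function(traj, inputs, p, y0) {
  P_filt <- traj[, "P_filt"]; c1 <- traj[, "c1"]; c2 <- traj[, "c2"]
  r <- traj[, "r"]; NADH <- traj[, "NADH"]; CuA_red <- traj[, "CuA_red"]
  a3_red <- traj[, "a3_red"]; O2 <- traj[, "O2"]; Dp <- traj[, "Dp"]
  MABP <- inputs$MABP; SpO2 <- inputs$SpO2; PaCO2 <- inputs$PaCO2

  CBF <- p$CBF_n * (r / p$r_n)^4 * (MABP - p$P_v) / (p$P_an - p$P_v)
  u_eff <- pmax(p$u * (1 + p$uf * c2), 0)
  e1 <- exp(-p$gamma1 * (Dp - p$Dp_n) / p$Z)
  e2 <- exp(-p$gamma2 * (Dp - p$Dp_n) / p$Z)
  e3 <- exp(-p$gamma3 * (Dp - p$Dp_n) / p$Z)
  O2c <- pmax(O2, 0)
  f1 <- p$k1 * (1 - CuA_red) * NADH * e1
  f2 <- p$k2 * CuA_red * (1 - a3_red) * e2
  f3 <- p$k3 * a3_red * (O2c / (O2c + p$Km_O2)) * e3
  CMRO2 <- f3 / 4
  SvO2 <- pmin(pmax(SpO2 - CMRO2 / (CBF * p$H_b), 0), SpO2)
  O2cap <- p$K_O2cap * (SpO2 + SvO2) / 2
  J_O2 <- p$D_O2 * (O2cap - O2)
  L_CV <- ifelse(Dp > p$Dp_CV0,
                 p$r_CV * u_eff * (exp((Dp - p$Dp_CV0) / p$Z) - 1), 0)
  L_leak <- p$k_leak * Dp
  w_a <- if (p$avr_dynamic != 0) {
    rr2 <- (r / p$r_n)^2
    p$AVR_n * rr2 / (p$AVR_n * rr2 + (1 - p$AVR_n))
  } else {
    rep(p$AVR_n, length(r))
  }

  cbf0 <- p$CBF_n * (y0[["r"]] / p$r_n)^4 * (MABP[1] - p$P_v) / (p$P_an - p$P_v)
  cua_ox0 <- 1 - y0[["CuA_red"]]
  dcbf <- 100 * (CBF / cbf0 - 1)

  tibble(
    t = inputs$t,
    CBF = CBF, dCBF_pct = dcbf, Vmca_pct = dcbf,
    TOI = 100 * (w_a * SpO2 + (1 - w_a) * SvO2),
    oxCCO = p$cytox_tot * ((1 - CuA_red) - cua_ox0),
    CMRO2 = CMRO2, SvO2 = SvO2, Dp = Dp,
    NADNADHrat = (1 - NADH) / NADH, O2_mito = O2,
    f1 = f1, f2 = f2, f3 = f3, J_O2 = J_O2, L_CV = L_CV, L_leak = L_leak
  )
}

validate_input_trace <- function(inputs) {
  inputs <- as_tibble(inputs)
  need <- c("t", "MABP", "SpO2", "PaCO2")
  missing <- setdiff(need, names(inputs))
  if (length(missing)) {
    abort(paste0("input trace is missing channel(s): ", paste(missing, collapse = ", ")))
  }
  if (nrow(inputs) < 2) abort("input trace needs at least two samples")
  dt <- diff(inputs$t)
  if (any(dt <= 0) || diff(range(dt)) > 1e-6 * mean(dt)) {
    abort("input trace must have a strictly increasing uniform time grid")
  }
  for (ch in need) {
    if (!all(is.finite(inputs[[ch]]))) abort(paste0("non-finite values in channel ", ch))
  }
  if (any(inputs$MABP <= 0)) abort("MABP must be positive")
  if (any(inputs$PaCO2 <= 0)) abort("PaCO2 must be positive")
  if (any(inputs$SpO2 < 0 | inputs$SpO2 > 1)) abort("SpO2 must be a fraction in [0, 1]")
  inputs
}

#' Mean plateau change of simulated or observed channels
#'
#' Summarizes a trace over a plateau window (by default the last 100 s of the
#' challenge window, 300-400 s) as the mean minus the mean over a baseline
#' window (0-100 s by default).
#'
#' @param data A data frame with a `t` column and signal channels.
#' @param channels Character vector of channel names to summarize (default:
#'   all numeric channels except `t`).
#' @param plateau Two-element window (s) for the plateau mean.
#' @param baseline Two-element window (s) for the baseline mean.
#' @return A tibble with columns `channel`, `baseline`, `plateau`, `change`.
#' @export
plateau_change <- function(data, channels = NULL,
                           plateau = c(300, 400), baseline = c(0, 100)) {
  data <- as_tibble(data)
  if (is.null(channels)) {
    channels <- setdiff(names(data)[vapply(data, is.numeric, logical(1))], "t")
  }
  in_b <- data$t >= baseline[1] & data$t <= baseline[2]
  in_p <- data$t >= plateau[1] & data$t <= plateau[2]
  if (!any(in_b) || !any(in_p)) abort("plateau/baseline windows fall outside the record")
  purrr::map_dfr(channels, function(ch) {
    b <- mean(data[[ch]][in_b]); q <- mean(data[[ch]][in_p])
    tibble(channel = ch, baseline = b, plateau = q, change = q - b)
  })
}
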