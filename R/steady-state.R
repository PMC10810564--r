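#' Solve the model steady state at constant inputs
#'
#' The filter states have closed-form fixed points (`P_filt = MABP`,
#' `c1 = c2 =` normalized CO2 excursion, `r` from the radius target), leaving
#' five coupled metabolic states (`NADH`, `CuA_red`, `a3_red`, `O2`, `Dp`).
#' These are solved by damped Newton iteration with a finite-difference
#' Jacobian, falling back to a long relaxation integration when Newton alone
#' does not converge. The result is deterministic.
#'
#' @param params A [bc_params()] object.
#' @param inputs0 Constant inputs as a named list (`MABP`, `SpO2`, `PaCO2`);
#'   defaults to the calibration baseline [baseline_inputs_at()].
#' @param tol Convergence tolerance on the maximum absolute derivative of the
#'   full 9-state system (default `1e-9`).
#' @return Named state vector (order of [bc_state_names()]) whose maximum
#'   absolute derivative is below `tol`.
#' @examples
#' p <- bc_params()
#' s <- bc_steady_state(p)
#' s[["Dp"]]   # = Dp_n at baseline
#' @export
bc_steady_state <- function(params, inputs0 = baseline_inputs_at(params),
                            tol = 1e-9) {
  p <- params
  x <- (inputs0$PaCO2 - p$PaCO2_n) / p$dPaCO2_ref
  P_filt <- inputs0$MABP
  r <- p$r_n * (1 + p$k_r * tanh(p$R_autc * x - p$R_autp * (P_filt / p$P_an - 1)))

  full_state <- function(y5) {
    setNames(c(P_filt, x, x, r, y5), bc_state_names())
  }
  resid <- function(y5) {
    unname(bc_derivs(full_state(y5), inputs0, p)[5:9])
  }

  y5 <- c(p$NADH_frac_n, 1 - p$CuA_ox_n, p$a3_red_n, p$O2_mito_n, p$Dp_n)
  scale <- c(0.1, 0.1, 0.05, p$O2_mito_n, 10)  # fd steps / damping scales

  newton <- function(y5, iter = 60) {
    for (i in seq_len(iter)) {
      f0 <- resid(y5)
      if (max(abs(bc_derivs(full_state(y5), inputs0, p))) < tol) {
        return(list(y5 = y5, ok = TRUE))
      }
      J <- matrix(0, 5, 5)
      for (j in 1:5) {
        h <- 1e-7 * scale[j]
        yp <- y5; yp[j] <- yp[j] + h
        J[, j] <- (resid(yp) - f0) / h
      }
      step <- tryCatch(solve(J, -f0), error = function(e) NULL)
      if (is.null(step) || !all(is.finite(step))) return(list(y5 = y5, ok = FALSE))
      lambda <- 1
      n0 <- sqrt(sum((f0 / scale)^2))
      repeat {
        cand <- y5 + lambda * step
        cand[1:3] <- pmin(pmax(cand[1:3], 1e-9), 1 - 1e-9)
        cand[4] <- max(cand[4], 1e-12)
        cand[5] <- max(cand[5], 1e-6)
        n1 <- sqrt(sum((resid(cand) / scale)^2))
        if (is.finite(n1) && (n1 < n0 || lambda < 1e-4)) break
        lambda <- lambda / 2
      }
      y5 <- cand
    }
    list(y5 = y5, ok = max(abs(bc_derivs(full_state(y5), inputs0, p))) < tol)
  }

  sol <- newton(y5)
  if (!sol$ok) {
    # relaxation fallback: integrate at constant inputs, then polish
    y0 <- full_state(y5)
    relax <- bc_integrate(p, times = c(0, 5000),
                          forcings = bc_const_forcings(inputs0, 5000), y0 = y0)
    sol <- newton(unname(relax[nrow(relax), 1 + 5:9]))
  }
  if (!sol$ok) {
    res <- max(abs(bc_derivs(full_state(sol$y5), inputs0, p)))
    abort(sprintf("steady state did not converge: residual norm %.3e (tol %.0e)", res, tol))
  }
  full_state(sol$y5)
}

bc_const_forcings <- function(inputs0, t_end) {
  tm <- c(-1, t_end + 1)
  list(cbind(tm, rep(inputs0$MABP, 2)),
       cbind(tm, rep(inputs0$SpO2, 2)),
       cbind(tm, rep(inputs0$PaCO2, 2)))
}

# Low-level wrapper around deSolve with the compiled RHS.
bc_integrate <- function(params, times, forcings, y0,
                         rtol = 1e-6, atol = 1e-9) {
  out <- deSolve::ode(
    y = unname(y0), times = times, func = "bc_rhs",
    parms = bc_param_vector(params), dllname = "brainco2",
    initfunc = "bc_initpar", initforc = "bc_initforc",
    forcings = forcings, fcontrol = list(method = "linear", rule = 2),
    method = "lsoda", rtol = rtol, atol = atol, maxsteps = 50000
  )
  if (attr(out, "istate")[1] < 0) {
    abort(sprintf("ODE integration failed near t = %.1f s", max(out[, 1])))
  }
  colnames(out) <- c("time", bc_state_names())
  out
}
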