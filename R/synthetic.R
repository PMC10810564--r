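#' Specify a synthetic hypercapnia challenge
#'
#' Describes the study protocol emulated by the generator: a 6% CO2
#' administration for 300 s targeting a ~2 kPa rise in end-tidal CO2, with a
#' small accompanying MABP rise and unchanged SpO2, plus the descriptive
#' plateau responses used when observations are generated without a forward
#' model (delayed CBF/TOI rise, slower sustained oxCCO rise of ~0.58 uM).
#'
#' @param duration Record length (s).
#' @param dt Sample interval (s), default 1 (1 Hz).
#' @param onset,offset Challenge window (s).
#' @param baseline_MABP,baseline_SpO2,baseline_ETCO2 Baseline levels
#'   (mmHg, fraction, kPa).
#' @param dETCO2 ETCO2 step (kPa).
#' @param dMABP MABP step (mmHg).
#' @param ramp_tc Time constant of the saturating input ramps (s).
#' @param dVmca Descriptive plateau CBF/Vmca change (%).
#' @param dTOI Descriptive plateau TOI change (%-points).
#' @param doxCCO Descriptive plateau oxCCO change (uM).
#' @param toi_baseline Descriptive TOI baseline (%).
#' @param vasc_tc Time constant of the descriptive Vmca/TOI response (s).
#' @param oxcco_tc Time constant of the descriptive (delayed) oxCCO
#'   response (s).
#' @param noise_inputs,noise_obs Named numeric vectors of per-channel Gaussian
#'   noise SDs (input channels: `MABP` mmHg, `SpO2` fraction, `ETCO2` kPa;
#'   observation channels: `dCBF_pct`, `TOI`, `oxCCO` in signal units).
#'   Defaults are 2% of each channel's dynamic range.
#' @return A list of class `bc_challenge_spec`.
#' @export
challenge_spec <- function(duration = 600, dt = 1,
                           onset = 100, offset = 400,
                           baseline_MABP = 90, baseline_SpO2 = 0.98,
                           baseline_ETCO2 = 5,
                           dETCO2 = 2, dMABP = 5, ramp_tc = 20,
                           dVmca = 45, dTOI = 10, doxCCO = 0.58,
                           toi_baseline = 73.5,
                           vasc_tc = 30, oxcco_tc = 180,
                           noise_inputs = NULL, noise_obs = NULL) {
  if (!(onset < offset && offset < duration)) {
    abort("require onset < offset < duration")
  }
  # default noise: 2% of each channel's dynamic range
  ni <- c(MABP = 0.02 * abs(dMABP), SpO2 = 0, ETCO2 = 0.02 * abs(dETCO2))
  no <- c(dCBF_pct = 0.02 * abs(dVmca), TOI = 0.02 * abs(dTOI),
          oxCCO = 0.02 * abs(doxCCO))
  if (!is.null(noise_inputs)) ni[names(noise_inputs)] <- noise_inputs
  if (!is.null(noise_obs)) no[names(noise_obs)] <- noise_obs
  if (any(ni < 0) || any(no < 0)) abort("noise SDs must be >= 0")
  structure(list(
    duration = duration, dt = dt, onset = onset, offset = offset,
    baseline_MABP = baseline_MABP, baseline_SpO2 = baseline_SpO2,
    baseline_ETCO2 = baseline_ETCO2,
    dETCO2 = dETCO2, dMABP = dMABP, ramp_tc = ramp_tc,
    dVmca = dVmca, dTOI = dTOI, doxCCO = doxCCO,
    toi_baseline = toi_baseline, vasc_tc = vasc_tc, oxcco_tc = oxcco_tc,
    noise_inputs = ni, noise_obs = no
  ), class = "bc_challenge_spec")
}

# Saturating ramp: 0 before onset, 1-exp(-(t-onset)/tc) during the challenge,
# exponential return to 0 after offset.
bc_ramp <- function(t, onset, offset, tc) {
  up <- ifelse(t >= onset, 1 - exp(-(pmax(t - onset, 0)) / tc), 0)
  at_off <- 1 - exp(-(offset - onset) / tc)
  ifelse(t <= offset, up, at_off * exp(-(t - offset) / tc))
}

#' Generate synthetic input traces for a hypercapnia challenge
#'
#' @param spec A [challenge_spec()].
#' @param seed Integer seed for the channel noise; `NULL` leaves noise off.
#' @return An input-trace tibble with columns `t`, `MABP` (mmHg), `SpO2`
#'   (fraction), `PaCO2` (mmHg, converted from the ETCO2 profile) and
#'   `ETCO2` (kPa).
#' @examples
#' inp <- make_inputs(challenge_spec())
#' range(inp$PaCO2)
#' @export
make_inputs <- function(spec = challenge_spec(), seed = NULL) {
  stopifnot(inherits(spec, "bc_challenge_spec"))
  t <- seq(0, spec$duration, by = spec$dt)
  ramp <- bc_ramp(t, spec$onset, spec$offset, spec$ramp_tc)
  etco2 <- spec$baseline_ETCO2 + spec$dETCO2 * ramp
  mabp <- spec$baseline_MABP + spec$dMABP * ramp
  spo2 <- rep(spec$baseline_SpO2, length(t))
  if (!is.null(seed)) {
    withr_seed(seed, {
      mabp <- mabp + rnorm(length(t), 0, spec$noise_inputs[["MABP"]])
      spo2 <- pmin(pmax(spo2 + rnorm(length(t), 0, spec$noise_inputs[["SpO2"]]), 0), 1)
      etco2 <- etco2 + rnorm(length(t), 0, spec$noise_inputs[["ETCO2"]])
    })
  }
  tibble(t = t, MABP = mabp, SpO2 = spo2,
         PaCO2 = kpa_to_mmhg(etco2), ETCO2 = etco2)
}

#' Generate synthetic observation traces
#'
#' Two modes. `"forward"` runs the forward model with `params` on `inputs`
#' and adds i.i.d. Gaussian noise, so the generating parameters are known
#' exactly (parameter-recovery testing). `"descriptive"` draws smooth
#' saturating-ramp curves that hit the plateaus in `spec` with the stated
#' delays (the oxCCO response lags the vascular responses), emulating the
#' group-mean response shapes without assuming the model.
#'
#' @param inputs Input trace, typically from [make_inputs()]; observations are
#'   generated on its time grid.
#' @param mode `"forward"` or `"descriptive"`.
#' @param params A [bc_params()] object (forward mode).
#' @param spec A [challenge_spec()] (descriptive mode; also supplies noise
#'   SDs in both modes; default [challenge_spec()]).
#' @param seed Integer seed for the noise; `NULL` leaves noise off.
#' @return An observed-trace tibble with columns `t`, `dCBF_pct` (%), `TOI`
#'   (%), `oxCCO` (uM change).
#' @examples
#' inp <- make_inputs(challenge_spec())
#' obs <- make_observations(inp, mode = "descriptive")
#' @export
make_observations <- function(inputs, mode = c("descriptive", "forward"),
                              params = NULL, spec = challenge_spec(),
                              seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(spec, "bc_challenge_spec"))
  t <- inputs$t
  if (mode == "forward") {
    if (is.null(params)) abort("forward mode requires a bc_params object")
    sim <- bc_simulate(inputs, params)
    obs <- tibble(t = t, dCBF_pct = sim$dCBF_pct, TOI = sim$TOI,
                  oxCCO = sim$oxCCO)
  } else {
    if (!all(is.finite(c(spec$dVmca, spec$dTOI, spec$doxCCO)))) {
      abort("descriptive plateaus must be finite")
    }
    # ramps normalized so each channel attains its stated plateau at the
    # challenge offset (a 180 s response would otherwise never get there)
    vasc <- bc_ramp(t, spec$onset, spec$offset, spec$vasc_tc)
    vasc <- vasc / (1 - exp(-(spec$offset - spec$onset) / spec$vasc_tc))
    slow <- bc_ramp(t, spec$onset, spec$offset, spec$oxcco_tc)
    slow <- slow / (1 - exp(-(spec$offset - spec$onset) / spec$oxcco_tc))
    obs <- tibble(
      t = t,
      dCBF_pct = spec$dVmca * vasc,
      TOI = spec$toi_baseline + spec$dTOI * vasc,
      oxCCO = spec$doxCCO * slow
    )
  }
  if (!is.null(seed)) {
    no <- spec$noise_obs
    withr_seed(seed, {
      obs$dCBF_pct <- obs$dCBF_pct + rnorm(length(t), 0, no[["dCBF_pct"]])
      obs$TOI <- obs$TOI + rnorm(length(t), 0, no[["TOI"]])
      obs$oxCCO <- obs$oxCCO + rnorm(length(t), 0, no[["oxCCO"]])
    })
  }
  obs
}

# Evaluate expr with a local RNG state seeded by `seed`.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  eval.parent(substitute(expr))
}
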