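#' Venous saturation from the tissue oxygenation index
#'
#' Inverts the TOI mixing model `TOI = 100 * (AVR * SaO2 + (1-AVR) * SvO2)`
#' under a static arterial-to-venous volume ratio.
#'
#' @param TOI Tissue oxygenation index (%).
#' @param SaO2 Arterial saturation (fraction).
#' @param AVR Arterial volume fraction of the optical field (default 0.25).
#' @return Venous saturation (fraction), guaranteed in `[0, SaO2]`.
#' @examples
#' svo2_from_toi(65, 0.98)   # 0.54
#' @export
svo2_from_toi <- function(TOI, SaO2, AVR = 0.25) {
  if (AVR < 0 || AVR >= 1) abort("AVR must lie in [0, 1)")
  svo2 <- (TOI / 100 - AVR * SaO2) / (1 - AVR)
  bad <- svo2 < -1e-12 | svo2 > SaO2 + 1e-12
  if (any(bad)) {
    abort(sprintf(
      "SvO2 outside [0, SaO2] at %d sample(s): the static-AVR assumption is violated",
      sum(bad)))
  }
  pmin(pmax(svo2, 0), SaO2)
}

#' Modified-Fick relative CMRO2 change
#'
#' Model-independent comparator for the fitted simulations: by the Fick
#' principle CMRO2 is proportional to CBF times the arterio-venous saturation
#' difference, with venous saturation obtained from TOI via
#' [svo2_from_toi()]. The result is the percent change
#' `100 * ((1 + dCBF_pct/100) * (SaO2 - SvO2) / (SaO2_0 - SvO2_0) - 1)`
#' with baseline-window means in the denominator.
#'
#' @param data Data frame with columns `t`, `dCBF_pct` (%), `TOI` (%) and an
#'   arterial-saturation column `SpO2` or `SaO2` (fraction).
#' @param avr Arterial volume fraction used to invert TOI (default 0.25).
#' @param baseline_window Pre-challenge window (s) defining the reference
#'   extraction, default 0-100 s.
#' @return A tibble with columns `t` and `dCMRO2_pct`.
#' @examples
#' d <- tibble::tibble(t = 0:3, dCBF_pct = c(0, 0, 30, 30),
#'                     TOI = c(65, 65, 68, 68), SpO2 = 0.98)
#' fick_cmro2(d, baseline_window = c(0, 1))$dCMRO2_pct  # 0, 0, 18.18, 18.18
#' @export
fick_cmro2 <- function(data, avr = 0.25, baseline_window = c(0, 100)) {
  data <- as_tibble(data)
  need <- c("t", "dCBF_pct", "TOI")
  missing <- setdiff(need, names(data))
  if (length(missing)) {
    abort(paste0("missing channel(s): ", paste(missing, collapse = ", ")))
  }
  sao2 <- data[["SpO2"]] %||% data[["SaO2"]]
  if (is.null(sao2)) abort("missing arterial saturation channel (SpO2 or SaO2)")
  if (length(sao2) == 1) sao2 <- rep(sao2, nrow(data))

  in_b <- data$t >= baseline_window[1] & data$t <= baseline_window[2]
  if (!any(in_b)) abort("baseline window lies outside the record")

  svo2 <- svo2_from_toi(data$TOI, sao2, avr)
  sao2_0 <- mean(sao2[in_b])
  svo2_0 <- mean(svo2[in_b])
  e0 <- sao2_0 - svo2_0
  if (e0 <= 0) abort("zero baseline oxygen extraction (SaO2_0 = SvO2_0)")

  rel <- (1 + data$dCBF_pct / 100) * (sao2 - svo2) / e0
  tibble(t = data$t, dCMRO2_pct = 100 * (rel - 1))
}
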