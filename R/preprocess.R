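#' Unit conversions between kPa and mmHg
#'
#' End-tidal CO2 is recorded in kPa; the model works in mmHg
#' (1 kPa = 7.50062 mmHg).
#'
#' @param x Numeric vector.
#' @return Converted numeric vector.
#' @examples
#' kpa_to_mmhg(5)    # 37.5031
#' @export
kpa_to_mmhg <- function(x) x * 7.50062

#' @rdname kpa_to_mmhg
#' @export
mmhg_to_kpa <- function(x) x / 7.50062

bc_input_channels <- c("MABP", "SpO2", "PaCO2")
bc_obs_channels <- c("dCBF_pct", "TOI", "oxCCO")

#' Read and write physiological trace CSV files
#'
#' Traces are CSV files with a `t` column (seconds, uniform grid) plus named
#' channels. On read, units are normalized: an `ETCO2` column (kPa) is
#' converted to `PaCO2` (mmHg), `SpO2` recorded in percent is rescaled to a
#' fraction, and a `Vmca` column is converted to `dCBF_pct` (percent change
#' relative to the mean over the pre-challenge baseline window, constant
#' vessel cross-section assumed). NaN gaps of up to `max_gap` seconds are
#' linearly interpolated; longer gaps are an error.
#'
#' @param path CSV file path.
#' @param role `"inputs"` (requires `MABP`, `SpO2` and `PaCO2`/`ETCO2`) or
#'   `"observations"` (requires `TOI`, `oxCCO` and `dCBF_pct`/`Vmca`).
#' @param baseline_window Window (s) used as the Vmca baseline, default
#'   0-100 s.
#' @param max_gap Longest NaN run (s) repaired by interpolation.
#' @return A validated trace tibble.
#' @export
read_trace <- function(path, role = c("inputs", "observations"),
                       baseline_window = c(0, 100), max_gap = 5) {
  role <- match.arg(role)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!"t" %in% names(df)) abort("trace file must contain a 't' column")
  dt <- diff(df$t)
  if (nrow(df) < 2 || any(dt <= 0) || diff(range(dt)) > 1e-6 * mean(dt)) {
    abort("trace must have a strictly increasing uniform time grid")
  }

  for (ch in setdiff(names(df), "t")) {
    df[[ch]] <- bc_fill_gaps(df$t, df[[ch]], ch, max_gap)
  }

  if ("ETCO2" %in% names(df) && !"PaCO2" %in% names(df)) {
    df$PaCO2 <- kpa_to_mmhg(df$ETCO2)
  }
  if ("SpO2" %in% names(df) && any(df$SpO2 > 1.5, na.rm = TRUE)) {
    df$SpO2 <- df$SpO2 / 100   # recorded in percent
  }
  if ("Vmca" %in% names(df) && !"dCBF_pct" %in% names(df)) {
    in_b <- df$t >= baseline_window[1] & df$t <= baseline_window[2]
    if (!any(in_b)) abort("baseline window lies outside the record")
    v0 <- mean(df$Vmca[in_b])
    if (v0 == 0) abort("Vmca baseline mean is zero; cannot form dCBF_pct")
    df$dCBF_pct <- 100 * (df$Vmca / v0 - 1)
  }

  need <- if (role == "inputs") bc_input_channels else bc_obs_channels
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    abort(paste0("trace with role '", role, "' is missing channel(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (role == "inputs") validate_input_trace(df[c("t", intersect(names(df), c(bc_input_channels, "ETCO2")))])
  as_tibble(df)
}

bc_fill_gaps <- function(t, v, name, max_gap) {
  bad <- !is.finite(v)
  if (!any(bad)) return(v)
  runs <- rle(bad)
  dt <- t[2] - t[1]
  if (any(runs$values & runs$lengths * dt > max_gap)) {
    abort(paste0("channel ", name, " has a NaN gap longer than ", max_gap, " s"))
  }
  if (all(bad)) abort(paste0("channel ", name, " is entirely NaN"))
  approx(t[!bad], v[!bad], xout = t, rule = 2)$y
}

#' @rdname read_trace
#' @param trace A trace tibble (must be non-empty and contain `t`).
#' @export
write_trace <- function(trace, path) {
  trace <- as_tibble(trace)
  if (nrow(trace) == 0) abort("refusing to write an empty trace")
  if (!"t" %in% names(trace)) abort("trace must contain a 't' column")
  ord <- c("t", intersect(c(bc_input_channels, "ETCO2", bc_obs_channels),
                          names(trace)))
  ord <- c(ord, setdiff(names(trace), ord))
  readr::write_csv(trace[ord], path, progress = FALSE)
  invisible(path)
}

#' Zero-phase low-pass filtering and resampling
#'
#' Applies a forward-backward (zero-phase) Butterworth low-pass filter of the
#' given order and cutoff, then decimates onto a uniform output grid, the
#' signal-conditioning step used on 100 Hz monitoring data before modelling
#' (0.25 Hz, fifth order, resampled at 1 Hz).
#'
#' @param data Data frame with a `t` column and one or more signal channels.
#' @param fc Cutoff frequency (Hz).
#' @param order Filter order.
#' @param fs_out Output sampling rate (Hz).
#' @return A tibble on the new grid with the same channels.
#' @examples
#' t <- seq(0, 60, by = 0.1)
#' raw <- tibble::tibble(t = t, MABP = 90 + sin(2 * pi * 0.5 * t))
#' clean <- lowpass_resample(raw)      # 0.5 Hz component suppressed
#' @export
lowpass_resample <- function(data, fc = 0.25, order = 5, fs_out = 1) {
  data <- as_tibble(data)
  if (!"t" %in% names(data)) abort("data must contain a 't' column")
  dt <- diff(data$t)
  if (nrow(data) < 2 || any(dt <= 0) || diff(range(dt)) > 1e-6 * mean(dt)) {
    abort("data must have a strictly increasing uniform time grid")
  }
  fs_in <- 1 / mean(dt)
  if (fs_in < 2 * fc) abort("input sampling rate must be at least twice the cutoff")
  flt <- signal::butter(order, fc / (fs_in / 2), type = "low")
  # filtfilt needs a few filter lengths of data
  if (nrow(data) < 3 * 3 * (order + 1)) abort("trace too short to filter")
  t_out <- seq(data$t[1], data$t[nrow(data)], by = 1 / fs_out)
  out <- tibble(t = t_out)
  for (ch in setdiff(names(data), "t")) {
    y <- data[[ch]]
    if (!all(is.finite(y))) abort(paste0("non-finite values in channel ", ch))
    yf <- signal::filtfilt(flt, y - y[1]) + y[1]  # remove DC before filtering
    out[[ch]] <- approx(data$t, yf, xout = t_out)$y
  }
  out
}
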