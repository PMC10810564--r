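test_that("kPa/mmHg conversions are exact and invertible", {
  expect_identical(kpa_to_mmhg(0), 0)
  expect_equal(kpa_to_mmhg(5), 37.5031, tolerance = 1e-7)
  x <- c(0.3, 5, 7.2)
  expect_equal(mmhg_to_kpa(kpa_to_mmhg(x)), x, tolerance = 1e-12)
})

test_that("traces round-trip through CSV losslessly with stable column order", {
  inp <- std_inputs()
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace(inp, path)
  back <- read_trace(path, "inputs")
  for (ch in c("t", "MABP", "SpO2", "PaCO2")) {
    expect_equal(back[[ch]], inp[[ch]], tolerance = 1e-12)
  }
  header1 <- readLines(path, n = 1)
  write_trace(inp[sample(names(inp))], path)   # shuffled input columns
  expect_identical(readLines(path, n = 1), header1)
  expect_error(write_trace(inp[0, ], path), "empty")
})

test_that("read_trace normalizes units and derives dCBF_pct from Vmca", {
  t <- 0:299
  raw <- tibble::tibble(
    t = t, MABP = 90, SpO2 = 98, ETCO2 = 5,
    Vmca = 60 * (1 + 0.4 * (t > 150)), TOI = 70, oxCCO = 0
  )
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(raw, path)
  inp <- read_trace(path, "inputs")
  expect_equal(inp$SpO2, rep(0.98, 300))           # percent -> fraction
  expect_equal(inp$PaCO2, rep(kpa_to_mmhg(5), 300))
  obs <- read_trace(path, "observations")
  expect_equal(mean(obs$dCBF_pct[obs$t <= 100]), 0, tolerance = 1e-9)
  expect_equal(obs$dCBF_pct[300], 40, tolerance = 1e-9)
})

test_that("missing channels are reported by name", {
  d <- tibble::tibble(t = 0:10, TOI = 70, dCBF_pct = 0)
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(d, path)
  expect_error(read_trace(path, "observations"), "oxCCO")
})

test_that("short NaN gaps are interpolated and long gaps rejected", {
  d <- tibble::tibble(t = 0:99, MABP = 90 + sin(0:99 / 10), SpO2 = 0.98,
                      PaCO2 = 37.5)
  d$MABP[40:42] <- NA            # 3 s gap
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(d, path)
  inp <- read_trace(path, "inputs")
  expect_true(all(is.finite(inp$MABP)))

  d$MABP[60:67] <- NA            # 8 s gap
  readr::write_csv(d, path)
  expect_error(read_trace(path, "inputs"), "gap")
})

test_that("the low-pass stage passes DC unchanged and resamples to 1 Hz", {
  t <- seq(0, 120, by = 0.02)    # 50 Hz input
  raw <- tibble::tibble(t = t, MABP = rep(92.5, length(t)))
  out <- lowpass_resample(raw)
  expect_lt(max(abs(out$MABP - 92.5)), 1e-9)
  expect_equal(unique(diff(out$t)), 1)
})

test_that("Butterworth attenuation at 2x the cutoff matches the closed form", {
  fs <- 50
  t <- seq(0, 120, by = 1 / fs)
  raw <- tibble::tibble(t = t, MABP = sin(2 * pi * 0.5 * t))
  out <- lowpass_resample(raw, fc = 0.25, order = 5, fs_out = fs)
  mid <- out$t > 30 & out$t < 90  # avoid filter edge transients
  # zero-phase filtering applies |H|^2; |H| = 1/sqrt(1 + (f/fc)^10)
  gain_expected <- (1 / sqrt(1 + (0.5 / 0.25)^10))^2
  # amplitude by quadrature projection at 0.5 Hz
  amp <- 2 * sqrt(mean(out$MABP[mid] * sin(2 * pi * 0.5 * out$t[mid]))^2 +
                  mean(out$MABP[mid] * cos(2 * pi * 0.5 * out$t[mid]))^2)
  expect_equal(amp, gain_expected, tolerance = 0.05)
})

test_that("filtering and resampling commute with amplitude scaling", {
  t <- seq(0, 60, by = 0.1)
  y <- sin(2 * pi * 0.1 * t) + 0.3 * sin(2 * pi * 1.3 * t)
  a <- lowpass_resample(tibble::tibble(t = t, MABP = 90 + y))
  b <- lowpass_resample(tibble::tibble(t = t, MABP = 90 + 10 * y))
  expect_lt(max(abs((b$MABP - 90) - 10 * (a$MABP - 90))), 1e-9)
})

test_that("undersampled input relative to the cutoff is rejected", {
  t <- seq(0, 300, by = 3)       # 1/3 Hz < 2 * fc
  expect_error(lowpass_resample(tibble::tibble(t = t, MABP = 90)), "twice")
})
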