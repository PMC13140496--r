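fs <- 20000
fset <- design_filters(filter_spec(), fs)

test_that("bandpass magnitude meets its design contract", {
  gain_db <- function(f) 20 * log10(Mod(filter_response(fset, f, "bandpass")))
  expect_lt(gain_db(1e-6), -60)              # DC blocked
  expect_equal(gain_db(30), -3.01, tolerance = 0.5 / 3.01)
  expect_equal(gain_db(1000), -3.01, tolerance = 0.5 / 3.01)
  expect_gt(gain_db(300), -0.1)              # mid-band flat
  # independent oracle: signal::freqz on the same coefficients
  fr <- signal::freqz(fset$bandpass$b, fset$bandpass$a,
                      Fs = fs, region = "half", n = 4096)
  ours <- Mod(filter_response(fset, fr$f[100:200], "bandpass"))
  expect_equal(ours, Mod(fr$h[100:200]), tolerance = 1e-6)
})

test_that("notch removes 50 Hz with little collateral attenuation", {
  x50 <- make_tone(50)
  y50 <- apply_filters(x50, fset)
  expect_lt(mid_amp(y50) / mid_amp(x50), 0.10)   # >= 20 dB zero-phase
  x300 <- make_tone(300)
  y300 <- apply_filters(x300, fset)
  expect_lt(abs(20 * log10(mid_amp(y300) / mid_amp(x300))), 1)
})

test_that("bandpass is idempotent in passband energy", {
  x <- make_tone(300)
  y1 <- apply_filters(x, fset)
  y2 <- apply_filters(y1, fset)
  expect_lt(abs(20 * log10(mid_amp(y2) / mid_amp(y1))), 2)
})

test_that("unstable transfer-function designs fall back to stable SOS", {
  spec10 <- filter_spec(order = 10, band_low = 30, band_high = 100)
  f10 <- design_filters(spec10, fs)
  expect_identical(f10$bandpass_form, "sos")
  pole_mods <- apply(f10$bandpass, 1,
                     function(s) max(Mod(polyroot(rev(s[4:6])))))
  expect_true(all(pole_mods < 1 - 1e-9))
  gain_db <- function(f) 20 * log10(Mod(filter_response(f10, f, "bandpass")))
  expect_equal(gain_db(30), -3.01, tolerance = 0.5 / 3.01)
  expect_equal(gain_db(100), -3.01, tolerance = 0.5 / 3.01)
  expect_gt(gain_db(55), -0.5)
  # and filtering through the cascade behaves like the design
  x <- make_tone(55, dur = 3)
  expect_equal(mid_amp(apply_filters(x, f10)), 1, tolerance = 0.05)
})

test_that("filter design and application guard their contracts", {
  expect_error(design_filters(filter_spec(band_high = 12000), fs),
               "Nyquist")
  z <- sampled_signal(numeric(2000), fs)
  expect_equal(apply_filters(z, fset)$samples, numeric(2000))
  short <- sampled_signal(rnorm(20), fs)
  expect_error(apply_filters(short, fset), "too short")
  expect_error(apply_filters(make_tone(50, rate = 1000), fset), "rate")
})

test_that("envelope rectifies and is sign-invariant", {
  fs2 <- 1000
  const <- sampled_signal(rep(2, 1000), fs2)
  env <- emg_envelope(const, 0.05)
  expect_equal(env$samples[100:900], rep(2, 801))
  env_neg <- emg_envelope(sampled_signal(rep(-2, 1000), fs2), 0.05)
  expect_equal(env_neg$samples, env$samples)
  set.seed(2)
  x <- sampled_signal(rnorm(2000), fs2)
  xm <- sampled_signal(-x$samples, fs2)
  expect_equal(emg_envelope(xm, 0.05)$samples, emg_envelope(x, 0.05)$samples)
  # square burst much longer than the window -> plateau at the amplitude
  sq <- sampled_signal(c(numeric(300), rep(3, 1000), numeric(300)), fs2)
  plateau <- emg_envelope(sq, 0.05)$samples[500:1100]
  expect_equal(plateau, rep(3, length(plateau)), tolerance = 0.01)
  expect_error(emg_envelope(const, 1e-9), "window")
})

test_that("breath EMG integral matches closed forms and is homogeneous", {
  fs2 <- 10000
  tt <- seq(0, 0.5, by = 1 / fs2)
  # rectangle: constant 2 uV over 0.1 s -> 0.2 uV.s
  const <- sampled_signal(rep(2, length(tt)), fs2)
  expect_equal(breath_emg_integral(const, 0.1, 0.2), 0.2, tolerance = 1e-3)
  expect_equal(breath_emg_integral(sampled_signal(numeric(length(tt)), fs2),
                                   0.1, 0.2), 0)
  # half-sine burst amplitude 5 over 0.1 s -> (2/pi)*5*0.1
  burst <- ifelse(tt >= 0.2 & tt <= 0.3, 5 * sin(pi * (tt - 0.2) / 0.1), 0)
  sig <- sampled_signal(burst, fs2)
  expect_equal(breath_emg_integral(sig, 0.2, 0.3), 2 / pi * 5 * 0.1,
               tolerance = 0.005)
  # homogeneity under amplitude scaling
  half <- sampled_signal(0.5 * burst, fs2)
  expect_equal(breath_emg_integral(half, 0.2, 0.3),
               0.5 * breath_emg_integral(sig, 0.2, 0.3), tolerance = 1e-12)
  expect_error(breath_emg_integral(sig, 0.3, 0.3), "empty")
})
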