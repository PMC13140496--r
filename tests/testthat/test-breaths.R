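# envelope test signal: rectified half-sine bursts on a Gaussian noise
# floor, smoothed the way the pipeline's envelope stage would produce it
burst_envelope_signal <- function(n_bursts = 10, ti = 0.15, ttot = 0.5,
                                  amp = 10, rate = 1000, noise_sd = 0.05,
                                  seed = 5) {
  set.seed(seed)
  dur <- 0.3 + n_bursts * ttot + 0.3
  tt <- seq(0, dur, by = 1 / rate)
  x <- rnorm(length(tt), sd = noise_sd)
  for (k in seq_len(n_bursts)) {
    on <- 0.3 + (k - 1) * ttot
    idx <- tt >= on & tt <= on + ti
    x[idx] <- x[idx] + amp * sin(pi * (tt[idx] - on) / ti)
  }
  emg_envelope(sampled_signal(x, rate, label = "dia"), 0.05)
}

test_that("a flat signal yields no breaths", {
  z <- sampled_signal(numeric(2000), 1000)
  expect_equal(nrow(detect_breaths(z)), 0L)
})

test_that("regular bursts at 2 Hz are each detected with correct timing", {
  sig <- burst_envelope_signal()
  br <- detect_breaths(sig)
  expect_equal(nrow(br), 10L)
  expect_equal(br$ttot[1:9], rep(0.5, 9), tolerance = 0.05 / 0.5)
  expect_true(all(br$onset_time <= br$peak_time & br$peak_time <= br$offset_time))
  expect_lte(sum(br$ti), signal_duration(sig))
})

test_that("detected breath count is invariant to amplitude scaling", {
  sig <- burst_envelope_signal(seed = 9)
  n0 <- nrow(detect_breaths(sig))
  for (f in c(0.25, 40)) {
    scaled <- sampled_signal(f * sig$samples, sig$rate, "dia")
    expect_equal(nrow(detect_breaths(scaled)), n0)
  }
})

test_that("bursts closer than min_separation merge into one breath", {
  rate <- 1000
  tt <- seq(0, 2, by = 1 / rate)
  x <- numeric(length(tt))
  x[tt >= 0.5 & tt <= 0.6] <- 5
  x[tt >= 0.62 & tt <= 0.72] <- 5   # 0.02 s gap < 0.05 s
  x[tt >= 1.5 & tt <= 1.6] <- 5
  sig <- sampled_signal(x, rate, "dia")  # noise-free: merge rule is forced
  br <- detect_breaths(sig)
  expect_equal(nrow(br), 2L)
  expect_gt(br$ti[1], 0.2)  # merged burst spans both
})

test_that("breath timing is onset-to-onset arithmetic", {
  br <- data.frame(onset_time = c(0, 0.5, 1.0),
                   peak_time = c(0.1, 0.6, 1.1),
                   offset_time = c(0.2, 0.7, 1.2),
                   ti = 0.2)
  tm <- breath_timing(br)
  expect_equal(tm$ttot, c(0.5, 0.5))
  expect_equal(tm$duty_cycle, c(0.4, 0.4))
  expect_warning(empty <- breath_timing(br[1, ]), "fewer than 2")
  expect_equal(nrow(empty), 0L)
})

test_that("onset-to-peak slope is the endpoint slope", {
  rate <- 1000
  tt <- seq(0, 1, by = 1 / rate)
  ramp <- sampled_signal(ifelse(tt < 0.1, 100 * tt, 10), rate, "dia")
  b <- list(onset_time = 0, peak_time = 0.1)
  expect_equal(onset_to_peak_slope(ramp, b), 100, tolerance = 0.02)
  flat <- sampled_signal(rep(4, length(tt)), rate, "dia")
  expect_equal(onset_to_peak_slope(flat, b), 0)
  # pressure: inspiratory deflection magnitude -> positive slope
  pr <- sampled_signal(ifelse(tt < 0.1, -100 * tt, -10), rate, "pressure",
                       "cmH2O")
  expect_equal(onset_to_peak_slope(pr, b), 100, tolerance = 0.02)
  # antisymmetry under time reversal of the segment
  rev_sig <- sampled_signal(rev(ramp$samples[tt <= 0.1]), rate, "dia")
  expect_equal(onset_to_peak_slope(rev_sig, b),
               -onset_to_peak_slope(ramp, b), tolerance = 0.03)
  expect_error(onset_to_peak_slope(ramp, list(onset_time = 0.1, peak_time = 0.1)),
               "degenerate")
})

test_that("too-short intervals are rejected", {
  sig <- burst_envelope_signal()
  expect_error(detect_breaths(sig, list(start = 0, end = 0.3)), "too short")
})
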