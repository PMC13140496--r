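test_that("a pure tone peaks in the correct Welch bin", {
  fs <- 20000
  x <- make_tone(100, dur = 2, rate = fs)
  w <- welch_psd(x)
  bin <- fs / 2048
  expect_equal(w$freq[which.max(w$psd)], 100, tolerance = bin / 100)
  # independent oracle: single rectangular periodogram peak
  n <- length(x$samples)
  pg <- Mod(stats::fft(x$samples - mean(x$samples))[1:(n %/% 2)])^2
  f_pg <- (0:(n %/% 2 - 1)) * fs / n
  expect_lt(abs(f_pg[which.max(pg)] - w$freq[which.max(w$psd)]), bin)
})

test_that("short signals fall back to a single full-length window", {
  w <- welch_psd(sampled_signal(rnorm(1500), 20000), spectral_params())
  expect_equal(w$n_segments, 1L)
  expect_equal(w$window_len, 1500L)
  expect_error(welch_psd(sampled_signal(rnorm(50), 20000)), "shorter than 64")
})

test_that("zero input gives a zero, invalid spectrum", {
  w <- welch_psd(sampled_signal(numeric(5000), 20000))
  expect_true(all(w$psd == 0))
  ss <- spectrum_params(w)
  expect_false(ss$valid)
  expect_equal(ss$total_power, 0)
  expect_true(is.nan(ss$mean_freq))
})

test_that("degenerate and uniform spectra give forced parameter values", {
  f <- seq(0, 1000, by = 10)
  p <- numeric(length(f)); p[f == 100] <- 5
  ss <- spectrum_params(list(freq = f, psd = p), band = c(30, 1000))
  expect_equal(ss$mean_freq, 100)
  expect_equal(ss$median_freq, 100)
  expect_equal(ss$max_freq, 100)
  expect_equal(ss$total_power, 5 * 10)  # triangle over two 10 Hz bins
  flat <- spectrum_params(list(freq = f, psd = rep(1, length(f))),
                          band = c(30, 1000))
  expect_equal(flat$mean_freq, 515, tolerance = 10 / 515)
  expect_equal(flat$median_freq, 515, tolerance = 10 / 515)
})

test_that("spectrum parameters scale correctly with amplitude", {
  set.seed(4)
  fs <- 20000
  x <- band_limited_noise(fs * 3, fs, c(30, 1000))
  w1 <- welch_psd(x, rate = fs)
  w2 <- welch_psd(2 * x, rate = fs)
  s1 <- spectrum_params(w1); s2 <- spectrum_params(w2)
  expect_equal(s2$total_power / s1$total_power, 4, tolerance = 0.01)
  expect_equal(s1$mean_freq, s2$mean_freq)
  expect_equal(s1$median_freq, s2$median_freq)
  expect_equal(s1$max_freq, s2$max_freq)
})

test_that("band power integrates to the time-domain mean square", {
  set.seed(6)
  fs <- 20000
  x <- band_limited_noise(fs * 3, fs, c(30, 1000))
  w <- welch_psd(x, rate = fs)
  full <- spectrum_params(w, band = c(0, fs / 2))
  expect_equal(full$total_power, mean(x^2), tolerance = 0.05)
})

test_that("median frequency splits band power into halves", {
  set.seed(8)
  fs <- 20000
  x <- band_limited_noise(fs * 3, fs, c(30, 1000))
  w <- welch_psd(x, rate = fs)
  ss <- spectrum_params(w)
  keep <- w$freq >= 30 & w$freq <= 1000
  fb <- w$freq[keep]; pb <- w$psd[keep]
  below <- fb <= ss$median_freq
  lower <- sum(pb[below]); total <- sum(pb)
  bin_power <- max(pb)
  expect_lt(abs(lower - total / 2), bin_power + 0.02 * total)
})

test_that("band-limited noise recovers its band centre", {
  set.seed(10)
  fs <- 20000
  x <- band_limited_noise(fs * 4, fs, c(200, 400))  # >= 30 Welch segments
  ss <- spectrum_params(welch_psd(x, rate = fs), band = c(30, 1000))
  expect_equal(ss$mean_freq, 300, tolerance = 0.05)
  expect_gte(ss$max_freq, 200 - fs / 2048)
  expect_lte(ss$max_freq, 400 + fs / 2048)
})
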