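test_that("cleaning removes non-finite samples and linear trends", {
  x <- rnorm(300); x[c(3, 60, 100, 200, 299)] <- c(NA, NaN, Inf, -Inf, NA)
  v <- clean_for_entropy(x)
  expect_equal(length(v), 295L)
  ramp <- clean_for_entropy(seq(0, 10, length.out = 500))
  expect_lt(max(abs(ramp)), 1e-9)
  set.seed(12)
  clean <- rnorm(400); clean <- clean - mean(clean)
  resid <- clean_for_entropy(clean)
  slope <- stats::coef(stats::lm(clean ~ seq_along(clean)))[2]
  expect_equal(resid, clean - (seq_along(clean) - mean(seq_along(clean))) * slope,
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_error(clean_for_entropy(rep(NA_real_, 10)), "non-finite")
})

test_that("Shannon entropy matches analytic distributions exactly", {
  expect_equal(as.numeric(shannon_entropy(rep(0.5, 100))), 0)
  two <- rep(c(0.000, 0.001), 50)
  expect_equal(as.numeric(shannon_entropy(two)), 1)
  four <- rep(c(0.000, 0.001, 0.002, 0.003), 50)
  expect_equal(as.numeric(shannon_entropy(four)), 2)
  short <- shannon_entropy(rnorm(30))
  expect_false(attr(short, "valid"))
})

test_that("ApEn and SampEn equal their brute-force oracles", {
  params <- entropy_params()
  per3 <- rep(c(1, 2, 3), length.out = 300)
  r3 <- 0.25 * sd(clean_for_entropy(per3))
  expect_equal(as.numeric(approximate_entropy(per3, params)),
               oracle_apen(clean_for_entropy(per3), 2, r3), tolerance = 1e-9)
  set.seed(21)
  wn <- rnorm(500)
  wnc <- clean_for_entropy(wn)
  rw <- 0.25 * sd(wnc)
  ap_wn <- as.numeric(approximate_entropy(wn, params))
  expect_equal(ap_wn, oracle_apen(wnc, 2, rw), tolerance = 1e-9)
  expect_gt(ap_wn, as.numeric(approximate_entropy(per3, params)))

  per2 <- rep(c(1, 2), length.out = 300)
  p2c <- clean_for_entropy(per2)
  sp2 <- sample_entropy(per2, params)
  expect_equal(as.numeric(sp2), oracle_sampen(p2c, 2, 0.25 * sd(p2c)),
               tolerance = 1e-9)
  expect_lte(as.numeric(sp2), 0.02)
  set.seed(22)
  wn2 <- rnorm(1000)
  w2c <- clean_for_entropy(wn2)
  expect_equal(as.numeric(sample_entropy(wn2, params)),
               oracle_sampen(w2c, 2, 0.25 * sd(w2c)), tolerance = 1e-9)
})

test_that("degenerate and short inputs are flagged, not errors", {
  const <- rep(3.3, 300)
  ap <- approximate_entropy(const)
  expect_equal(as.numeric(ap), 0)
  expect_true(attr(ap, "degenerate"))
  sp <- sample_entropy(const)
  expect_equal(as.numeric(sp), 0)
  expect_true(attr(sp, "degenerate"))
  short <- sample_entropy(rnorm(100))
  expect_false(attr(short, "valid"))
  expect_true(is.na(as.numeric(short)))
})

test_that("template entropies are affine-invariant (r scales with SD)", {
  set.seed(31)
  x <- rnorm(400)
  for (fn in list(approximate_entropy, sample_entropy)) {
    v1 <- as.numeric(fn(x))
    v2 <- as.numeric(fn(3 * x + 7))
    expect_equal(v1, v2, tolerance = 1e-9)
  }
})

test_that("A <= B always, so SampEn is non-negative", {
  set.seed(41)
  for (k in 1:20) {
    x <- rnorm(300)
    sp <- sample_entropy(x)
    expect_lte(attr(sp, "A"), attr(sp, "B"))
    expect_gte(as.numeric(sp), 0)
  }
})

test_that("sampled signals above the decimation rate are decimated", {
  set.seed(51)
  v <- rnorm(4000)
  sig <- sampled_signal(v, 20000, "dia")
  ap <- approximate_entropy(sig, entropy_params(decimate_to_hz = 2000))
  expect_equal(attr(ap, "n"), 400L)  # every 10th sample
  ap_full <- approximate_entropy(sig, entropy_params(decimate_to_hz = NULL))
  expect_equal(attr(ap_full, "n"), 4000L)
})
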