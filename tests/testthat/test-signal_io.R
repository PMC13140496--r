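test_that("sampling rate is inferred from the time column spacing", {
  f <- withr::local_tempdir()
  tm <- (0:1999) / 1000
  writeLines(paste(tm, sin(tm), sep = ","), file.path(f, "m1_dia.txt"))
  writeLines("baseline,0,1.9", file.path(f, "m1_states.txt"))
  rec <- read_recording(f, "m1", channels = "dia")
  expect_equal(rec$channels$dia$rate, 1000)
  expect_equal(length(rec$channels$dia), 2000L)
})

test_that("write/read round-trips samples and rates exactly", {
  set.seed(11)
  x <- rnorm(400) * 37.5
  p <- -abs(rnorm(300))
  rec <- recording(
    list(dia = sampled_signal(x, 2000, "dia"),
         pressure = sampled_signal(p, 1500, "pressure", "cmH2O")),
    state_intervals("baseline", 0, 0.19),
    subject_meta = list(id = "rt1", genotype = "mdx", age_months = 12))
  d <- withr::local_tempdir()
  write_recording(rec, d)
  rec2 <- read_recording(d, "rt1", channels = c("dia", "pressure"))
  expect_identical(rec2$channels$dia$samples, x)
  expect_identical(rec2$channels$pressure$samples, p)
  expect_equal(rec2$channels$dia$rate, 2000)
  expect_equal(rec2$channels$pressure$rate, 1500)
  expect_identical(rec2$subject_meta$genotype, "mdx")
})

test_that("malformed signal files are rejected with clear contracts", {
  f <- withr::local_tempdir()
  writeLines("baseline,0,0.8", file.path(f, "s_states.txt"))
  # non-monotone time
  tm <- (0:999) / 1000
  tm[500] <- tm[499] - 0.01
  writeLines(paste(tm, rnorm(1000), sep = ","), file.path(f, "s_dia.txt"))
  expect_error(read_recording(f, "s", channels = "dia"), "non-monotone")
  # irregular sampling
  tm2 <- cumsum(c(0, runif(999, 0.0005, 0.0015)))
  writeLines(paste(tm2, rnorm(1000), sep = ","), file.path(f, "s_eic.txt"))
  expect_error(read_recording(f, "s", channels = "eic"), "irregular")
  # unit mismatch in a declared header
  writeLines(c("time,cmH2O", paste((0:999) / 1000, rnorm(1000), sep = ",")),
             file.path(f, "s_ps.txt"))
  expect_error(read_recording(f, "s", channels = "ps"), "unit mismatch")
})

test_that("missing channels give a warning and a partial recording", {
  g <- generate_recording(light_config(seed = 3))
  d <- withr::local_tempdir()
  write_recording(g$recording, d)
  file.remove(file.path(d, "sim1_ps.txt"))
  expect_warning(rec <- read_recording(d), "missing channel")
  expect_setequal(names(rec$channels), c("dia", "eic", "pressure"))
})

test_that("non-finite samples are flagged, not dropped, at read time", {
  f <- withr::local_tempdir()
  writeLines("baseline,0,0.2", file.path(f, "s_states.txt"))
  amp <- rnorm(500); amp[c(5, 10)] <- NA
  writeLines(paste((0:499) / 1000, amp, sep = ","), file.path(f, "s_dia.txt"))
  rec <- read_recording(f, "s", channels = "dia")
  expect_equal(length(rec$channels$dia), 500L)
  expect_equal(attr(rec$channels$dia, "n_nonfinite"), 2L)
})

test_that("summary tables are deterministic, ordered and NA-safe", {
  rows <- data.frame(subject = c("b", "a", "a"), genotype = "wt",
                     age_months = 4, muscle = c("dia", "ps", "dia"),
                     state = "baseline",
                     metric = c("nrd", "nme", "nrd"),
                     value = c(1.5, NaN, 2.5))
  d <- withr::local_tempdir()
  p1 <- file.path(d, "t1.csv"); p2 <- file.path(d, "t2.csv")
  write_summary_table(rows, p1)
  write_summary_table(rows, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  out <- read.csv(p1)
  expect_equal(out$subject, c("a", "a", "b"))  # sorted keys
  expect_true(is.na(out$value[out$muscle == "ps"]))
  # empty input -> header-only file
  p3 <- file.path(d, "t3.csv")
  write_summary_table(rows[0, ], p3)
  expect_equal(length(readLines(p3)), 1L)
})
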