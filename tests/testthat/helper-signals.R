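# shared fixtures and independent oracles

make_tone <- function(freq, dur = 2, rate = 20000, amp = 1) {
  sampled_signal(amp * sin(2 * pi * freq * seq(0, dur, by = 1 / rate)),
                 rate, label = "dia", units = "uV")
}

# steady-state amplitude of a (possibly filtered) tone, middle half
mid_amp <- function(x) {
  n <- length(x$samples)
  max(abs(x$samples[(n %/% 4):(3 * n %/% 4)]))
}

# a light generator configuration for unit tests (lower EMG rate; the
# full-rate defaults are exercised in the acceptance suite)
light_config <- function(seed = 1, rate_emg = 4000, ...) {
  generator_config(seed = seed, rate_emg = rate_emg, n_breaths = 6,
                   occlusion = list(n_efforts = 8, escalation_frac = 0.3,
                                    failure_onset_effort = 6,
                                    failure_decline_frac = 0.85,
                                    effort_period = 0.5, amp_factor = 3),
                   ...)
}

# ---- brute-force entropy oracles (independent double-loop forms) ----

oracle_apen <- function(x, m = 2, r) {
  n <- length(x)
  phi <- function(mm) {
    nt <- n - mm + 1
    acc <- 0
    for (i in seq_len(nt)) {
      cnt <- 0
      for (j in seq_len(nt)) {
        if (max(abs(x[i:(i + mm - 1)] - x[j:(j + mm - 1)])) <= r) cnt <- cnt + 1
      }
      acc <- acc + log(cnt / nt)
    }
    acc / nt
  }
  phi(m) - phi(m + 1)
}

oracle_sampen <- function(x, m = 2, r) {
  n <- length(x)
  nt <- n - m
  A <- 0; B <- 0
  for (i in seq_len(nt - 1)) {
    for (j in (i + 1):nt) {
      if (max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)])) <= r) {
        B <- B + 1
        if (max(abs(x[i:(i + m)] - x[j:(j + m)])) <= r) A <- A + 1
      }
    }
  }
  if (A == 0 || B == 0) return(NA_real_)
  -log(A / B)
}
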