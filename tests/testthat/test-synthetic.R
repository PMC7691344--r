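# Synthetic thoracoabdominal-motion generator: reproducibility, presets,
# and ground-truth recovery of lag, LBI and breathing rate.

test_that("generation is bit-reproducible and leaves the RNG alone", {
  p <- synthetic_params(seed = 7)
  r1 <- generate_recording(p)
  r2 <- generate_recording(p)
  expect_identical(r1$rc, r2$rc)
  expect_identical(r1$ab, r2$ab)

  set.seed(123)
  before <- rnorm(3)
  set.seed(123)
  invisible(generate_recording(p))
  expect_identical(rnorm(3), before)   # caller's stream untouched
})

test_that("cohort child seeds make subjects independent of cohort size", {
  c1 <- generate_cohort(1, seed = 42)
  c5 <- generate_cohort(5, seed = 42)
  expect_identical(c1[[1]]$rc, c5[[1]]$rc)
  expect_identical(c1[[1]]$metadata, c5[[1]]$metadata)
  expect_identical(length(c5), 5L)
  for (rec in c5) {
    expect_s3_class(rec, "rip_recording")
    expect_true(all(is.finite(rec$rc)))
    expect_true(is.numeric(rec$metadata$weight_g))
  }
  # different subjects differ
  expect_false(identical(c5[[1]]$rc, c5[[2]]$rc))
})

test_that("presets encode the four breathing phenotypes", {
  expect_equal(wob_preset("healthy_synchronous")$phase_lag_deg, 10)
  expect_equal(wob_preset("mild_async")$phase_lag_deg, 45)
  expect_equal(wob_preset("paradoxical")$phase_lag_deg, 175)
  deep <- wob_preset("anesthesia_deep")
  expect_equal(deep$amp_ab, 0.3)
  expect_equal(deep$rate_jitter_cv, 0.25)
  expect_equal(deep$noise_sd, 0.15)
  expect_error(wob_preset("bogus"), class = "ripwob_unknown_preset")

  ser <- analyze_recording(generate_recording(wob_preset("paradoxical",
                                                         seed = 3)))
  expect_gt(mean(ser$phase_deg[ser$valid]), 150)
})

test_that("parameter validation rejects impossible settings", {
  expect_error(synthetic_params(fs = 1.5),       # Nyquist: fs <= 2 * 0.943
               class = "ripwob_contract_violation")
  expect_error(synthetic_params(phase_lag_deg = 200),
               class = "ripwob_contract_violation")
  expect_error(synthetic_params(noise_sd = -0.1),
               class = "ripwob_contract_violation")
  expect_error(synthetic_params(duration_s = 0),
               class = "ripwob_contract_violation")
  expect_error(generate_cohort(0), class = "ripwob_contract_violation")
})

test_that("windowed analysis recovers the imposed phase lag", {
  # zero noise: mean recovered phase within 2 degrees across the grid
  for (lag in seq(0, 180, by = 15)) {
    p <- synthetic_params(phase_lag_deg = lag, noise_sd = 0,
                          rate_jitter_cv = 0, amp_jitter_cv = 0, seed = 1)
    ser <- analyze_recording(generate_recording(p))
    expect_lt(abs(mean(ser$phase_deg[ser$valid]) - lag), 2)
  }
  # 5% noise: within 5 degrees away from the ends of the scale; at the
  # folds (0 and 180) the unsigned estimator's noise floor (~5 degrees
  # at this SNR) adds to the truth, so the bound there is floor + 1
  for (lag in seq(15, 165, by = 30)) {
    p <- synthetic_params(phase_lag_deg = lag, seed = 1)
    ser <- analyze_recording(generate_recording(p))
    expect_lt(abs(mean(ser$phase_deg[ser$valid]) - lag), 5)
  }
  for (lag in c(0, 180)) {
    p <- synthetic_params(phase_lag_deg = lag, seed = 1)
    ser <- analyze_recording(generate_recording(p))
    expect_lt(abs(mean(ser$phase_deg[ser$valid]) - lag), 6)
  }
})

test_that("generated LBI matches 1/cos(lag/2) at zero noise", {
  for (lag in seq(15, 150, by = 45)) {
    p <- synthetic_params(phase_lag_deg = lag, noise_sd = 0,
                          rate_jitter_cv = 0, amp_jitter_cv = 0,
                          amp_rc = 1, seed = 1)
    ser <- analyze_recording(generate_recording(p))
    truth <- 1 / cos(lag * pi / 360)
    expect_equal(mean(ser$lbi[ser$valid]), truth, tolerance = 0.01)
  }
})

test_that("spectral rate recovers the generated breathing frequency", {
  # rate-stable breathing at 0.943 Hz over 210 s: recovered within one
  # spectral bin width (rate jitter broadens the line beyond sub-bin
  # accuracy, so the rate-stable generator defines this check)
  p <- synthetic_params(rate_jitter_cv = 0, seed = 1)
  est <- breaths_per_minute(generate_recording(p))
  expect_true(est$valid)
  expect_lt(abs(est$bpm / 60 - 0.943), est$bin_width_hz)
  expect_equal(est$bpm, 56.6, tolerance = 0.01)

  # 0.5 Hz -> 30 BPM within a bin
  p <- synthetic_params(f_breath_hz = 0.5, rate_jitter_cv = 0, seed = 2)
  est <- breaths_per_minute(generate_recording(p))
  expect_lt(abs(est$bpm / 60 - 0.5), est$bin_width_hz)
})

test_that("the default cohort lands in the healthy synchrony range", {
  cohort <- generate_cohort(5, seed = 42)
  series <- lapply(cohort, analyze_recording)
  summ <- summarize_cohort(series, recordings = cohort)
  rc <- summ[summ$variable == "rc_percent", "mean"]
  phi <- summ[summ$variable == "phase_deg", "mean"]
  expect_gt(rc, 45); expect_lt(rc, 60)
  expect_lt(phi, 30)
  lbi_mean <- summ[summ$variable == "lbi", "mean"]
  expect_gte(lbi_mean, 1); expect_lt(lbi_mean, 1.05)
})
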