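# Per-window index formulas: RC%, phase angle, LBI, synchrony labels.

test_that("rc_percent reflects the compartment amplitude ratio", {
  # equal amplitudes split 50/50 regardless of phase: exact when the lag
  # is grid-aligned over whole periods, near-exact for arbitrary lag
  th <- 2 * pi * (0:40) / 40
  expect_equal(rc_percent(sin(th), cos(th)), 50)
  s <- lagged_sines(77, k = 1, spp = 400, closed = TRUE)
  expect_equal(rc_percent(s$x, s$y), 50, tolerance = 1e-4)

  # 3:1 triangle waves -> 75% (waveform-agnostic: ratio of excursions)
  tri_f <- function(u) 2 * abs(2 * (u - floor(u + 0.5))) - 1
  tt <- (0:60) / 20                      # 3 whole periods, closed
  expect_equal(rc_percent(3 * tri_f(tt), tri_f(tt + 7 / 20)), 75)
  expect_equal(rc_percent(3 * tri_f(tt), -tri_f(tt)), 75)

  # seeded sinusoid scaled 1.38 vs 1.0 -> 100 * 1.38/2.38
  set.seed(11)
  w <- sin(2 * pi * 1.1 * (0:199) / 50 + runif(1, 0, 2 * pi))
  expect_equal(rc_percent(1.38 * w, w), 57.98, tolerance = 0.01 / 57.98)

  # complementarity: RC% + AB% = 100 (to machine rounding)
  set.seed(12)
  for (i in 1:50) {
    x <- random_window(); y <- random_window()
    expect_equal(rc_percent(x, y) + rc_percent(y, x), 100,
                 tolerance = 1e-13)
  }
})

test_that("phase angle hits the synchrony anchors and recovers imposed lags", {
  x <- sin(2 * pi * (0:19) / 20)
  expect_equal(phase_angle(x, x), 0)          # perfect synchrony
  expect_equal(phase_angle(x, -x), 180)       # paradoxical motion

  # one full period at 20 samples, lag 60 deg: orthogonality makes the
  # normalised inner product exactly cos(60 deg)
  s <- lagged_sines(60)
  expect_equal(phase_angle(s$x, s$y), 60, tolerance = 1e-6 / 60)

  # full-period lag grid recovered to < 0.1 degree
  for (lag in seq(0, 180, by = 15)) {
    s <- lagged_sines(lag, k = 3, spp = 40)
    expect_lt(abs(phase_angle(s$x, s$y) - lag), 0.1)
    expect_lt(abs(oracle_phase(s$x, s$y) - lag), 0.1)
  }
})

test_that("phase angle is symmetric, scale-invariant and bounded", {
  set.seed(21)
  for (i in 1:100) {
    x <- random_window(); y <- random_window()
    p <- phase_angle(x, y)
    expect_gte(p, 0); expect_lte(p, 180)
    expect_identical(p, phase_angle(y, x))
    expect_equal(phase_angle(3.7 * x, y), p)
    expect_equal(phase_angle(x, 0.004 * y), p)
    expect_equal(p, oracle_phase(x, y), tolerance = 1e-12)
  }
})

test_that("lbi matches the 1/cos(lag/2) closed form on dense sinusoids", {
  # in unison -> exactly 1
  th <- 2 * pi * (0:79) / 40
  expect_equal(lbi(sin(th), sin(th)), 1)

  # lag 60, dense whole-period record -> 1/cos(30 deg)
  s <- lagged_sines(60, k = 2, spp = 400, closed = TRUE)
  expect_equal(lbi(s$x, s$y), 1.1547, tolerance = 0.001 / 1.1547)

  # lag 120 -> 1/cos(60 deg) = 2
  s <- lagged_sines(120, k = 2, spp = 400, closed = TRUE)
  expect_equal(lbi(s$x, s$y), 2.0, tolerance = 0.005 / 2)

  # sweep: non-decreasing in lag, within 0.5% of 1/cos(lag/2)
  prev <- 1
  for (lag in seq(10, 150, by = 10)) {
    s <- lagged_sines(lag, k = 2, spp = 400, closed = TRUE)
    v <- lbi(s$x, s$y)
    expect_gte(v, prev)
    expect_equal(v, 1 / cos(lag * pi / 360),
                 tolerance = 0.005)
    prev <- v
  }
})

test_that("lbi and rc_percent are invariant to common trends and scaling", {
  set.seed(31)
  for (i in 1:60) {
    x <- random_window(40); y <- random_window(40)
    trend <- runif(1, -2, 2) + runif(1, -0.5, 0.5) * seq_len(40)
    l0 <- lbi(x, y)
    expect_gte(l0, 1 - 1e-9)
    expect_equal(lbi(x + trend, y + trend), l0)
    expect_equal(lbi(5.5 * x, 5.5 * y), l0)
    expect_equal(rc_percent(x + trend, y + trend), rc_percent(x, y))
    expect_equal(l0, oracle_lbi(x, y), tolerance = 1e-9)
    expect_equal(rc_percent(x, y), oracle_rc_percent(x, y),
                 tolerance = 1e-9)
  }
})

test_that("degenerate windows raise classed errors, not values", {
  flat <- rep(2.5, 20)
  wave <- sin(2 * pi * (0:19) / 20)
  expect_error(rc_percent(flat, flat), class = "ripwob_degenerate_window")
  expect_error(phase_angle(flat, wave), class = "ripwob_degenerate_window")
  expect_error(lbi(flat, flat), class = "ripwob_degenerate_window")
  # exact paradox with equal amplitudes: summed signal vanishes
  expect_error(lbi(wave, -wave), class = "ripwob_degenerate_window")
  # window below the 4-sample minimum
  expect_error(phase_angle(wave[1:3], wave[1:3]),
               class = "ripwob_invalid_window")
})

test_that("synchrony classification follows the threshold rule", {
  expect_identical(classify_synchrony(8.94, 1.04), "synchronous")
  expect_identical(classify_synchrony(180, 1.5), "paradoxical")
  expect_identical(classify_synchrony(45, 1.2), "asynchronous")
  # boundary behaviour: strict < for synchrony, >= for paradox
  expect_identical(classify_synchrony(30, 1.0), "asynchronous")
  expect_identical(classify_synchrony(10, 1.05), "asynchronous")
  expect_identical(classify_synchrony(150, 1.3), "paradoxical")
  # vectorised
  expect_identical(classify_synchrony(c(5, 60, 170), c(1.0, 1.2, 3)),
                   c("synchronous", "asynchronous", "paradoxical"))
  # configurable thresholds
  th <- wob_thresholds(phase_sync_deg = 20, lbi_sync = 1.02,
                       phase_paradox_deg = 170)
  expect_identical(classify_synchrony(25, 1.0, th), "asynchronous")
  expect_identical(classify_synchrony(160, 1.3, th), "asynchronous")
  # contract violations
  expect_error(classify_synchrony(-1, 1.0),
               class = "ripwob_contract_violation")
  expect_error(classify_synchrony(200, 1.0),
               class = "ripwob_contract_violation")
  expect_error(classify_synchrony(20, 0.5),
               class = "ripwob_contract_violation")
})

test_that("recording constructor enforces its invariants", {
  expect_error(rip_recording(1:5, 1:4, fs = 10),
               class = "ripwob_invalid_recording")
  expect_error(rip_recording(1, 1, fs = 10),
               class = "ripwob_invalid_recording")
  expect_error(rip_recording(1:10, 1:10, fs = 0),
               class = "ripwob_invalid_recording")
  expect_error(rip_recording(c(1:9, NA), 1:10, fs = 10),
               class = "ripwob_invalid_recording")
  expect_error(rip_recording(c(1:9, Inf), 1:10, fs = 10),
               class = "ripwob_invalid_recording")
  rec <- rip_recording(1:10, 10:1, fs = 10, subject_id = "r1",
                       metadata = list(weight_g = 250))
  expect_s3_class(rec, "rip_recording")
  expect_identical(length(rec), 10L)
})
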