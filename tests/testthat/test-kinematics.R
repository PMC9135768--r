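test_that("the 20 Hz low-pass keeps the passband and rejects noise", {
  t <- seq(0, 5, by = 1 / 500)
  x6 <- sin(2 * pi * 6 * t)
  y6 <- lowpass_20(x6, 500)
  expect_equal(diff(range(y6[500:2000])) / 2, 1, tolerance = 0.02)
  mix <- x6 + 0.5 * sin(2 * pi * 60 * t)
  ym <- lowpass_20(mix, 500)
  resid60 <- ym - y6
  atten_db <- 20 * log10(0.5 / (diff(range(resid60[500:2000])) / 2))
  expect_gt(atten_db, 20)
  expect_equal(mean(lowpass_20(x6 + 3, 500)), 3, tolerance = 0.01)
  expect_error(lowpass_20(x6, 30), "rate")
})

test_that("swim cycles are segmented at hysteresis-qualified onsets", {
  t <- seq(0, 3, length.out = 1501)[-1501]
  x <- 5 * sin(2 * pi * 6 * t)
  cyc <- segment_swim_cycles(x, 500, hysteresis_deg = 1)
  expect_equal(nrow(cyc), 18)
  expect_true(all(diff(cyc$onset_s) > 0))
  expect_equal(cyc$instant_freq_hz[1:17], rep(6, 17), tolerance = 0.02)
  expect_equal(nrow(segment_swim_cycles(rep(0, 1500), 500)), 0)
  # robust to noise at SNR 10
  set.seed(5)
  xn <- x + rnorm(length(x), 0, 0.5)
  expect_equal(nrow(segment_swim_cycles(lowpass_20(xn, 500), 500, 1)), 18)
})

test_that("per-cycle amplitudes are peak-to-peak excursions", {
  t <- seq(0, 3, length.out = 1500)
  tail <- 5 * sin(2 * pi * 6 * t)
  eye <- 0.4 * tail
  cyc <- segment_swim_cycles(tail, 500)
  cyc <- per_cycle_amplitudes(eye, tail, cyc, 500)
  expect_equal(cyc$tail_p2p_deg, rep(10, nrow(cyc)), tolerance = 0.02)
  expect_equal(cyc$eye_p2p_deg, 0.4 * cyc$tail_p2p_deg, tolerance = 1e-9)
  expect_error(per_cycle_amplitudes(eye[1:100], tail[1:100],
                                    cyc, 500), "span")
})

test_that("spino-ocular gain and phase follow their construction", {
  t <- seq(0, 5, length.out = 2500)
  tail <- 8 * sin(2 * pi * 6 * t)
  cyc0 <- segment_swim_cycles(tail, 500)
  # compensatory eye (counter-rotating), no lag
  eye <- -0.5 * tail
  cyc <- per_cycle_amplitudes(eye, tail, cyc0, 500)
  gp <- spino_ocular_gain_phase(cyc, eye, tail, 500)
  expect_equal(gp$gain, 0.5, tolerance = 1e-6)
  expect_equal(gp$phase_deg, 0, tolerance = 2)
  # delay of one twelfth of a cycle -> 30 deg lag
  lagn <- round(500 / 6 / 12)
  eye_lag <- c(rep(0, lagn), -0.5 * tail)[seq_along(tail)]
  cyc2 <- per_cycle_amplitudes(eye_lag, tail, cyc0, 500)
  gp2 <- spino_ocular_gain_phase(cyc2, eye_lag, tail, 500)
  expect_lt(abs(gp2$phase_deg - 30), 5)
  # amplitude scaling of both traces leaves the gain unchanged
  cyc3 <- per_cycle_amplitudes(3 * eye, 3 * tail, cyc0, 500)
  gp3 <- spino_ocular_gain_phase(cyc3, 3 * eye, 3 * tail, 500)
  expect_equal(gp3$gain, gp$gain, tolerance = 1e-9)
  expect_error(spino_ocular_gain_phase(cyc[1:3, ], eye, tail, 500), "5")
})

test_that("sinusoid fits report gain and lead-positive phase", {
  stim <- make_stimulus_trace(1, 10, 10, 500)
  fit <- sinusoid_response_fit(stim, stim, 500, 1)
  expect_equal(fit$gain, 1, tolerance = 1e-9)
  expect_equal(fit$phase_deg, 0, tolerance = 1e-6)
  resp <- make_stimulus_trace(1, 5, 10, 500, phase_deg = 30)
  fit2 <- sinusoid_response_fit(resp, stim, 500, 1)
  expect_equal(fit2$gain, 0.5, tolerance = 1e-9)
  expect_equal(fit2$phase_deg, 30, tolerance = 1e-6)
  expect_error(sinusoid_response_fit(stim, 0 * stim, 500, 1), "zero")
  expect_error(sinusoid_response_fit(stim[1:500], stim[1:500], 500, 1),
               "4 stimulus cycles")
})

test_that("eccentricity extraction recovers slow carriers and drifts", {
  t <- seq(0, 10, length.out = 5000)
  rate <- 500
  fast <- 4 * sin(2 * pi * 6 * t)
  # plain oscillation about zero -> slow trace about zero
  cyc <- segment_swim_cycles(fast, rate)
  cyc <- per_cycle_amplitudes(fast, fast, cyc, rate)
  expect_lt(max(abs(eccentricity_trace(fast, cyc, rate))), 0.2)
  # oscillation riding on a 1 Hz, 5 deg carrier
  carrier <- 5 * sin(2 * pi * 1 * t)
  eye <- fast + carrier
  cyc2 <- per_cycle_amplitudes(eye, fast, segment_swim_cycles(fast, rate), rate)
  slow <- eccentricity_trace(eye, cyc2, rate)
  mid <- t > 1 & t < 9
  expect_equal(diff(range(slow[mid])), 10, tolerance = 0.1)
  # decomposition consistency: slow + fast explains the trace
  resid <- eye - slow - fast
  expect_lt(var(resid[mid]) / var(eye[mid]), 0.05)
  # linear drift is recovered
  drifted <- fast + 2 * t
  cyc3 <- per_cycle_amplitudes(drifted, fast, segment_swim_cycles(fast, rate), rate)
  slow3 <- eccentricity_trace(drifted, cyc3, rate)
  expect_equal(unname(coef(lm(slow3[mid] ~ t[mid]))[2]), 2, tolerance = 0.1)
  expect_error(eccentricity_trace(eye, cyc2[1, ], rate), "2 cycles")
})

test_that("modulation metrics recover imposed depths and reject short windows", {
  p <- stage_preset("52", magnitude_depth_deg = 8, eccentricity_depth_deg = 0)
  k <- kin_pipeline(p)
  mm <- modulation_metrics(k$cycles, k$slow, 1, k$duration, k$rate)
  expect_equal(mm$delta_magnitude_deg, 8, tolerance = 0.12)
  expect_lt(mm$delta_eccentricity_deg, 1.2)      # documented noise floor
  p2 <- stage_preset("52", magnitude_depth_deg = 0, eccentricity_depth_deg = 12)
  k2 <- kin_pipeline(p2)
  mm2 <- modulation_metrics(k2$cycles, k2$slow, 1, k2$duration, k2$rate)
  expect_equal(mm2$delta_eccentricity_deg, 12, tolerance = 0.12)
  expect_lt(mm2$delta_magnitude_deg, 1.2)
  expect_error(modulation_metrics(k$cycles, k$slow, 0.3, k$duration, k$rate),
               "4 vestibular")
})

test_that("the drift screen flags slow stimulus-unrelated deviations", {
  t <- seq(0, 10, length.out = 5000)
  good <- 5 * sin(2 * pi * 1 * t) + 3 * sin(2 * pi * 6 * t)
  expect_true(drift_screen(good, 500, 1)$pass)
  ramped <- good + 4 * t                         # 4 deg/s ramp
  ds <- drift_screen(ramped, 500, 1)
  expect_false(ds$pass)
  expect_equal(ds$slope_deg_s, 4, tolerance = 0.1)
  # deterministic on repeated evaluation
  expect_identical(drift_screen(ramped, 500, 1), drift_screen(ramped, 500, 1))
  expect_error(drift_screen(good[1:1000], 500, 1), "4 stimulus cycles")
})
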