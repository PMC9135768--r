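test_that("generators are seeded and reproducible", {
  p <- stage_preset("52")
  t1 <- make_tail_trace(p, 6, seed = 9)
  t2 <- make_tail_trace(p, 6, seed = 9)
  expect_identical(as.numeric(t1), as.numeric(t2))
  e1 <- make_eye_traces(t1, p, seed = 4)
  e2 <- make_eye_traces(t2, p, seed = 4)
  expect_identical(e1$left, e2$left)
  expect_false(identical(as.numeric(t1),
                         as.numeric(make_tail_trace(p, 6, seed = 10))))
})

test_that("a noise-free tail is an enveloped sinusoid with the right cycle count", {
  p <- stage_preset("52", noise_sd_deg = 0)
  tail <- make_tail_trace(p, 6, seed = 1)
  cyc <- segment_swim_cycles(as.numeric(tail), 500, 1)
  expect_equal(nrow(cyc), 6 * p$swim_freq_hz)
  expect_equal(max(abs(tail)), p$tail_amp_deg, tolerance = 1e-3)
  expect_error(make_tail_trace(stage_preset("48"), 2), "4 vestibular")
  expect_error(make_tail_trace(stage_preset("48"), 6, rate_hz = 20), "twice")
})

test_that("stage presets carry their printed frequencies into the spectra", {
  p52 <- stage_preset("52")
  tail <- make_tail_trace(p52, 8, seed = 3)
  pg <- periodogram(cwt_spectrogram(as.numeric(tail), 500))
  expect_equal(dominant_frequency(pg), 6, tolerance = 0.05)
  p48 <- stage_preset("48")
  expect_equal(p48$swim_freq_hz, 13)
  expect_equal(p48$magnitude_depth_deg + p48$eccentricity_depth_deg, 0)
  expect_true(stage_preset("49")$eye_mode == "invariant")
})

test_that("invariant and proportional eye modes separate as in development", {
  # tail amplitude swept across the episode: with invariant eye amplitude
  # the gain falls as the tail grows (negative regression slope); with
  # proportional coupling the gain is flat
  slope_for <- function(stage) {
    p <- stage_preset(stage, tail_amp_ramp = c(0.7, 1.3), vest_amp_deg = 0,
                      magnitude_depth_deg = 0, eccentricity_depth_deg = 0)
    k <- kin_pipeline(p, duration_s = 8, seed_tail = 31, seed_eye = 32)
    keep <- !is.na(k$cycles$eye_p2p_deg) & k$cycles$tail_p2p_deg > 1
    g <- k$cycles$eye_p2p_deg[keep] / k$cycles$tail_p2p_deg[keep]
    fit <- summary(lm(g ~ k$cycles$tail_p2p_deg[keep]))
    fit$coefficients[2, c(1, 4)]   # slope, p
  }
  s49 <- slope_for("49")
  s58 <- slope_for("58")
  expect_lt(s49[1], 0)
  expect_lt(s49[2], 0.01)          # clearly negative
  expect_gt(abs(s49[1]), 3 * abs(s58[1]))
})

test_that("nerve traces carry the imposed burst structure", {
  rate <- 10000
  t <- seq(0, 5, by = 1 / rate)
  # 7 Hz burst-shaped multi-unit rate envelope, 600 sp/s at burst crest
  env_rate <- 600 * pmax(sin(2 * pi * 7 * t), 0)^2
  nerve <- make_nerve_trace(env_rate, rate, seed = 6)
  env <- rectify_integrate(as.numeric(nerve), rate, 25, 1)
  ev <- detect_burst_peaks(env, min_separation_ms = 60)
  expect_equal(length(ev) / 5, 7, tolerance = 0.05)
  # envelope shape is recovered (compare against the equally smoothed rate)
  ref <- rectify_integrate(env_rate, rate, 25, 1)
  expect_gt(cor(as.numeric(env), as.numeric(ref)), 0.9)
  # zero envelope: noise only, no bursts at the signal's detection level
  quiet <- make_nerve_trace(rep(0, length(t)), rate, seed = 6)
  evq <- detect_burst_peaks(rectify_integrate(as.numeric(quiet), rate, 25, 1),
                            threshold = 0.5 * max(env),
                            min_separation_ms = 60)
  expect_length(evq, 0)
  expect_identical(attr(make_nerve_trace(env_rate, rate, seed = 2), "spike_times_s"),
                   attr(make_nerve_trace(env_rate, rate, seed = 2), "spike_times_s"))
  expect_error(make_nerve_trace(c(-1, 1)), "non-negative")
})
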