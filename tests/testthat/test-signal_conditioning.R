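test_that("rectify-integrate preserves DC and averages |sin| to 2/pi", {
  env <- rectify_integrate(rep(3, 1000), 1000, 25, 1)
  expect_equal(as.numeric(env), rep(3, 1000), tolerance = 1e-12)
  env_neg <- rectify_integrate(rep(-3, 1000), 1000, 25, 1)
  expect_equal(as.numeric(env_neg), rep(3, 1000), tolerance = 1e-12)
  # unit 50 Hz sine smoothed with a window of many periods -> mean of |sin|
  x <- sin(2 * pi * 50 * seq(0, 2, by = 1e-3))
  env2 <- rectify_integrate(x, 1000, window_ms = 400, iterations = 1)
  mid <- as.numeric(env2)[600:1400]
  expect_equal(mean(mid), 2 / pi, tolerance = 0.01)
  # positive homogeneity
  env3 <- rectify_integrate(5 * x, 1000, 25, 2)
  env1 <- rectify_integrate(x, 1000, 25, 2)
  expect_equal(as.numeric(env3), 5 * as.numeric(env1), tolerance = 1e-10)
  expect_error(rectify_integrate(x[1:10], 1000, 400, 1), "window")
})

test_that("burst peaks are counted once per supra-threshold maximum", {
  t <- seq(0, 5, by = 1e-3)
  bump <- function(c) exp(-(t - c)^2 / (2 * 0.02^2))
  two <- bump(1) + bump(3)
  ev <- detect_burst_peaks(two, rate_hz = 1000, min_separation_ms = 50)
  expect_length(ev, 2)
  expect_equal(ev, c(1, 3), tolerance = 0.005)
  expect_length(detect_burst_peaks(rep(1, 5000), rate_hz = 1000), 0)
  # 7 Hz periodic bumps over 5 s -> 35 events
  seven <- Reduce(`+`, lapply(seq(1 / 14, 5 - 1 / 14, by = 1 / 7), bump))
  ev7 <- detect_burst_peaks(seven, rate_hz = 1000, min_separation_ms = 50)
  expect_length(ev7, 35)
})

test_that("burst metrics recover amplitude, baseline and their shifts", {
  t <- seq(0, 5, by = 1e-3)
  centers <- seq(0.5, 4.5, by = 0.5)
  x <- Reduce(`+`, lapply(centers, function(c) exp(-(t - c)^2 / (2 * 0.02^2))))
  env <- structure(x, class = "envelope", rate_hz = 1000)
  ev <- detect_burst_peaks(env, min_separation_ms = 100)
  bm <- burst_metrics(env, ev)
  expect_equal(nrow(bm), length(centers))
  expect_equal(bm$baseline, rep(0, nrow(bm)), tolerance = 1e-3)
  expect_equal(bm$amplitude, rep(1, nrow(bm)), tolerance = 1e-3)
  # lifting the trace moves the baseline, not the amplitude
  env_up <- structure(x + 2, class = "envelope", rate_hz = 1000)
  bm_up <- burst_metrics(env_up, detect_burst_peaks(env_up, min_separation_ms = 100))
  expect_equal(bm_up$baseline, bm$baseline + 2, tolerance = 1e-3)
  expect_equal(bm_up$amplitude, bm$amplitude, tolerance = 1e-3)
  # ramped bump heights are recovered
  ramp <- seq(1, 2, length.out = length(centers))
  xr <- Reduce(`+`, Map(function(c, a) a * exp(-(t - c)^2 / (2 * 0.02^2)),
                        centers, ramp))
  env_r <- structure(xr, class = "envelope", rate_hz = 1000)
  bm_r <- burst_metrics(env_r, detect_burst_peaks(env_r, threshold = 0.5,
                                                  min_separation_ms = 100))
  expect_equal(bm_r$amplitude, ramp, tolerance = 0.05)
})

test_that("rhythm frequency is the mean reciprocal inter-event interval", {
  ev <- seq(0, 5, by = 1 / 7)
  expect_equal(rhythm_frequency(ev)$mean_hz, 7, tolerance = 1e-9)
  rf <- rhythm_frequency(c(0, 0.1, 0.3))
  expect_equal(rf$instantaneous_hz, c(10, 5))
  expect_equal(rf$mean_hz, 7.5)
  expect_error(rhythm_frequency(1.0), "2 events")
  # jittered 6 Hz train
  set.seed(42)
  evj <- seq(0, 10, by = 1 / 6) + rnorm(61, 0, 0.005)
  expect_lt(abs(rhythm_frequency(sort(evj))$mean_hz - 6), 0.2)
})

test_that("downsampling preserves content below the new Nyquist", {
  x <- sin(2 * pi * 5 * seq(0, 1, by = 1e-4))    # 5 Hz at 10 kHz
  y <- downsample(x, 1e4, 500)
  expect_length(y, 501)
  sp <- Mod(fft(as.numeric(y)))[1:250]
  expect_equal(which.max(sp[-1]), 5)             # dominant bin at 5 Hz
  expect_identical(as.numeric(downsample(x, 1e4, 1e4)), x)
  expect_error(downsample(x, 500, 1000), "upsampling")
})
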