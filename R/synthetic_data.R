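#' Developmental stage presets for the trace generators
#'
#' Encodes the stage-specific quantities the generators emulate: swim
#' frequency (the larval range is 6-15 Hz, decreasing with age), tail
#' amplitude, spino-ocular gain and phase lag, whether the eye oscillation
#' magnitude is amplitude-invariant (young larvae, gain ~0.74 at ~10 deg
#' tail deflections with invariant 5-7 deg eye excursions) or proportional
#' to the tail (older larvae, gain ~0.4), the vestibular stimulus, and the
#' modulation depths of eye magnitude and eccentricity.  Noise level and
#' episode envelope are synthetic-only choices.
#'
#' @param stage One of `"48"`, `"49"`, `"52"`, `"58"`.
#' @param ... Overrides of individual preset fields.
#' @return List of class `stage_preset`.
#' @export
stage_preset <- function(stage = c("52", "48", "49", "58"), ...) {
  stage <- match.arg(stage)
  p <- switch(stage,
    "48" = list(swim_freq_hz = 13, tail_amp_deg = 12, gain = 0.6,
                phase_lag_deg = 15, eye_mode = "invariant",
                eye_amp_deg = 6, vest_freq_hz = 1, vest_amp_deg = 10,
                magnitude_depth_deg = 0, eccentricity_depth_deg = 0),
    "49" = list(swim_freq_hz = 10, tail_amp_deg = 10, gain = 0.74,
                phase_lag_deg = 15, eye_mode = "invariant",
                eye_amp_deg = 6, vest_freq_hz = 1, vest_amp_deg = 10,
                magnitude_depth_deg = 6.23, eccentricity_depth_deg = 3.78),
    "52" = list(swim_freq_hz = 6, tail_amp_deg = 12, gain = 0.55,
                phase_lag_deg = 20, eye_mode = "proportional",
                eye_amp_deg = NA, vest_freq_hz = 1, vest_amp_deg = 10,
                magnitude_depth_deg = 5.12, eccentricity_depth_deg = 3.89),
    "58" = list(swim_freq_hz = 6, tail_amp_deg = 15, gain = 0.4,
                phase_lag_deg = 20, eye_mode = "proportional",
                eye_amp_deg = NA, vest_freq_hz = 1, vest_amp_deg = 10,
                magnitude_depth_deg = 8.05, eccentricity_depth_deg = 12.09))
  p$stage <- stage
  p$noise_sd_deg <- 0.5
  p$ramp_s <- 0.2
  p$tail_amp_ramp <- c(1, 1)  # linear amplitude sweep across the episode
  over <- list(...)
  p[names(over)] <- over
  if (p$swim_freq_hz < 0) stop("swim frequency must be positive")
  stopifnot(p$magnitude_depth_deg >= 0, p$eccentricity_depth_deg >= 0)
  class(p) <- "stage_preset"
  p
}

#' @export
print.stage_preset <- function(x, ...) {
  cat(sprintf("Stage %s preset: swim %g Hz, tail %g deg, gain %.2f (%s eye amplitude)\n",
              x$stage, x$swim_freq_hz, x$tail_amp_deg, x$gain, x$eye_mode))
  invisible(x)
}

episode_envelope <- function(n, rate_hz, ramp_s) {
  tt <- (seq_len(n) - 1) / rate_hz
  dur <- tt[n]
  env <- rep(1, n)
  up <- tt < ramp_s
  env[up] <- 0.5 * (1 - cos(pi * tt[up] / ramp_s))
  dn <- tt > dur - ramp_s
  env[dn] <- 0.5 * (1 - cos(pi * (dur - tt[dn]) / ramp_s))
  env
}

#' Synthetic tail angle trace
#'
#' Sinusoid-like left-right tail undulation at the preset swim frequency
#' with raised-cosine episode onset/offset ramps and additive Gaussian
#' noise; fully reproducible for a fixed seed.  The noise-free oscillation
#' is kept in `attr(, "clean")` so that downstream generators can build
#' phase-locked eye traces.
#'
#' @param preset A [stage_preset()].
#' @param duration_s Episode length (s); must span at least 4 vestibular
#'   cycles when a vestibular stimulus is configured.
#' @param rate_hz Sampling rate (Hz, default 500, the video frame rate).
#' @param seed Seed for the noise.
#' @return Numeric trace (degrees) with attributes `rate_hz`, `clean`,
#'   `envelope`, `preset`.
#' @export
make_tail_trace <- function(preset, duration_s = 10, rate_hz = 500, seed = 1) {
  if (rate_hz < 2 * preset$swim_freq_hz)
    stop("sampling rate below twice the swim frequency")
  if (preset$vest_amp_deg > 0 && duration_s < 4 / preset$vest_freq_hz)
    stop("duration must span at least 4 vestibular cycles")
  n <- round(duration_s * rate_hz) + 1
  tt <- (seq_len(n) - 1) / rate_hz
  env <- episode_envelope(n, rate_hz, preset$ramp_s)
  unit <- sin(2 * pi * preset$swim_freq_hz * tt) * env
  ramp <- seq(preset$tail_amp_ramp[1], preset$tail_amp_ramp[2],
              length.out = n)
  clean <- preset$tail_amp_deg * ramp * unit
  set.seed(seed)
  x <- clean + rnorm(n, 0, preset$noise_sd_deg)
  structure(x, rate_hz = rate_hz, clean = clean, unit = unit, ramp = ramp,
            envelope = env, preset = preset)
}

#' Synthetic conjugate eye traces coupled to a tail trace
#'
#' Builds left and right eye angle traces from a [make_tail_trace()]
#' output: the swim-locked fast component is the phase-lagged,
#' counter-rotating copy of the tail oscillation (scaled by the gain, with
#' amplitude either proportional to the tail or invariant per preset),
#' multiplied by a vestibular-frequency amplitude modulation whose
#' peak-to-peak range equals `magnitude_depth_deg`; the slow
#' eccentricity carrier is a sinusoid at the vestibular frequency with
#' range `eccentricity_depth_deg`.  The two eyes are conjugate (identical
#' deterministic part) with independent measurement noise.
#'
#' @param tail Trace from [make_tail_trace()].
#' @param preset The same [stage_preset()]; defaults to the tail's.
#' @param seed Seed for the eye noise.
#' @return List with `left`, `right` (degrees, attributes as the tail) and
#'   the deterministic components `fast`, `slow`.
#' @export
make_eye_traces <- function(tail, preset = attr(tail, "preset"), seed = 2) {
  rate_hz <- attr(tail, "rate_hz")
  if (is.null(rate_hz)) stop("tail must come from make_tail_trace()")
  if (!identical(preset$swim_freq_hz, attr(tail, "preset")$swim_freq_hz))
    stop("preset/tail mismatch")
  clean <- attr(tail, "clean")
  unit <- attr(tail, "unit")
  ramp <- attr(tail, "ramp")
  env <- attr(tail, "envelope")
  n <- length(clean)
  tt <- (seq_len(n) - 1) / rate_hz
  lag_s <- preset$phase_lag_deg / 360 / preset$swim_freq_hz
  lag_n <- round(lag_s * rate_hz)
  shift <- function(v) c(rep(0, lag_n), v)[seq_len(n)]
  # invariant: eye amplitude is fixed regardless of the tail excursion;
  # proportional: eye is the gain-scaled copy of the tail oscillation
  fast <- if (preset$eye_mode == "invariant") {
    -preset$eye_amp_deg * shift(unit)
  } else {
    -preset$gain * shift(clean)
  }
  half_amp <- max(abs(fast))
  m <- if (preset$magnitude_depth_deg > 0 && half_amp > 0)
    (preset$magnitude_depth_deg / 4) / half_amp else 0
  fast <- fast * (1 + m * sin(2 * pi * preset$vest_freq_hz * tt))
  slow <- (preset$eccentricity_depth_deg / 2) *
    sin(2 * pi * preset$vest_freq_hz * tt) * env
  det <- fast + slow
  set.seed(seed)
  left <- det + rnorm(n, 0, preset$noise_sd_deg)
  right <- det + rnorm(n, 0, preset$noise_sd_deg)
  list(left = structure(left, rate_hz = rate_hz, preset = preset),
       right = structure(right, rate_hz = rate_hz, preset = preset),
       fast = fast, slow = slow)
}

#' Synthetic sinusoidal stimulus-position trace
#'
#' @param freq_hz Stimulus frequency (Hz, > 0).
#' @param amplitude_deg Maximal positional eccentricity (degrees).
#' @param duration_s Length (s).
#' @param rate_hz Sampling rate (Hz).
#' @param phase_deg Starting phase (degrees).
#' @return Numeric trace (degrees) with attribute `rate_hz`.
#' @export
make_stimulus_trace <- function(freq_hz, amplitude_deg, duration_s = 10,
                                rate_hz = 500, phase_deg = 0) {
  if (freq_hz <= 0) stop("stimulus frequency must be positive")
  tt <- seq(0, duration_s, by = 1 / rate_hz)
  structure(amplitude_deg * sin(2 * pi * freq_hz * tt + phase_deg * pi / 180),
            rate_hz = rate_hz)
}

#' Synthetic extracellular nerve discharge
#'
#' Emulates a multi-unit motor-nerve recording: an inhomogeneous Poisson
#' spike train whose instantaneous rate follows the supplied envelope,
#' convolved with a biphasic spike waveform, plus Gaussian electrode
#' noise.  Rectify-and-integrate recovers the envelope shape.
#'
#' @param rate_envelope_hz Non-negative instantaneous firing-rate series
#'   (spikes/s, summed over units).
#' @param rate_hz Sampling rate of the envelope and output (Hz).
#' @param seed Seed for spike placement and noise.
#' @param noise_sd Electrode noise SD (same units as the waveform, whose
#'   peak is 1).
#' @return Voltage-like numeric trace with attributes `rate_hz`,
#'   `spike_times_s`.
#' @export
make_nerve_trace <- function(rate_envelope_hz, rate_hz = 10000, seed = 1,
                             noise_sd = 0.05) {
  env <- as.numeric(rate_envelope_hz)
  if (any(env < 0)) stop("rate envelope must be non-negative")
  n <- length(env)
  set.seed(seed)
  p <- pmin(env / rate_hz, 1)
  spikes <- which(runif(n) < p)
  x <- numeric(n)
  # biphasic waveform: ~1 ms, peak amplitude 1
  wt <- seq(0, 0.002, by = 1 / rate_hz)
  wav <- sin(2 * pi * wt / 0.002) * exp(-wt / 0.001)
  wav <- wav / max(abs(wav))
  for (s in spikes) {
    j <- s:min(s + length(wav) - 1, n)
    x[j] <- x[j] + wav[seq_along(j)]
  }
  x <- x + rnorm(n, 0, noise_sd)
  structure(x, rate_hz = rate_hz, spike_times_s = (spikes - 1) / rate_hz)
}
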