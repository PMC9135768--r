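#' 20 Hz low-pass filter for angular traces
#'
#' Standard pre-processing of eye/tail position traces: 4th-order
#' zero-phase Butterworth low-pass at 20 Hz (applied forward and backward,
#' so passband components keep their phase).
#'
#' @param trace Numeric angular series (degrees).
#' @param rate_hz Sampling rate; must exceed 40 Hz.
#' @param cutoff_hz Cut-off frequency (Hz).
#' @return Filtered numeric vector.
#' @export
lowpass_20 <- function(trace, rate_hz, cutoff_hz = 20) {
  if (rate_hz <= 2 * cutoff_hz) stop("rate must exceed twice the cut-off")
  bf <- signal::butter(4, cutoff_hz / (rate_hz / 2))
  as.numeric(signal::filtfilt(bf, as.numeric(trace)))
}

#' Segment swim cycles from a tail trace
#'
#' A swim cycle starts at each hysteresis-qualified departure of the
#' (low-pass filtered) tail angle from the null position (the longitudinal
#' head/body axis): the trace must first return below `-hysteresis_deg`
#' and then cross above `+hysteresis_deg` (Schmitt trigger), giving one
#' onset per full oscillation.  Quiescent traces yield an empty table.
#'
#' @param tail Low-pass-filtered tail angle trace (degrees).
#' @param rate_hz Sampling rate (Hz).
#' @param hysteresis_deg Hysteresis half-band (degrees).
#' @return Data frame of class `swim_cycle_table` with `onset_s`, `end_s`
#'   and `instant_freq_hz` per cycle (last cycle closed at the trace end).
#' @export
segment_swim_cycles <- function(tail, rate_hz, hysteresis_deg = 1) {
  x <- as.numeric(tail)
  n <- length(x)
  state <- 0L  # 0 unknown, 1 high, -1 low
  onsets <- integer(0)
  for (i in seq_len(n)) {
    if (x[i] > hysteresis_deg) {
      if (state != 1L) {
        if (state == -1L || (state == 0L && length(onsets) == 0L))
          onsets <- c(onsets, i)
        state <- 1L
      }
    } else if (x[i] < -hysteresis_deg) {
      state <- -1L
    }
  }
  if (length(onsets) < 1)
    return(structure(data.frame(onset_s = numeric(0), end_s = numeric(0),
                                instant_freq_hz = numeric(0)),
                     class = c("swim_cycle_table", "data.frame"),
                     rate_hz = rate_hz))
  onset_s <- (onsets - 1) / rate_hz
  end_s <- c(onset_s[-1], (n - 1) / rate_hz)
  freq <- 1 / diff(c(onset_s, (n - 1) / rate_hz))
  # the final (open) cycle inherits the preceding instantaneous frequency
  if (length(onset_s) > 1) freq[length(freq)] <- freq[length(freq) - 1]
  structure(data.frame(onset_s = onset_s, end_s = end_s,
                       instant_freq_hz = freq),
            class = c("swim_cycle_table", "data.frame"), rate_hz = rate_hz)
}

cycle_indices <- function(cycles, rate_hz, n) {
  lapply(seq_len(nrow(cycles)), function(k) {
    i0 <- round(cycles$onset_s[k] * rate_hz) + 1
    i1 <- min(round(cycles$end_s[k] * rate_hz) + 1, n)
    if (i1 <= i0) return(integer(0))
    i0:i1
  })
}

#' Per-cycle peak-to-peak amplitudes and mean eye position
#'
#' Computes, for each segmented swim cycle, the maximal angular excursion
#' (peak-to-peak amplitude) of tail and eye and the cycle-mean eye
#' position.  When `remove_slow` is set, a previously extracted slow
#' eye-position component is subtracted before the eye amplitude is
#' measured, so vestibular eccentricity drift does not leak into the
#' per-cycle oscillation magnitude.
#'
#' @param eye,tail Angle traces (degrees) on a shared time base.
#' @param cycles A [segment_swim_cycles()] table.
#' @param rate_hz Sampling rate (Hz).
#' @param remove_slow Optional slow eye component (same length as `eye`)
#'   subtracted before the eye peak-to-peak measurement.
#' @return The cycle table extended with `tail_p2p_deg`, `eye_p2p_deg`,
#'   `eye_mean_deg`.
#' @export
per_cycle_amplitudes <- function(eye, tail, cycles, rate_hz,
                                 remove_slow = NULL) {
  eye <- as.numeric(eye); tail <- as.numeric(tail)
  if (length(eye) != length(tail)) stop("eye and tail must share a time base")
  if (nrow(cycles) && max(cycles$end_s) > (length(tail) - 1) / rate_hz + 1e-9)
    stop("cycle outside trace span")
  eye_fast <- if (is.null(remove_slow)) eye else eye - as.numeric(remove_slow)
  idx <- cycle_indices(cycles, rate_hz, length(tail))
  cycles$tail_p2p_deg <- vapply(idx, function(i)
    if (length(i)) diff(range(tail[i])) else NA_real_, numeric(1))
  cycles$eye_p2p_deg <- vapply(idx, function(i)
    if (length(i)) diff(range(eye_fast[i])) else NA_real_, numeric(1))
  cycles$eye_mean_deg <- vapply(idx, function(i)
    if (length(i)) mean(eye[i]) else NA_real_, numeric(1))
  cycles
}

#' Gain and phase of spino-ocular coupling
#'
#' Gain is the per-cycle ratio of eye to tail peak-to-peak amplitude
#' (cycles with vanishing tail amplitude are dropped).  The phase of the
#' eye response relative to the rostral tail deflection is measured from
#' the cross-correlation peak between the compensatory eye signal
#' (`eye_sign * eye`, default `-1`: eyes counter-rotate relative to the
#' tail) and the tail, searched within one swim cycle; a positive phase is
#' a lag of the eye re the tail, in degrees of the swim cycle.
#'
#' @param table Output of [per_cycle_amplitudes()] (>= 5 cycles).
#' @param eye,tail Traces used to build `table`.
#' @param rate_hz Sampling rate.
#' @param eye_sign Sign mapping eye angles onto the compensatory direction.
#' @return List with `gain_per_cycle`, `gain` (mean), `phase_deg`,
#'   `n_cycles`.
#' @export
spino_ocular_gain_phase <- function(table, eye, tail, rate_hz,
                                    eye_sign = -1) {
  if (nrow(table) < 5) stop("need at least 5 swim cycles")
  ok <- table$tail_p2p_deg > 1e-6
  g <- table$eye_p2p_deg[ok] / table$tail_p2p_deg[ok]
  f_swim <- mean(table$instant_freq_hz, na.rm = TRUE)
  half_cycle <- round(rate_hz / f_swim / 2)
  e <- detrend_linear(eye_sign * as.numeric(eye))
  t2 <- detrend_linear(as.numeric(tail))
  cc <- stats::ccf(e, t2, lag.max = half_cycle, plot = FALSE)
  # positive lag: eye follows tail
  lag <- cc$lag[which.max(cc$acf)]
  phase <- 360 * f_swim * lag / rate_hz
  list(gain_per_cycle = g, gain = mean(g), phase_deg = phase,
       n_cycles = sum(ok), swim_freq_hz = f_swim)
}

#' Least-squares sinusoid fit of a reflex response
#'
#' Fits response and stimulus with sine/cosine regressors at the stimulus
#' frequency.  Gain is the ratio of fitted amplitudes; phase is the angle
#' of the response relative to the stimulus in the compensatory convention
#' (a response identical to the recorded stimulus trace has phase 0;
#' positive phase = response leads the stimulus).
#'
#' @param response,stimulus Angle traces (degrees) on a shared time base
#'   spanning at least 4 stimulus cycles.
#' @param rate_hz Sampling rate (Hz).
#' @param freq_hz Stimulus frequency (Hz).
#' @return List of class `response_fit`: `gain`, `phase_deg`,
#'   `freq_hz`, fitted amplitudes.
#' @export
sinusoid_response_fit <- function(response, stimulus, rate_hz, freq_hz) {
  r <- as.numeric(response); s <- as.numeric(stimulus)
  if (length(r) != length(s)) stop("traces must share a time base")
  n <- length(r)
  if ((n - 1) / rate_hz < 4 / freq_hz)
    stop("need at least 4 stimulus cycles")
  tt <- (seq_len(n) - 1) / rate_hz
  X <- cbind(1, sin(2 * pi * freq_hz * tt), cos(2 * pi * freq_hz * tt))
  cr <- stats::lm.fit(X, r)$coefficients
  cs <- stats::lm.fit(X, s)$coefficients
  amp_r <- sqrt(cr[2]^2 + cr[3]^2)
  amp_s <- sqrt(cs[2]^2 + cs[3]^2)
  if (amp_s < 1e-9) stop("stimulus amplitude is zero")
  ph_r <- atan2(cr[3], cr[2])
  ph_s <- atan2(cs[3], cs[2])
  phase <- wrap_deg((ph_r - ph_s) * 180 / pi)
  structure(list(gain = unname(amp_r / amp_s), phase_deg = unname(phase),
                 freq_hz = freq_hz, response_amp = unname(amp_r),
                 stimulus_amp = unname(amp_s)),
            class = "response_fit")
}

wrap_deg <- function(x) {
  y <- (x + 180) %% 360 - 180
  ifelse(y == -180, 180, y)
}

#' @export
print.response_fit <- function(x, ...) {
  cat(sprintf("Sinusoid fit at %g Hz: gain %.3f, phase %+.1f deg\n",
              x$freq_hz, x$gain, x$phase_deg))
  invisible(x)
}

#' Slow eye-position (eccentricity) component
#'
#' The head-motion-evoked eye-position component during concurrent fictive
#' swimming: per-swim-cycle mean eye positions are interpolated (monotone
#' cubic) onto the full time base, revealing the slow medio-lateral
#' eccentricity carrier that the fast swim-cycle oscillation would mask.
#'
#' @param eye Eye angle trace (degrees).
#' @param cycles Cycle table with `eye_mean_deg` (from
#'   [per_cycle_amplitudes()]); at least 2 cycles.
#' @param rate_hz Sampling rate (Hz).
#' @return Numeric vector (same length as `eye`) of the slow component.
#' @export
eccentricity_trace <- function(eye, cycles, rate_hz) {
  if (nrow(cycles) < 2) stop("need at least 2 cycles for interpolation")
  mid <- (cycles$onset_s + cycles$end_s) / 2
  val <- cycles$eye_mean_deg
  ok <- !is.na(val)
  if (sum(ok) < 2) stop("need at least 2 cycles with defined mean position")
  f <- splinefun(mid[ok], val[ok], method = "monoH.FC")
  tt <- (seq_along(eye) - 1) / rate_hz
  y <- f(tt)
  # clamp the extrapolated ends to the boundary cycle means
  y[tt < min(mid[ok])] <- val[ok][1]
  y[tt > max(mid[ok])] <- val[ok][sum(ok)]
  y
}

#' Modulation of eye motion magnitude and eccentricity
#'
#' Quantifies the vestibular modulation of swim-related eye movements over
#' a window of at least four stimulus cycles.  `delta_magnitude_deg` is
#' the peak-to-peak range of the stimulus-locked variation of the
#' per-swim-cycle eye amplitude: a sinusoid at the vestibular frequency is
#' fitted to the per-cycle amplitude series and its full swing reported
#' (twice the fitted amplitude), which keeps the estimate unbiased by
#' frame noise; the raw max - min range is kept as `magnitude_range_deg`.
#' `delta_eccentricity_deg` is the range of the slow eye-position
#' component.  Swim cycles overlapping the episode on/offset ramps are
#' excluded (`edge_trim_s`).
#'
#' @param table Cycle table with `eye_p2p_deg`.
#' @param slow Slow component from [eccentricity_trace()].
#' @param vest_freq_hz Vestibular stimulus frequency (Hz).
#' @param duration_s Length of the analyzed window (s).
#' @param rate_hz Sampling rate of `slow`; taken from
#'   `attr(table, "rate_hz")` when missing.
#' @param edge_trim_s Episode edge to exclude at each end (s).
#' @return List of class `modulation_metrics`.
#' @export
modulation_metrics <- function(table, slow, vest_freq_hz, duration_s,
                               rate_hz = NULL, edge_trim_s = 0.3) {
  n_cycles <- floor(duration_s * vest_freq_hz)
  if (n_cycles < 4)
    stop("need at least 4 vestibular stimulus cycles (got ", n_cycles, ")")
  rate_hz <- rate_hz %||% attr(table, "rate_hz")
  keep <- !is.na(table$eye_p2p_deg) &
    table$onset_s >= edge_trim_s & table$end_s <= duration_s - edge_trim_s
  if (sum(keep) < 4) stop("fewer than 4 usable swim cycles")
  amp <- table$eye_p2p_deg[keep]
  mid <- (table$onset_s[keep] + table$end_s[keep]) / 2
  X <- cbind(1, sin(2 * pi * vest_freq_hz * mid), cos(2 * pi * vest_freq_hz * mid))
  cf <- stats::lm.fit(X, amp)$coefficients
  delta_mag <- 2 * sqrt(cf[2]^2 + cf[3]^2)
  slow_v <- as.numeric(slow)
  if (!is.null(rate_hz)) {
    tt <- (seq_along(slow_v) - 1) / rate_hz
    slow_v <- slow_v[tt >= edge_trim_s & tt <= duration_s - edge_trim_s]
  }
  structure(list(delta_magnitude_deg = unname(delta_mag),
                 magnitude_range_deg = diff(range(amp)),
                 delta_eccentricity_deg = diff(range(slow_v)),
                 n_vest_cycles = n_cycles, n_swim_cycles = sum(keep)),
            class = "modulation_metrics")
}

#' @export
print.modulation_metrics <- function(x, ...) {
  cat(sprintf("Delta magnitude %.2f deg, delta eccentricity %.2f deg (%d vestibular cycles)\n",
              x$delta_magnitude_deg, x$delta_eccentricity_deg, x$n_vest_cycles))
  invisible(x)
}

#' Screen a trace for stimulus-unrelated positional drift
#'
#' Flags traces with obvious slow positional deviations unrelated to the
#' stimulus: the linear slope of the low-frequency trend (below a quarter
#' of the stimulus frequency) and the fraction of spectral power in that
#' sub-band are compared against configurable thresholds.
#'
#' @param trace Angle trace (degrees).
#' @param rate_hz Sampling rate (Hz).
#' @param stim_freq_hz Stimulus frequency (Hz); the trace must span at
#'   least 4 cycles.
#' @param slope_thresh_deg_s Maximal tolerated trend slope (deg/s).
#' @param power_ratio_thresh Maximal tolerated sub-band power fraction.
#' @return List: `pass`, `slope_deg_s`, `power_ratio`.
#' @export
drift_screen <- function(trace, rate_hz, stim_freq_hz,
                         slope_thresh_deg_s = 2, power_ratio_thresh = 0.5) {
  x <- as.numeric(trace)
  n <- length(x)
  if ((n - 1) / rate_hz < 4 / stim_freq_hz)
    stop("trace must span at least 4 stimulus cycles")
  tt <- (seq_len(n) - 1) / rate_hz
  slope <- unname(stats::lm.fit(cbind(1, tt), x)$coefficients[2])
  xc <- x - mean(x)
  sp <- Mod(fft(xc))[2:(n %/% 2)]^2
  fr <- (1:(n %/% 2 - 1)) * rate_hz / n
  lf <- fr <= stim_freq_hz / 4
  ratio <- if (any(lf)) sum(sp[lf]) / sum(sp) else 0
  list(pass = abs(slope) <= slope_thresh_deg_s & ratio <= power_ratio_thresh,
       slope_deg_s = slope, power_ratio = ratio)
}
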