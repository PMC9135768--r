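#' Rectify and integrate a discharge trace
#'
#' Emulates the standard treatment of nerve and motoneuron recordings: the
#' trace is rectified (absolute value) and smoothed with a boxcar moving
#' average of the given width, applied one or more times.  Nerve recordings
#' use 25 ms / one iteration; simulated motoneuron output uses 15 ms / two
#' iterations.  Edges are reflect-padded so short episodes carry no onset
#' artifact, and a constant input passes through unchanged.
#'
#' @param trace Numeric series (voltage or angle).
#' @param rate_hz Sampling rate (Hz).
#' @param window_ms Moving-average window width (ms).
#' @param iterations Number of smoothing passes (>= 1).
#' @return Object of class `envelope`: non-negative numeric vector with
#'   attributes `rate_hz`, `window_ms`, `iterations`.
#' @export
rectify_integrate <- function(trace, rate_hz, window_ms = 25, iterations = 1) {
  stopifnot(iterations >= 1, window_ms > 0, rate_hz > 0)
  w <- max(1L, as.integer(round(window_ms * rate_hz / 1000)))
  if (w > length(trace)) stop("window longer than trace")
  x <- abs(trace)
  kern <- rep(1 / w, w)
  for (k in seq_len(iterations)) x <- boxcar_reflect(x, kern)
  structure(x, class = "envelope", rate_hz = rate_hz,
            window_ms = window_ms, iterations = iterations)
}

boxcar_reflect <- function(x, kern) {
  w <- length(kern)
  pad <- w  # enough for centered kernel
  xp <- c(rev(x[seq_len(min(pad, length(x)))]), x,
          rev(x[seq.int(length(x) - min(pad, length(x)) + 1, length(x))]))
  y <- stats::filter(xp, kern, sides = 2)
  out <- as.numeric(y[(pad + 1):(pad + length(x))])
  # a centered even-width filter can leave NA at the very edge of the pad
  if (anyNA(out)) out[is.na(out)] <- x[is.na(out)]
  out
}

#' Detect burst peaks in an integrated envelope
#'
#' Marks one event per supra-threshold local maximum of the envelope,
#' enforcing a minimal separation (taller peaks win).  The default
#' threshold is mean + 1 SD of the envelope.
#'
#' @param env An [rectify_integrate()] envelope (or numeric vector with a
#'   `rate_hz` attribute / explicit `rate_hz`).
#' @param threshold Absolute threshold; overrides the rule when given.
#' @param threshold_sd Threshold rule: mean + `threshold_sd` * SD.
#' @param min_separation_ms Minimal peak separation (ms).
#' @param rate_hz Sampling rate, taken from `env` when absent.
#' @return Event times (s), possibly empty.
#' @export
detect_burst_peaks <- function(env, threshold = NULL, threshold_sd = 1,
                               min_separation_ms = 20, rate_hz = NULL) {
  rate_hz <- rate_hz %||% attr(env, "rate_hz")
  if (is.null(rate_hz)) stop("rate_hz needed")
  x <- as.numeric(env)
  if (!length(x)) stop("empty envelope")
  thr <- threshold %||% (mean(x) + threshold_sd * sd(x))
  n <- length(x)
  if (n < 3) return(numeric(0))
  is_max <- c(FALSE, x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n], FALSE)
  idx <- which(is_max & x > thr)
  if (!length(idx)) return(numeric(0))
  # enforce separation, keeping taller peaks
  ord <- idx[order(x[idx], decreasing = TRUE)]
  min_gap <- min_separation_ms * rate_hz / 1000
  keep <- logical(0)
  kept <- integer(0)
  for (i in ord) {
    if (!length(kept) || all(abs(kept - i) >= min_gap)) kept <- c(kept, i)
  }
  sort(kept - 1) / rate_hz
}

#' Per-burst amplitude and baseline metrics
#'
#' For each detected burst peak, the baseline is the mean envelope value
#' over the two flanking inter-burst windows (the central third of each
#' inter-event interval); the burst amplitude is peak minus baseline.  A
#' single event without flanking troughs falls back to the global minimum
#' as baseline (recorded in the `baseline_rule` attribute).
#'
#' @param env Envelope from [rectify_integrate()].
#' @param events Event times (s) from [detect_burst_peaks()].
#' @return Data frame of class `burst_table`: `onset_s`, `peak_time_s`,
#'   `peak_value`, `baseline`, `amplitude`.
#' @export
burst_metrics <- function(env, events) {
  rate <- attr(env, "rate_hz")
  x <- as.numeric(env)
  n <- length(x)
  if (!length(events))
    return(structure(data.frame(onset_s = numeric(0), peak_time_s = numeric(0),
                                peak_value = numeric(0), baseline = numeric(0),
                                amplitude = numeric(0)),
                     class = c("burst_table", "data.frame")))
  pk_idx <- pmin(pmax(round(events * rate) + 1, 1), n)
  rule <- "flanking inter-burst mean"
  k <- length(events)
  inter_mean <- function(i1, i2) {      # mean over central third of [i1, i2]
    if (i2 <= i1) return(NA_real_)
    span <- i2 - i1
    lo <- i1 + floor(span / 3); hi <- i2 - floor(span / 3)
    mean(x[max(1, lo):min(n, hi)])
  }
  bounds <- c(1, pk_idx, n)
  baseline <- numeric(k)
  onset <- numeric(k)
  if (k == 1) {
    baseline[1] <- min(x)
    rule <- "global minimum (single event)"
  } else {
    for (j in seq_len(k)) {
      left <- inter_mean(bounds[j], pk_idx[j])
      right <- inter_mean(pk_idx[j], bounds[j + 2])
      baseline[j] <- mean(c(left, right), na.rm = TRUE)
    }
  }
  # onset: last crossing of the midline between baseline and peak before the peak
  for (j in seq_len(k)) {
    half <- baseline[j] + 0.5 * (x[pk_idx[j]] - baseline[j])
    lo <- if (j == 1) 1 else pk_idx[j - 1]
    seg <- x[lo:pk_idx[j]]
    below <- which(seg < half)
    onset[j] <- (lo + (if (length(below)) max(below) else 1) - 2) / rate
  }
  structure(data.frame(onset_s = onset, peak_time_s = events,
                       peak_value = x[pk_idx], baseline = baseline,
                       amplitude = pmax(x[pk_idx] - baseline, 0)),
            class = c("burst_table", "data.frame"),
            baseline_rule = rule)
}

#' Mean and instantaneous rhythm frequency from event times
#'
#' @param events Event times (s), at least 2.
#' @return List with `mean_hz` (mean of the instantaneous frequencies) and
#'   `instantaneous_hz` (1 / inter-event interval).
#' @export
rhythm_frequency <- function(events) {
  if (length(events) < 2) stop("at least 2 events needed for a frequency")
  inst <- 1 / diff(sort(events))
  list(mean_hz = mean(inst), instantaneous_hz = inst)
}

#' Down-sample a trace by interpolation
#'
#' Interpolation-based resampling to a lower rate (the procedure used to
#' bring 10 kHz nerve recordings to the 500 Hz video rate before spectral
#' analysis).  An anti-alias low-pass (8th-order Butterworth at 0.45 of the
#' target rate) is applied first unless disabled.
#'
#' @param trace Numeric series.
#' @param rate_hz Original sampling rate.
#' @param target_hz Target rate (<= `rate_hz`).
#' @param anti_alias Apply the protective low-pass first.
#' @return Resampled numeric vector with attribute `rate_hz`.
#' @export
downsample <- function(trace, rate_hz, target_hz = 500, anti_alias = TRUE) {
  if (target_hz > rate_hz) stop("upsampling not supported (target > rate)")
  x <- as.numeric(trace)
  if (target_hz == rate_hz) return(structure(x, rate_hz = rate_hz))
  if (anti_alias && rate_hz > 2.5 * target_hz) {
    bf <- signal::butter(8, 0.9 * target_hz / rate_hz)  # = 0.45*target/(rate/2)
    x <- as.numeric(signal::filtfilt(bf, x))
  }
  t_old <- (seq_along(x) - 1) / rate_hz
  t_new <- seq(0, t_old[length(t_old)], by = 1 / target_hz)
  structure(approx(t_old, x, xout = t_new)$y, rate_hz = target_hz)
}
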