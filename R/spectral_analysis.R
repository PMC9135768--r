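#' Principal oscillation frequencies by FFT
#'
#' First stage of the spectral pipeline: the linearly detrended trace is
#' Fourier-transformed and the local maxima of the amplitude spectrum within
#' the band of interest (0.5-16 Hz by default) are returned, ranked by
#' amplitude.  Candidates must exceed a noise-floor criterion (a multiple of
#' the median in-band amplitude), so white noise yields no candidates.
#'
#' @param trace Uniformly sampled numeric series.
#' @param rate_hz Sampling rate (Hz).
#' @param fmin,fmax Frequency band (Hz).
#' @param floor_factor Candidate amplitude must exceed `floor_factor` times
#'   the median in-band amplitude.
#' @return Data frame `freq_hz`, `amplitude`, ranked by amplitude.
#' @export
principal_frequencies_fft <- function(trace, rate_hz, fmin = 0.5, fmax = 16,
                                      floor_factor = 4) {
  x <- as.numeric(trace)
  n <- length(x)
  if (n < 2 * rate_hz / fmin)
    stop("trace shorter than two periods of fmin")
  x <- detrend_linear(x)
  sp <- Mod(fft(x))[1:(n %/% 2)] / n
  fr <- (seq_len(n %/% 2) - 1) * rate_hz / n
  band <- fr >= fmin & fr <= fmax
  fb <- fr[band]; ab <- sp[band]
  m <- length(ab)
  if (m < 3) return(data.frame(freq_hz = numeric(0), amplitude = numeric(0)))
  is_max <- c(FALSE, ab[2:(m - 1)] > ab[1:(m - 2)] & ab[2:(m - 1)] >= ab[3:m], FALSE)
  thr <- floor_factor * median(ab)
  idx <- which(is_max & ab > thr)
  out <- data.frame(freq_hz = fb[idx], amplitude = ab[idx])
  out[order(out$amplitude, decreasing = TRUE), , drop = FALSE]
}

detrend_linear <- function(x) {
  t <- seq_along(x)
  stats::residuals(stats::lm.fit(cbind(1, t), x))
}

#' Morlet continuous wavelet spectrogram
#'
#' Time-frequency power of a motor trace by continuous Morlet wavelet
#' transform (center frequency parameter `omega0 = 6`, scale resolution
#' 1/20 octave), over 0.5-16 Hz by default.  Computed by FFT convolution
#' with zero padding; the cone of influence (e-folding time of edge
#' effects) is returned and excluded from significance decisions.
#'
#' @param trace Numeric series (detrended internally).
#' @param rate_hz Sampling rate; must be at least `2 * fmax`.
#' @param fmin,fmax Frequency band (Hz).
#' @param dj Scale resolution in octaves (default 1/20).
#' @param omega0 Morlet center frequency parameter.
#' @return Object of class `spectrogram`: `freq_hz` (increasing), `time_s`,
#'   `power` (frequency x time), `coi_s` (per time point, the shortest
#'   period free of edge effects is `1/coi_freq`), and bookkeeping needed
#'   for surrogate significance.
#' @export
cwt_spectrogram <- function(trace, rate_hz, fmin = 0.5, fmax = 16,
                            dj = 1 / 20, omega0 = 6) {
  if (fmin >= fmax) stop("fmin must be below fmax")
  if (rate_hz < 2 * fmax)
    stop("sampling rate below 2*fmax; downsample() the trace first or lower fmax")
  x <- detrend_linear(as.numeric(trace))
  n <- length(x)
  dt <- 1 / rate_hz
  fourier_factor <- 4 * pi / (omega0 + sqrt(2 + omega0^2))
  freqs <- 2^seq(log2(fmin), log2(fmax), by = dj)
  scales <- 1 / (fourier_factor * freqs)
  npad <- 2^ceiling(log2(n))
  xf <- fft(c(x, rep(0, npad - n)))
  w <- 2 * pi * c(0:(npad %/% 2), -((npad - npad %/% 2 - 1):1)) / (npad * dt)
  power <- matrix(0, length(freqs), n)
  for (j in seq_along(scales)) {
    s <- scales[j]
    psi <- rep(0, npad)
    pos <- w > 0
    psi[pos] <- pi^(-0.25) * sqrt(2 * pi * s / dt) * exp(-(s * w[pos] - omega0)^2 / 2)
    wt <- fft(xf * psi, inverse = TRUE)[1:n] / npad
    power[j, ] <- Mod(wt)^2
  }
  t_s <- (seq_len(n) - 1) * dt
  # cone of influence: e-folding time sqrt(2)*scale from each edge
  dist_edge <- pmin(t_s, t_s[n] - t_s)
  coi_scale <- dist_edge / sqrt(2)             # max valid scale at each t
  coi_freq <- 1 / (fourier_factor * pmax(coi_scale, 1e-12))
  structure(list(freq_hz = freqs, time_s = t_s, power = power,
                 coi_freq_hz = coi_freq, rate_hz = rate_hz,
                 sd_x = sd(x), n = n, dj = dj, omega0 = omega0,
                 fmin = fmin, fmax = fmax),
            class = "spectrogram")
}

#' @export
print.spectrogram <- function(x, ...) {
  cat("Wavelet spectrogram:", length(x$freq_hz), "frequencies",
      sprintf("(%.2g-%.2g Hz),", min(x$freq_hz), max(x$freq_hz)),
      length(x$time_s), "time points\n")
  invisible(x)
}

coi_valid <- function(spec) {
  outer(spec$freq_hz, spec$coi_freq_hz, ">=")
}

#' Surrogate-based significance mask for a spectrogram
#'
#' Compares the wavelet power pointwise against the `(1 - alpha)` quantile
#' of seeded white-noise surrogates matched in length and variance.  The
#' null distribution is pooled over time within each frequency row (wavelet
#' power of white noise is stationary), which keeps the per-cell
#' false-positive rate calibrated at `alpha`.  Cells inside the cone of
#' influence are never marked significant.  Thresholds for the
#' time-averaged power (used by [periodogram()] peak marking) are derived
#' from the same surrogates.
#'
#' @param spec A [cwt_spectrogram()].
#' @param n_surrogates Number of white-noise surrogates (>= 30).
#' @param alpha Significance level in (0, 1).
#' @param seed Seed for the surrogate noise.
#' @return The spectrogram with `$mask` (logical matrix), `$cell_thresh`
#'   and `$mean_thresh` (per-frequency thresholds) added.
#' @export
significance_mask <- function(spec, n_surrogates = 100, alpha = 0.05,
                              seed = 1) {
  stopifnot(inherits(spec, "spectrogram"))
  if (n_surrogates < 30) stop("use at least 30 surrogates")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  set.seed(seed)
  nf <- length(spec$freq_hz)
  valid <- coi_valid(spec)
  pooled <- vector("list", nf)
  means <- matrix(NA_real_, n_surrogates, nf)
  for (k in seq_len(n_surrogates)) {
    xs <- rnorm(spec$n, 0, spec$sd_x)
    ss <- cwt_spectrogram(xs, spec$rate_hz, spec$fmin, spec$fmax,
                          spec$dj, spec$omega0)
    for (j in seq_len(nf)) {
      v <- ss$power[j, valid[j, ]]
      if (k == 1) pooled[[j]] <- v else
        if (k <= 30) pooled[[j]] <- c(pooled[[j]], v)  # cell null: pool 30 surrogates
      means[k, j] <- mean(v)
    }
  }
  spec$cell_thresh <- vapply(pooled, quantile, numeric(1), probs = 1 - alpha,
                             names = FALSE)
  spec$mean_thresh <- apply(means, 2, quantile, probs = 1 - alpha, names = FALSE)
  spec$mask <- sweep(spec$power, 1, spec$cell_thresh, ">") & valid
  spec$alpha <- alpha
  spec
}

#' Time-averaged periodogram of a spectrogram
#'
#' Averages the wavelet power of each frequency over time (outside the cone
#' of influence), and, when the spectrogram carries surrogate thresholds
#' from [significance_mask()], marks the significant peaks: local maxima of
#' the mean power exceeding the surrogate mean-power quantile.
#'
#' @param spec A [cwt_spectrogram()], ideally after [significance_mask()].
#' @return Object of class `periodogram`: data frame `freq_hz`,
#'   `mean_power`, `significant`; peaks in `attr(, "peaks")`.
#' @export
periodogram <- function(spec) {
  stopifnot(inherits(spec, "spectrogram"))
  valid <- coi_valid(spec)
  mp <- vapply(seq_along(spec$freq_hz), function(j) {
    v <- spec$power[j, valid[j, ]]
    if (!length(v)) NA_real_ else mean(v)
  }, numeric(1))
  out <- data.frame(freq_hz = spec$freq_hz, mean_power = mp)
  nf <- nrow(out)
  is_max <- rep(FALSE, nf)
  ok <- !is.na(mp)
  is_max[2:(nf - 1)] <- ok[2:(nf - 1)] &
    mp[2:(nf - 1)] > c(mp[1:(nf - 2)]) & mp[2:(nf - 1)] >= c(mp[3:nf])
  # include band edges as candidate maxima
  is_max[1] <- ok[1] && ok[2] && mp[1] > mp[2]
  is_max[nf] <- ok[nf] && ok[nf - 1] && mp[nf] > mp[nf - 1]
  if (!is.null(spec$mean_thresh)) {
    out$significant <- is_max & ok & mp > spec$mean_thresh
  } else {
    out$significant <- is_max
  }
  peaks <- out[out$significant, , drop = FALSE]
  peaks <- peaks[order(peaks$mean_power, decreasing = TRUE), , drop = FALSE]
  structure(out, class = c("periodogram", "data.frame"), peaks = peaks)
}

#' @export
print.periodogram <- function(x, ...) {
  pk <- attr(x, "peaks")
  cat("Periodogram over", nrow(x), "frequencies;",
      nrow(pk), "significant peak(s)")
  if (nrow(pk)) cat(" at", paste(signif(pk$freq_hz, 3), collapse = ", "), "Hz")
  cat("\n")
  invisible(x)
}

#' Dominant frequency of a periodogram
#'
#' @param pgram A [periodogram()].
#' @return Frequency (Hz) of maximal mean power.
#' @export
dominant_frequency <- function(pgram) {
  pgram$freq_hz[which.max(pgram$mean_power)]
}
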