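#' Read / write the standard trace CSV
#'
#' Traces are exchanged as CSV with a `time_s` column and any subset of
#' `left_eye_deg`, `right_eye_deg`, `tail_deg`, `stimulus_deg`.  The
#' sampling rate is inferred from `time_s` and attached as an attribute.
#'
#' @param path CSV file path.
#' @return Data frame with attribute `rate_hz`.
#' @export
read_trace_csv <- function(path) {
  df <- read.csv(path)
  if (!nrow(df)) stop("schema error: empty trace file")
  if (!"time_s" %in% names(df)) stop("schema error: missing column time_s")
  known <- c("time_s", "left_eye_deg", "right_eye_deg", "tail_deg", "stimulus_deg")
  bad <- setdiff(names(df), known)
  if (length(bad))
    stop("schema error: unknown column(s): ", paste(bad, collapse = ", "))
  dt <- diff(df$time_s)
  if (any(dt <= 0) || diff(range(dt)) > 1e-6 * mean(dt) + 1e-12)
    stop("schema error: time_s must be strictly increasing and uniform")
  attr(df, "rate_hz") <- 1 / mean(dt)
  df
}

#' @rdname read_trace_csv
#' @param df Trace data frame (columns as above).
#' @export
write_trace_csv <- function(df, path) {
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Assemble a trace data frame from generator outputs
#'
#' @param tail Output of [make_tail_trace()].
#' @param eyes Output of [make_eye_traces()] (optional).
#' @param stimulus Output of [make_stimulus_trace()] (optional).
#' @return Standard trace data frame with attribute `rate_hz`.
#' @export
trace_frame <- function(tail, eyes = NULL, stimulus = NULL) {
  rate <- attr(tail, "rate_hz")
  df <- data.frame(time_s = (seq_along(tail) - 1) / rate,
                   tail_deg = as.numeric(tail))
  if (!is.null(eyes)) {
    df$left_eye_deg <- as.numeric(eyes$left)
    df$right_eye_deg <- as.numeric(eyes$right)
  }
  if (!is.null(stimulus))
    df$stimulus_deg <- as.numeric(stimulus)[seq_len(nrow(df))]
  attr(df, "rate_hz") <- rate
  df
}

#' End-to-end analysis of an eye/tail/stimulus trace bundle
#'
#' Runs the full pipeline on a standard trace data frame (or CSV path):
#' 20 Hz low-pass, drift screen, swim-cycle segmentation, per-cycle
#' amplitudes, eccentricity extraction, magnitude/eccentricity modulation,
#' spino-ocular gain and phase, and the wavelet spectrogram/periodogram of
#' the left eye with surrogate significance.
#'
#' @param trace Data frame from [read_trace_csv()] / [trace_frame()], or a
#'   CSV path.
#' @param vest_freq_hz Vestibular stimulus frequency (Hz).
#' @param n_surrogates,alpha,seed Spectral significance settings.
#' @param hysteresis_deg Cycle-onset hysteresis (degrees).
#' @param out_dir Optional directory: writes the cycle table CSV, metrics
#'   JSON, periodogram CSV and a run manifest.
#' @return List of class `trace_analysis` with the per-stage results.
#' @export
analyze_trace_pipeline <- function(trace, vest_freq_hz = 1,
                                   n_surrogates = 100, alpha = 0.05,
                                   seed = 1, hysteresis_deg = 1,
                                   out_dir = NULL) {
  t0 <- Sys.time()
  if (is.character(trace)) trace <- read_trace_csv(trace)
  rate <- attr(trace, "rate_hz")
  if (is.null(rate)) stop("trace has no rate_hz attribute; use read_trace_csv()")
  for (col in c("tail_deg", "left_eye_deg"))
    if (!col %in% names(trace)) stop("schema error: missing column ", col)
  dur <- max(trace$time_s)

  eye <- lowpass_20(trace$left_eye_deg, rate)
  tail <- lowpass_20(trace$tail_deg, rate)
  drift <- drift_screen(eye, rate, vest_freq_hz)

  cycles <- segment_swim_cycles(tail, rate, hysteresis_deg)
  cycles <- per_cycle_amplitudes(eye, tail, cycles, rate)
  slow <- eccentricity_trace(eye, cycles, rate)
  cycles <- per_cycle_amplitudes(eye, tail, cycles, rate, remove_slow = slow)
  modulation <- modulation_metrics(cycles, slow, vest_freq_hz, dur, rate)
  gp <- spino_ocular_gain_phase(cycles, eye, tail, rate)

  eye500 <- if (rate > 500) downsample(trace$left_eye_deg, rate, 500) else trace$left_eye_deg
  spec <- cwt_spectrogram(as.numeric(eye500), min(rate, 500))
  spec <- significance_mask(spec, n_surrogates, alpha, seed)
  pgram <- periodogram(spec)

  res <- structure(list(drift = drift, cycles = cycles, slow = slow,
                        modulation = modulation, gain_phase = gp,
                        spectrogram = spec, periodogram = pgram,
                        rate_hz = rate, vest_freq_hz = vest_freq_hz),
                   class = "trace_analysis")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    files <- c(cycles = "cycles.csv", metrics = "metrics.json",
               periodogram = "periodogram.csv")
    write.csv(cycles, file.path(out_dir, files["cycles"]), row.names = FALSE)
    jsonlite::write_json(list(
      drift = drift,
      gain = gp$gain, phase_deg = gp$phase_deg,
      swim_freq_hz = gp$swim_freq_hz,
      delta_magnitude_deg = modulation$delta_magnitude_deg,
      delta_eccentricity_deg = modulation$delta_eccentricity_deg,
      significant_peaks_hz = attr(pgram, "peaks")$freq_hz),
      file.path(out_dir, files["metrics"]), auto_unbox = TRUE, digits = NA)
    write.csv(as.data.frame(pgram), file.path(out_dir, files["periodogram"]),
              row.names = FALSE)
    write_manifest(out_dir, files,
                   settings = list(vest_freq_hz = vest_freq_hz,
                                   n_surrogates = n_surrogates,
                                   alpha = alpha, seed = seed,
                                   hysteresis_deg = hysteresis_deg),
                   t0 = t0)
  }
  res
}

#' @export
print.trace_analysis <- function(x, ...) {
  cat(sprintf("Trace analysis: swim %.2f Hz, gain %.2f, phase %+.1f deg\n",
              x$gain_phase$swim_freq_hz, x$gain_phase$gain, x$gain_phase$phase_deg))
  cat(sprintf("  delta magnitude %.2f deg, delta eccentricity %.2f deg; drift screen: %s\n",
              x$modulation$delta_magnitude_deg,
              x$modulation$delta_eccentricity_deg,
              if (x$drift$pass) "pass" else "FAIL"))
  print(x$periodogram)
  invisible(x)
}

write_manifest <- function(out_dir, files, settings, t0) {
  jsonlite::write_json(list(
    package = "tadgaze",
    version = as.character(utils::packageVersion("tadgaze")),
    settings = settings,
    files = as.list(files),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
}

#' Reproduce the model's current-to-frequency map and gating scan
#'
#' Sweeps the dIN step current with concurrent sinusoidal vestibular drive
#' and tabulates swim frequency, VO spike counts and abducens modulation
#' depths — the model's operating map, with the gate switching off VO
#' signalling above the transition current.
#'
#' @param istim_values Step currents (nA).
#' @param config Model configuration; must contain the calibrated dIN
#'   adaptation parameters.
#' @param vest_freq_hz,vest_amplitude_na Vestibular drive.
#' @param duration_s Simulated time per point (s).
#' @param seed Simulation seed.
#' @param out_dir Optional output directory (map CSV + manifest).
#' @return Data frame as [run_protocol_grid()].
#' @export
reproduce_model_map <- function(istim_values = c(0.11, 0.12, 0.13, 0.14, 0.15,
                                                 0.16, 0.18, 0.2, 0.25, 0.3),
                                config = default_model_config(),
                                vest_freq_hz = 1, vest_amplitude_na = 0.1,
                                duration_s = 5, seed = 1, out_dir = NULL) {
  t0 <- Sys.time()
  din <- config$membrane$dIN
  if (is.null(din$adapt_increment) || is.null(din$adapt_tau))
    stop("model configuration lacks the calibrated dIN adaptation ",
         "parameters; run scripts/calibrate_model.R first")
  net <- build_default_network(config)
  map <- run_protocol_grid(net, istim_values, vest_freq_hz,
                           vest_amplitude_na, duration_s, seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(map, file.path(out_dir, "model_map.csv"), row.names = FALSE)
    write_manifest(out_dir, c(map = "model_map.csv"),
                   settings = list(istim_values = istim_values,
                                   vest_freq_hz = vest_freq_hz,
                                   vest_amplitude_na = vest_amplitude_na,
                                   duration_s = duration_s, seed = seed),
                   t0 = t0)
  }
  map
}

#' Export a simulation to CSV
#'
#' Writes the membrane-potential matrix (time + one column per neuron) and
#' the spike times (neuron, time_s); both round-trip readable.
#'
#' @param sim A `tad_sim` result.
#' @param voltage_path,spikes_path Output CSV paths.
#' @return Invisibly, the two paths.
#' @export
export_sim_csv <- function(sim, voltage_path, spikes_path) {
  v <- data.frame(time_s = sim$time_s, sim$V, check.names = FALSE)
  write.csv(v, voltage_path, row.names = FALSE)
  sp <- do.call(rbind, lapply(names(sim$spikes_s), function(nm) {
    if (!length(sim$spikes_s[[nm]])) return(NULL)
    data.frame(neuron = nm, time_s = sim$spikes_s[[nm]])
  }))
  if (is.null(sp)) sp <- data.frame(neuron = character(0), time_s = numeric(0))
  write.csv(sp, spikes_path, row.names = FALSE)
  invisible(c(voltage_path, spikes_path))
}
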