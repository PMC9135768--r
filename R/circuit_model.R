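#' Sigmoidal gating coefficient for the locomotor gate on VO neurons
#'
#' The strength of the rhythmic inhibitory synapse onto the vestibulo-ocular
#' (VO) neurons is scaled with the intensity of the locomotor drive through a
#' logistic function of the mean dIN injection current (`iCPG`):
#' \deqn{sigmCoeff = sigmAmp \cdot \frac{e^{sigmSteep (iCPG - iTrans)}}
#'   {e^{sigmSteep (iCPG - iTrans)} + 1}}
#' so that VO activity is switched off once the central-pattern-generator
#' drive rises above the transition current `iTrans`.
#'
#' @param icpg Mean current injected into the two dIN neurons (nA).
#' @param gating A [gating_params()] list.
#' @return Dimensionless coefficient in `[0, sigmAmp]`, strictly increasing
#'   in `icpg`.
#' @export
gating_coefficient <- function(icpg, gating = gating_params()) {
  if (!all(is.finite(icpg))) stop("icpg must be finite")
  gating <- validate_gating(gating)
  x <- gating$sigm_steep * (icpg - gating$i_trans)
  gating$sigm_amp * stats::plogis(x)
}

#' Maximal conductance of the gated inhibitory synapse
#'
#' `gGABA_max = num_syn_inh * unitary_ggaba * coeff`: the number of
#' converging inhibitory synapses times the unitary synaptic conductance,
#' scaled by the sigmoidal gating coefficient.
#'
#' @param gating A [gating_params()] list.
#' @param coeff Gating coefficient from [gating_coefficient()].
#' @return Conductance in nS.
#' @export
max_inhibitory_conductance <- function(gating, coeff) {
  gating <- validate_gating(gating)
  if (any(coeff < 0)) stop("coeff must be non-negative")
  if (any(coeff > gating$sigm_amp + 1e-12))
    stop("coeff exceeds sigm_amp")
  gating$num_syn_inh * gating$unitary_ggaba * coeff
}

#' Parameters of the swim-frequency-dependent gate on VO neurons
#'
#' @param i_trans Sigmoid midpoint (nA): mean dIN drive above which the gate
#'   closes VO signalling.
#' @param sigm_amp Sigmoid amplitude (dimensionless).
#' @param sigm_steep Sigmoid steepness (1/nA).
#' @param num_syn_inh Number of converging inhibitory synapses.
#' @param unitary_ggaba Unitary synaptic conductance (nS).
#' @param rate_hz Rate of the rhythmic inhibitory event train (Hz).
#' @param tau1,tau2 Rise and decay time constants of the two-exponential
#'   inhibitory conductance (ms).
#' @param e_rev Reversal potential of the inhibitory synapse (mV).
#' @return A list of class `gating_params`.
#' @export
gating_params <- function(i_trans = 0.16, sigm_amp = 1, sigm_steep = 200,
                          num_syn_inh = 10, unitary_ggaba = 1.5,
                          rate_hz = 10, tau1 = 0.5, tau2 = 100,
                          e_rev = -75) {
  g <- list(i_trans = i_trans, sigm_amp = sigm_amp, sigm_steep = sigm_steep,
            num_syn_inh = num_syn_inh, unitary_ggaba = unitary_ggaba,
            rate_hz = rate_hz, tau1 = tau1, tau2 = tau2, e_rev = e_rev)
  class(g) <- "gating_params"
  validate_gating(g)
}

validate_gating <- function(g) {
  stopifnot(g$sigm_amp >= 0, g$sigm_steep > 0,
            g$tau2 > g$tau1, g$tau1 > 0,
            g$num_syn_inh >= 0, g$num_syn_inh == round(g$num_syn_inh),
            g$unitary_ggaba >= 0, g$rate_hz > 0)
  g
}

neuron_roles <- c("dIN", "cIN", "spMN", "EC", "VO", "VS", "AbdMN")

#' Default model configuration
#'
#' Reads the versioned configuration shipped with the package:
#' membrane templates (`dIN`, `MN`, `vest_spin`), synaptic conductances and
#' kinetics, gate parameters and integration settings.  The rhythm-setting
#' parameters (dIN adaptation, commissural inhibition, recurrent dIN
#' excitation) carry the calibrated values that place the current-to-swim-
#' frequency map on its anchors (0 nA -> no rhythm, 0.13 -> 6 Hz,
#' 0.15 -> 7 Hz, 0.16 -> 8 Hz, 0.3 -> 12 Hz).
#'
#' @param path Optional path to a YAML file overriding the shipped defaults.
#' @return Nested list with sections `membrane`, `synapses`, `gating`,
#'   `integration`.
#' @export
default_model_config <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "default_model.yaml", package = "tadgaze")
  cfg <- yaml::read_yaml(path)
  for (tmpl in c("dIN", "MN", "vest_spin"))
    if (is.null(cfg$membrane[[tmpl]]))
      stop("configuration error: missing membrane template '", tmpl, "'")
  cfg
}

membrane_row <- function(mp) {
  c(C = mp$capacitance, gNa = mp$g_na, gK = mp$g_k, gL = mp$g_leak,
    ENa = mp$e_na, EK = mp$e_k, EL = mp$e_leak,
    z_inc = mp$adapt_increment %||% 0,
    tau_z = mp$adapt_tau %||% 100,
    z2_inc = mp$adapt2_increment %||% 0,
    tau_z2 = mp$adapt2_tau %||% 500,
    bias_pa = mp$bias_pa %||% 0,
    v0 = mp$v_init %||% -65)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build the default 14-neuron bilateral network
#'
#' Constructs the bilateral circuit: on each side a descending excitatory
#' interneuron (dIN) excites the ipsilateral commissural inhibitory
#' interneuron (cIN) and spinal motoneuron (spMN) and itself through
#' recurrent AMPA and NMDA synapses; each cIN inhibits the contralateral
#' dIN, cIN and spMN; each spMN excites the ipsilateral efference-copy
#' neuron (EC) which projects to the contralateral abducens motoneuron
#' (AbdMN); the vestibulo-ocular neuron (VO) excites the contralateral
#' AbdMN; the vestibulo-spinal neuron (VS) excites the ipsilateral spMN and
#' EC.  Each VO additionally receives the rhythmic inhibitory synapse whose
#' maximal conductance is set by the swim-drive-dependent gate.
#'
#' @param config Configuration list from [default_model_config()].
#' @return Object of class `tad_network`: data frame of neurons, data frame
#'   of synapses, gating parameters and the membrane parameter matrix.
#' @export
build_default_network <- function(config = default_model_config()) {
  neurons <- data.frame(
    id = 1:14,
    side = rep(c("L", "R"), each = 7),
    role = rep(neuron_roles, 2),
    template = rep(c("dIN", "MN", "MN", "MN", "vest_spin", "vest_spin", "MN"), 2),
    stringsAsFactors = FALSE
  )
  nid <- function(side, role) neurons$id[neurons$side == side & neurons$role == role]
  other <- c(L = "R", R = "L")

  syn_cfg <- config$synapses
  need <- c("din_cin", "din_spmn", "din_self_ampa", "din_self_nmda",
            "cin_inhibition", "spmn_ec", "ec_abd", "vo_abd", "vs_spmn", "vs_ec")
  missing <- setdiff(need, names(syn_cfg))
  if (length(missing))
    stop("configuration error: missing synapse specs: ", paste(missing, collapse = ", "))

  rows <- list()
  add <- function(src, tgt, spec, nmda = FALSE) {
    rows[[length(rows) + 1]] <<- data.frame(
      src = src, tgt = tgt, e_rev = spec$e_rev, gmax = spec$gmax,
      tau1 = spec$tau1, tau2 = spec$tau2, nmda = as.numeric(nmda))
  }
  for (s in c("L", "R")) {
    o <- other[[s]]
    add(nid(s, "dIN"), nid(s, "cIN"), syn_cfg$din_cin)
    add(nid(s, "dIN"), nid(s, "spMN"), syn_cfg$din_spmn)
    add(nid(s, "dIN"), nid(s, "dIN"), syn_cfg$din_self_ampa)
    add(nid(s, "dIN"), nid(s, "dIN"), syn_cfg$din_self_nmda, nmda = TRUE)
    for (rol in c("cIN", "dIN", "spMN"))
      add(nid(s, "cIN"), nid(o, rol), syn_cfg$cin_inhibition)
    add(nid(s, "spMN"), nid(s, "EC"), syn_cfg$spmn_ec)
    add(nid(s, "EC"), nid(o, "AbdMN"), syn_cfg$ec_abd)
    add(nid(s, "VO"), nid(o, "AbdMN"), syn_cfg$vo_abd)
    add(nid(s, "VS"), nid(s, "spMN"), syn_cfg$vs_spmn)
    add(nid(s, "VS"), nid(s, "EC"), syn_cfg$vs_ec)
  }
  synapses <- do.call(rbind, rows)

  params <- t(vapply(neurons$template, function(tmpl) {
    mp <- config$membrane[[tmpl]]
    if (is.null(mp)) stop("configuration error: missing template ", tmpl)
    membrane_row(mp)
  }, numeric(13)))
  rownames(params) <- paste(neurons$role, neurons$side, sep = "_")

  gating <- do.call(gating_params, config$gating)

  net <- list(neurons = neurons, synapses = synapses, params = params,
              gating = gating, integration = config$integration)
  class(net) <- "tad_network"
  net
}

#' @export
print.tad_network <- function(x, ...) {
  cat("Bilateral spino-ocular network:", nrow(x$neurons), "neurons,",
      nrow(x$synapses), "synapses\n")
  cat("Gate midpoint iTrans =", x$gating$i_trans, "nA\n")
  invisible(x)
}

#' Stimulus protocols
#'
#' `stim_step()` injects a constant current step, `stim_sinusoid()` a
#' continuous sinusoidal current (mimicking horizontal head-rotation-related
#' vestibular signals when targeted at VO/VS neurons).
#'
#' @param target Neuron selector: role name (`"dIN"`, `"VO"`, ...) applied to
#'   both sides, or explicit neuron ids.
#' @param amplitude_na Current amplitude (nA).
#' @param onset_s,duration_s Stimulus window (s).
#' @param lr_offset_ms For bilateral steps: onset delay of the right side
#'   relative to the left (ms); the asymmetric start seeds the alternating
#'   rhythm.
#' @param freq_hz Sinusoid frequency (Hz).
#' @param phase_deg Sinusoid phase (degrees).
#' @return A `tad_stimulus` list.
#' @export
stim_step <- function(target, amplitude_na, onset_s = 0, duration_s = 5,
                      lr_offset_ms = 50) {
  structure(list(kind = "step", target = target, amplitude_na = amplitude_na,
                 onset_s = onset_s, duration_s = duration_s,
                 lr_offset_ms = lr_offset_ms),
            class = "tad_stimulus")
}

#' @rdname stim_step
#' @export
stim_sinusoid <- function(target, amplitude_na, freq_hz, onset_s = 0,
                          duration_s = 5, phase_deg = 0) {
  if (freq_hz <= 0) stop("sinusoid frequency must be > 0")
  structure(list(kind = "sinusoid", target = target,
                 amplitude_na = amplitude_na, freq_hz = freq_hz,
                 onset_s = onset_s, duration_s = duration_s,
                 phase_deg = phase_deg),
            class = "tad_stimulus")
}

resolve_targets <- function(net, target) {
  if (is.numeric(target)) return(as.integer(target))
  ids <- net$neurons$id[net$neurons$role %in% target]
  if (!length(ids)) stop("unknown stimulus target: ", paste(target, collapse = ", "))
  ids
}

stimulus_matrix <- function(net, stimuli) {
  rows <- list()
  for (st in stimuli) {
    ids <- resolve_targets(net, st$target)
    for (id in ids) {
      onset_ms <- st$onset_s * 1000
      if (st$kind == "step" && net$neurons$side[id] == "R")
        onset_ms <- onset_ms + st$lr_offset_ms
      rows[[length(rows) + 1]] <- c(
        target = id,
        type = if (st$kind == "step") 0 else 1,
        amp_pA = st$amplitude_na * 1000,
        onset_ms = onset_ms,
        dur_ms = st$duration_s * 1000,
        freq_hz = st$freq_hz %||% 0,
        phase_deg = st$phase_deg %||% 0)
    }
  }
  if (!length(rows)) return(matrix(numeric(0), ncol = 7))
  do.call(rbind, rows)
}

#' Mean dIN drive (iCPG) of a stimulus set
#'
#' iCPG is the mean value of the step currents injected into the two dINs;
#' it is defined only when both dINs receive a step (0 nA otherwise).
#' @param net A `tad_network`.
#' @param stimuli List of stimuli.
#' @return iCPG in nA.
#' @export
icpg_of <- function(net, stimuli) {
  amps <- numeric(0)
  for (st in stimuli) {
    if (st$kind != "step") next
    ids <- resolve_targets(net, st$target)
    din <- net$neurons$id[net$neurons$role == "dIN"]
    amps <- c(amps, rep(st$amplitude_na, sum(ids %in% din)))
  }
  if (length(amps) < 2) return(0)
  mean(amps)
}

#' Simulate the bilateral network
#'
#' Integrates the Hodgkin-Huxley network with a fixed step.  The rhythmic
#' inhibitory event train onto each VO neuron runs at the configured rate
#' (10 Hz) for the whole simulation; its maximal conductance is
#' `gGABA_max = num_syn_inh * unitary_ggaba * sigmCoeff(iCPG)`, so VO
#' signalling is suppressed when the locomotor drive exceeds `iTrans` while
#' VS discharge is never touched by the gate.
#'
#' @param net Network from [build_default_network()].
#' @param stimuli List of [stim_step()] / [stim_sinusoid()] protocols.
#' @param duration_s Simulated time (s).
#' @param step_ms Integration step (ms).
#' @param seed Seed for the optional jitter of the inhibitory event train
#'   (the default train is strictly periodic, so the simulation is fully
#'   deterministic).
#' @param jitter_sd_ms Standard deviation of optional Gaussian jitter on the
#'   inhibitory event times (ms); 0 disables it.
#' @param record_hz Sampling rate of the recorded membrane potentials (Hz).
#' @return Object of class `tad_sim`: `time_s`, voltage matrix `V` (mV, one
#'   column per neuron), `spikes_s` (list of spike-time vectors), the
#'   applied stimuli and the gate state.
#' @export
simulate_network <- function(net, stimuli, duration_s = 5,
                             step_ms = NULL, seed = 1,
                             jitter_sd_ms = 0, record_hz = 10000) {
  stopifnot(inherits(net, "tad_network"))
  step_ms <- step_ms %||% (net$integration$step_ms %||% 0.025)
  duration_ms <- duration_s * 1000
  stim <- stimulus_matrix(net, stimuli)
  if (nrow(stim)) {
    if (any(stim[, "onset_ms"] >= duration_ms))
      stop("duration must cover the longest stimulus")
    # the left-right onset offset may push a bilateral step past the end;
    # clip rather than reject
    stim[, "dur_ms"] <- pmin(stim[, "dur_ms"], duration_ms - stim[, "onset_ms"])
  }

  icpg <- icpg_of(net, stimuli)
  coeff <- gating_coefficient(icpg, net$gating)
  ggaba <- max_inhibitory_conductance(net$gating, coeff)

  ev <- list()
  vo_ids <- net$neurons$id[net$neurons$role == "VO"]
  times <- seq(0, duration_ms, by = 1000 / net$gating$rate_hz)
  if (jitter_sd_ms > 0) {
    set.seed(seed)
    times <- sort(pmax(0, times + rnorm(length(times), 0, jitter_sd_ms)))
  }
  for (id in vo_ids)
    ev[[length(ev) + 1]] <- list(target = id, e_rev = net$gating$e_rev,
                                 gmax = ggaba, tau1 = net$gating$tau1,
                                 tau2 = net$gating$tau2, times_ms = times)

  record_every <- max(1L, as.integer(round(1000 / record_hz / step_ms)))
  raw <- .simulate_hh_network(net$params, as.matrix(net$synapses[, c("src", "tgt", "e_rev", "gmax", "tau1", "tau2", "nmda")]),
                              stim, ev, duration_ms, step_ms,
                              net$integration$delay_ms %||% 1, record_every)
  V <- raw$V
  colnames(V) <- rownames(net$params)
  spikes <- lapply(raw$spikes_ms, function(s) s / 1000)
  names(spikes) <- rownames(net$params)
  res <- list(time_s = raw$time_ms / 1000, V = V, spikes_s = spikes,
              stimuli = stimuli, icpg = icpg, gating_coeff = coeff,
              ggaba_max = ggaba, step_ms = step_ms,
              rate_hz = 1000 / (record_every * step_ms))
  class(res) <- "tad_sim"
  res
}

#' @export
print.tad_sim <- function(x, ...) {
  cat("Network simulation:", round(max(x$time_s), 3), "s,",
      ncol(x$V), "neurons, iCPG =", x$icpg, "nA, gGABA_max =",
      signif(x$ggaba_max, 4), "nS\n")
  invisible(x)
}

#' Burst frequency of a simulated motoneuron
#'
#' Applies the standard trace pipeline to one neuron of a simulation:
#' the membrane potential (relative to rest) is rectified and integrated
#' (15 ms moving average, two iterations), burst peaks are detected and the
#' mean instantaneous burst frequency returned.  This is the quantity called
#' "fictive swim frequency" when applied to a spinal motoneuron.
#'
#' @param sim A `tad_sim` result.
#' @param neuron Column name, e.g. `"spMN_L"`.
#' @param window_ms,iterations Integration settings.
#' @param min_separation_ms Minimal burst separation.
#' @return Mean burst frequency (Hz); 0 when fewer than 2 bursts.
#' @export
motoneuron_burst_frequency <- function(sim, neuron = "spMN_L",
                                       window_ms = 15, iterations = 2,
                                       min_separation_ms = 55) {
  env <- neuron_envelope(sim, neuron, window_ms, iterations)
  ev <- detect_burst_peaks(env, min_separation_ms = min_separation_ms)
  if (length(ev) < 2) return(0)
  rhythm_frequency(ev)$mean_hz
}

#' Rectified-integrated envelope of one simulated neuron
#'
#' @inheritParams motoneuron_burst_frequency
#' @return An [rectify_integrate()] envelope at 1 kHz.
#' @export
neuron_envelope <- function(sim, neuron, window_ms = 15, iterations = 2) {
  v <- sim$V[, neuron]
  rest <- stats::quantile(v, 0.1)            # sub-threshold floor
  x <- pmax(v - rest, 0)
  x <- downsample(x, sim$rate_hz, 1000)
  rectify_integrate(x, 1000, window_ms = window_ms, iterations = iterations)
}

#' Sweep the dIN drive and quantify rhythm and gating
#'
#' Runs the network over a grid of dIN step currents with a concurrent
#' sinusoidal vestibular drive into VO and VS, and tabulates per grid point
#' the fictive swim frequency (spMN bursts), the number of VO spikes, and
#' the modulation depths of the integrated AbdMN burst amplitude and
#' discharge baseline across vestibular cycles.
#'
#' @param net Network.
#' @param istim_values Step currents into both dINs (nA).
#' @param vest_freq_hz,vest_amplitude_na Sinusoidal drive into VO and VS.
#' @param duration_s Simulated time per grid point (s).
#' @param seed Passed to [simulate_network()].
#' @return Data frame with one row per `istim` value.
#' @export
run_protocol_grid <- function(net, istim_values, vest_freq_hz = 1,
                              vest_amplitude_na = 0.1, duration_s = 5,
                              seed = 1) {
  rows <- lapply(istim_values, function(i) {
    stimuli <- list()
    if (i > 0) stimuli <- c(stimuli, list(stim_step("dIN", i, duration_s = duration_s)))
    if (vest_amplitude_na > 0)
      stimuli <- c(stimuli, list(
        stim_sinusoid(c("VO", "VS"), vest_amplitude_na, vest_freq_hz,
                      duration_s = duration_s)))
    sim <- simulate_network(net, stimuli, duration_s = duration_s, seed = seed)
    mod <- abd_modulation(sim, vest_freq_hz)
    data.frame(istim_na = i,
               swim_freq_hz = motoneuron_burst_frequency(sim, "spMN_L"),
               vo_spikes = length(sim$spikes_s$VO_L) + length(sim$spikes_s$VO_R),
               abd_burst_amp_mod = mod$burst_amp_mod,
               abd_baseline_mod = mod$baseline_mod)
  })
  do.call(rbind, rows)
}

# Modulation depths of the integrated AbdMN trace across vestibular cycles.
# A rolling lower-decile envelope floor tracks the discharge baseline; its
# range over the analysis span is the baseline modulation depth.  Burst
# amplitudes are peak heights above the local floor; their range is the
# burst-amplitude modulation depth.  The rolling floor stays meaningful
# when bursts crowd at high swim frequencies and the envelope no longer
# returns to zero between bursts.
abd_modulation <- function(sim, vest_freq_hz, neuron = "AbdMN_L",
                           floor_window_s = 0.25) {
  env <- neuron_envelope(sim, neuron)
  ev <- detect_burst_peaks(env, min_separation_ms = 55)
  dur <- max(sim$time_s)
  if (length(ev) < 4 || dur * vest_freq_hz < 2)
    return(list(burst_amp_mod = 0, baseline_mod = 0))
  rate <- attr(env, "rate_hz")
  x <- as.numeric(env)
  tt <- (seq_along(x) - 1) / rate
  # rolling lower decile, evaluated on a coarse grid then interpolated
  grid_t <- seq(floor_window_s / 2, dur - floor_window_s / 2, by = 0.025)
  half <- floor_window_s / 2
  floor_g <- vapply(grid_t, function(tc)
    stats::quantile(x[tt >= tc - half & tt <= tc + half], 0.1, names = FALSE),
    numeric(1))
  floor_t <- approx(grid_t, floor_g, xout = tt, rule = 2)$y
  span <- tt >= 0.5 & tt <= dur - 0.25       # skip the rhythm start-up
  pk_idx <- pmin(pmax(round(ev * rate) + 1, 1), length(x))
  in_span <- ev >= 0.5 & ev <= dur - 0.25
  if (sum(in_span) < 3) return(list(burst_amp_mod = 0, baseline_mod = 0))
  amps <- x[pk_idx[in_span]] - floor_t[pk_idx[in_span]]
  list(burst_amp_mod = diff(range(amps)),
       baseline_mod = diff(range(floor_t[span])))
}
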