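# Shared fixtures: small, fast, deterministic.

# Build the default network once per test run.
default_net <- local({
  net <- NULL
  function() {
    if (is.null(net)) net <<- build_default_network()
    net
  }
})

# Short simulation cache keyed by protocol, to avoid repeating identical runs.
sim_cache <- new.env(parent = emptyenv())
cached_sim <- function(key, stimuli, duration_s = 5) {
  if (is.null(sim_cache[[key]]))
    sim_cache[[key]] <- simulate_network(default_net(), stimuli,
                                         duration_s = duration_s)
  sim_cache[[key]]
}

# Analysis front-end used by several kinematics tests.
kin_pipeline <- function(preset, duration_s = 10, seed_tail = 11,
                         seed_eye = 12, rate = 500) {
  tail <- make_tail_trace(preset, duration_s, rate, seed = seed_tail)
  eyes <- make_eye_traces(tail, preset, seed = seed_eye)
  eye <- lowpass_20(as.numeric(eyes$left), rate)
  tl <- lowpass_20(as.numeric(tail), rate)
  cyc <- per_cycle_amplitudes(eye, tl, segment_swim_cycles(tl, rate), rate)
  slow <- eccentricity_trace(eye, cyc, rate)
  cyc <- per_cycle_amplitudes(eye, tl, cyc, rate, remove_slow = slow)
  list(eye = eye, tail = tl, cycles = cyc, slow = slow, rate = rate,
       duration = duration_s)
}
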