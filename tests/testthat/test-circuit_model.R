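test_that("gating coefficient follows the logistic of the dIN drive", {
  g <- gating_params(i_trans = 0.16, sigm_amp = 1, sigm_steep = 200)
  expect_equal(gating_coefficient(0.16, g), 0.5)
  expect_lt(gating_coefficient(-10, g), 1e-12)
  # iCPG at midpoint + 4/steepness: exp(4)/(1+exp(4))
  expect_equal(gating_coefficient(0.16 + 4 / 200, g),
               exp(4) / (1 + exp(4)), tolerance = 1e-12)
  # strictly increasing and bounded by the amplitude
  ic <- seq(-0.1, 0.5, by = 0.01)
  v <- gating_coefficient(ic, g)
  expect_true(all(diff(v) >= 0))
  strict <- v > 1e-12 & v < 1 - 1e-12        # away from float saturation
  expect_true(all(diff(v[strict]) > 0))
  expect_true(all(v >= 0 & v <= g$sigm_amp))
  g2 <- gating_params(sigm_amp = 2.5)
  expect_equal(gating_coefficient(1e3, g2), 2.5, tolerance = 1e-9)
  expect_error(gating_coefficient(NaN, g), "finite")
})

test_that("maximal inhibitory conductance is the product of its factors", {
  g <- gating_params(num_syn_inh = 5, unitary_ggaba = 1)
  expect_equal(max_inhibitory_conductance(g, 0.5), 2.5)
  expect_equal(max_inhibitory_conductance(g, 0), 0)
  g1 <- gating_params(num_syn_inh = 1, unitary_ggaba = 3.7)
  expect_equal(max_inhibitory_conductance(g1, 1), 3.7)
  # linear in each factor
  expect_equal(max_inhibitory_conductance(g, 0.4),
               2 * max_inhibitory_conductance(g, 0.2))
  expect_error(max_inhibitory_conductance(g, -0.1), "non-negative")
})

test_that("the default network has the published wiring", {
  net <- default_net()
  expect_s3_class(net, "tad_network")
  expect_equal(nrow(net$neurons), 14)
  expect_equal(sort(unique(net$neurons$role)),
               sort(c("dIN", "cIN", "spMN", "EC", "VO", "VS", "AbdMN")))
  expect_true(all(table(net$neurons$role) == 2))

  id <- function(role, side)
    net$neurons$id[net$neurons$role == role & net$neurons$side == side]
  has_edge <- function(src, tgt)
    any(net$synapses$src == src & net$synapses$tgt == tgt)
  edge_exc <- function(src, tgt)
    all(net$synapses$e_rev[net$synapses$src == src & net$synapses$tgt == tgt] == 0)

  # VO projects to the contralateral abducens motoneuron, excitatory
  expect_true(has_edge(id("VO", "L"), id("AbdMN", "R")))
  expect_true(edge_exc(id("VO", "L"), id("AbdMN", "R")))
  expect_false(has_edge(id("VO", "L"), id("AbdMN", "L")))
  # efference copy crosses the midline
  expect_true(has_edge(id("EC", "R"), id("AbdMN", "L")))
  expect_true(has_edge(id("spMN", "L"), id("EC", "L")))
  # CPG wiring is side-respecting except through cIN
  expect_true(has_edge(id("dIN", "L"), id("spMN", "L")))
  expect_false(has_edge(id("dIN", "L"), id("spMN", "R")))
  expect_true(has_edge(id("cIN", "L"), id("dIN", "R")))
  inh <- net$synapses$src == id("cIN", "L")
  expect_true(all(net$synapses$e_rev[inh] < 0))
  # vestibulo-spinal neurons act ipsilaterally
  expect_true(has_edge(id("VS", "R"), id("spMN", "R")))
  expect_true(has_edge(id("VS", "R"), id("EC", "R")))
  expect_false(has_edge(id("VS", "R"), id("spMN", "L")))
})

test_that("a missing membrane template is a configuration error", {
  cfg <- default_model_config()
  cfg$membrane$dIN <- NULL
  expect_error(default_model_config_check <- build_default_network(cfg),
               "template")
  cfg2 <- default_model_config()
  cfg2$synapses$vo_abd <- NULL
  expect_error(build_default_network(cfg2), "vo_abd")
})

test_that("simulation is deterministic and spikes are threshold crossings", {
  sim <- cached_sim("step0.15", list(stim_step("dIN", 0.15)))
  sim2 <- simulate_network(default_net(), list(stim_step("dIN", 0.15)),
                           duration_s = 5)
  expect_identical(sim$spikes_s, sim2$spikes_s)
  expect_identical(sim$V, sim2$V)
  # every recorded spMN spike sits on a suprathreshold excursion
  v <- sim$V[, "spMN_L"]
  t <- sim$time_s
  for (ts in head(sim$spikes_s$spMN_L, 10)) {
    win <- v[t >= ts - 0.002 & t <= ts + 0.002]
    expect_gt(max(win), 0)
  }
  expect_true(all(diff(sim$time_s) > 0))
  expect_equal(sd(diff(sim$time_s)), 0, tolerance = 1e-9)
})

test_that("no injected current leaves the motoneurons silent", {
  sim <- cached_sim("rest", list(), 5)
  expect_lte(length(sim$spikes_s$spMN_L) + length(sim$spikes_s$spMN_R), 2)
  expect_equal(motoneuron_burst_frequency(sim, "spMN_L"), 0)
})

test_that("suprathreshold drive produces left-right alternating bursts", {
  sim <- cached_sim("step0.15", list(stim_step("dIN", 0.15)))
  onsets <- function(sp) sp[c(TRUE, diff(sp) > 0.04)]
  onL <- onsets(sim$spikes_s$spMN_L)
  onR <- onsets(sim$spikes_s$spMN_R)
  expect_gt(length(onL), 20)
  expect_gt(length(onR), 20)
  ph <- vapply(onR, function(tt) {
    k <- findInterval(tt, onL)
    if (k < 1 || k >= length(onL)) return(NA_real_)
    (tt - onL[k]) / (onL[k + 1] - onL[k])
  }, numeric(1))
  mean_phase <- mean(ph, na.rm = TRUE) * 360
  expect_gt(mean_phase, 160)
  expect_lt(mean_phase, 200)
})

test_that("the gate silences VO above the transition current, sparing VS", {
  lo <- cached_sim("gate0.13", list(stim_step("dIN", 0.13),
                                    stim_sinusoid(c("VO", "VS"), 0.1, 1)))
  hi <- cached_sim("gate0.2", list(stim_step("dIN", 0.2),
                                   stim_sinusoid(c("VO", "VS"), 0.1, 1)))
  expect_gt(length(lo$spikes_s$VO_L), 50)
  expect_equal(length(hi$spikes_s$VO_L) + length(hi$spikes_s$VO_R), 0)
  # VS discharge is never touched by the gate
  expect_equal(length(lo$spikes_s$VS_L), length(hi$spikes_s$VS_L))
  expect_gt(length(hi$spikes_s$VS_L), 50)
})

test_that("iCPG is the mean step current into the two dINs", {
  net <- default_net()
  expect_equal(icpg_of(net, list(stim_step("dIN", 0.15))), 0.15)
  expect_equal(icpg_of(net, list(stim_sinusoid("VO", 0.1, 1))), 0)
  # a step into a single neuron id does not define an iCPG
  expect_equal(icpg_of(net, list(stim_step(1, 0.15))), 0)
})
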