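# Default configuration of the bilateral spino-ocular network model.
# Units: capacitance pF, conductances nS, potentials mV, time constants ms.
# The dIN adaptation and commissural inhibition values are calibrated so
# that bilateral dIN step currents map onto fictive swim frequencies as
# 0 nA -> no rhythm, 0.13 -> 6 Hz, 0.15 -> 7 Hz, 0.16 -> 8 Hz, 0.3 -> 12 Hz
# (see scripts/calibrate_model.R).
membrane:
  dIN:
    capacitance: 8
    g_na: 960
    g_k: 288
    g_leak: 2.4
    e_na: 50
    e_k: -77
    e_leak: -54.4
    adapt_increment: 5
    adapt_tau: 70
    adapt2_increment: 0.52
    adapt2_tau: 500
    bias_pa: 66
    v_init: -65
  MN:
    capacitance: 10
    g_na: 1200
    g_k: 360
    g_leak: 3
    e_na: 50
    e_k: -77
    e_leak: -54.4
    adapt_increment: 0
    adapt_tau: 100
    v_init: -65
  vest_spin:
    capacitance: 5
    g_na: 600
    g_k: 180
    g_leak: 1.5
    e_na: 50
    e_k: -77
    e_leak: -54.4
    adapt_increment: 0
    adapt_tau: 100
    v_init: -65
synapses:
  din_cin:       {gmax: 15, tau1: 0.2, tau2: 3,  e_rev: 0}
  din_spmn:      {gmax: 10, tau1: 0.2, tau2: 30, e_rev: 0}
  din_self_ampa: {gmax: 3,  tau1: 0.2, tau2: 3,  e_rev: 0}
  din_self_nmda: {gmax: 2,  tau1: 5,   tau2: 80, e_rev: 0}
  cin_inhibition: {gmax: 10, tau1: 0.5, tau2: 15, e_rev: -75}
  spmn_ec:       {gmax: 15, tau1: 0.2, tau2: 3,  e_rev: 0}
  ec_abd:        {gmax: 15, tau1: 0.2, tau2: 3,  e_rev: 0}
  vo_abd:        {gmax: 15, tau1: 0.2, tau2: 3,  e_rev: 0}
  vs_spmn:       {gmax: 0.25, tau1: 0.2, tau2: 15, e_rev: 0}
  vs_ec:         {gmax: 0.25, tau1: 0.2, tau2: 15, e_rev: 0}
gating:
  i_trans: 0.16
  sigm_amp: 1
  sigm_steep: 200
  num_syn_inh: 10
  unitary_ggaba: 1.5
  rate_hz: 10
  tau1: 0.5
  tau2: 100
  e_rev: -75
integration:
  step_ms: 0.025
  delay_ms: 1
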