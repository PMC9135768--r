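#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Fixed-step integrator for a small network of single-compartment
// Hodgkin-Huxley neurons with two-exponential conductance synapses,
// spike-triggered adaptation, NMDA magnesium block, step/sinusoid current
// injection and externally scheduled (gated) synaptic event trains.
//
// Units: mV, ms, nS, pF, pA.  dV/dt = I/C is then mV/ms.
//
// Gating variables use an exponential update (exact for frozen V); the
// membrane equation is advanced semi-implicitly in the conductances,
// which keeps the scheme stable at the default 0.025 ms step.

static inline double vtrap(double x, double y) {
  // x/(1 - exp(-x/y)) with the removable singularity at x = 0 handled
  if (std::fabs(x / y) < 1e-6) return y * (1.0 - x / y / 2.0);
  return x / (1.0 - std::exp(-x / y));
}

struct Syn {
  int src, tgt;
  double e_rev, gmax, tau1, tau2, norm;
  bool nmda;
  double a, b;              // rise / decay states
  std::vector<double> ring; // pending increments (conduction delay)
};

static double biexp_norm(double tau1, double tau2) {
  double tp = tau1 * tau2 / (tau2 - tau1) * std::log(tau2 / tau1);
  double peak = std::exp(-tp / tau2) - std::exp(-tp / tau1);
  return 1.0 / peak;
}

// [[Rcpp::export(name = ".simulate_hh_network")]]
List simulate_hh_network(NumericMatrix neuron_params,
                         NumericMatrix synapses,
                         NumericMatrix stimuli,
                         List event_synapses,
                         double duration_ms,
                         double dt,
                         double delay_ms,
                         int record_every) {
  const int n = neuron_params.nrow();
  // neuron_params columns:
  // 0 C, 1 gNa, 2 gK, 3 gL, 4 ENa, 5 EK, 6 EL, 7 z_inc, 8 tau_z,
  // 9 z2_inc, 10 tau_z2 (second, slow adaptation component),
  // 11 bias_pA (tonic background drive), 12 v0
  const int nsteps = (int)std::round(duration_ms / dt);
  const int delay_steps = std::max(1, (int)std::round(delay_ms / dt));

  std::vector<double> V(n), m(n), h(n), nn(n), z(n, 0.0), z2(n, 0.0), last_spike(n, -1e9);
  for (int i = 0; i < n; ++i) {
    double v = neuron_params(i, 12);
    V[i] = v;
    double am = 0.1 * vtrap(v + 40.0, 10.0), bm = 4.0 * std::exp(-(v + 65.0) / 18.0);
    double ah = 0.07 * std::exp(-(v + 65.0) / 20.0), bh = 1.0 / (1.0 + std::exp(-(v + 35.0) / 10.0));
    double an = 0.01 * vtrap(v + 55.0, 10.0), bn = 0.125 * std::exp(-(v + 65.0) / 80.0);
    m[i] = am / (am + bm); h[i] = ah / (ah + bh); nn[i] = an / (an + bn);
  }

  // chemical synapses
  std::vector<Syn> syn;
  for (int s = 0; s < synapses.nrow(); ++s) {
    Syn sy;
    sy.src = (int)synapses(s, 0) - 1;
    sy.tgt = (int)synapses(s, 1) - 1;
    sy.e_rev = synapses(s, 2);
    sy.gmax = synapses(s, 3);
    sy.tau1 = synapses(s, 4);
    sy.tau2 = synapses(s, 5);
    sy.nmda = synapses(s, 6) > 0.5;
    sy.norm = biexp_norm(sy.tau1, sy.tau2);
    sy.a = sy.b = 0.0;
    sy.ring.assign(delay_steps, 0.0);
    syn.push_back(sy);
  }
  // scheduled event synapses: list of lists(tgt, e_rev, gmax, tau1, tau2, times_ms)
  struct EvSyn { int tgt; double e_rev, gmax, tau1, tau2, norm, a, b; std::vector<double> times; size_t next; };
  std::vector<EvSyn> evs;
  for (int k = 0; k < event_synapses.size(); ++k) {
    List el = event_synapses[k];
    EvSyn e;
    e.tgt = as<int>(el["target"]) - 1;
    e.e_rev = as<double>(el["e_rev"]);
    e.gmax = as<double>(el["gmax"]);
    e.tau1 = as<double>(el["tau1"]);
    e.tau2 = as<double>(el["tau2"]);
    e.norm = biexp_norm(e.tau1, e.tau2);
    e.a = e.b = 0.0;
    e.times = as<std::vector<double> >(el["times_ms"]);
    e.next = 0;
    evs.push_back(e);
  }

  // stimuli columns: 0 target, 1 type(0 step,1 sine), 2 amp_pA, 3 onset_ms,
  // 4 dur_ms, 5 freq_Hz, 6 phase_deg
  const int nstim = stimuli.nrow();

  // synapse decay factors
  std::vector<double> dec1(syn.size()), dec2(syn.size());
  for (size_t s = 0; s < syn.size(); ++s) {
    dec1[s] = std::exp(-dt / syn[s].tau1);
    dec2[s] = std::exp(-dt / syn[s].tau2);
  }
  std::vector<double> edec1(evs.size()), edec2(evs.size());
  for (size_t s = 0; s < evs.size(); ++s) {
    edec1[s] = std::exp(-dt / evs[s].tau1);
    edec2[s] = std::exp(-dt / evs[s].tau2);
  }

  const int nrec = nsteps / record_every + 1;
  NumericMatrix Vrec(nrec, n);
  NumericVector trec(nrec);
  std::vector< std::vector<double> > spikes(n);
  int irec = 0;

  for (int step = 0; step <= nsteps; ++step) {
    double t = step * dt;
    if (step % record_every == 0 && irec < nrec) {
      trec[irec] = t;
      for (int i = 0; i < n; ++i) Vrec(irec, i) = V[i];
      ++irec;
    }
    if (step == nsteps) break;

    // per-neuron summed synaptic conductance terms for semi-implicit update
    std::vector<double> gsum(n, 0.0), gesum(n, 0.0); // sum g, sum g*E
    int slot = step % delay_steps;
    for (size_t s = 0; s < syn.size(); ++s) {
      Syn &sy = syn[s];
      // deliver delayed events scheduled for this step
      if (sy.ring[slot] > 0.0) {
        sy.a += sy.ring[slot];
        sy.b += sy.ring[slot];
        sy.ring[slot] = 0.0;
      }
      double g = sy.gmax * sy.norm * (sy.b - sy.a);
      if (g < 0) g = 0;
      if (sy.nmda) {
        double block = 1.0 / (1.0 + std::exp(-0.062 * V[sy.tgt]) / 3.57);
        g *= block;
      }
      gsum[sy.tgt] += g;
      gesum[sy.tgt] += g * sy.e_rev;
      sy.a *= dec1[s];
      sy.b *= dec2[s];
    }
    for (size_t s = 0; s < evs.size(); ++s) {
      EvSyn &e = evs[s];
      while (e.next < e.times.size() && e.times[e.next] <= t) {
        e.a += 1.0; e.b += 1.0; ++e.next;
      }
      double g = e.gmax * e.norm * (e.b - e.a);
      if (g < 0) g = 0;
      gsum[e.tgt] += g;
      gesum[e.tgt] += g * e.e_rev;
      e.a *= edec1[s];
      e.b *= edec2[s];
    }

    // injected currents (tonic background + protocol stimuli)
    std::vector<double> iinj(n, 0.0);
    for (int i = 0; i < n; ++i) iinj[i] = neuron_params(i, 11);
    for (int q = 0; q < nstim; ++q) {
      int tgt = (int)stimuli(q, 0) - 1;
      double onset = stimuli(q, 3), dur = stimuli(q, 4);
      if (t < onset || t >= onset + dur) continue;
      if (stimuli(q, 1) < 0.5) {
        iinj[tgt] += stimuli(q, 2);
      } else {
        double ph = stimuli(q, 6) * M_PI / 180.0;
        iinj[tgt] += stimuli(q, 2) * std::sin(2.0 * M_PI * stimuli(q, 5) * (t - onset) / 1000.0 + ph);
      }
    }

    // advance neurons
    for (int i = 0; i < n; ++i) {
      double C = neuron_params(i, 0), gNa = neuron_params(i, 1), gK = neuron_params(i, 2),
             gL = neuron_params(i, 3), ENa = neuron_params(i, 4), EK = neuron_params(i, 5),
             EL = neuron_params(i, 6), z_inc = neuron_params(i, 7), tau_z = neuron_params(i, 8),
             z2_inc = neuron_params(i, 9), tau_z2 = neuron_params(i, 10);
      double v = V[i];
      double am = 0.1 * vtrap(v + 40.0, 10.0), bm = 4.0 * std::exp(-(v + 65.0) / 18.0);
      double ah = 0.07 * std::exp(-(v + 65.0) / 20.0), bh = 1.0 / (1.0 + std::exp(-(v + 35.0) / 10.0));
      double an = 0.01 * vtrap(v + 55.0, 10.0), bn = 0.125 * std::exp(-(v + 65.0) / 80.0);
      double taum = 1.0 / (am + bm), tauh = 1.0 / (ah + bh), taun = 1.0 / (an + bn);
      m[i] += (am * taum - m[i]) * (1.0 - std::exp(-dt / taum));
      h[i] += (ah * tauh - h[i]) * (1.0 - std::exp(-dt / tauh));
      nn[i] += (an * taun - nn[i]) * (1.0 - std::exp(-dt / taun));
      if (z_inc > 0.0) z[i] *= std::exp(-dt / tau_z);
      if (z2_inc > 0.0) z2[i] *= std::exp(-dt / tau_z2);

      double gna = gNa * m[i] * m[i] * m[i] * h[i];
      double gk = gK * nn[i] * nn[i] * nn[i] * nn[i];
      double gz = z[i] + z2[i]; // adaptation conductances, reverse at EK
      double gtot = gna + gk + gL + gz + gsum[i];
      double getot = gna * ENa + gk * EK + gL * EL + gz * EK + gesum[i];
      double vnew = (v + dt / C * (getot + iinj[i])) / (1.0 + dt / C * gtot);
      if (!std::isfinite(vnew))
        stop("non-finite membrane potential at t = %f ms (neuron %d); reduce the integration step", t, i + 1);

      // spike detection: upward crossing of 0 mV, 2 ms refractory
      if (v < 0.0 && vnew >= 0.0 && (t - last_spike[i]) >= 2.0) {
        last_spike[i] = t;
        spikes[i].push_back(t + dt);
        if (z_inc > 0.0) z[i] += z_inc;
        if (z2_inc > 0.0) z2[i] += z2_inc;
        // schedule synaptic events on outgoing synapses
        for (size_t s = 0; s < syn.size(); ++s)
          if (syn[s].src == i) syn[s].ring[slot] += 1.0; // delivered delay_steps later
      }
      V[i] = vnew;
    }
  }

  List spk(n);
  for (int i = 0; i < n; ++i) spk[i] = wrap(spikes[i]);
  return List::create(_["time_ms"] = trec, _["V"] = Vrec, _["spikes_ms"] = spk);
}
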