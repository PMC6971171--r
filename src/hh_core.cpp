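// Compiled simulation core: time-steps one neuron layer (single-compartment
// interneurons or two-compartment motoneurons) with exponential-Euler gating
// updates, exact linear updates for calcium and synaptic conductance, and
// forward-Euler voltage updates.  Gating steady states and the per-step
// exponential-Euler propagators are tabulated on a fine voltage grid and
// linearly interpolated.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

constexpr double V_MIN = -130.0;
constexpr double V_MAX = 70.0;
constexpr double DV = 0.02;
constexpr int NV = static_cast<int>((V_MAX - V_MIN) / DV) + 1;

struct GateTable {
  std::vector<double> inf;  // steady state
  std::vector<double> a;    // 1 - exp(-dt / tau)
};

inline double boltz(double v, double v12, double k) {
  return 1.0 / (1.0 + std::exp((v - v12) / k));
}

// generic tau forms
struct TauConst { double tau; double operator()(double) const { return tau; } };
struct TauBiExp {
  double scale, v0, k1, k2;
  double operator()(double v) const {
    return scale / (std::exp((v - v0) / k1) + std::exp(-(v - v0) / k2));
  }
};
struct TauCosh {
  double tmax, v0, k;
  double operator()(double v) const { return tmax / std::cosh((v - v0) / k); }
};

template <typename TauFn>
GateTable make_table(double v12, double k, TauFn tau, double dt) {
  GateTable t;
  t.inf.resize(NV);
  t.a.resize(NV);
  for (int i = 0; i < NV; ++i) {
    double v = V_MIN + i * DV;
    t.inf[i] = boltz(v, v12, k);
    t.a[i] = 1.0 - std::exp(-dt / tau(v));
  }
  return t;
}

struct Interp {
  int i;
  double w;
};

inline Interp locate(double v) {
  if (v < V_MIN) v = V_MIN;
  if (v > V_MAX) v = V_MAX;
  double x = (v - V_MIN) / DV;
  int i = static_cast<int>(x);
  if (i >= NV - 1) i = NV - 2;
  return {i, x - i};
}

inline double gate_inf(const GateTable& t, const Interp& p) {
  return t.inf[p.i] + p.w * (t.inf[p.i + 1] - t.inf[p.i]);
}
inline double gate_a(const GateTable& t, const Interp& p) {
  return t.a[p.i] + p.w * (t.a[p.i + 1] - t.a[p.i]);
}

inline void step_gate(double& x, const GateTable& t, const Interp& p) {
  x += (gate_inf(t, p) - x) * gate_a(t, p);
}

double pget(const List& par, const char* name) {
  if (!par.containsElementNamed(name)) stop("missing parameter: %s", name);
  return as<double>(par[name]);
}

}  // namespace

// Simulate one layer of neurons for n_steps internal steps.
//
// class_id: 1 = interneuron (single compartment), 2 = motoneuron.
// par: named list of neuron parameters (see the shipped parameter file).
// E_L: per-neuron leak reversal potential (mV), length n.
// dt: internal step (ms); 1 / dt must be an integer (steps per ms).
// n_ms: total simulated milliseconds; n_steps = n_ms * steps_per_ms.
// dc: scalar DC drive (uA/cm^2), applied to the soma of every neuron.
// common: common injected waveform sampled at 1 kHz (length n_ms or 0).
// noise: per-neuron injected waveform, n x n_ms matrix (or 0 x 0).
// src_spike_step / src_spike_neuron: presynaptic spikes (internal step index,
//   0-based source neuron), sorted by step; may be empty.
// adj_ptr / adj_tgt / adj_w: CSR adjacency from source neuron to target
//   neurons with per-edge peak conductances.
// record_every: store somatic V every this many internal steps (0 = none).
// dead_ms: spike-detector dead time (ms).
//
// Returns spike times (internal step of upward 0 mV crossing) per neuron and
// the optional somatic voltage record.
// [[Rcpp::export(name = ".sim_layer_cpp")]]
List sim_layer_cpp(int class_id, List par, NumericVector E_L, double dt,
                   int n_ms, double dc, NumericVector common,
                   NumericMatrix noise, IntegerVector src_spike_step,
                   IntegerVector src_spike_neuron, IntegerVector adj_ptr,
                   IntegerVector adj_tgt, NumericVector adj_w,
                   int record_every = 0, double dead_ms = 2.0,
                   bool record_vd = false) {
  const int n = E_L.size();
  const int spm = static_cast<int>(std::lround(1.0 / dt));
  if (std::fabs(spm * dt - 1.0) > 1e-9) stop("1/dt must be an integer number of steps per ms");
  const long n_steps = static_cast<long>(n_ms) * spm;
  const bool mn = (class_id == 2);
  const bool has_common = common.size() > 0;
  const bool has_noise = noise.ncol() > 0;
  if (has_common && common.size() != n_ms) stop("common drive must have n_ms samples");
  if (has_noise && (noise.nrow() != n || noise.ncol() != n_ms))
    stop("noise must be an n x n_ms matrix");

  // parameters
  const double C = pget(par, "C");
  const double gNa = pget(par, "g_Na"), gK = pget(par, "g_K"), gL = pget(par, "g_L");
  const double ENa = pget(par, "E_Na"), EK = pget(par, "E_K");
  const double ESynE = pget(par, "E_SynE"), tauSynE = pget(par, "tau_synE");
  double gNaP = 0, gCaNS = 0, gCaND = 0, gCaL = 0, gKCaS = 0, gKCaD = 0;
  double ECa = 0, gC = 0, psr = 0, Kd = 1, f_ca = 0, alpha_ca = 0, k_Ca = 1;
  if (mn) {
    gNaP = pget(par, "g_NaP");
    gCaNS = pget(par, "g_CaN_S");
    gCaND = pget(par, "g_CaN_D");
    gCaL = pget(par, "g_CaL");
    gKCaS = pget(par, "g_KCa_S");
    gKCaD = pget(par, "g_KCa_D");
    ECa = pget(par, "E_Ca");
    gC = pget(par, "g_C");
    psr = pget(par, "p");
    if (psr <= 0.0 || psr >= 1.0) stop("somatic surface ratio p must be in (0, 1)");
    Kd = pget(par, "K_d");
    f_ca = pget(par, "f_ca");
    alpha_ca = pget(par, "alpha_ca");
    k_Ca = pget(par, "k_Ca");
  }

  // gating tables
  GateTable t_mNa = make_table(pget(par, "mNa_V12"), pget(par, "mNa_k"),
                               TauConst{pget(par, "mNa_tau")}, dt);
  GateTable t_hNa = make_table(pget(par, "hNa_V12"), pget(par, "hNa_k"),
                               TauBiExp{pget(par, "hNa_tau_scale"), pget(par, "hNa_tau_V"),
                                        pget(par, "hNa_tau_k1"), pget(par, "hNa_tau_k2")},
                               dt);
  GateTable t_mK = make_table(pget(par, "mK_V12"), pget(par, "mK_k"),
                              TauBiExp{pget(par, "mK_tau_scale"), pget(par, "mK_tau_V"),
                                       pget(par, "mK_tau_k1"), pget(par, "mK_tau_k2")},
                              dt);
  GateTable t_mCaN, t_hCaN, t_mCaL, t_mNaP, t_hNaP;
  if (mn) {
    t_mCaN = make_table(pget(par, "mCaN_V12"), pget(par, "mCaN_k"),
                        TauConst{pget(par, "mCaN_tau")}, dt);
    t_hCaN = make_table(pget(par, "hCaN_V12"), pget(par, "hCaN_k"),
                        TauConst{pget(par, "hCaN_tau")}, dt);
    t_mCaL = make_table(pget(par, "mCaL_V12"), pget(par, "mCaL_k"),
                        TauConst{pget(par, "mCaL_tau")}, dt);
    t_mNaP = make_table(pget(par, "mNaP_V12"), pget(par, "mNaP_k"),
                        TauConst{pget(par, "mNaP_tau")}, dt);
    t_hNaP = make_table(pget(par, "hNaP_V12"), pget(par, "hNaP_k"),
                        TauCosh{pget(par, "hNaP_tau_max"), pget(par, "hNaP_tau_V"),
                                pget(par, "hNaP_tau_k")},
                        dt);
  }

  // state (structure of arrays), initialized at rest; calcium starts at the
  // fixed point of its kinetics for the resting Ca currents (starting at 0
  // would transiently remove the K(Ca) stabilization and can fire spurious
  // initialization spikes in near-rheobase motoneurons)
  std::vector<double> VS(n), VD(n), mNa(n), hNa(n), mK(n);
  std::vector<double> mCaNs(n), hCaNs(n), mCaNd(n), hCaNd(n), mCaL(n), mNaP(n), hNaP(n);
  std::vector<double> CaS(n, 0.0), CaD(n, 0.0), gsyn(n, 0.0);
  for (int i = 0; i < n; ++i) {
    double v = E_L[i];
    VS[i] = v;
    VD[i] = v;
    Interp p = locate(v);
    mNa[i] = gate_inf(t_mNa, p);
    hNa[i] = gate_inf(t_hNa, p);
    mK[i] = gate_inf(t_mK, p);
    if (mn) {
      mCaNs[i] = gate_inf(t_mCaN, p);
      hCaNs[i] = gate_inf(t_hCaN, p);
      mCaNd[i] = gate_inf(t_mCaN, p);
      hCaNd[i] = gate_inf(t_hCaN, p);
      mCaL[i] = gate_inf(t_mCaL, p);
      mNaP[i] = gate_inf(t_mNaP, p);
      hNaP[i] = gate_inf(t_hNaP, p);
      const double ICaNs0 = gCaNS * mCaNs[i] * mCaNs[i] * hCaNs[i] * (v - ECa);
      const double ICaNd0 = gCaND * mCaNd[i] * mCaNd[i] * hCaNd[i] * (v - ECa);
      const double ICaLd0 = gCaL * mCaL[i] * (v - ECa);
      CaS[i] = std::max(0.0, -alpha_ca * ICaNs0 / k_Ca);
      CaD[i] = std::max(0.0, -alpha_ca * (ICaNd0 + ICaLd0) / k_Ca);
    }
  }

  const double syn_decay = std::exp(-dt / tauSynE);
  const double ca_decay = std::exp(-f_ca * k_Ca * dt);
  const double ca_gain = (k_Ca > 0) ? (1.0 - ca_decay) * alpha_ca / k_Ca : 0.0;
  const int dead_steps = static_cast<int>(std::lround(dead_ms / dt));

  std::vector<long> last_spike(n, -1000000);
  std::vector<int> spike_neuron;
  std::vector<double> spike_step;

  const int n_events = src_spike_step.size();
  int ev = 0;

  NumericMatrix vrec;
  NumericMatrix vdrec;
  long n_rec = 0;
  if (record_every > 0) {
    n_rec = n_steps / record_every;
    vrec = NumericMatrix(static_cast<int>(n_rec), n);
    if (record_vd && mn) vdrec = NumericMatrix(static_cast<int>(n_rec), n);
  }
  long rec_i = 0;

  for (int ms = 0; ms < n_ms; ++ms) {
    double base = dc + (has_common ? common[ms] : 0.0);
    for (int sub = 0; sub < spm; ++sub) {
      const long step = static_cast<long>(ms) * spm + sub;
      // deliver presynaptic spikes scheduled for this step
      while (ev < n_events && src_spike_step[ev] == step) {
        int s = src_spike_neuron[ev];
        for (int e = adj_ptr[s]; e < adj_ptr[s + 1]; ++e) gsyn[adj_tgt[e]] += adj_w[e];
        ++ev;
      }
      if (ev < n_events && src_spike_step[ev] < step) stop("source spikes must be sorted by step");

      for (int i = 0; i < n; ++i) {
        const double el = E_L[i];
        double v = VS[i];
        const double prev_v = v;
        Interp ps = locate(v);
        step_gate(mNa[i], t_mNa, ps);
        step_gate(hNa[i], t_hNa, ps);
        step_gate(mK[i], t_mK, ps);
        // voltage update: exponential Euler with the conductances frozen
        // over the step (V' = (V_inf - V) g_tot / C is linear in V), which
        // is unconditionally stable where forward Euler oscillates when
        // dt * g_tot / C approaches 1 during the spike upstroke
        const double m3 = mNa[i] * mNa[i] * mNa[i];
        const double n4 = mK[i] * mK[i] * mK[i] * mK[i];
        const double gna = gNa * m3 * hNa[i];
        const double gk = gK * n4;
        const double Iinj = base + (has_noise ? noise(i, ms) : 0.0);
        if (!mn) {
          const double gsum = gna + gk + gL + gsyn[i];
          const double isum = gna * ENa + gk * EK + gL * el + gsyn[i] * ESynE + Iinj;
          const double vinf = isum / gsum;
          VS[i] = vinf + (v - vinf) * std::exp(-dt * gsum / C);
        } else {
          double vd = VD[i];
          Interp pd = locate(vd);
          step_gate(mCaNs[i], t_mCaN, ps);
          step_gate(hCaNs[i], t_hCaN, ps);
          step_gate(mCaNd[i], t_mCaN, pd);
          step_gate(hCaNd[i], t_hCaN, pd);
          step_gate(mCaL[i], t_mCaL, pd);
          step_gate(mNaP[i], t_mNaP, pd);
          step_gate(hNaP[i], t_hNaP, pd);
          const double gcans = gCaNS * mCaNs[i] * mCaNs[i] * hCaNs[i];
          const double gkcas = gKCaS * (CaS[i] / (CaS[i] + Kd));
          const double gcs = gC / psr;          // soma-side coupling conductance
          const double gcand = gCaND * mCaNd[i] * mCaNd[i] * hCaNd[i];
          const double gcald = gCaL * mCaL[i];
          const double gnapd = gNaP * mNaP[i] * hNaP[i];
          const double gkcad = gKCaD * (CaD[i] / (CaD[i] + Kd));
          const double gcd = gC / (1.0 - psr);  // dendrite-side coupling
          // Ca currents at the pre-update voltages (for the Ca kinetics)
          const double ICaNs = gcans * (v - ECa);
          const double ICaNd = gcand * (vd - ECa);
          const double ICaLd = gcald * (vd - ECa);
          const double gsum_s = gna + gk + gcans + gkcas + gL + gsyn[i] + gcs;
          const double isum_s = gna * ENa + gk * EK + gcans * ECa + gkcas * EK +
                                gL * el + gsyn[i] * ESynE + gcs * vd + Iinj;
          const double vinf_s = isum_s / gsum_s;
          const double gsum_d = gnapd + gcand + gcald + gkcad + gL + gcd;
          const double isum_d = gnapd * ENa + (gcand + gcald) * ECa + gkcad * EK +
                                gL * el + gcd * v;
          const double vinf_d = isum_d / gsum_d;
          VS[i] = vinf_s + (v - vinf_s) * std::exp(-dt * gsum_s / C);
          VD[i] = vinf_d + (vd - vinf_d) * std::exp(-dt * gsum_d / C);
          // exact update of the linear Ca kinetics at frozen Ca current
          CaS[i] = CaS[i] * ca_decay - ca_gain * ICaNs;
          CaD[i] = CaD[i] * ca_decay - ca_gain * (ICaNd + ICaLd);
          if (CaS[i] < 0) CaS[i] = 0;
          if (CaD[i] < 0) CaD[i] = 0;
        }
        gsyn[i] *= syn_decay;
        // spike detection: upward 0 mV crossing with dead time
        if (prev_v < 0.0 && VS[i] >= 0.0 && step - last_spike[i] >= dead_steps) {
          last_spike[i] = step;
          spike_neuron.push_back(i + 1);
          spike_step.push_back(static_cast<double>(step));
        }
        if (VS[i] > 200.0 || VS[i] < -200.0 || !std::isfinite(VS[i])) {
          stop("numerical blow-up: |V| > 200 mV (neuron %d, t = %.3f ms)", i + 1,
               step * dt);
        }
      }
      if (record_every > 0 && (step + 1) % record_every == 0 && rec_i < n_rec) {
        for (int i = 0; i < n; ++i) {
          vrec(static_cast<int>(rec_i), i) = VS[i];
          if (record_vd && mn) vdrec(static_cast<int>(rec_i), i) = VD[i];
        }
        ++rec_i;
      }
    }
  }

  List out = List::create(
      _["spike_neuron"] = wrap(spike_neuron), _["spike_step"] = wrap(spike_step),
      _["n_steps"] = static_cast<double>(n_steps), _["dt"] = dt);
  if (record_every > 0) out["V"] = vrec;
  if (record_every > 0 && record_vd && mn) out["V_D"] = vdrec;
  return out;
}
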