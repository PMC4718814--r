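// Conductance-based LIF winner-take-all network, Euler-integrated.
//
// All-to-all connectivity with pool-uniform weights means the recurrent
// drive onto any cell depends only on pool-summed synaptic gating, so each
// step is O(N) rather than O(N^2). Pools are laid out contiguously:
// [A | B | non-selective | inhibitory].
//
// Units: time ms, voltage mV, conductance nS, capacitance nF (so g*(V-E)
// is pA and dV = dt * I / (1000 * Cm)).

#include <Rcpp.h>
using namespace Rcpp;

// Poisson draw for small means via Knuth's product method; L = exp(-lambda)
static inline int rpois_knuth(double L) {
  int k = 0;
  double p = 1.0;
  do {
    ++k;
    p *= unif_rand();
  } while (p > L);
  return k - 1;
}

// [[Rcpp::export]]
List lif_simulate_cpp(int nA, int nB, int nNS, int nI,
                      double w_plus, double w_minus,
                      List neuron_E, List neuron_I, List syn,
                      NumericVector rate_A_hz, NumericVector rate_B_hz,
                      double seg_ms, double bg_rate_khz,
                      double t_total_ms, double dt_ms,
                      bool record_spikes) {
  const int nE = nA + nB + nNS;
  const int N = nE + nI;
  const int n_steps = (int)std::floor(t_total_ms / dt_ms + 0.5);
  const int n_bins = (int)std::ceil(t_total_ms);  // 1 ms count bins

  // neuron parameters
  const double CmE = as<double>(neuron_E["Cm_nF"]);
  const double gLE = as<double>(neuron_E["gL_nS"]);
  const double ELE = as<double>(neuron_E["EL_mV"]);
  const double VthE = as<double>(neuron_E["Vth_mV"]);
  const double VrE = as<double>(neuron_E["Vreset_mV"]);
  const double trefE = as<double>(neuron_E["tref_ms"]);
  const double CmI = as<double>(neuron_I["Cm_nF"]);
  const double gLI = as<double>(neuron_I["gL_nS"]);
  const double ELI = as<double>(neuron_I["EL_mV"]);
  const double VthI = as<double>(neuron_I["Vth_mV"]);
  const double VrI = as<double>(neuron_I["Vreset_mV"]);
  const double trefI = as<double>(neuron_I["tref_ms"]);

  const double gextE = as<double>(syn["g_ext_ampa_E_nS"]);
  const double gextI = as<double>(syn["g_ext_ampa_I_nS"]);
  const double gampE = as<double>(syn["g_rec_ampa_E_nS"]);
  const double gampI = as<double>(syn["g_rec_ampa_I_nS"]);
  const double gnmdE = as<double>(syn["g_nmda_E_nS"]);
  const double gnmdI = as<double>(syn["g_nmda_I_nS"]);
  const double ggabE = as<double>(syn["g_gaba_E_nS"]);
  const double ggabI = as<double>(syn["g_gaba_I_nS"]);
  const double tauA = as<double>(syn["tau_ampa_ms"]);
  const double tauNr = as<double>(syn["tau_nmda_rise_ms"]);
  const double tauNd = as<double>(syn["tau_nmda_decay_ms"]);
  const double alpha = as<double>(syn["alpha_per_ms"]);
  const double tauG = as<double>(syn["tau_gaba_ms"]);
  const double VEx = as<double>(syn["V_E_mV"]);
  const double VIn = as<double>(syn["V_I_mV"]);
  const double Mg = as<double>(syn["Mg_mM"]);

  // state
  std::vector<double> V(N), sext(N, 0.0), sampa(nE, 0.0),
      xnmda(nE, 0.0), snmda(nE, 0.0), sgaba(nI, 0.0);
  std::vector<int> refr(N, 0);
  for (int i = 0; i < N; ++i) V[i] = (i < nE ? ELE : ELI);

  const int refE = std::max(1, (int)std::floor(trefE / dt_ms + 0.5));
  const int refI = std::max(1, (int)std::floor(trefI / dt_ms + 0.5));

  IntegerMatrix counts(n_bins, 4);  // per-ms spike counts per pool
  std::vector<double> sp_t;
  std::vector<int> sp_id;

  const double dA = dt_ms / tauA, dNr = dt_ms / tauNr,
               dNd = dt_ms / tauNd, dG = dt_ms / tauG;

  int seg = -1;
  double LA = 0.0, LB = 0.0, Lbg = std::exp(-bg_rate_khz * dt_ms);

  for (int step = 0; step < n_steps; ++step) {
    const double t = step * dt_ms;
    const int s = (int)(t / seg_ms);
    if (s != seg) {
      seg = s;
      const double rA = (seg < rate_A_hz.size()) ? rate_A_hz[seg] : 0.0;
      const double rB = (seg < rate_B_hz.size()) ? rate_B_hz[seg] : 0.0;
      LA = std::exp(-(bg_rate_khz + rA / 1000.0) * dt_ms);
      LB = std::exp(-(bg_rate_khz + rB / 1000.0) * dt_ms);
    }

    // pool-summed gating (before this step's spikes)
    double SAa = 0, SBa = 0, SNa = 0, SAn = 0, SBn = 0, SNn = 0, SG = 0;
    for (int i = 0; i < nA; ++i) { SAa += sampa[i]; SAn += snmda[i]; }
    for (int i = nA; i < nA + nB; ++i) { SBa += sampa[i]; SBn += snmda[i]; }
    for (int i = nA + nB; i < nE; ++i) { SNa += sampa[i]; SNn += snmda[i]; }
    for (int i = 0; i < nI; ++i) SG += sgaba[i];

    // recurrent drive per target pool (E->E weights; everything else 1)
    const double drvA_a = w_plus * SAa + w_minus * SBa + w_minus * SNa;
    const double drvB_a = w_minus * SAa + w_plus * SBa + w_minus * SNa;
    const double drvN_a = SAa + SBa + SNa;
    const double drvA_n = w_plus * SAn + w_minus * SBn + w_minus * SNn;
    const double drvB_n = w_minus * SAn + w_plus * SBn + w_minus * SNn;
    const double drvN_n = SAn + SBn + SNn;

    for (int i = 0; i < N; ++i) {
      const bool isE = i < nE;
      const int pool = isE ? (i < nA ? 0 : (i < nA + nB ? 1 : 2)) : 3;

      // external Poisson arrivals (background + selective input)
      const double L = (pool == 0) ? LA : (pool == 1) ? LB : Lbg;
      const int k = rpois_knuth(L);
      if (k > 0) sext[i] += k;

      // gating decay (own-spike increments applied after threshold check)
      sext[i] -= sext[i] * dA;
      if (isE) {
        sampa[i] -= sampa[i] * dA;
        snmda[i] += dt_ms * (-snmda[i] / tauNd +
                             alpha * xnmda[i] * (1.0 - snmda[i]));
        xnmda[i] -= xnmda[i] * dNr;
      } else {
        sgaba[i - nE] -= sgaba[i - nE] * dG;
      }

      if (refr[i] > 0) {
        --refr[i];
        V[i] = isE ? VrE : VrI;
        continue;
      }

      const double v = V[i];
      const double Bv = 1.0 / (1.0 + Mg * std::exp(-0.062 * v) / 3.57);
      double drv_a, drv_n;
      if (pool == 0) { drv_a = drvA_a; drv_n = drvA_n; }
      else if (pool == 1) { drv_a = drvB_a; drv_n = drvB_n; }
      else { drv_a = drvN_a; drv_n = drvN_n; }

      double I_syn, gL, EL, Cm, Vth, Vr;
      if (isE) {
        I_syn = gextE * sext[i] * (v - VEx) +
                gampE * drv_a * (v - VEx) +
                gnmdE * Bv * drv_n * (v - VEx) +
                ggabE * SG * (v - VIn);
        gL = gLE; EL = ELE; Cm = CmE; Vth = VthE; Vr = VrE;
      } else {
        I_syn = gextI * sext[i] * (v - VEx) +
                gampI * drv_a * (v - VEx) +
                gnmdI * Bv * drv_n * (v - VEx) +
                ggabI * SG * (v - VIn);
        gL = gLI; EL = ELI; Cm = CmI; Vth = VthI; Vr = VrI;
      }

      double vnew = v + dt_ms * (-gL * (v - EL) - I_syn) / (1000.0 * Cm);
      if (!(vnew > -200.0 && vnew < 100.0))
        stop("membrane potential diverged (dt = %f ms is too coarse)", dt_ms);

      if (vnew >= Vth) {
        vnew = Vr;
        refr[i] = isE ? refE : refI;
        if (isE) { sampa[i] += 1.0; xnmda[i] += 1.0; }
        else sgaba[i - nE] += 1.0;
        const int bin = std::min((int)t, n_bins - 1);
        counts(bin, pool) += 1;
        if (record_spikes) { sp_t.push_back(t); sp_id.push_back(i + 1); }
      }
      V[i] = vnew;
    }
  }

  List out = List::create(_["counts"] = counts);
  if (record_spikes) {
    out["spike_times"] = NumericVector(sp_t.begin(), sp_t.end());
    out["spike_ids"] = IntegerVector(sp_id.begin(), sp_id.end());
  }
  return out;
}
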