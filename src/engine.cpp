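#include <Rcpp.h>
#include <vector>
#include <cmath>
#include "rates.h"
#include "tables.h"

using namespace Rcpp;
using namespace blafear;

// table-backed intrinsic currents (same formulas as membrane_currents)
static inline double currents_tab(const RateTables& tabs, int type, double V,
                                  const double* g, const double* p) {
  const double gNa = p[0], ENa = p[1], gK = p[2], EK = p[3],
               gL = p[4], EL = p[5];
  switch (type) {
    case TYPE_VIP: {
      double m = tabs.minf(TYPE_VIP, V);
      double h = g[0], n = g[1], a = g[2], b = g[3];
      return gNa * m * m * m * h * (V - ENa) + gK * n * n * (V - EK) +
             gL * (V - EL) + p[6] * a * a * a * b * (V - EK);
    }
    case TYPE_SOM: {
      double m = g[0], h = g[1], n = g[2], hf = g[3], hs = g[4], pp = g[5];
      double n2 = n * n;
      return gNa * m * m * m * h * (V - ENa) + gK * n2 * n2 * (V - EK) +
             gL * (V - EL) + p[7] * (0.65 * hf + 0.35 * hs) * (V - p[8]) +
             p[9] * pp * (V - ENa);
    }
    case TYPE_PV: {
      double m = g[0], h = g[1], n = g[2];
      double n2 = n * n;
      return gNa * m * m * m * h * (V - ENa) + gK * n2 * n2 * (V - EK) +
             gL * (V - EL);
    }
    default: {
      double m = tabs.minf(TYPE_E, V);
      double h = g[0], n = g[1];
      double n2 = n * n;
      return gNa * m * m * m * h * (V - ENa) + gK * n2 * n2 * (V - EK) +
             gL * (V - EL);
    }
  }
}

// ---- single-point evaluators backing the R module surface -----------------

// [[Rcpp::export]]
NumericMatrix gate_kinetics_cpp(int type, double V) {
  NumericMatrix out(N_GATE_SLOTS, 2);
  std::fill(out.begin(), out.end(), NA_REAL);
  double xinf[N_GATE_SLOTS], tau[N_GATE_SLOTS];
  for (int i = 0; i < N_GATE_SLOTS; ++i) { xinf[i] = NA_REAL; tau[i] = NA_REAL; }
  gate_kinetics(type, V, xinf, tau);
  for (int i = 0; i < n_gates(type); ++i) { out(i, 0) = xinf[i]; out(i, 1) = tau[i]; }
  return out;
}

// [[Rcpp::export]]
double minf_inst_cpp(int type, double V) { return minf_inst(type, V); }

// [[Rcpp::export]]
NumericVector membrane_currents_cpp(int type, double V, NumericVector gates,
                                    NumericVector params) {
  double cur[6];
  int nc = membrane_currents(type, V, gates.begin(), params.begin(), cur);
  NumericVector out(nc);
  for (int i = 0; i < nc; ++i) out[i] = cur[i];
  return out;
}

// [[Rcpp::export]]
double open_rate_cpp(int form, double Vpre) { return open_rate(form, Vpre); }

// ---- network simulation ----------------------------------------------------

struct PulseTrack {
  const double* ev;
  int n, idx;
  double width;
  // virtual presynaptic voltage: 0 mV while a pulse is active, -70 otherwise
  double voltage(double t) {
    for (int k = idx; k < n; ++k) {
      if (ev[k] > t) break;
      if (t < ev[k] + width) return 0.0;
    }
    return -70.0;
  }
  void advance(double t) {
    while (idx < n && ev[idx] + width <= t) ++idx;
  }
};

// Coupled HH network, classical RK4 with per-step frozen Gaussian noise.
// State: V (per cell), gating slots (per cell), synaptic gates (per synapse).
// Plasticity (pair-based STDP with exponentially decaying traces) is applied
// between integration steps at detected spikes.
// [[Rcpp::export]]
List run_network_cpp(IntegerVector cell_type, NumericMatrix cell_params,
                     NumericVector v0, NumericMatrix iapp_sched,
                     IntegerVector syn_pre, IntegerVector syn_post,
                     IntegerVector syn_form, NumericVector syn_g,
                     NumericVector syn_E, NumericVector syn_tau,
                     IntegerVector syn_lfp, IntegerVector syn_rule,
                     NumericMatrix rules, List unit_events, double pulse_width,
                     double dt, double t_end, int v_every, int lfp_every,
                     int g_every, double spike_thr, double refractory,
                     bool noise_on) {
  const int nc = cell_type.size();
  const int ns = syn_pre.size();
  const int nu = unit_events.size();
  const int n_steps = (int)std::lround(t_end / dt);

  // plastic synapse bookkeeping
  std::vector<int> plastic_idx;          // synapse index of each plastic synapse
  for (int j = 0; j < ns; ++j) if (syn_rule[j] >= 0) plastic_idx.push_back(j);
  const int np = (int)plastic_idx.size();
  std::vector<double> trP(np, 0.0), trM(np, 0.0);
  std::vector<std::vector<int> > pre_map(nc), post_map(nc);
  for (int q = 0; q < np; ++q) {
    int j = plastic_idx[q];
    pre_map[syn_pre[j]].push_back(q);
    post_map[syn_post[j]].push_back(q);
  }
  std::vector<double> fP(rules.nrow()), fM(rules.nrow());
  for (int r = 0; r < rules.nrow(); ++r) {
    fP[r] = std::exp(-dt / rules(r, 2));
    fM[r] = std::exp(-dt / rules(r, 3));
  }
  std::vector<double> gsyn(syn_g.begin(), syn_g.end());  // live conductances

  // virtual input units
  std::vector<PulseTrack> units(nu);
  std::vector<NumericVector> keep_ev(nu);
  for (int u = 0; u < nu; ++u) {
    keep_ev[u] = as<NumericVector>(unit_events[u]);
    units[u].ev = keep_ev[u].begin();
    units[u].n = keep_ev[u].size();
    units[u].idx = 0;
    units[u].width = pulse_width;
  }

  const RateTables tabs;

  // per-cell parameter rows, contiguous
  std::vector<double> par(nc * 12);
  for (int i = 0; i < nc; ++i)
    for (int k = 0; k < 12; ++k) par[i * 12 + k] = cell_params(i, k);

  // state
  std::vector<double> V(v0.begin(), v0.end());
  std::vector<double> G(nc * N_GATE_SLOTS, 0.0);
  for (int i = 0; i < nc; ++i) {
    double xinf[N_GATE_SLOTS], tau[N_GATE_SLOTS];
    gate_kinetics(cell_type[i], V[i], xinf, tau);
    for (int k = 0; k < n_gates(cell_type[i]); ++k) G[i * N_GATE_SLOTS + k] = xinf[k];
  }
  std::vector<double> S(ns, 0.0);
  std::vector<double> inoise(nc, 0.0);

  // scratch for RK4
  const int nV = nc, nG = nc * N_GATE_SLOTS;
  std::vector<double> kV(4 * nV), kG(4 * nG), kS(4 * ns);
  std::vector<double> tV(nV), tG(nG), tS(ns), isyn(nc);

  // applied-current schedule
  int phase = 0;
  const int n_phase = iapp_sched.nrow();

  // recording
  const int n_vrec = n_steps / v_every + 1;
  NumericMatrix Vrec(n_vrec, nc);
  NumericVector Vtime(n_vrec);
  for (int i = 0; i < nc; ++i) Vrec(0, i) = V[i];
  Vtime[0] = 0.0;
  int vrow = 1;

  const int n_lrec = n_steps / lfp_every;
  NumericMatrix Lrec(n_lrec, 10);
  NumericVector Ltime(n_lrec);
  double lacc[10] = {0};
  int lrow = 0, lcount = 0;

  const int n_grec = n_steps / g_every + 1;
  NumericMatrix Grec(np > 0 ? n_grec : 0, np);
  NumericVector Gtime(np > 0 ? n_grec : 0);
  int grow = 0;
  if (np > 0) {
    for (int q = 0; q < np; ++q) Grec(0, q) = gsyn[plastic_idx[q]];
    Gtime[0] = 0.0;
    grow = 1;
  }

  std::vector<std::vector<double> > spikes(nc);
  std::vector<double> last_spike(nc, -1e18);
  std::vector<double> Vold(nc);

  const double c_rk[4] = {0.0, 0.5, 0.5, 1.0};

  for (int step = 0; step < n_steps; ++step) {
    double t = step * dt;
    while (phase + 1 < n_phase && t >= iapp_sched(phase, 1) - 1e-9) ++phase;

    if (noise_on) {
      for (int i = 0; i < nc; ++i)
        inoise[i] = par[i * 12 + 10] * R::norm_rand();
    }
    for (int u = 0; u < nu; ++u) units[u].advance(t);
    for (int i = 0; i < nc; ++i) Vold[i] = V[i];

    // four RK4 stages on the deterministic field + frozen noise
    for (int st = 0; st < 4; ++st) {
      double ts = t + c_rk[st] * dt;
      const double *pV, *pG, *pS;
      if (st == 0) { pV = V.data(); pG = G.data(); pS = S.data(); }
      else {
        double w = (st == 3) ? dt : 0.5 * dt;
        int prev = st - 1;
        for (int i = 0; i < nV; ++i) tV[i] = V[i] + w * kV[prev * nV + i];
        for (int i = 0; i < nG; ++i) tG[i] = G[i] + w * kG[prev * nG + i];
        for (int i = 0; i < ns; ++i) tS[i] = S[i] + w * kS[prev * ns + i];
        pV = tV.data(); pG = tG.data(); pS = tS.data();
      }
      std::fill(isyn.begin(), isyn.end(), 0.0);
      for (int j = 0; j < ns; ++j) {
        int pre = syn_pre[j];
        double Vpre = (pre < nc) ? pV[pre] : units[pre - nc].voltage(ts);
        double s = pS[j];
        kS[st * ns + j] = tabs.open(syn_form[j], Vpre) * (1.0 - s) - s / syn_tau[j];
        isyn[syn_post[j]] += gsyn[j] * s * (pV[syn_post[j]] - syn_E[j]);
      }
      for (int i = 0; i < nc; ++i) {
        int ty = cell_type[i];
        double xinf[N_GATE_SLOTS], tau[N_GATE_SLOTS];
        tabs.gates(ty, pV[i], xinf, tau);
        int ng = n_gates(ty);
        for (int k = 0; k < ng; ++k)
          kG[st * nG + i * N_GATE_SLOTS + k] =
              (xinf[k] - pG[i * N_GATE_SLOTS + k]) / tau[k];
        double imem = currents_tab(tabs, ty, pV[i], pG + i * N_GATE_SLOTS,
                                   par.data() + i * 12);
        kV[st * nV + i] = (-imem - isyn[i] + iapp_sched(phase, 2 + i) +
                           inoise[i]) / par[i * 12 + 11];
      }
    }

    for (int i = 0; i < nV; ++i)
      V[i] += dt / 6.0 * (kV[i] + 2 * kV[nV + i] + 2 * kV[2 * nV + i] + kV[3 * nV + i]);
    for (int i = 0; i < nG; ++i) {
      G[i] += dt / 6.0 * (kG[i] + 2 * kG[nG + i] + 2 * kG[2 * nG + i] + kG[3 * nG + i]);
      if (G[i] < 0.0) G[i] = 0.0; else if (G[i] > 1.0) G[i] = 1.0;
    }
    for (int i = 0; i < ns; ++i) {
      S[i] += dt / 6.0 * (kS[i] + 2 * kS[ns + i] + 2 * kS[2 * ns + i] + kS[3 * ns + i]);
      if (S[i] < 0.0) S[i] = 0.0; else if (S[i] > 1.0) S[i] = 1.0;
    }

    double tnew = t + dt;
    for (int i = 0; i < nc; ++i) {
      if (!std::isfinite(V[i]))
        stop("simulation diverged at t = %f ms (cell %d)", tnew, i + 1);
    }

    // STDP traces decay continuously between spikes
    for (int q = 0; q < np; ++q) {
      int r = syn_rule[plastic_idx[q]];
      trP[q] *= fP[r];
      trM[q] *= fM[r];
    }

    // spike detection (upward crossing with refractory) + plasticity events
    std::vector<int> fired;
    for (int i = 0; i < nc; ++i) {
      if (Vold[i] < spike_thr && V[i] >= spike_thr &&
          tnew - last_spike[i] >= refractory) {
        last_spike[i] = tnew;
        spikes[i].push_back(tnew);
        fired.push_back(i);
      }
    }
    if (np > 0 && !fired.empty()) {
      // presynaptic updates first, then postsynaptic (documented ordering)
      for (size_t f = 0; f < fired.size(); ++f) {
        int c = fired[f];
        for (size_t a = 0; a < pre_map[c].size(); ++a) {
          int q = pre_map[c][a], j = plastic_idx[q], r = syn_rule[j];
          gsyn[j] += trM[q];
          if (gsyn[j] < 0.0) gsyn[j] = 0.0;
          trP[q] += rules(r, 0);
        }
      }
      for (size_t f = 0; f < fired.size(); ++f) {
        int c = fired[f];
        for (size_t a = 0; a < post_map[c].size(); ++a) {
          int q = post_map[c][a], j = plastic_idx[q], r = syn_rule[j];
          gsyn[j] += trP[q];
          if (gsyn[j] > rules(r, 4)) gsyn[j] = rules(r, 4);
          trM[q] -= rules(r, 1);
        }
      }
    }

    // LFP component accumulation (boxcar over lfp_every steps).
    // Columns: AMPA, GABA, D, H, NaP and their absolute-value versions.
    double comp[10] = {0};
    for (int j = 0; j < ns; ++j) {
      if (syn_lfp[j] == 0) continue;
      double I = gsyn[j] * S[j] * (V[syn_post[j]] - syn_E[j]);
      int c0 = (syn_lfp[j] == 1) ? 0 : 1;
      comp[c0] += I;
      comp[5 + c0] += std::fabs(I);
    }
    for (int i = 0; i < nc; ++i) {
      const double* pp = par.data() + i * 12;
      const double* gg = G.data() + i * N_GATE_SLOTS;
      if (cell_type[i] == TYPE_VIP) {
        double I = pp[6] * gg[2] * gg[2] * gg[2] * gg[3] * (V[i] - pp[3]);
        comp[2] += I; comp[7] += std::fabs(I);
      } else if (cell_type[i] == TYPE_SOM) {
        double IH = pp[7] * (0.65 * gg[3] + 0.35 * gg[4]) * (V[i] - pp[8]);
        double IP = pp[9] * gg[5] * (V[i] - pp[1]);
        comp[3] += IH; comp[8] += std::fabs(IH);
        comp[4] += IP; comp[9] += std::fabs(IP);
      }
    }
    for (int k = 0; k < 10; ++k) lacc[k] += comp[k];
    if (++lcount == lfp_every) {
      for (int k = 0; k < 10; ++k) { Lrec(lrow, k) = lacc[k] / lfp_every; lacc[k] = 0.0; }
      Ltime[lrow] = tnew;
      ++lrow; lcount = 0;
    }

    if ((step + 1) % v_every == 0) {
      for (int i = 0; i < nc; ++i) Vrec(vrow, i) = V[i];
      Vtime[vrow] = tnew;
      ++vrow;
    }
    if (np > 0 && (step + 1) % g_every == 0) {
      for (int q = 0; q < np; ++q) Grec(grow, q) = gsyn[plastic_idx[q]];
      Gtime[grow] = tnew;
      ++grow;
    }
  }

  List spk(nc);
  for (int i = 0; i < nc; ++i) spk[i] = wrap(spikes[i]);
  NumericVector gfin(ns);
  for (int j = 0; j < ns; ++j) gfin[j] = gsyn[j];
  NumericVector Pfin(np), Mfin(np);
  for (int q = 0; q < np; ++q) { Pfin[q] = trP[q]; Mfin[q] = trM[q]; }

  return List::create(
      _["time_v"] = Vtime, _["V"] = Vrec, _["spikes"] = spk,
      _["lfp_time"] = Ltime, _["lfp"] = Lrec,
      _["g_time"] = Gtime, _["g"] = Grec,
      _["syn_g_final"] = gfin, _["P_final"] = Pfin, _["M_final"] = Mfin,
      _["final_V"] = wrap(V));
}
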