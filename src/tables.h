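#ifndef BLAFEAR_TABLES_H
#define BLAFEAR_TABLES_H

#include <vector>
#include "rates.h"

// Voltage-indexed lookup tables (linear interpolation, 0.01 mV grid) for the
// gate kinetics, instantaneous sodium activation and synaptic open rates.
// Built once per simulation; removes all transcendental calls from the RK4
// inner loop.

namespace blafear {

struct RateTables {
  double vmin, vmax, dv, inv_dv;
  int n;
  // [type][slot*2 + {0:xinf,1:tau}][i]
  std::vector<std::vector<double> > gate_tab;  // 4 types x 12 columns packed
  std::vector<std::vector<double> > minf_tab;  // VIP, E
  std::vector<std::vector<double> > open_tab;  // 4 forms

  RateTables(double lo = -130.0, double hi = 70.0, double step = 0.01) {
    vmin = lo; vmax = hi; dv = step; inv_dv = 1.0 / step;
    n = (int)((hi - lo) / step) + 2;
    gate_tab.assign(4, std::vector<double>());
    for (int ty = 0; ty < 4; ++ty) {
      gate_tab[ty].assign((size_t)n * 12, 0.0);
      for (int i = 0; i < n; ++i) {
        double V = vmin + i * dv;
        double xinf[N_GATE_SLOTS] = {0}, tau[N_GATE_SLOTS] = {1, 1, 1, 1, 1, 1};
        gate_kinetics(ty, V, xinf, tau);
        for (int k = 0; k < N_GATE_SLOTS; ++k) {
          gate_tab[ty][(size_t)i * 12 + 2 * k] = xinf[k];
          gate_tab[ty][(size_t)i * 12 + 2 * k + 1] = tau[k];
        }
      }
    }
    minf_tab.assign(2, std::vector<double>(n));
    open_tab.assign(4, std::vector<double>(n));
    for (int i = 0; i < n; ++i) {
      double V = vmin + i * dv;
      minf_tab[0][i] = minf_inst(TYPE_VIP, V);
      minf_tab[1][i] = minf_inst(TYPE_E, V);
      for (int f = 0; f < 4; ++f) open_tab[f][i] = open_rate(f, V);
    }
  }

  inline void locate(double V, int& i, double& w) const {
    if (V < vmin) V = vmin;
    if (V > vmax) V = vmax;
    double u = (V - vmin) * inv_dv;
    i = (int)u;
    if (i >= n - 1) i = n - 2;
    w = u - i;
  }

  inline void gates(int type, double V, double* xinf, double* tau) const {
    int i; double w;
    locate(V, i, w);
    const double* a = &gate_tab[type][(size_t)i * 12];
    const double* b = a + 12;
    for (int k = 0; k < N_GATE_SLOTS; ++k) {
      xinf[k] = a[2 * k] + w * (b[2 * k] - a[2 * k]);
      tau[k] = a[2 * k + 1] + w * (b[2 * k + 1] - a[2 * k + 1]);
    }
  }

  inline double minf(int type, double V) const {
    int i; double w;
    locate(V, i, w);
    const std::vector<double>& t = minf_tab[type == TYPE_VIP ? 0 : 1];
    return t[i] + w * (t[i + 1] - t[i]);
  }

  inline double open(int form, double V) const {
    int i; double w;
    locate(V, i, w);
    const std::vector<double>& t = open_tab[form];
    return t[i] + w * (t[i + 1] - t[i]);
  }
};

}  // namespace blafear

#endif
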