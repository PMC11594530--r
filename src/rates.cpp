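#include <cmath>
#include "rates.h"

namespace blafear {

// x/(1 - exp(-x/b)): removable singularity at x = 0 handled by series.
static inline double vtrap(double x, double b) {
  if (std::fabs(x / b) < 1e-6) return b + 0.5 * x;
  return x / (1.0 - std::exp(-x / b));
}

static inline double sig(double x) { return 1.0 / (1.0 + std::exp(x)); }

int n_gates(int type) {
  switch (type) {
    case TYPE_VIP: return 4;
    case TYPE_SOM: return 6;
    case TYPE_PV:  return 3;
    default:       return 2;
  }
}

double minf_inst(int type, double V) {
  if (type == TYPE_VIP) {
    return sig(-(V + 24.0) / 11.5);
  }
  // E cells: m_inf from the alpha/beta rates
  double am = 0.1 * vtrap(V + 35.0, 10.0);
  double bm = 4.0 * std::exp(-(V + 60.0) / 18.0);
  return am / (am + bm);
}

void gate_kinetics(int type, double V, double* xinf, double* tau) {
  switch (type) {
    case TYPE_VIP: {
      // 0 h, 1 n, 2 a, 3 b
      xinf[0] = sig((V + 58.3) / 6.7);
      tau[0]  = 0.5 + 14.0 / (1.0 + std::exp((V + 60.0) / 12.0));
      xinf[1] = sig(-(V + 12.4) / 6.8);
      tau[1]  = (0.087 + 11.4 / (1.0 + std::exp((V + 14.6) / 8.6))) *
                (0.087 + 11.4 / (1.0 + std::exp(-(V - 1.3) / 18.7)));
      xinf[2] = sig(-(V + 50.0) / 20.0);
      tau[2]  = 2.0;
      xinf[3] = sig((V + 70.0) / 6.0);
      tau[3]  = 150.0;
      break;
    }
    case TYPE_SOM: {
      // 0 m, 1 h, 2 n, 3 hf, 4 hs, 5 p
      double am = 0.1 * vtrap(V + 23.0, 10.0);
      double bm = 4.0 * std::exp(-(V + 48.0) / 18.0);
      xinf[0] = am / (am + bm);  tau[0] = 1.0 / (am + bm);
      double ah = 0.07 * std::exp(-(V + 37.0) / 20.0);
      double bh = 1.0 / (std::exp(-0.1 * (V + 7.0)) + 1.0);
      xinf[1] = ah / (ah + bh);  tau[1] = 1.0 / (ah + bh);
      double an = 0.01 * vtrap(V + 27.0, 10.0);
      double bn = 0.125 * std::exp(-(V + 37.0) / 80.0);
      xinf[2] = an / (an + bn);  tau[2] = 1.0 / (an + bn);
      // H-current fast/slow inactivation (O-LM forms)
      xinf[3] = sig((V + 79.2) / 9.78);
      tau[3]  = 0.51 / (std::exp((V - 1.7) / 10.0) +
                        std::exp(-(V + 340.0) / 52.0)) + 1.0;
      xinf[4] = std::pow(sig((V + 2.83) / 15.9), 58.0);
      tau[4]  = 5.6 / (std::exp((V - 1.7) / 14.0) +
                       std::exp(-(V + 260.0) / 43.0)) + 1.0;
      // persistent sodium activation
      xinf[5] = sig(-(V + 38.0) / 6.5);
      tau[5]  = 0.15;
      break;
    }
    case TYPE_PV: {
      // 0 m, 1 h, 2 n
      double am = 0.32 * vtrap(V + 54.0, 4.0);
      double bm = 0.28 * vtrap(-(V + 27.0), 5.0);
      xinf[0] = am / (am + bm);  tau[0] = 1.0 / (am + bm);
      double ah = 0.128 * std::exp(-(V + 50.0) / 18.0);
      double bh = 4.0 / (1.0 + std::exp(-(V + 27.0) / 5.0));
      xinf[1] = ah / (ah + bh);  tau[1] = 1.0 / (ah + bh);
      double an = 0.032 * vtrap(V + 52.0, 5.0);
      double bn = 0.5 * std::exp(-(V + 57.0) / 40.0);
      xinf[2] = an / (an + bn);  tau[2] = 1.0 / (an + bn);
      break;
    }
    default: {
      // E: 0 h, 1 n (m instantaneous). The h/n rates carry the source
      // model's temperature factor phi = 5 (scales both alpha and beta, so
      // it shortens tau and leaves x_inf untouched); with it the cell fires
      // at its ~11 Hz natural frequency at the baseline drive.
      const double phi = 5.0;
      double ah = 0.07 * std::exp(-(V + 58.0) / 20.0);
      double bh = 1.0 / (std::exp(-0.1 * (V + 28.0)) + 1.0);
      xinf[0] = ah / (ah + bh);  tau[0] = 1.0 / (phi * (ah + bh));
      double an = 0.01 * vtrap(V + 34.0, 10.0);
      double bn = 0.125 * std::exp(-(V + 44.0) / 80.0);
      xinf[1] = an / (an + bn);  tau[1] = 1.0 / (phi * (an + bn));
      break;
    }
  }
}

int membrane_currents(int type, double V, const double* g, const double* p,
                      double* cur) {
  const double gNa = p[0], ENa = p[1], gK = p[2], EK = p[3],
               gL = p[4], EL = p[5];
  switch (type) {
    case TYPE_VIP: {
      double m = minf_inst(TYPE_VIP, V);
      double h = g[0], n = g[1], a = g[2], b = g[3];
      cur[0] = gNa * m * m * m * h * (V - ENa);
      cur[1] = gK * n * n * (V - EK);  // two activation gates for VIP
      cur[2] = gL * (V - EL);
      cur[3] = p[6] * a * a * a * b * (V - EK);  // D-current
      return 4;
    }
    case TYPE_SOM: {
      double m = g[0], h = g[1], n = g[2], hf = g[3], hs = g[4], pp = g[5];
      cur[0] = gNa * m * m * m * h * (V - ENa);
      cur[1] = gK * n * n * n * n * (V - EK);
      cur[2] = gL * (V - EL);
      cur[3] = p[7] * (0.65 * hf + 0.35 * hs) * (V - p[8]);  // H
      cur[4] = p[9] * pp * (V - ENa);                        // NaP
      return 5;
    }
    case TYPE_PV: {
      double m = g[0], h = g[1], n = g[2];
      cur[0] = gNa * m * m * m * h * (V - ENa);
      cur[1] = gK * n * n * n * n * (V - EK);
      cur[2] = gL * (V - EL);
      return 3;
    }
    default: {
      double m = minf_inst(TYPE_E, V);
      double h = g[0], n = g[1];
      cur[0] = gNa * m * m * m * h * (V - ENa);
      cur[1] = gK * n * n * n * n * (V - EK);
      cur[2] = gL * (V - EL);
      return 3;
    }
  }
}

double open_rate(int form, double Vpre) {
  switch (form) {
    case 0: return 2.0 * (1.0 + std::tanh(Vpre / 4.0));   // VIP GABAa
    case 1: return 7.5 * (1.0 + std::tanh(Vpre / 0.1));   // PV GABAa
    case 2: return 2.5 * (1.0 + std::tanh(Vpre / 0.1));   // SOM GABAa
    default: return 5.0 * (1.0 + std::tanh(Vpre / 4.0));  // AMPA
  }
}

}  // namespace blafear
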