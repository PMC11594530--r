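#ifndef BLAFEAR_RATES_H
#define BLAFEAR_RATES_H

// Cell type codes shared with R: 0 = VIP, 1 = SOM, 2 = PV, 3 = E
// Gate slot layout (fixed 6 slots per cell):
//   VIP: 0 h, 1 n, 2 a, 3 b            (m instantaneous)
//   SOM: 0 m, 1 h, 2 n, 3 hf, 4 hs, 5 p
//   PV : 0 m, 1 h, 2 n
//   E  : 0 h, 1 n                      (m instantaneous)
// Param columns (12): 0 gNa, 1 ENa, 2 gK, 3 EK, 4 gL, 5 EL,
//                     6 gD, 7 gH, 8 EH, 9 gP, 10 noise_amp, 11 cm

namespace blafear {

const int TYPE_VIP = 0, TYPE_SOM = 1, TYPE_PV = 2, TYPE_E = 3;
const int N_GATE_SLOTS = 6;

int n_gates(int type);

// Steady states and time constants for all gate slots of a cell type.
// Unused slots are left untouched.
void gate_kinetics(int type, double V, double* xinf, double* tau);

// Instantaneous sodium activation m_inf for VIP and E ("first formulation").
double minf_inst(int type, double V);

// Intrinsic membrane currents, outward-positive convention
// I = gbar * gates * (V - E).  Fills cur[]:
//   VIP: 0 Na, 1 K, 2 L, 3 D
//   SOM: 0 Na, 1 K, 2 L, 3 H, 4 P
//   PV/E: 0 Na, 1 K, 2 L
// Returns the number of currents written; total = sum(cur).
int membrane_currents(int type, double V, const double* g, const double* p,
                      double* cur);

// GABAa/AMPA open-rate forms: 0 VIP, 1 PV, 2 SOM, 3 AMPA (E)
double open_rate(int form, double Vpre);

}  // namespace blafear

#endif
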