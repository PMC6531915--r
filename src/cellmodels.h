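#ifndef IVTLAB_CELLMODELS_H
#define IVTLAB_CELLMODELS_H

#include <cmath>

// ten Tusscher & Panfilov (2006) human ventricular myocyte model and the
// MacCannell et al. (2007) active fibroblast model.
//
// State layout (myocyte, NV_MYO doubles):
//  0 V    (mV)      7 fCass      14 Cai  (mM)
//  1 m              8 r          15 CaSR (mM)
//  2 h              9 s          16 CaSS (mM)
//  3 j             10 Xr1        17 Nai  (mM)
//  4 d             11 Xr2        18 Ki   (mM)
//  5 f             12 Xs
//  6 f2            13 Rbar (SR release adaptation)
//
// Fibroblast state (NV_FIB doubles): 0 Vf (mV), 1 r, 2 s.
//
// Currents are normalized per unit capacitance (pA/pF), dV/dt in mV/ms:
//   dV/dt = -(I_ion + I_stim)

namespace ivt {

constexpr int NV_MYO = 19;
constexpr int NV_FIB = 3;
constexpr int N_GATES = 12;  // gates updated by Rush-Larsen (indices 1..12)

constexpr double R_GAS = 8314.472;   // mJ/(mol K)
constexpr double T_ABS = 310.0;      // K
constexpr double F_CONST = 96485.3415;
constexpr double RTONF = R_GAS * T_ABS / F_CONST;  // ~26.7137 mV
constexpr double CM_MYO_PF = 185.0;  // whole-cell capacitance, pF
constexpr double CM_FIB_PF = 6.3;    // pF

enum Layer { LAYER_ENDO = 0, LAYER_M = 1, LAYER_EPI = 2 };

struct Phenotype {
  int layer;        // Layer enum
  double sc_gna;    // multiplicative scalings on maximal conductances
  double sc_gcal;
  double sc_gkr;
  double sc_gks;
};

// ---- model constants (TP06 published values) ----
namespace tp {
constexpr double Ko = 5.4, Nao = 140.0, Cao = 2.0;
constexpr double Vc = 0.016404, Vsr = 0.001094, Vss = 0.00005468;
constexpr double Bufc = 0.2, Kbufc = 0.001;
constexpr double Bufsr = 10.0, Kbufsr = 0.3;
constexpr double Bufss = 0.4, Kbufss = 0.00025;
constexpr double Vmaxup = 0.006375, Kup = 0.00025;
constexpr double Vrel = 0.102, k1p = 0.15, k2p = 0.045, k3 = 0.060,
                 k4 = 0.005, EC = 1.5, maxsr = 2.5, minsr = 1.0;
constexpr double Vleak = 0.00036, Vxfer = 0.0038;
constexpr double GNa = 14.838, GK1 = 5.405, GKr = 0.153;
constexpr double GCaL = 0.0000398;
constexpr double pKNa = 0.03;
constexpr double knak = 2.724, KmK = 1.0, KmNa = 40.0;
constexpr double knaca = 1000.0, KmNai = 87.5, KmCa = 1.38, ksat = 0.1,
                 ncx_gamma = 0.35, ncx_alpha = 2.5;
constexpr double GpCa = 0.1238, KpCa = 0.0005, GpK = 0.0146;
constexpr double GbNa = 0.00029, GbCa = 0.000592;
constexpr double CAP = 0.185;  // uF/cm^2 scaling used in the published code
inline double Gto(int layer) { return layer == LAYER_ENDO ? 0.073 : 0.294; }
inline double GKs(int layer) { return layer == LAYER_M ? 0.098 : 0.392; }
}  // namespace tp

// Published resting initial condition.
inline void tp06_initial_state(double* s) {
  s[0] = -86.2;    s[1] = 0.0;      s[2] = 0.75;   s[3] = 0.75;
  s[4] = 0.0;      s[5] = 1.0;      s[6] = 1.0;    s[7] = 1.0;
  s[8] = 0.0;      s[9] = 1.0;      s[10] = 0.0;   s[11] = 1.0;
  s[12] = 0.0;     s[13] = 1.0;     s[14] = 0.00007; s[15] = 1.3;
  s[16] = 0.00007; s[17] = 7.67;    s[18] = 138.3;
}

// Voltage-dependent gate kinetics: steady state and time constant (ms).
inline void tp06_gate_rates(double V, int layer, double* ginf, double* gtau) {
  // m
  double mi = 1.0 / ((1.0 + std::exp((-56.86 - V) / 9.03)) *
                     (1.0 + std::exp((-56.86 - V) / 9.03)));
  double am = 1.0 / (1.0 + std::exp((-60.0 - V) / 5.0));
  double bm = 0.1 / (1.0 + std::exp((V + 35.0) / 5.0)) +
              0.1 / (1.0 + std::exp((V - 50.0) / 200.0));
  ginf[0] = mi; gtau[0] = am * bm;
  // h
  double hi = 1.0 / ((1.0 + std::exp((V + 71.55) / 7.43)) *
                     (1.0 + std::exp((V + 71.55) / 7.43)));
  double ah, bh;
  if (V >= -40.0) {
    ah = 0.0;
    bh = 0.77 / (0.13 * (1.0 + std::exp(-(V + 10.66) / 11.1)));
  } else {
    ah = 0.057 * std::exp(-(V + 80.0) / 6.8);
    bh = 2.7 * std::exp(0.079 * V) + 3.1e5 * std::exp(0.3485 * V);
  }
  ginf[1] = hi; gtau[1] = 1.0 / (ah + bh);
  // j
  double aj, bj;
  if (V >= -40.0) {
    aj = 0.0;
    bj = 0.6 * std::exp(0.057 * V) / (1.0 + std::exp(-0.1 * (V + 32.0)));
  } else {
    aj = (-2.5428e4 * std::exp(0.2444 * V) - 6.948e-6 * std::exp(-0.04391 * V)) *
         (V + 37.78) / (1.0 + std::exp(0.311 * (V + 79.23)));
    bj = 0.02424 * std::exp(-0.01052 * V) /
         (1.0 + std::exp(-0.1378 * (V + 40.14)));
  }
  ginf[2] = hi; gtau[2] = 1.0 / (aj + bj);
  // d
  double di = 1.0 / (1.0 + std::exp((-8.0 - V) / 7.5));
  double ad = 1.4 / (1.0 + std::exp((-35.0 - V) / 13.0)) + 0.25;
  double bd = 1.4 / (1.0 + std::exp((V + 5.0) / 5.0));
  double cd = 1.0 / (1.0 + std::exp((50.0 - V) / 20.0));
  ginf[3] = di; gtau[3] = ad * bd + cd;
  // f
  double fi = 1.0 / (1.0 + std::exp((V + 20.0) / 7.0));
  double af = 1102.5 * std::exp(-((V + 27.0) * (V + 27.0)) / 225.0);
  double bf = 200.0 / (1.0 + std::exp((13.0 - V) / 10.0));
  double cf = 180.0 / (1.0 + std::exp((V + 30.0) / 10.0)) + 20.0;
  ginf[4] = fi; gtau[4] = af + bf + cf;
  // f2
  double f2i = 0.67 / (1.0 + std::exp((V + 35.0) / 7.0)) + 0.33;
  double af2 = 562.0 * std::exp(-((V + 27.0) * (V + 27.0)) / 240.0);
  double bf2 = 31.0 / (1.0 + std::exp((25.0 - V) / 10.0));
  double cf2 = 80.0 / (1.0 + std::exp((V + 30.0) / 10.0));
  ginf[5] = f2i; gtau[5] = af2 + bf2 + cf2;
  // r
  double ri = 1.0 / (1.0 + std::exp((20.0 - V) / 6.0));
  ginf[6] = ri;
  gtau[6] = 9.5 * std::exp(-(V + 40.0) * (V + 40.0) / 1800.0) + 0.8;
  // s (layer-dependent)
  if (layer == LAYER_ENDO) {
    ginf[7] = 1.0 / (1.0 + std::exp((V + 28.0) / 5.0));
    gtau[7] = 1000.0 * std::exp(-(V + 67.0) * (V + 67.0) / 1000.0) + 8.0;
  } else {
    ginf[7] = 1.0 / (1.0 + std::exp((V + 20.0) / 5.0));
    gtau[7] = 85.0 * std::exp(-(V + 45.0) * (V + 45.0) / 320.0) +
              5.0 / (1.0 + std::exp((V - 20.0) / 5.0)) + 3.0;
  }
  // Xr1
  double xr1i = 1.0 / (1.0 + std::exp((-26.0 - V) / 7.0));
  double axr1 = 450.0 / (1.0 + std::exp((-45.0 - V) / 10.0));
  double bxr1 = 6.0 / (1.0 + std::exp((V + 30.0) / 11.5));
  ginf[8] = xr1i; gtau[8] = axr1 * bxr1;
  // Xr2
  double xr2i = 1.0 / (1.0 + std::exp((V + 88.0) / 24.0));
  double axr2 = 3.0 / (1.0 + std::exp((-60.0 - V) / 20.0));
  double bxr2 = 1.12 / (1.0 + std::exp((V - 60.0) / 20.0));
  ginf[9] = xr2i; gtau[9] = axr2 * bxr2;
  // Xs
  double xsi = 1.0 / (1.0 + std::exp((-5.0 - V) / 14.0));
  double axs = 1400.0 / std::sqrt(1.0 + std::exp((5.0 - V) / 6.0));
  double bxs = 1.0 / (1.0 + std::exp((V - 35.0) / 15.0));
  ginf[10] = xsi; gtau[10] = axs * bxs + 80.0;
  // slot 11 unused at the voltage level (fCass depends on CaSS); fill
  // neutral values so table code can loop uniformly.
  ginf[11] = 0.0; gtau[11] = 1.0;
}

// fCass gate kinetics (depends on subspace calcium, not voltage).
inline void tp06_fcass_rate(double CaSS, double* inf, double* tau) {
  double q = CaSS / 0.05;
  *inf = 0.6 / (1.0 + q * q) + 0.4;
  *tau = 80.0 / (1.0 + q * q) + 2.0;
}

// Total ionic current (pA/pF) and concentration derivatives for the
// current state; gate derivatives are returned separately.
// dconc: derivatives of state slots 13..18 (Rbar, Cai, CaSR, CaSS, Nai, Ki)
// The stimulus current enters the Ki balance as in the published code.
inline double tp06_currents(const double* s, const Phenotype& ph,
                            double Istim, double* dconc) {
  using namespace tp;
  const double V = s[0], m = s[1], h = s[2], j = s[3], d = s[4], f = s[5],
               f2 = s[6], fCass = s[7], r = s[8], sg = s[9], Xr1 = s[10],
               Xr2 = s[11], Xs = s[12], Rbar = s[13], Cai = s[14],
               CaSR = s[15], CaSS = s[16], Nai = s[17], Ki = s[18];
  const double Ek = RTONF * std::log(Ko / Ki);
  const double Ena = RTONF * std::log(Nao / Nai);
  const double Eks = RTONF * std::log((Ko + pKNa * Nao) / (Ki + pKNa * Nai));
  const double Eca = 0.5 * RTONF * std::log(Cao / Cai);

  const double gna = GNa * ph.sc_gna;
  const double gcal = GCaL * ph.sc_gcal;
  const double gkr = GKr * ph.sc_gkr;
  const double gks = GKs(ph.layer) * ph.sc_gks;
  const double gto = Gto(ph.layer);

  const double INa = gna * m * m * m * h * j * (V - Ena);

  double ICaL;
  {
    double z = 2.0 * (V - 15.0) * F_CONST / (R_GAS * T_ABS);
    double num = 0.25 * CaSS * std::exp(z) - Cao;
    double pref;
    if (std::fabs(z) < 1e-7) {
      pref = 2.0 * F_CONST;  // limit of 4*(V-15)*F^2/(RT) / (e^z - 1)
    } else {
      pref = 4.0 * (V - 15.0) * F_CONST * F_CONST / (R_GAS * T_ABS) /
             (std::exp(z) - 1.0);
    }
    ICaL = gcal * d * f * f2 * fCass * pref * num;
  }

  const double Ito = gto * r * sg * (V - Ek);
  const double IKr = gkr * std::sqrt(Ko / 5.4) * Xr1 * Xr2 * (V - Ek);
  const double IKs = gks * Xs * Xs * (V - Eks);

  double IK1;
  {
    double ak1 = 0.1 / (1.0 + std::exp(0.06 * (V - Ek - 200.0)));
    double bk1 = (3.0 * std::exp(0.0002 * (V - Ek + 100.0)) +
                  std::exp(0.1 * (V - Ek - 10.0))) /
                 (1.0 + std::exp(-0.5 * (V - Ek)));
    IK1 = GK1 * ak1 / (ak1 + bk1) * (V - Ek);
  }

  const double INaK =
      knak * (Ko / (Ko + KmK)) * (Nai / (Nai + KmNa)) /
      (1.0 + 0.1245 * std::exp(-0.1 * V * F_CONST / (R_GAS * T_ABS)) +
       0.0353 * std::exp(-V * F_CONST / (R_GAS * T_ABS)));

  double INaCa;
  {
    double e1 = std::exp(ncx_gamma * V * F_CONST / (R_GAS * T_ABS));
    double e2 = std::exp((ncx_gamma - 1.0) * V * F_CONST / (R_GAS * T_ABS));
    INaCa = knaca *
            (1.0 / (KmNai * KmNai * KmNai + Nao * Nao * Nao)) *
            (1.0 / (KmCa + Cao)) * (1.0 / (1.0 + ksat * e2)) *
            (e1 * Nai * Nai * Nai * Cao - e2 * Nao * Nao * Nao * Cai * ncx_alpha);
  }

  const double IpCa = GpCa * Cai / (KpCa + Cai);
  const double IpK = GpK * (V - Ek) / (1.0 + std::exp((25.0 - V) / 5.98));
  const double IbNa = GbNa * (V - Ena);
  const double IbCa = GbCa * (V - Eca);

  const double Iion = INa + ICaL + Ito + IKr + IKs + IK1 + INaK + INaCa +
                      IpCa + IpK + IbNa + IbCa;

  // calcium dynamics
  double kCaSR = maxsr - (maxsr - minsr) / (1.0 + (EC / CaSR) * (EC / CaSR));
  double kk1 = k1p / kCaSR;
  double kk2 = k2p * kCaSR;
  double dRbar = k4 * (1.0 - Rbar) - kk2 * CaSS * Rbar;
  double O = kk1 * CaSS * CaSS * Rbar / (k3 + kk1 * CaSS * CaSS);
  double Irel = Vrel * O * (CaSR - CaSS);
  double Ileak = Vleak * (CaSR - Cai);
  double Iup = Vmaxup / (1.0 + (Kup * Kup) / (Cai * Cai));
  double Ixfer = Vxfer * (CaSS - Cai);

  const double invVcF2 = 1.0 / (2.0 * Vc * F_CONST);
  const double invVcF = 1.0 / (Vc * F_CONST);
  const double invVssF2 = 1.0 / (2.0 * Vss * F_CONST);

  double bufc_fac = 1.0 / (1.0 + Bufc * Kbufc / ((Cai + Kbufc) * (Cai + Kbufc)));
  double bufsr_fac =
      1.0 / (1.0 + Bufsr * Kbufsr / ((CaSR + Kbufsr) * (CaSR + Kbufsr)));
  double bufss_fac =
      1.0 / (1.0 + Bufss * Kbufss / ((CaSS + Kbufss) * (CaSS + Kbufss)));

  double dCai = bufc_fac * (-(IbCa + IpCa - 2.0 * INaCa) * invVcF2 * CAP -
                            (Iup - Ileak) * (Vsr / Vc) + Ixfer);
  double dCaSR = bufsr_fac * (Iup - Irel - Ileak);
  double dCaSS = bufss_fac * (-Ixfer * (Vc / Vss) + Irel * (Vsr / Vss) -
                              ICaL * invVssF2 * CAP);
  double dNai = -(INa + IbNa + 3.0 * INaK + 3.0 * INaCa) * invVcF * CAP;
  double dKi = -(Istim + IK1 + Ito + IKr + IKs - 2.0 * INaK + IpK) * invVcF * CAP;

  dconc[0] = dRbar;
  dconc[1] = dCai;
  dconc[2] = dCaSR;
  dconc[3] = dCaSS;
  dconc[4] = dNai;
  dconc[5] = dKi;
  return Iion;
}

// Full RHS (for oracle integrators and the exported derivative op).
inline void tp06_rhs(const double* s, const Phenotype& ph, double Istim,
                     double* ds) {
  double dconc[6];
  double Iion = tp06_currents(s, ph, Istim, dconc);
  double ginf[N_GATES], gtau[N_GATES];
  tp06_gate_rates(s[0], ph.layer, ginf, gtau);
  double fci, fct;
  tp06_fcass_rate(s[16], &fci, &fct);
  ds[0] = -(Iion + Istim);
  // gates: state slots 1..12 map to rate slots {0..10} + fCass
  const int map[12] = {0, 1, 2, 3, 4, 5, -1, 6, 7, 8, 9, 10};
  for (int g = 0; g < 12; ++g) {
    int slot = g + 1;
    if (slot == 7) {
      ds[slot] = (fci - s[slot]) / fct;
    } else {
      int k = map[g];
      ds[slot] = (ginf[k] - s[slot]) / gtau[k];
    }
  }
  ds[13] = dconc[0];
  ds[14] = dconc[1];
  ds[15] = dconc[2];
  ds[16] = dconc[3];
  ds[17] = dconc[4];
  ds[18] = dconc[5];
}

// ---- MacCannell (2007) active fibroblast ----
namespace fb {
constexpr double Ko = 5.4, Kif = 129.4349, Naif = 8.5547, Nao = 140.0;
constexpr double GKv = 0.25;      // nS/pF
constexpr double GK1 = 0.4822;    // nS/pF
constexpr double GbNa = 0.0095;   // nS/pF
constexpr double INaKmax = 2.002; // pA/pF
constexpr double KmK = 1.0, KmNa = 11.0, Vrev = -150.0;
}  // namespace fb

inline void fib_initial_state(double* s) {
  s[0] = -49.6;  // near published resting potential; relaxes on integration
  s[1] = 0.0;
  s[2] = 1.0;
}

inline void fib_gate_rates(double V, double* rinf, double* rtau, double* sinf,
                           double* stau) {
  *rinf = 1.0 / (1.0 + std::exp(-(V + 20.0) / 11.0));
  double xr = (V + 20.0) / 25.9;
  *rtau = 20.3 + 138.0 * std::exp(-xr * xr);
  *sinf = 1.0 / (1.0 + std::exp((V + 23.0) / 2.7));
  double xs = (V + 23.0) / 22.7;
  *stau = 1574.0 + 5268.0 * std::exp(-xs * xs);
}

inline double fib_current(const double* s) {
  using namespace fb;
  const double V = s[0], r = s[1], sg = s[2];
  const double EK = RTONF * std::log(Ko / Kif);
  const double ENa = RTONF * std::log(Nao / Naif);
  double IKv = GKv * r * sg * (V - EK);
  double ak1 = 0.1 / (1.0 + std::exp(0.06 * (V - EK - 200.0)));
  double bk1 = (3.0 * std::exp(0.0002 * (V - EK + 100.0)) +
                std::exp(0.1 * (V - EK - 10.0))) /
               (1.0 + std::exp(-0.5 * (V - EK)));
  double IK1 = GK1 * ak1 / (ak1 + bk1) * (V - EK);
  double na15 = std::pow(Naif, 1.5);
  double INaK = INaKmax * (Ko / (Ko + KmK)) * (na15 / (na15 + std::pow(KmNa, 1.5))) *
                (V - Vrev) / (V + 200.0);
  double IbNa = GbNa * (V - ENa);
  return IKv + IK1 + INaK + IbNa;
}

inline void fib_rhs(const double* s, double Icoup, double* ds) {
  double ri, rt, si, st;
  fib_gate_rates(s[0], &ri, &rt, &si, &st);
  ds[0] = -(fib_current(s) + Icoup);
  ds[1] = (ri - s[1]) / rt;
  ds[2] = (si - s[2]) / st;
}

}  // namespace ivt

#endif
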