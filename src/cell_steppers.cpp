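#include <Rcpp.h>
#include <vector>
#include "cellmodels.h"

using namespace Rcpp;
using namespace ivt;

namespace {

// Lookup table of voltage-gate kinetics for one layer at a fixed base dt.
// Stores steady states and exp(-dt/tau) factors on a uniform V grid with
// linear interpolation; substeps of dt/n reuse the tabulated factor via
// pow(e, 1/n) (rare: only during upstrokes).
struct GateLut {
  double vmin, vmax, dv, inv_dv;
  int n;
  int layer;
  double dt;
  std::vector<double> ginf;   // n * 11
  std::vector<double> edt;    // n * 11

  void build(int layer_, double dt_) {
    layer = layer_;
    dt = dt_;
    vmin = -150.0;
    vmax = 150.0;
    dv = 0.05;
    inv_dv = 1.0 / dv;
    n = static_cast<int>((vmax - vmin) * inv_dv) + 2;
    ginf.resize(static_cast<size_t>(n) * 11);
    edt.resize(static_cast<size_t>(n) * 11);
    double gi[N_GATES], gt[N_GATES];
    for (int k = 0; k < n; ++k) {
      double V = vmin + k * dv;
      tp06_gate_rates(V, layer, gi, gt);
      for (int g = 0; g < 11; ++g) {
        ginf[static_cast<size_t>(k) * 11 + g] = gi[g];
        edt[static_cast<size_t>(k) * 11 + g] = std::exp(-dt / gt[g]);
      }
    }
  }

  // Rush-Larsen update of the 11 voltage gates in state s for substep dt/nsub.
  inline void update_gates(double* s, int nsub) const {
    double V = s[0];
    if (V < vmin) V = vmin;
    if (V > vmax) V = vmax;
    double u = (V - vmin) * inv_dv;
    int k = static_cast<int>(u);
    if (k > n - 2) k = n - 2;
    double w = u - k;
    const double* gi0 = &ginf[static_cast<size_t>(k) * 11];
    const double* gi1 = &ginf[static_cast<size_t>(k + 1) * 11];
    const double* e0 = &edt[static_cast<size_t>(k) * 11];
    const double* e1 = &edt[static_cast<size_t>(k + 1) * 11];
    // state slots for the 11 voltage gates, in rate order
    static const int slot[11] = {1, 2, 3, 4, 5, 6, 8, 9, 10, 11, 12};
    for (int g = 0; g < 11; ++g) {
      double inf = gi0[g] + w * (gi1[g] - gi0[g]);
      double e = e0[g] + w * (e1[g] - e0[g]);
      if (nsub > 1) e = std::pow(e, 1.0 / nsub);
      int sl = slot[g];
      s[sl] = inf - (inf - s[sl]) * e;
    }
  }
};

// One operator-split reaction step of length dt for a myocyte node:
// Rush-Larsen gates + forward-Euler V/concentrations, with adaptive
// substepping limited to dvmax mV of free-running dV per substep.
inline void myocyte_react_step(double* s, const Phenotype& ph,
                               const GateLut& lut, double dt, double Istim,
                               double dvmax, int maxsub) {
  double dconc[6];
  double Iion = tp06_currents(s, ph, Istim, dconc);
  double dV = -(Iion + Istim);
  int nsub = 1;
  double adv = std::fabs(dV) * dt;
  if (adv > dvmax) {
    nsub = static_cast<int>(std::ceil(adv / dvmax));
    if (nsub > maxsub) nsub = maxsub;
  }
  double h = dt / nsub;
  for (int k = 0; k < nsub; ++k) {
    if (k > 0) {
      Iion = tp06_currents(s, ph, Istim, dconc);
      dV = -(Iion + Istim);
    }
    lut.update_gates(s, nsub);
    double fci, fct;
    tp06_fcass_rate(s[16], &fci, &fct);
    s[7] = fci - (fci - s[7]) * std::exp(-h / fct);
    for (int c = 0; c < 6; ++c) s[13 + c] += h * dconc[c];
    s[0] += h * dV;
  }
}

inline void fibroblast_react_step(double* s, double dt, double Icoup) {
  double ri, rt, si, st;
  fib_gate_rates(s[0], &ri, &rt, &si, &st);
  double dV = -(fib_current(s) + Icoup);
  s[1] = ri - (ri - s[1]) * std::exp(-dt / rt);
  s[2] = si - (si - s[2]) * std::exp(-dt / st);
  s[0] += dt * dV;
}

}  // namespace

static Phenotype make_phenotype(int layer, NumericVector scalings) {
  if (scalings.size() != 4) stop("scalings must have length 4");
  Phenotype ph;
  ph.layer = layer;
  ph.sc_gna = scalings[0];
  ph.sc_gcal = scalings[1];
  ph.sc_gkr = scalings[2];
  ph.sc_gks = scalings[3];
  return ph;
}

// [[Rcpp::export(name = ".cpp_tp06_initial")]]
NumericVector cpp_tp06_initial() {
  NumericVector s(NV_MYO);
  tp06_initial_state(REAL(s));
  return s;
}

// [[Rcpp::export(name = ".cpp_fib_initial")]]
NumericVector cpp_fib_initial() {
  NumericVector s(NV_FIB);
  fib_initial_state(REAL(s));
  return s;
}

// [[Rcpp::export(name = ".cpp_myocyte_rhs")]]
NumericVector cpp_myocyte_rhs(NumericVector state, int layer,
                              NumericVector scalings, double istim) {
  if (state.size() != NV_MYO) stop("state must have length %d", NV_MYO);
  for (int i = 0; i < state.size(); ++i)
    if (!R_finite(state[i])) stop("non-finite state");
  Phenotype ph = make_phenotype(layer, scalings);
  NumericVector ds(NV_MYO);
  tp06_rhs(REAL(state), ph, istim, REAL(ds));
  return ds;
}

// [[Rcpp::export(name = ".cpp_fibroblast_rhs")]]
NumericVector cpp_fibroblast_rhs(NumericVector state, double icoup) {
  if (state.size() != NV_FIB) stop("state must have length %d", NV_FIB);
  for (int i = 0; i < state.size(); ++i)
    if (!R_finite(state[i])) stop("non-finite state");
  NumericVector ds(NV_FIB);
  fib_rhs(REAL(state), icoup, REAL(ds));
  return ds;
}

// Paced single-cell simulation with the production integrator
// (Rush-Larsen + adaptive forward Euler). Stimuli fire at
// t = k * bcl for k = 0..nbeats-1. Records every `stride` steps.
// [[Rcpp::export(name = ".cpp_pace_cell")]]
List cpp_pace_cell(NumericVector init, int layer, NumericVector scalings,
                   double bcl, int nbeats, double extra, double dt,
                   double stim_amp, double stim_dur, int stride,
                   double dvmax, int maxsub) {
  Phenotype ph = make_phenotype(layer, scalings);
  GateLut lut;
  lut.build(layer, dt);
  std::vector<double> s(NV_MYO);
  if (init.size() == NV_MYO)
    std::copy(init.begin(), init.end(), s.begin());
  else
    tp06_initial_state(s.data());
  double duration = bcl * nbeats + extra;
  int nsteps = static_cast<int>(std::ceil(duration / dt));
  int nrec = nsteps / stride + 1;
  NumericVector time(nrec);
  NumericMatrix traj(nrec, NV_MYO);
  int rec = 0;
  for (int step = 0; step <= nsteps; ++step) {
    double t = step * dt;
    if (step % stride == 0 && rec < nrec) {
      time[rec] = t;
      for (int v = 0; v < NV_MYO; ++v) traj(rec, v) = s[v];
      ++rec;
    }
    if (step == nsteps) break;
    double Istim = 0.0;
    if (nbeats > 0 && bcl > 0) {
      double tm = t - std::floor(t / bcl) * bcl;
      int beat = static_cast<int>(t / bcl);
      if (beat < nbeats && tm < stim_dur) Istim = stim_amp;
    }
    myocyte_react_step(s.data(), ph, lut, dt, Istim, dvmax, maxsub);
    if (!std::isfinite(s[0])) stop("state became non-finite at t = %f ms", t);
  }
  NumericVector fin(NV_MYO);
  std::copy(s.begin(), s.end(), fin.begin());
  return List::create(_["time"] = time, _["state"] = traj, _["final"] = fin);
}

// Fixed-step classic RK4 oracle on the exact RHS (no lookup tables).
// [[Rcpp::export(name = ".cpp_pace_cell_rk4")]]
List cpp_pace_cell_rk4(NumericVector init, int layer, NumericVector scalings,
                       double bcl, int nbeats, double extra, double dt,
                       double stim_amp, double stim_dur, int stride) {
  Phenotype ph = make_phenotype(layer, scalings);
  std::vector<double> s(NV_MYO), k1(NV_MYO), k2(NV_MYO), k3(NV_MYO),
      k4(NV_MYO), tmp(NV_MYO);
  if (init.size() == NV_MYO)
    std::copy(init.begin(), init.end(), s.begin());
  else
    tp06_initial_state(s.data());
  double duration = bcl * nbeats + extra;
  long nsteps = static_cast<long>(std::ceil(duration / dt));
  long nrec = nsteps / stride + 1;
  NumericVector time(nrec);
  NumericMatrix traj(nrec, NV_MYO);
  long rec = 0;
  auto istim_at = [&](double t) {
    if (nbeats <= 0 || bcl <= 0) return 0.0;
    double tm = t - std::floor(t / bcl) * bcl;
    int beat = static_cast<int>(t / bcl);
    return (beat < nbeats && tm < stim_dur) ? stim_amp : 0.0;
  };
  for (long step = 0; step <= nsteps; ++step) {
    double t = step * dt;
    if (step % stride == 0 && rec < nrec) {
      time[rec] = t;
      for (int v = 0; v < NV_MYO; ++v) traj(rec, v) = s[v];
      ++rec;
    }
    if (step == nsteps) break;
    double I1 = istim_at(t), I2 = istim_at(t + 0.5 * dt), I4 = istim_at(t + dt);
    tp06_rhs(s.data(), ph, I1, k1.data());
    for (int v = 0; v < NV_MYO; ++v) tmp[v] = s[v] + 0.5 * dt * k1[v];
    tp06_rhs(tmp.data(), ph, I2, k2.data());
    for (int v = 0; v < NV_MYO; ++v) tmp[v] = s[v] + 0.5 * dt * k2[v];
    tp06_rhs(tmp.data(), ph, I2, k3.data());
    for (int v = 0; v < NV_MYO; ++v) tmp[v] = s[v] + dt * k3[v];
    tp06_rhs(tmp.data(), ph, I4, k4.data());
    for (int v = 0; v < NV_MYO; ++v)
      s[v] += dt / 6.0 * (k1[v] + 2.0 * k2[v] + 2.0 * k3[v] + k4[v]);
    // clamp gates against roundoff excursions
    for (int g = 1; g <= 12; ++g) {
      if (s[g] < 0.0) s[g] = 0.0;
      if (s[g] > 1.0) s[g] = 1.0;
    }
    if (!std::isfinite(s[0])) stop("state became non-finite at t = %f ms", t);
  }
  NumericVector fin(NV_MYO);
  std::copy(s.begin(), s.end(), fin.begin());
  return List::create(_["time"] = time, _["state"] = traj, _["final"] = fin);
}

// Myocyte-fibroblast pair coupled by a gap conductance ggap (nS).
// Coupling current density: myocyte receives ggap*(Vm-Vf)/Cm_myo, the
// fibroblast ggap*(Vf-Vm)/Cm_fib (pA/pF each).
// [[Rcpp::export(name = ".cpp_pace_pair")]]
List cpp_pace_pair(NumericVector initm, NumericVector initf, int layer,
                   NumericVector scalings, double ggap, double bcl, int nbeats,
                   double extra, double dt, double stim_amp, double stim_dur,
                   int stride, double dvmax, int maxsub) {
  Phenotype ph = make_phenotype(layer, scalings);
  GateLut lut;
  lut.build(layer, dt);
  std::vector<double> sm(NV_MYO), sf(NV_FIB);
  if (initm.size() == NV_MYO)
    std::copy(initm.begin(), initm.end(), sm.begin());
  else
    tp06_initial_state(sm.data());
  if (initf.size() == NV_FIB)
    std::copy(initf.begin(), initf.end(), sf.begin());
  else
    fib_initial_state(sf.data());
  double duration = bcl * nbeats + extra;
  long nsteps = static_cast<long>(std::ceil(duration / dt));
  long nrec = nsteps / stride + 1;
  NumericVector time(nrec), vm(nrec), vf(nrec);
  long rec = 0;
  for (long step = 0; step <= nsteps; ++step) {
    double t = step * dt;
    if (step % stride == 0 && rec < nrec) {
      time[rec] = t;
      vm[rec] = sm[0];
      vf[rec] = sf[0];
      ++rec;
    }
    if (step == nsteps) break;
    double Istim = 0.0;
    if (nbeats > 0 && bcl > 0) {
      double tm = t - std::floor(t / bcl) * bcl;
      int beat = static_cast<int>(t / bcl);
      if (beat < nbeats && tm < stim_dur) Istim = stim_amp;
    }
    double icm = ggap * (sm[0] - sf[0]) / CM_MYO_PF;
    double icf = ggap * (sf[0] - sm[0]) / CM_FIB_PF;
    myocyte_react_step(sm.data(), ph, lut, dt, Istim + icm, dvmax, maxsub);
    fibroblast_react_step(sf.data(), dt, icf);
    if (!std::isfinite(sm[0]) || !std::isfinite(sf[0]))
      stop("state became non-finite at t = %f ms", t);
  }
  NumericVector finm(NV_MYO), finf(NV_FIB);
  std::copy(sm.begin(), sm.end(), finm.begin());
  std::copy(sf.begin(), sf.end(), finf.begin());
  return List::create(_["time"] = time, _["vm"] = vm, _["vf"] = vf,
                      _["final_myo"] = finm, _["final_fib"] = finf);
}

// Integrate a resting fibroblast (for fixed-point and rest-finding tests).
// [[Rcpp::export(name = ".cpp_relax_fibroblast")]]
NumericVector cpp_relax_fibroblast(NumericVector init, double duration,
                                   double dt) {
  std::vector<double> s(NV_FIB);
  if (init.size() == NV_FIB)
    std::copy(init.begin(), init.end(), s.begin());
  else
    fib_initial_state(s.data());
  long nsteps = static_cast<long>(std::ceil(duration / dt));
  for (long i = 0; i < nsteps; ++i) fibroblast_react_step(s.data(), dt, 0.0);
  NumericVector out(NV_FIB);
  std::copy(s.begin(), s.end(), out.begin());
  return out;
}
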