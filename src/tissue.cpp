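#include <Rcpp.h>
#include <vector>
#include <cmath>
#include "cellmodels.h"

using namespace Rcpp;
using namespace ivt;

namespace {

struct Lut {
  double vmin = -150.0, vmax = 150.0, dv = 0.05, inv_dv = 20.0;
  int n = 0;
  std::vector<double> ginf, edt;
  void build(int layer, double dt) {
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

// Voltage-factor tables for the expensive current terms; the inward
// rectifier is tabulated against V - E_K.
struct CurLut {
  double vmin = -150.0, dv = 0.05, inv_dv = 20.0;
  int n = 0;
  std::vector<double> inak, ncx1, ncx2, calz, calpref, ipk;
  double kmin = -250.0, kdv = 0.1, inv_kdv = 10.0;
  int nk = 0;
  std::vector<double> reck1;
  void build() {
    using namespace tp;
    n = static_cast<int>((150.0 - vmin) * inv_dv) + 2;
    inak.resize(n); ncx1.resize(n); ncx2.resize(n);
    calz.resize(n); calpref.resize(n); ipk.resize(n);
    const double FRT = F_CONST / (R_GAS * T_ABS);
    for (int k = 0; k < n; ++k) {
      double V = vmin + k * dv;
      inak[k] = 1.0 / (1.0 + 0.1245 * std::exp(-0.1 * V * FRT) +
                       0.0353 * std::exp(-V * FRT));
      ncx1[k] = std::exp(ncx_gamma * V * FRT);
      ncx2[k] = std::exp((ncx_gamma - 1.0) * V * FRT);
      double z = 2.0 * (V - 15.0) * FRT;
      calz[k] = std::exp(z);
      // 4 (V-15) F^2 / RT / (e^z - 1), with its V -> 15 limit
      calpref[k] = std::fabs(z) < 1e-7
          ? 2.0 * F_CONST
          : 4.0 * (V - 15.0) * F_CONST * F_CONST / (R_GAS * T_ABS) /
                (calz[k] - 1.0);
      ipk[k] = 1.0 / (1.0 + std::exp((25.0 - V) / 5.98));
    }
    nk = static_cast<int>((250.0 - kmin) * inv_kdv) + 2;
    reck1.resize(nk);
    for (int k = 0; k < nk; ++k) {
      double d = kmin + k * kdv;
      double ak1 = 0.1 / (1.0 + std::exp(0.06 * (d - 200.0)));
      double bk1 = (3.0 * std::exp(0.0002 * (d + 100.0)) +
                    std::exp(0.1 * (d - 10.0))) /
                   (1.0 + std::exp(-0.5 * d));
      reck1[k] = ak1 / (ak1 + bk1);
    }
  }
  inline double at(const std::vector<double>& tab, double V) const {
    if (V < vmin) V = vmin;
    double u = (V - vmin) * inv_dv;
    int k = static_cast<int>(u);
    if (k > n - 2) k = n - 2;
    double w = u - k;
    return tab[k] + w * (tab[k + 1] - tab[k]);
  }
  inline double k1(double d) const {
    if (d < kmin) d = kmin;
    double u = (d - kmin) * inv_kdv;
    int k = static_cast<int>(u);
    if (k > nk - 2) k = nk - 2;
    double w = u - k;
    return reck1[k] + w * (reck1[k + 1] - reck1[k]);
  }
};

// tp06_currents with tabulated voltage factors (identical model, ~1e-6
// interpolation error); reversal potentials passed in (updated lazily).
inline double tp06_currents_fast(const double* s, const Phenotype& ph,
                                 const CurLut& cl, double Istim,
                                 const double* rev, double* dconc) {
  using namespace tp;
  const double V = s[0], m = s[1], h = s[2], j = s[3], d = s[4], f = s[5],
               f2 = s[6], fCass = s[7], r = s[8], sg = s[9], Xr1 = s[10],
               Xr2 = s[11], Xs = s[12], Rbar = s[13], Cai = s[14],
               CaSR = s[15], CaSS = s[16], Nai = s[17];
  const double Ek = rev[0], Ena = rev[1], Eks = rev[2], Eca = rev[3];
  const double gna = GNa * ph.sc_gna;
  const double gcal = GCaL * ph.sc_gcal;
  const double gkr = GKr * ph.sc_gkr;
  const double gks = GKs(ph.layer) * ph.sc_gks;
  const double gto = Gto(ph.layer);

  const double INa = gna * m * m * m * h * j * (V - Ena);
  const double ICaL = gcal * d * f * f2 * fCass * cl.at(cl.calpref, V) *
                      (0.25 * CaSS * cl.at(cl.calz, V) - Cao);
  const double Ito = gto * r * sg * (V - Ek);
  const double IKr = gkr * std::sqrt(Ko / 5.4) * Xr1 * Xr2 * (V - Ek);
  const double IKs = gks * Xs * Xs * (V - Eks);
  const double IK1 = GK1 * cl.k1(V - Ek) * (V - Ek);
  const double INaK =
      knak * (Ko / (Ko + KmK)) * (Nai / (Nai + KmNa)) * cl.at(cl.inak, V);
  const double INaCa =
      knaca * (1.0 / (KmNai * KmNai * KmNai + Nao * Nao * Nao)) *
      (1.0 / (KmCa + Cao)) * (1.0 / (1.0 + ksat * cl.at(cl.ncx2, V))) *
      (cl.at(cl.ncx1, V) * Nai * Nai * Nai * Cao -
       cl.at(cl.ncx2, V) * Nao * Nao * Nao * Cai * ncx_alpha);
  const double IpCa = GpCa * Cai / (KpCa + Cai);
  const double IpK = GpK * (V - Ek) * cl.at(cl.ipk, V);
  const double IbNa = GbNa * (V - Ena);
  const double IbCa = GbCa * (V - Eca);
  const double Iion = INa + ICaL + Ito + IKr + IKs + IK1 + INaK + INaCa +
                      IpCa + IpK + IbNa + IbCa;

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
  dconc[0] = dRbar;
  dconc[1] = bufc_fac * (-(IbCa + IpCa - 2.0 * INaCa) * invVcF2 * CAP -
                         (Iup - Ileak) * (Vsr / Vc) + Ixfer);
  dconc[2] = bufsr_fac * (Iup - Irel - Ileak);
  dconc[3] = bufss_fac * (-Ixfer * (Vc / Vss) + Irel * (Vsr / Vss) -
                          ICaL * invVssF2 * CAP);
  dconc[4] = -(INa + IbNa + 3.0 * INaK + 3.0 * INaCa) * invVcF * CAP;
  dconc[5] = -(Istim + IK1 + Ito + IKr + IKs - 2.0 * INaK + IpK) * invVcF * CAP;
  return Iion;
}

inline void update_reversals(const double* s, double* rev) {
  using namespace tp;
  rev[0] = RTONF * std::log(Ko / s[18]);
  rev[1] = RTONF * std::log(Nao / s[17]);
  rev[2] = RTONF * std::log((Ko + pKNa * Nao) / (s[18] + pKNa * s[17]));
  rev[3] = 0.5 * RTONF * std::log(Cao / s[14]);
}

inline void react_myocyte(double* s, const Phenotype& ph, const Lut& lut,
                          const CurLut& cl, double* rev, double dt,
                          double Istim, double dvmax, int maxsub) {
  double dconc[6];
  double Iion = tp06_currents_fast(s, ph, cl, Istim, rev, dconc);
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
      Iion = tp06_currents_fast(s, ph, cl, Istim, rev, dconc);
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

inline void react_fibroblast(double* s, double dt, double Istim) {
  double ri, rt, si, st;
  fib_gate_rates(s[0], &ri, &rt, &si, &st);
  double dV = -(fib_current(s) + Istim);
  s[1] = ri - (ri - s[1]) * std::exp(-dt / rt);
  s[2] = si - (si - s[2]) * std::exp(-dt / st);
  s[0] += dt * dV;
}

// Per-node activation tracker for one measurement window.
struct ApdTracker {
  // phase: 0 pre-activation, 1 activated, 2 threshold frozen, 3 done
  signed char phase = 0;
  float vmin_pre = 1e9f;
  float vpeak = -1e9f;
  double t_dvdt = NA_REAL;
  float dvdtmax = -1e9f;
  double t_up = NA_REAL;
  float v90 = 0.0f;
  double apd = NA_REAL;
};

}  // namespace

// Monodomain operator-splitting time stepper.
//
// Arguments:
//   ap, ai, ax : CSC slots of the symmetric implicit system A = M + c*K
//   mass       : lumped mass vector (length n)
//   node_type  : per node, 0..5 = myocyte (layer + 3*remodeled), 6 = fibroblast
//   scalings   : 6 x 4 matrix of conductance scalings per phenotype index
//   init       : n x 19 state matrix, or empty (resting initial states)
//   t0         : simulation clock at entry (ms); stimulus times are absolute
//   nsteps, dt : step count and step (ms)
//   stim_*     : stimulus trains (node lists are 1-based)
//   windows    : m x 2 matrix of [start, end) LAT/APD measurement windows
//   probes     : 1-based node indices recorded every probe_stride steps
//   snap_nodes : 1-based node indices snapshotted every snap_stride steps
//                (snap_stride = 0 disables)
//   watch      : 1-based node indices for 0 mV upstroke crossing logs
//   cg_tol     : relative residual tolerance; cg_maxit iteration cap
// [[Rcpp::export(name = ".cpp_run_monodomain")]]
List cpp_run_monodomain(IntegerVector ap, IntegerVector ai, NumericVector ax,
                        NumericVector mass, IntegerVector node_type,
                        NumericMatrix scalings, NumericMatrix init, double t0,
                        int nsteps, double dt, List stim_nodes,
                        NumericMatrix stim_spec, NumericMatrix windows,
                        IntegerVector probes, int probe_stride,
                        IntegerVector snap_nodes, int snap_stride,
                        IntegerVector watch, double cg_tol, int cg_maxit,
                        double dvmax, int maxsub, IntegerVector mp,
                        IntegerVector mi, NumericVector mx, IntegerVector kp,
                        IntegerVector ki, NumericVector kx, double rhs_kfac,
                        bool svi, IntegerMatrix elem_nodes, double elem_vol) {
  const int n = mass.size();
  if (node_type.size() != n) stop("node_type length mismatch");

  // phenotype table
  Phenotype phen[6];
  for (int p = 0; p < 6; ++p) {
    phen[p].layer = p % 3;
    phen[p].sc_gna = scalings(p, 0);
    phen[p].sc_gcal = scalings(p, 1);
    phen[p].sc_gkr = scalings(p, 2);
    phen[p].sc_gks = scalings(p, 3);
  }
  Lut luts[3];
  bool lut_built[3] = {false, false, false};
  CurLut clut;
  clut.build();
  for (int i = 0; i < n; ++i) {
    int ty = node_type[i];
    if (ty < 0 || ty > 6) stop("invalid node type");
    if (ty < 6) {
      int lay = ty % 3;
      if (!lut_built[lay]) {
        luts[lay].build(lay, dt);
        lut_built[lay] = true;
      }
    }
  }

  // state
  std::vector<double> S(static_cast<size_t>(n) * NV_MYO);
  if (init.nrow() == n && init.ncol() == NV_MYO) {
    for (int i = 0; i < n; ++i)
      for (int v = 0; v < NV_MYO; ++v)
        S[static_cast<size_t>(i) * NV_MYO + v] = init(i, v);
  } else {
    double sm[NV_MYO], sf[NV_FIB];
    tp06_initial_state(sm);
    fib_initial_state(sf);
    for (int i = 0; i < n; ++i) {
      double* si = &S[static_cast<size_t>(i) * NV_MYO];
      if (node_type[i] == 6) {
        std::fill(si, si + NV_MYO, 0.0);
        for (int v = 0; v < NV_FIB; ++v) si[v] = sf[v];
      } else {
        std::copy(sm, sm + NV_MYO, si);
      }
    }
  }

  // cached reversal potentials (E_K, E_Na, E_Ks, E_Ca), refreshed
  // periodically: intracellular concentrations drift slowly
  std::vector<double> rev(static_cast<size_t>(n) * 4, 0.0);
  auto refresh_reversals = [&]() {
    for (int i = 0; i < n; ++i)
      if (node_type[i] < 6)
        update_reversals(&S[static_cast<size_t>(i) * NV_MYO],
                         &rev[static_cast<size_t>(i) * 4]);
  };
  refresh_reversals();

  // stimulus bookkeeping
  const int nstim = stim_spec.nrow();
  std::vector<std::vector<int>> stimidx(nstim);
  for (int k = 0; k < nstim; ++k) {
    IntegerVector nd = stim_nodes[k];
    stimidx[k].assign(nd.begin(), nd.end());
    for (auto& v : stimidx[k]) {
      if (v < 1 || v > n) stop("stimulus node out of range");
      v -= 1;
    }
  }

  // state-variable interpolation setup: ionic currents evaluated at the
  // 2x2x2 Gauss points of elements whose eight corners share one myocyte
  // phenotype; other elements fall back to nodal (lumped) currents.
  const int ne_svi = svi ? elem_nodes.nrow() : 0;
  std::vector<int> svi_ok(ne_svi, 0);
  std::vector<double> Fion;      // assembled reaction load (current * volume)
  std::vector<double> node_w;    // fallback lumped volume share per node
  double Ngauss[8][8];           // N_a evaluated at Gauss point g
  if (svi) {
    if (elem_nodes.ncol() != 8) stop("elem_nodes must be ne x 8");
    Fion.assign(n, 0.0);
    node_w.assign(n, 0.0);
    const double gp[2] = {0.5 - 0.5 / std::sqrt(3.0), 0.5 + 0.5 / std::sqrt(3.0)};
    int g = 0;
    for (int gz = 0; gz < 2; ++gz)
      for (int gy = 0; gy < 2; ++gy)
        for (int gx = 0; gx < 2; ++gx, ++g)
          for (int a = 0; a < 8; ++a) {
            int ax = a & 1, ay = (a >> 1) & 1, az = (a >> 2) & 1;
            double sx = ax ? gp[gx] : 1.0 - gp[gx];
            double sy = ay ? gp[gy] : 1.0 - gp[gy];
            double sz = az ? gp[gz] : 1.0 - gp[gz];
            Ngauss[g][a] = sx * sy * sz;
          }
    for (int e = 0; e < ne_svi; ++e) {
      int ty0 = node_type[elem_nodes(e, 0) - 1];
      bool ok = ty0 < 6;
      for (int a = 1; a < 8 && ok; ++a)
        if (node_type[elem_nodes(e, a) - 1] != ty0) ok = false;
      svi_ok[e] = ok ? 1 : 0;
      if (!ok)
        for (int a = 0; a < 8; ++a) node_w[elem_nodes(e, a) - 1] += elem_vol / 8.0;
    }
  }

  // trackers
  const int nwin = windows.nrow();
  std::vector<ApdTracker> trk(static_cast<size_t>(n) * nwin);
  std::vector<double> vprev(n), vstim(n, 0.0);
  for (int i = 0; i < n; ++i) vprev[i] = S[static_cast<size_t>(i) * NV_MYO];

  // probe storage
  const int nprobe = probes.size();
  int nprec = probe_stride > 0 ? nsteps / probe_stride + 1 : 0;
  NumericMatrix probe_v(nprec, nprobe);
  NumericVector probe_t(nprec);
  // snapshots
  const int nsnap_nodes = snap_nodes.size();
  int nsrec = snap_stride > 0 ? nsteps / snap_stride + 1 : 0;
  NumericMatrix snap_v(nsrec, snap_stride > 0 ? nsnap_nodes : 0);
  NumericVector snap_t(nsrec);
  // watch crossings
  const int nwatch = watch.size();
  std::vector<std::vector<double>> crossings(nwatch);
  std::vector<signed char> armed(nwatch, 1);

  // CG work vectors
  std::vector<double> b(n), x(n), rres(n), z(n), pvec(n), q(n), dinv(n);
  const int* App = ap.begin();
  const int* Aii = ai.begin();
  const double* Axx = ax.begin();
  for (int j = 0; j < n; ++j) {
    double dj = 0.0;
    for (int k = App[j]; k < App[j + 1]; ++k)
      if (Aii[k] == j) dj = Axx[k];
    if (dj <= 0.0) stop("non-positive diagonal in system matrix");
    dinv[j] = 1.0 / dj;
  }
  auto spmv = [&](const std::vector<double>& v, std::vector<double>& out) {
    // A symmetric: CSC columns double as CSR rows
    for (int j = 0; j < n; ++j) {
      double acc = 0.0;
      for (int k = App[j]; k < App[j + 1]; ++k) acc += Axx[k] * v[Aii[k]];
      out[j] = acc;
    }
  };
  // optional consistent mass matrix for the right-hand side
  const bool consistent_mass = mp.size() == n + 1;
  const int* Mpp = mp.begin();
  const int* Mii = mi.begin();
  const double* Mxx = mx.begin();
  // optional explicit stiffness contribution to the right-hand side
  // (theta-method: b -= rhs_kfac * K v*)
  const bool theta_rhs = kp.size() == n + 1 && rhs_kfac != 0.0;
  const int* Kpp = kp.begin();
  const int* Kii = ki.begin();
  const double* Kxx = kx.begin();
  int cg_itmax_used = 0;

  int prec = 0, srec = 0;
  for (int step = 0; step <= nsteps; ++step) {
    double t = t0 + step * dt;
    if (probe_stride > 0 && step % probe_stride == 0 && prec < nprec) {
      probe_t[prec] = t;
      for (int p = 0; p < nprobe; ++p)
        probe_v(prec, p) = S[static_cast<size_t>(probes[p] - 1) * NV_MYO];
      ++prec;
    }
    if (snap_stride > 0 && step % snap_stride == 0 && srec < nsrec) {
      snap_t[srec] = t;
      for (int p = 0; p < nsnap_nodes; ++p)
        snap_v(srec, p) = S[static_cast<size_t>(snap_nodes[p] - 1) * NV_MYO];
      ++srec;
    }
    if (step == nsteps) break;

    // stimulus currents for this step
    std::fill(vstim.begin(), vstim.end(), 0.0);
    for (int k = 0; k < nstim; ++k) {
      double st0 = stim_spec(k, 0), dur = stim_spec(k, 1),
             amp = stim_spec(k, 2), per = stim_spec(k, 3);
      int cnt = static_cast<int>(stim_spec(k, 4));
      double rel = t - st0;
      if (rel < -1e-9) continue;
      bool on = false;
      if (per > 0.0 && cnt > 1) {
        int rep = static_cast<int>(std::floor(rel / per + 1e-9));
        if (rep < cnt && rel - rep * per < dur - 1e-9) on = true;
      } else {
        if (rel < dur - 1e-9) on = true;
      }
      if (on)
        for (int idx : stimidx[k]) vstim[idx] += amp;
    }

    // reaction step
    if (!svi) {
      for (int i = 0; i < n; ++i) {
        double* si = &S[static_cast<size_t>(i) * NV_MYO];
        int ty = node_type[i];
        if (ty == 6)
          react_fibroblast(si, dt, vstim[i]);
        else
          react_myocyte(si, phen[ty], luts[ty % 3], clut,
                        &rev[static_cast<size_t>(i) * 4], dt, vstim[i],
                        dvmax, maxsub);
      }
    } else {
      // Gauss-point currents from interpolated states
      std::fill(Fion.begin(), Fion.end(), 0.0);
      double sg[NV_MYO], dconc[6];
      for (int e = 0; e < ne_svi; ++e) {
        if (!svi_ok[e]) continue;
        const int i0 = elem_nodes(e, 0) - 1;
        const Phenotype& ph = phen[node_type[i0]];
        for (int g = 0; g < 8; ++g) {
          for (int v = 0; v < NV_MYO; ++v) sg[v] = 0.0;
          for (int a = 0; a < 8; ++a) {
            const double* sa = &S[static_cast<size_t>(elem_nodes(e, a) - 1) * NV_MYO];
            double w = Ngauss[g][a];
            for (int v = 0; v < NV_MYO; ++v) sg[v] += w * sa[v];
          }
          double Ig = tp06_currents(sg, ph, 0.0, dconc);
          for (int a = 0; a < 8; ++a)
            Fion[elem_nodes(e, a) - 1] += (elem_vol / 8.0) * Ngauss[g][a] * Ig;
        }
      }
      // nodal updates: gates/concentrations everywhere; V from the
      // assembled load (plus lumped fallback current and stimulus)
      for (int i = 0; i < n; ++i) {
        double* si = &S[static_cast<size_t>(i) * NV_MYO];
        int ty = node_type[i];
        if (ty == 6) {
          react_fibroblast(si, dt, vstim[i]);
          continue;
        }
        double Ii = tp06_currents(si, phen[ty], vstim[i], dconc);
        luts[ty % 3].update_gates(si, 1);
        double fci, fct;
        tp06_fcass_rate(si[16], &fci, &fct);
        si[7] = fci - (fci - si[7]) * std::exp(-dt / fct);
        for (int c = 0; c < 6; ++c) si[13 + c] += dt * dconc[c];
        double load = Fion[i] + node_w[i] * Ii;
        si[0] += dt * (-(load / mass[i]) - vstim[i]);
      }
    }

    // implicit diffusion: (M + c K) V+ = M V*
    for (int i = 0; i < n; ++i)
      x[i] = S[static_cast<size_t>(i) * NV_MYO];  // warm start
    if (consistent_mass) {
      for (int j = 0; j < n; ++j) {
        double acc = 0.0;
        for (int k = Mpp[j]; k < Mpp[j + 1]; ++k) acc += Mxx[k] * x[Mii[k]];
        b[j] = acc;
      }
    } else {
      for (int i = 0; i < n; ++i) b[i] = mass[i] * x[i];
    }
    if (theta_rhs) {
      for (int j = 0; j < n; ++j) {
        double acc = 0.0;
        for (int k = Kpp[j]; k < Kpp[j + 1]; ++k) acc += Kxx[k] * x[Kii[k]];
        b[j] -= rhs_kfac * acc;
      }
    }
    spmv(x, q);
    double bnorm = 0.0;
    for (int i = 0; i < n; ++i) {
      rres[i] = b[i] - q[i];
      bnorm += b[i] * b[i];
    }
    bnorm = std::sqrt(bnorm);
    if (bnorm < 1e-300) bnorm = 1.0;
    double rz = 0.0;
    for (int i = 0; i < n; ++i) {
      z[i] = dinv[i] * rres[i];
      rz += rres[i] * z[i];
    }
    pvec = z;
    int it = 0;
    double rnorm = 0.0;
    for (int i = 0; i < n; ++i) rnorm += rres[i] * rres[i];
    rnorm = std::sqrt(rnorm);
    while (rnorm / bnorm > cg_tol && it < cg_maxit) {
      spmv(pvec, q);
      double pq = 0.0;
      for (int i = 0; i < n; ++i) pq += pvec[i] * q[i];
      double alpha = rz / pq;
      rnorm = 0.0;
      for (int i = 0; i < n; ++i) {
        x[i] += alpha * pvec[i];
        rres[i] -= alpha * q[i];
        rnorm += rres[i] * rres[i];
      }
      rnorm = std::sqrt(rnorm);
      double rz_new = 0.0;
      for (int i = 0; i < n; ++i) {
        z[i] = dinv[i] * rres[i];
        rz_new += rres[i] * z[i];
      }
      double beta = rz_new / rz;
      rz = rz_new;
      for (int i = 0; i < n; ++i) pvec[i] = z[i] + beta * pvec[i];
      ++it;
    }
    if (rnorm / bnorm > cg_tol)
      stop("conjugate gradient failed to converge at t = %f ms (%d iterations, rel. residual %g)",
           t, it, rnorm / bnorm);
    if (it > cg_itmax_used) cg_itmax_used = it;
    for (int i = 0; i < n; ++i) S[static_cast<size_t>(i) * NV_MYO] = x[i];

    double tnew = t + dt;
    // activation tracking against total per-step dV/dt
    for (int i = 0; i < n; ++i) {
      double v = S[static_cast<size_t>(i) * NV_MYO];
      double dvdt = (v - vprev[i]) / dt;
      for (int w = 0; w < nwin; ++w) {
        if (tnew < windows(w, 0) || tnew >= windows(w, 1)) continue;
        ApdTracker& tk = trk[static_cast<size_t>(i) * nwin + w];
        if (tk.phase == 3) continue;
        if (tk.phase == 0) {
          if (v < tk.vmin_pre) tk.vmin_pre = static_cast<float>(v);
          if (vprev[i] < -40.0 && v >= -40.0) {
            tk.phase = 1;
            tk.t_up = tnew;
          }
        }
        if (tk.phase >= 1) {
          if (dvdt > tk.dvdtmax) {
            tk.dvdtmax = static_cast<float>(dvdt);
            tk.t_dvdt = tnew;
          }
          if (tk.phase == 1) {
            if (v > tk.vpeak) tk.vpeak = static_cast<float>(v);
            if (tnew > tk.t_up + 8.0) {
              tk.v90 = tk.vpeak - 0.9f * (tk.vpeak - tk.vmin_pre);
              tk.phase = 2;
            }
          } else if (tk.phase == 2) {
            if (vprev[i] >= tk.v90 && v < tk.v90) {
              tk.apd = tnew - tk.t_dvdt;
              tk.phase = 3;
            }
          }
        }
      }
      vprev[i] = v;
    }
    // watch crossings (0 mV upstrokes, re-armed below -40 mV)
    for (int wi = 0; wi < nwatch; ++wi) {
      int idx = watch[wi] - 1;
      double v = S[static_cast<size_t>(idx) * NV_MYO];
      if (armed[wi] && v >= 0.0) {
        crossings[wi].push_back(tnew);
        armed[wi] = 0;
      } else if (!armed[wi] && v < -40.0) {
        armed[wi] = 1;
      }
    }
    if (step % 25 == 0) refresh_reversals();
    if (step % 200 == 0) {
      for (int i = 0; i < n; ++i)
        if (!std::isfinite(S[static_cast<size_t>(i) * NV_MYO]))
          stop("membrane potential became non-finite at t = %f ms", tnew);
      Rcpp::checkUserInterrupt();
    }
  }

  NumericMatrix fin(n, NV_MYO);
  for (int i = 0; i < n; ++i)
    for (int v = 0; v < NV_MYO; ++v)
      fin(i, v) = S[static_cast<size_t>(i) * NV_MYO + v];

  NumericMatrix lat(n, nwin), apd(n, nwin), dvdtmax(n, nwin);
  for (int i = 0; i < n; ++i)
    for (int w = 0; w < nwin; ++w) {
      const ApdTracker& tk = trk[static_cast<size_t>(i) * nwin + w];
      bool act = tk.phase >= 1;
      lat(i, w) = act ? tk.t_dvdt : NA_REAL;
      apd(i, w) = tk.apd;
      dvdtmax(i, w) = act ? tk.dvdtmax : NA_REAL;
    }

  List cross(nwatch);
  for (int wi = 0; wi < nwatch; ++wi) cross[wi] = wrap(crossings[wi]);

  return List::create(
      _["final"] = fin, _["lat"] = lat, _["apd"] = apd,
      _["dvdtmax"] = dvdtmax, _["probe_t"] = probe_t, _["probe_v"] = probe_v,
      _["snap_t"] = snap_t, _["snap_v"] = snap_v, _["crossings"] = cross,
      _["cg_max_iterations"] = cg_itmax_used);
}
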