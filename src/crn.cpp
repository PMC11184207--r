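// Courtemanche-Ramirez-Nattel (1998) human atrial cell model with
// per-node conductance scaling, plus an anisotropic monodomain diffusion
// kernel on a masked structured grid. Operator splitting: conservative
// flux-form diffusion, then Rush-Larsen / forward-Euler reaction.
// Voltage-dependent gate kinetics are evaluated through voltage-indexed
// lookup tables (0.05 mV resolution, linear interpolation) built per time
// step size - the standard speed trick of cardiac tissue solvers.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// physical constants
static const double RGAS = 8.3143, TEMP = 310.0, FRD = 96.4867;
static const double RTF = RGAS * TEMP / FRD;
static const double CM = 100.0;                 // pF
static const double VI = 13668.0, VUP = 1109.52, VREL = 96.48; // um^3
static const double KO = 5.4, NAO = 140.0, CAO = 1.8;          // mM
static const double GB_CA = 0.001131, GB_NA = 0.0006744375;
static const double IPCA_MAX = 0.275, IUP_MAX = 0.005, CAUP_MAX = 15.0;
static const double KUP = 0.00092, KREL = 30.0, TAU_TR = 180.0;
static const double KM_NAI = 10.0, KM_KO = 1.5, KM_NA = 87.5, KM_CA = 1.38;
static const double KSAT = 0.1, GAMMA = 0.35;
static const double CMDN = 0.05, TRPN = 0.07, CSQN = 10.0;
static const double KM_CMDN = 0.00238, KM_TRPN = 0.0005, KM_CSQN = 0.8;
static const double KQ10 = 3.0;

// state layout (rows of the 21 x N state matrix)
enum { iV = 0, iM, iH, iJ, iOA, iOI, iUA, iUI, iXR, iXS, iD, iF, iFCA,
       iU, iVG, iW, iNAI, iKI, iCAI, iCAUP, iCAREL, NSTATE };
// scale layout (rows of the 9 x N scale matrix)
enum { sNA = 0, sCAL, sK1, sKR, sKS, sTO, sKUR, sNAK, sNCX, NSCALE };
// voltage-gated variables tabulated (xinf + Rush-Larsen factor each)
enum { gM = 0, gH, gJ, gOA, gOI, gUA, gUI, gXR, gXS, gD, gF, gW, NGATE };
// scalar auxiliary rows
enum { aIK1DEN = 0, aIKRDEN, aGKUR, aFNAK, aEXPG, aEXPG1, NAUX };

struct Pars {
  double gNa, gCaL, gK1, gKr, gKs, gto, gKur_sf, gNaK, gNCX;
};

static Pars read_pars(const NumericVector& p) {
  Pars q;
  q.gNa = p["gNa"];   q.gCaL = p["gCaL"]; q.gK1 = p["gK1"];
  q.gKr = p["gKr"];   q.gKs = p["gKs"];   q.gto = p["gto"];
  q.gKur_sf = p["gKur_sf"]; q.gNaK = p["gNaK"]; q.gNCX = p["gNCX"];
  return q;
}

// exact gate kinetics at one voltage: xinf[NGATE], tau[NGATE]
static void gate_kinetics(double V, double* xinf, double* tau) {
  double a, b;
  // m
  if (std::fabs(V + 47.13) < 1e-10) a = 3.2;
  else a = 0.32 * (V + 47.13) / (1.0 - std::exp(-0.1 * (V + 47.13)));
  b = 0.08 * std::exp(-V / 11.0);
  xinf[gM] = a / (a + b); tau[gM] = 1.0 / (a + b);
  // h, j
  double ah, bh, aj, bj;
  if (V >= -40.0) {
    ah = 0.0;
    bh = 1.0 / (0.13 * (1.0 + std::exp(-(V + 10.66) / 11.1)));
    aj = 0.0;
    bj = 0.3 * std::exp(-2.535e-7 * V) / (1.0 + std::exp(-0.1 * (V + 32.0)));
  } else {
    ah = 0.135 * std::exp(-(V + 80.0) / 6.8);
    bh = 3.56 * std::exp(0.079 * V) + 3.1e5 * std::exp(0.35 * V);
    aj = (-1.2714e5 * std::exp(0.2444 * V) - 3.474e-5 * std::exp(-0.04391 * V)) *
         (V + 37.78) / (1.0 + std::exp(0.311 * (V + 79.23)));
    bj = 0.1212 * std::exp(-0.01052 * V) / (1.0 + std::exp(-0.1378 * (V + 40.14)));
  }
  xinf[gH] = ah / (ah + bh); tau[gH] = 1.0 / (ah + bh);
  xinf[gJ] = aj / (aj + bj); tau[gJ] = 1.0 / (aj + bj);
  // oa, oi (Ito)
  a = 0.65 / (std::exp(-(V + 10.0) / 8.5) + std::exp(-(V - 30.0) / 59.0));
  b = 0.65 / (2.5 + std::exp((V + 82.0) / 17.0));
  tau[gOA] = 1.0 / ((a + b) * KQ10);
  xinf[gOA] = 1.0 / (1.0 + std::exp(-(V + 20.47) / 17.54));
  a = 1.0 / (18.53 + std::exp((V + 113.7) / 10.95));
  b = 1.0 / (35.56 + std::exp(-(V + 1.26) / 7.44));
  tau[gOI] = 1.0 / ((a + b) * KQ10);
  xinf[gOI] = 1.0 / (1.0 + std::exp((V + 43.1) / 5.3));
  // ua, ui (IKur)
  a = 0.65 / (std::exp(-(V + 10.0) / 8.5) + std::exp(-(V - 30.0) / 59.0));
  b = 0.65 / (2.5 + std::exp((V + 82.0) / 17.0));
  tau[gUA] = 1.0 / ((a + b) * KQ10);
  xinf[gUA] = 1.0 / (1.0 + std::exp(-(V + 30.3) / 9.6));
  a = 1.0 / (21.0 + std::exp(-(V - 185.0) / 28.0));
  b = std::exp((V - 158.0) / 16.0);
  tau[gUI] = 1.0 / ((a + b) * KQ10);
  xinf[gUI] = 1.0 / (1.0 + std::exp((V - 99.45) / 27.48));
  // xr
  if (std::fabs(V + 14.1) < 1e-10) a = 0.0015;
  else a = 0.0003 * (V + 14.1) / (1.0 - std::exp(-(V + 14.1) / 5.0));
  if (std::fabs(V - 3.3328) < 1e-10) b = 3.7866e-4;
  else b = 7.3898e-5 * (V - 3.3328) / (std::exp((V - 3.3328) / 5.1237) - 1.0);
  tau[gXR] = 1.0 / (a + b);
  xinf[gXR] = 1.0 / (1.0 + std::exp(-(V + 14.1) / 6.5));
  // xs
  if (std::fabs(V - 19.9) < 1e-10) { a = 6.8e-4; b = 3.15e-4; }
  else {
    a = 4.0e-5 * (V - 19.9) / (1.0 - std::exp(-(V - 19.9) / 17.0));
    b = 3.5e-5 * (V - 19.9) / (std::exp((V - 19.9) / 9.0) - 1.0);
  }
  tau[gXS] = 0.5 / (a + b);
  xinf[gXS] = std::pow(1.0 + std::exp(-(V - 19.9) / 12.7), -0.5);
  // d
  if (std::fabs(V + 10.0) < 1e-10) tau[gD] = 2.2894;
  else tau[gD] = (1.0 - std::exp(-(V + 10.0) / 6.24)) /
      (0.035 * (V + 10.0) * (1.0 + std::exp(-(V + 10.0) / 6.24)));
  xinf[gD] = 1.0 / (1.0 + std::exp(-(V + 10.0) / 8.0));
  // f
  tau[gF] = 9.0 / (0.0197 * std::exp(-0.0337 * 0.0337 * (V + 10.0) * (V + 10.0)) + 0.02);
  xinf[gF] = 1.0 / (1.0 + std::exp((V + 28.0) / 6.9));
  // w
  if (std::fabs(V - 7.9) < 1e-10) tau[gW] = 6.0 / (5.0 * 1.3);
  else tau[gW] = 6.0 * (1.0 - std::exp(-(V - 7.9) / 5.0)) /
      ((1.0 + 0.3 * std::exp(-(V - 7.9) / 5.0)) * (V - 7.9));
  xinf[gW] = 1.0 - 1.0 / (1.0 + std::exp(-(V - 40.0) / 17.0));
}

static void aux_terms(double V, double* aux) {
  aux[aIK1DEN] = 1.0 / (1.0 + std::exp(0.07 * (V + 80.0)));
  aux[aIKRDEN] = 1.0 / (1.0 + std::exp((V + 15.0) / 22.4));
  aux[aGKUR] = 0.005 + 0.05 / (1.0 + std::exp(-(V - 15.0) / 13.0));
  const double sigma_nk = (std::exp(NAO / 67.3) - 1.0) / 7.0;
  aux[aFNAK] = 1.0 / (1.0 + 0.1245 * std::exp(-0.1 * V / RTF) +
                      0.0365 * sigma_nk * std::exp(-V / RTF));
  aux[aEXPG] = std::exp(GAMMA * V / RTF);
  aux[aEXPG1] = std::exp((GAMMA - 1.0) * V / RTF);
}

// lookup table over V in [VMIN, VMAX] at DV resolution for one dt
struct Lut {
  double dt = -1.0;
  static constexpr double VMIN = -120.0, VMAX = 90.0, DV = 0.05;
  int n = 0;
  // layout: [gate][0=xinf,1=rlfac][i] and aux [row][i]
  std::vector<double> xinf, rl, aux;
  double rl_fca = 0, rl_u = 0;

  void build(double dt_) {
    dt = dt_;
    n = static_cast<int>((VMAX - VMIN) / DV) + 2;
    xinf.assign(NGATE * n, 0.0);
    rl.assign(NGATE * n, 0.0);
    aux.assign(NAUX * n, 0.0);
    double xi[NGATE], ta[NGATE], au[NAUX];
    for (int i = 0; i < n; ++i) {
      const double V = VMIN + i * DV;
      gate_kinetics(V, xi, ta);
      aux_terms(V, au);
      for (int g = 0; g < NGATE; ++g) {
        xinf[g * n + i] = xi[g];
        rl[g * n + i] = std::exp(-dt / ta[g]);
      }
      for (int a = 0; a < NAUX; ++a) aux[a * n + i] = au[a];
    }
    rl_fca = std::exp(-dt / 2.0);
    rl_u = std::exp(-dt / 8.0);
  }
  inline double look(const std::vector<double>& t, int row, double pos,
                     int i0) const {
    const double* p = t.data() + row * n + i0;
    const double f = pos - i0;
    return p[0] + f * (p[1] - p[0]);
  }
};

static Lut g_lut;

// one reaction step for one node; currents in pA/pF; istim depolarizing.
// if iout != NULL, fills 12 current values.
static void react(double* s, const double* sc, const Pars& p, double dt,
                  double istim, bool clampV, double* iout, const Lut& lut) {
  const double V = s[iV];
  const double Nai = s[iNAI], Ki = s[iKI], Cai = s[iCAI];
  const double Caup = s[iCAUP], Carel = s[iCAREL];

  double pos = (V - Lut::VMIN) / Lut::DV;
  if (pos < 0) pos = 0;
  if (pos > lut.n - 2) pos = lut.n - 2;
  const int i0 = static_cast<int>(pos);

  const double ENa = RTF * std::log(NAO / Nai);
  const double EK  = RTF * std::log(KO / Ki);
  const double ECa = 0.5 * RTF * std::log(CAO / Cai);

  // --- currents (pA/pF) ---
  const double INa = p.gNa * sc[sNA] * s[iM]*s[iM]*s[iM] * s[iH] * s[iJ] * (V - ENa);
  const double IK1 = p.gK1 * sc[sK1] * (V - EK) *
      lut.look(lut.aux, aIK1DEN, pos, i0);
  const double Ito = p.gto * sc[sTO] * s[iOA]*s[iOA]*s[iOA] * s[iOI] * (V - EK);
  const double gKur = p.gKur_sf * sc[sKUR] * lut.look(lut.aux, aGKUR, pos, i0);
  const double IKur = gKur * s[iUA]*s[iUA]*s[iUA] * s[iUI] * (V - EK);
  const double IKr = p.gKr * sc[sKR] * s[iXR] * (V - EK) *
      lut.look(lut.aux, aIKRDEN, pos, i0);
  const double IKs = p.gKs * sc[sKS] * s[iXS]*s[iXS] * (V - EK);
  const double ICaL = p.gCaL * sc[sCAL] * s[iD] * s[iF] * s[iFCA] * (V - 65.0);
  const double INaK = p.gNaK * sc[sNAK] * lut.look(lut.aux, aFNAK, pos, i0) /
      (1.0 + std::pow(KM_NAI / Nai, 1.5)) * KO / (KO + KM_KO);
  const double expg  = lut.look(lut.aux, aEXPG, pos, i0);
  const double expg1 = lut.look(lut.aux, aEXPG1, pos, i0);
  const double INCX = p.gNCX * sc[sNCX] *
      (expg * Nai*Nai*Nai * CAO - expg1 * NAO*NAO*NAO * Cai) /
      ((KM_NA*KM_NA*KM_NA + NAO*NAO*NAO) * (KM_CA + CAO) * (1.0 + KSAT * expg1));
  const double IbNa = GB_NA * (V - ENa);
  const double IbCa = GB_CA * (V - ECa);
  const double IpCa = IPCA_MAX * Cai / (0.0005 + Cai);

  if (iout) {
    iout[0] = INa;  iout[1] = ICaL; iout[2] = IK1; iout[3] = IKr;
    iout[4] = IKs;  iout[5] = Ito;  iout[6] = IKur; iout[7] = INaK;
    iout[8] = INCX; iout[9] = IbNa; iout[10] = IbCa; iout[11] = IpCa;
  }

  // --- calcium handling (absolute currents = pA/pF * CM) ---
  const double Irel = KREL * s[iU]*s[iU] * s[iVG] * s[iW] * (Carel - Cai);
  const double Fn = 1.0e-12 * VREL * Irel -
      (5.0e-13 / FRD) * (0.5 * ICaL * CM - 0.2 * INCX * CM);
  const double Iup = IUP_MAX / (1.0 + KUP / Cai);
  const double Iupleak = IUP_MAX * Caup / CAUP_MAX;
  const double Itr = (Caup - Carel) / TAU_TR;

  // --- voltage-gated variables: tabulated Rush-Larsen ---
  // mapping: gM..gJ -> iM..iJ, gOA..gF -> iOA..iF, gW -> iW
  for (int g = 0; g < NGATE; ++g) {
    const double xi = lut.look(lut.xinf, g, pos, i0);
    const double rf = lut.look(lut.rl, g, pos, i0);
    int si;
    if (g <= gJ) si = iM + g;
    else if (g == gW) si = iW;
    else si = iOA + (g - gOA);
    s[si] = xi + (s[si] - xi) * rf;
  }
  // fCa (Cai-dependent steady state, tau = 2 ms)
  {
    const double xi = 1.0 / (1.0 + Cai / 0.00035);
    s[iFCA] = xi + (s[iFCA] - xi) * lut.rl_fca;
  }
  // u, v (SR release; Fn-dependent, kept exact)
  {
    const double act = 1.0 / (1.0 + std::exp(-(Fn - 3.4175e-13) / 1.367e-15));
    s[iU] = act + (s[iU] - act) * lut.rl_u;
    const double tv = 1.91 + 2.09 * act;
    const double vinf = 1.0 - 1.0 / (1.0 + std::exp(-(Fn - 6.835e-14) / 1.367e-15));
    s[iVG] = vinf + (s[iVG] - vinf) * std::exp(-dt / tv);
  }

  // --- concentrations (forward Euler) ---
  s[iNAI] = Nai + dt * CM * (-3.0 * INaK - 3.0 * INCX - IbNa - INa) / (FRD * VI);
  s[iKI]  = Ki + dt * CM * (2.0 * INaK - IK1 - Ito - IKur - IKr - IKs) / (FRD * VI);
  const double B1 = CM * (2.0 * INCX - IpCa - ICaL - IbCa) / (2.0 * FRD * VI) +
      (VUP * (Iupleak - Iup) + Irel * VREL) / VI;
  const double ct = Cai + KM_TRPN, cc = Cai + KM_CMDN;
  const double B2 = 1.0 + TRPN * KM_TRPN / (ct * ct) +
      CMDN * KM_CMDN / (cc * cc);
  s[iCAI] = Cai + dt * B1 / B2;
  s[iCAUP] = Caup + dt * (Iup - Iupleak - Itr * VREL / VUP);
  const double cr = Carel + KM_CSQN;
  s[iCAREL] = Carel + dt * (Itr - Irel) / (1.0 + CSQN * KM_CSQN / (cr * cr));

  // --- membrane voltage ---
  if (!clampV) {
    const double Iion = INa + IK1 + Ito + IKur + IKr + IKs + ICaL +
        IpCa + INCX + INaK + IbNa + IbCa;
    s[iV] = V + dt * (-Iion + istim);
  }
}

// [[Rcpp::export]]
List cpp_monodomain_run(NumericMatrix state, NumericMatrix scales,
                        NumericVector pars, LogicalVector active,
                        int nx, int ny, double h,
                        NumericVector Dxx, NumericVector Dyy, NumericVector Dxy,
                        double dt, int n_steps, double t0,
                        List stims,
                        int record_stride, IntegerVector probe_idx,
                        int probe_stride, bool reaction_on, bool diffusion_on) {
  const int N = state.ncol();
  if (N != nx * ny) stop("state columns must equal nx*ny");
  const Pars P = read_pars(pars);
  if (g_lut.dt != dt) g_lut.build(dt);

  // unpack stimuli
  const int nst = stims.size();
  std::vector<std::vector<int>> st_nodes(nst);
  std::vector<double> st_t0(nst), st_t1(nst), st_amp(nst);
  for (int k = 0; k < nst; ++k) {
    List s = stims[k];
    IntegerVector nd = s["nodes"];
    st_nodes[k] = std::vector<int>(nd.begin(), nd.end());
    st_t0[k] = as<double>(s["t_start"]);
    st_t1[k] = st_t0[k] + as<double>(s["duration"]);
    st_amp[k] = as<double>(s["amplitude"]);
  }

  // copy heavy objects into raw buffers
  std::vector<double> S(state.begin(), state.end());      // 21 x N col-major
  std::vector<double> SC(scales.begin(), scales.end());   // 9 x N
  std::vector<char> act(N);
  for (int n = 0; n < N; ++n) act[n] = active[n] ? 1 : 0;
  std::vector<double> dxx(Dxx.begin(), Dxx.end()), dyy(Dyy.begin(), Dyy.end()),
      dxy(Dxy.begin(), Dxy.end());

  const int n_snap = record_stride > 0 ? n_steps / record_stride + 1 : 0;
  NumericMatrix snaps(n_snap > 0 ? n_snap : 1, n_snap > 0 ? N : 1);
  NumericVector snap_t(n_snap > 0 ? n_snap : 1);
  const int npb = probe_idx.size();
  const int n_pt = (npb > 0 && probe_stride > 0) ? n_steps / probe_stride + 1 : 0;
  NumericMatrix probes(n_pt > 0 ? n_pt : 1, npb > 0 ? npb : 1);
  NumericVector probe_t(n_pt > 0 ? n_pt : 1);

  std::vector<double> istim(N, 0.0), upd(N, 0.0), gx(N, 0.0), gy(N, 0.0);
  int isnap = 0, ipt = 0;
  std::string status = "ok";
  double bad_t = NA_REAL; int bad_node = NA_INTEGER;
  const double inv_h = 1.0 / h, inv_2h = 0.5 / h;

  for (int step = 0; step <= n_steps; ++step) {
    const double t = t0 + step * dt;
    if (record_stride > 0 && step % record_stride == 0 && isnap < n_snap) {
      for (int n = 0; n < N; ++n) snaps(isnap, n) = S[n * NSTATE + iV];
      snap_t[isnap++] = t;
    }
    if (n_pt > 0 && step % probe_stride == 0 && ipt < n_pt) {
      for (int q = 0; q < npb; ++q)
        probes(ipt, q) = S[probe_idx[q] * NSTATE + iV];
      probe_t[ipt++] = t;
    }
    if (step == n_steps) break;

    bool any_stim = false;
    std::fill(istim.begin(), istim.end(), 0.0);
    for (int k = 0; k < nst; ++k)
      if (t >= st_t0[k] && t < st_t1[k]) {
        any_stim = true;
        for (size_t m = 0; m < st_nodes[k].size(); ++m)
          istim[st_nodes[k][m]] += st_amp[k];
      }

    // diffusion (conservative flux form, no-flux at mask boundaries)
    bool any_dxy = false;
    for (int n = 0; n < N && !any_dxy; ++n) any_dxy = dxy[n] != 0.0;
    if (diffusion_on && !any_dxy) {
      // axis-aligned tensors: pure face-flux stencil, no gradient pass
      std::fill(upd.begin(), upd.end(), 0.0);
      for (int j = 0; j < ny; ++j) {
        for (int i = 0; i < nx; ++i) {
          const int n = i + j * nx;
          if (!act[n]) continue;
          const double Vn = S[n * NSTATE + iV];
          if (i + 1 < nx && act[n + 1]) {
            const double F = 0.5 * (dxx[n] + dxx[n + 1]) *
                (S[(n + 1) * NSTATE + iV] - Vn) * inv_h;
            upd[n] += F * inv_h;
            upd[n + 1] -= F * inv_h;
          }
          if (j + 1 < ny && act[n + nx]) {
            const double F = 0.5 * (dyy[n] + dyy[n + nx]) *
                (S[(n + nx) * NSTATE + iV] - Vn) * inv_h;
            upd[n] += F * inv_h;
            upd[n + nx] -= F * inv_h;
          }
        }
      }
      for (int n = 0; n < N; ++n)
        if (act[n]) S[n * NSTATE + iV] += dt * upd[n];
    } else if (diffusion_on) {
      // masked centered gradients of V
      for (int j = 0; j < ny; ++j) {
        for (int i = 0; i < nx; ++i) {
          const int n = i + j * nx;
          if (!act[n]) { gx[n] = gy[n] = 0.0; continue; }
          const double Vc = S[n * NSTATE + iV];
          const bool xl = i > 0 && act[n - 1], xr = i < nx - 1 && act[n + 1];
          const bool yl = j > 0 && act[n - nx], yr = j < ny - 1 && act[n + nx];
          gx[n] = xl && xr ? (S[(n + 1) * NSTATE + iV] - S[(n - 1) * NSTATE + iV]) * inv_2h
                : xr ? (S[(n + 1) * NSTATE + iV] - Vc) * inv_h
                : xl ? (Vc - S[(n - 1) * NSTATE + iV]) * inv_h : 0.0;
          gy[n] = yl && yr ? (S[(n + nx) * NSTATE + iV] - S[(n - nx) * NSTATE + iV]) * inv_2h
                : yr ? (S[(n + nx) * NSTATE + iV] - Vc) * inv_h
                : yl ? (Vc - S[(n - nx) * NSTATE + iV]) * inv_h : 0.0;
        }
      }
      std::fill(upd.begin(), upd.end(), 0.0);
      for (int j = 0; j < ny; ++j) {
        for (int i = 0; i < nx; ++i) {
          const int n = i + j * nx;
          if (!act[n]) continue;
          if (i + 1 < nx && act[n + 1]) {
            const int r = n + 1;
            const double F = 0.5 * (dxx[n] + dxx[r]) *
                (S[r * NSTATE + iV] - S[n * NSTATE + iV]) * inv_h +
                0.25 * (dxy[n] + dxy[r]) * (gy[n] + gy[r]);
            upd[n] += F * inv_h;
            upd[r] -= F * inv_h;
          }
          if (j + 1 < ny && act[n + nx]) {
            const int u2 = n + nx;
            const double F = 0.5 * (dyy[n] + dyy[u2]) *
                (S[u2 * NSTATE + iV] - S[n * NSTATE + iV]) * inv_h +
                0.25 * (dxy[n] + dxy[u2]) * (gx[n] + gx[u2]);
            upd[n] += F * inv_h;
            upd[u2] -= F * inv_h;
          }
        }
      }
      for (int n = 0; n < N; ++n)
        if (act[n]) S[n * NSTATE + iV] += dt * upd[n];
    }

    // reaction
    if (reaction_on) {
      for (int n = 0; n < N; ++n) {
        if (!act[n]) continue;
        react(&S[n * NSTATE], &SC[n * NSCALE], P, dt, istim[n], false,
              nullptr, g_lut);
      }
    } else if (any_stim) {
      for (int n = 0; n < N; ++n)
        if (act[n]) S[n * NSTATE + iV] += dt * istim[n];
    }

    // stability watch
    if (step % 50 == 0 || step == n_steps - 1) {
      for (int n = 0; n < N; ++n) {
        if (!act[n]) continue;
        const double v = S[n * NSTATE + iV];
        if (!std::isfinite(v) || std::fabs(v) > 200.0) {
          status = "unstable"; bad_t = t; bad_node = n + 1;
          break;
        }
      }
      if (status != "ok") break;
    }
  }

  NumericMatrix out_state(NSTATE, N);
  std::copy(S.begin(), S.end(), out_state.begin());
  return List::create(
      _["state"] = out_state,
      _["snapshots"] = snaps, _["snap_times"] = snap_t, _["n_snap"] = isnap,
      _["probes"] = probes, _["probe_times"] = probe_t, _["n_probe_t"] = ipt,
      _["status"] = status, _["bad_time"] = bad_t, _["bad_node"] = bad_node);
}

// voltage-clamp protocol on a single cell: V is prescribed per step;
// returns the 12 membrane currents at every step (pA/pF).
// [[Rcpp::export]]
List cpp_voltage_clamp(NumericVector state0, NumericVector scales,
                       NumericVector pars, NumericVector v_of_t, double dt) {
  const int n = v_of_t.size();
  const Pars P = read_pars(pars);
  if (g_lut.dt != dt) g_lut.build(dt);
  std::vector<double> s(state0.begin(), state0.end());
  std::vector<double> sc(scales.begin(), scales.end());
  NumericMatrix out(n, 12);
  double iout[12];
  for (int k = 0; k < n; ++k) {
    s[iV] = v_of_t[k];
    react(s.data(), sc.data(), P, dt, 0.0, true, iout, g_lut);
    for (int c = 0; c < 12; ++c) out(k, c) = iout[c];
  }
  colnames(out) = CharacterVector::create(
      "INa", "ICaL", "IK1", "IKr", "IKs", "Ito", "IKur", "INaK", "INCX",
      "IbNa", "IbCa", "IpCa");
  return List::create(_["currents"] = out,
                      _["state"] = NumericVector(s.begin(), s.end()));
}

// exact (non-tabulated) single reaction step; reference path for testing
// the lookup-table approximation.
// [[Rcpp::export]]
NumericVector cpp_react_exact(NumericVector state, NumericVector scales,
                              NumericVector pars, double dt, double istim) {
  const Pars P = read_pars(pars);
  std::vector<double> s(state.begin(), state.end());
  std::vector<double> sc(scales.begin(), scales.end());
  double xi[NGATE], ta[NGATE], au[NAUX];
  const double V = s[iV];
  gate_kinetics(V, xi, ta);
  aux_terms(V, au);
  // build a two-point local "table" so react() reproduces exact kinetics
  Lut local;
  local.dt = dt;
  local.n = 2;
  local.xinf.assign(NGATE * 2, 0.0);
  local.rl.assign(NGATE * 2, 0.0);
  local.aux.assign(NAUX * 2, 0.0);
  for (int g = 0; g < NGATE; ++g) {
    local.xinf[g * 2] = local.xinf[g * 2 + 1] = xi[g];
    local.rl[g * 2] = local.rl[g * 2 + 1] = std::exp(-dt / ta[g]);
  }
  for (int a = 0; a < NAUX; ++a)
    local.aux[a * 2] = local.aux[a * 2 + 1] = au[a];
  local.rl_fca = std::exp(-dt / 2.0);
  local.rl_u = std::exp(-dt / 8.0);
  react(s.data(), sc.data(), P, dt, istim, false, nullptr, local);
  return NumericVector(s.begin(), s.end());
}
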