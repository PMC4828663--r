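// Courtemanche-Ramirez-Nattel (1998) human atrial myocyte model and a
// monodomain reaction-diffusion stepper on triangulated surfaces.
//
// State layout (21 variables per cell):
//   0 V (mV), 1 m, 2 h, 3 j, 4 oa, 5 oi, 6 ua, 7 ui, 8 xr, 9 xs,
//   10 d, 11 f, 12 fca, 13 u, 14 v, 15 w,
//   16 Nai (mM), 17 Ki (mM), 18 Cai (mM), 19 Caup (mM), 20 Carel (mM)
//
// Region parameter vector (7 entries): gNa, gK1, gto, gKur_scale, gKr, gKs, gCaL.
// Kinetics are parameter-independent, so voltage-dependent gate rates and
// current coefficients can be tabulated once per (dt) and shared by regions.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const int NSTATE = 21;

// physical constants (units: mV, ms, mM, pA/pF; volumes um^3)
static const double R_ = 8.3143, T_ = 310.0, F_ = 96.4867;
static const double Cm_ = 100.0;                      // pF
static const double Vi_ = 13668.0, Vup_ = 1109.52, Vrel_ = 96.48;
static const double Ko_ = 5.4, Nao_ = 140.0, Cao_ = 1.8;
static const double gbCa_ = 0.001131, gbNa_ = 0.0006744375;
static const double INaKmax_ = 0.59933874, KmNai_ = 10.0, KmKo_ = 1.5;
static const double INaCamax_ = 1600.0, KmNa_ = 87.5, KmCa_ = 1.38,
                    ksat_ = 0.1, gama_ = 0.35;
static const double IpCamax_ = 0.275;
static const double Krel_ = 30.0;
static const double Iupmax_ = 0.005, Kup_ = 0.00092, Caupmax_ = 15.0;
static const double tautr_ = 180.0;
static const double CMDNmax_ = 0.05, TRPNmax_ = 0.07, CSQNmax_ = 10.0;
static const double KmCmdn_ = 0.00238, KmTrpn_ = 0.0005, KmCsqn_ = 0.8;
static const double KQ10_ = 3.0;

static inline double clampexp(double x) {
  if (x > 80.0) x = 80.0;
  if (x < -80.0) x = -80.0;
  return std::exp(x);
}

// ---- voltage-dependent gate kinetics (inf, tau) ---------------------------

struct GateVT { double inf, tau; };

static inline GateVT gate_m(double V) {
  double a = (std::fabs(V + 47.13) < 1e-10)
                 ? 3.2
                 : 0.32 * (V + 47.13) / (1.0 - std::exp(-0.1 * (V + 47.13)));
  double b = 0.08 * std::exp(-V / 11.0);
  GateVT g; g.inf = a / (a + b); g.tau = 1.0 / (a + b); return g;
}
static inline GateVT gate_h(double V) {
  double a, b;
  if (V >= -40.0) {
    a = 0.0;
    b = 1.0 / (0.13 * (1.0 + std::exp(-(V + 10.66) / 11.1)));
  } else {
    a = 0.135 * std::exp(-(V + 80.0) / 6.8);
    b = 3.56 * std::exp(0.079 * V) + 3.1e5 * std::exp(0.35 * V);
  }
  GateVT g; g.inf = a / (a + b); g.tau = 1.0 / (a + b); return g;
}
static inline GateVT gate_j(double V) {
  double a, b;
  if (V >= -40.0) {
    a = 0.0;
    b = 0.3 * std::exp(-2.535e-7 * V) / (1.0 + std::exp(-0.1 * (V + 32.0)));
  } else {
    a = (-1.2714e5 * std::exp(0.2444 * V) - 3.474e-5 * std::exp(-0.04391 * V)) *
        (V + 37.78) / (1.0 + std::exp(0.311 * (V + 79.23)));
    b = 0.1212 * std::exp(-0.01052 * V) / (1.0 + std::exp(-0.1378 * (V + 40.14)));
  }
  GateVT g; g.inf = a / (a + b); g.tau = 1.0 / (a + b); return g;
}
static inline GateVT gate_oa(double V) {
  double a = 0.65 / (std::exp(-(V + 10.0) / 8.5) + std::exp(-(V - 30.0) / 59.0));
  double b = 0.65 / (2.5 + std::exp((V + 82.0) / 17.0));
  GateVT g; g.tau = 1.0 / ((a + b) * KQ10_);
  g.inf = 1.0 / (1.0 + std::exp(-(V + 20.47) / 17.54)); return g;
}
static inline GateVT gate_oi(double V) {
  double a = 1.0 / (18.53 + std::exp((V + 113.7) / 10.95));
  double b = 1.0 / (35.56 + std::exp(-(V + 1.26) / 7.44));
  GateVT g; g.tau = 1.0 / ((a + b) * KQ10_);
  g.inf = 1.0 / (1.0 + std::exp((V + 43.1) / 5.3)); return g;
}
static inline GateVT gate_ua(double V) {
  double a = 0.65 / (std::exp(-(V + 10.0) / 8.5) + std::exp(-(V - 30.0) / 59.0));
  double b = 0.65 / (2.5 + std::exp((V + 82.0) / 17.0));
  GateVT g; g.tau = 1.0 / ((a + b) * KQ10_);
  g.inf = 1.0 / (1.0 + std::exp(-(V + 30.3) / 9.6)); return g;
}
static inline GateVT gate_ui(double V) {
  double a = 1.0 / (21.0 + std::exp(-(V - 185.0) / 28.0));
  double b = std::exp((V - 158.0) / 16.0);
  GateVT g; g.tau = 1.0 / ((a + b) * KQ10_);
  g.inf = 1.0 / (1.0 + std::exp((V - 99.45) / 27.48)); return g;
}
static inline GateVT gate_xr(double V) {
  double a = (std::fabs(V + 14.1) < 1e-10)
                 ? 0.0015
                 : 0.0003 * (V + 14.1) / (1.0 - std::exp(-(V + 14.1) / 5.0));
  double b = (std::fabs(V - 3.3328) < 1e-10)
                 ? 3.7861644e-4
                 : 7.3898e-5 * (V - 3.3328) /
                       (std::exp((V - 3.3328) / 5.1237) - 1.0);
  GateVT g; g.tau = 1.0 / (a + b);
  g.inf = 1.0 / (1.0 + std::exp(-(V + 14.1) / 6.5)); return g;
}
static inline GateVT gate_xs(double V) {
  double a = (std::fabs(V - 19.9) < 1e-10)
                 ? 6.8e-4
                 : 4e-5 * (V - 19.9) / (1.0 - std::exp(-(V - 19.9) / 17.0));
  double b = (std::fabs(V - 19.9) < 1e-10)
                 ? 3.15e-4
                 : 3.5e-5 * (V - 19.9) / (std::exp((V - 19.9) / 9.0) - 1.0);
  GateVT g; g.tau = 0.5 / (a + b);
  g.inf = 1.0 / std::sqrt(1.0 + std::exp(-(V - 19.9) / 12.7)); return g;
}
static inline GateVT gate_d(double V) {
  double x = V + 10.0;
  GateVT g;
  g.tau = (std::fabs(x) < 1e-10)
              ? 1.0 / (0.035 * 6.24 * 2.0)
              : (1.0 - std::exp(-x / 6.24)) /
                    (0.035 * x * (1.0 + std::exp(-x / 6.24)));
  g.inf = 1.0 / (1.0 + std::exp(-x / 8.0));
  return g;
}
static inline GateVT gate_f(double V) {
  GateVT g;
  g.tau = 9.0 / (0.0197 * std::exp(-0.0337 * 0.0337 * (V + 10.0) * (V + 10.0)) + 0.02);
  g.inf = std::exp(-(V + 28.0) / 6.9) / (1.0 + std::exp(-(V + 28.0) / 6.9));
  return g;
}
static inline GateVT gate_w(double V) {
  double x = V - 7.9;
  GateVT g;
  g.tau = (std::fabs(x) < 1e-10)
              ? 6.0 * 0.2 / 1.3
              : 6.0 * (1.0 - std::exp(-x / 5.0)) /
                    ((1.0 + 0.3 * std::exp(-x / 5.0)) * x);
  g.inf = 1.0 - 1.0 / (1.0 + std::exp(-(V - 40.0) / 17.0));
  return g;
}

// voltage-dependent current coefficients
static inline double coef_K1(double V) { return 1.0 / (1.0 + std::exp(0.07 * (V + 80.0))); }
static inline double coef_Kr(double V) { return 1.0 / (1.0 + std::exp((V + 15.0) / 22.4)); }
static inline double coef_gKur(double V) { return 0.005 + 0.05 / (1.0 + std::exp(-(V - 15.0) / 13.0)); }
static inline double coef_fNaK(double V) {
  double sigma = (std::exp(Nao_ / 67.3) - 1.0) / 7.0;
  double vfrt = V * F_ / (R_ * T_);
  return 1.0 / (1.0 + 0.1245 * std::exp(-0.1 * vfrt) + 0.0365 * sigma * std::exp(-vfrt));
}
static inline double coef_naca1(double V) { return clampexp(gama_ * V * F_ / (R_ * T_)); }
static inline double coef_naca2(double V) { return clampexp((gama_ - 1.0) * V * F_ / (R_ * T_)); }

// ---- full right-hand side (exact, scalar) ---------------------------------

static void crn_derivs(const double* y, const double* p, double stim, double* dy) {
  const double V = y[0], m = y[1], h = y[2], j = y[3], oa = y[4], oi = y[5],
               ua = y[6], ui = y[7], xr = y[8], xs = y[9], d = y[10], f = y[11],
               fca = y[12], u = y[13], v = y[14], w = y[15], Nai = y[16],
               Ki = y[17], Cai = y[18], Caup = y[19], Carel = y[20];
  const double gNa = p[0], gK1 = p[1], gto = p[2], gKurS = p[3], gKr = p[4],
               gKs = p[5], gCaL = p[6];
  const double rtf = R_ * T_ / F_;

  double ENa = rtf * std::log(Nao_ / Nai);
  double EK = rtf * std::log(Ko_ / Ki);
  double ECa = 0.5 * rtf * std::log(Cao_ / Cai);

  double iNa = gNa * m * m * m * h * j * (V - ENa);
  double iK1 = gK1 * (V - EK) * coef_K1(V);
  double ito = gto * oa * oa * oa * oi * (V - EK);
  double iKur = gKurS * coef_gKur(V) * ua * ua * ua * ui * (V - EK);
  double iKr = gKr * xr * (V - EK) * coef_Kr(V);
  double iKs = gKs * xs * xs * (V - EK);
  double iCaL = gCaL * d * f * fca * (V - 65.0);
  double iNaK = INaKmax_ * coef_fNaK(V) /
                (1.0 + std::pow(KmNai_ / Nai, 1.5)) * (Ko_ / (Ko_ + KmKo_));
  double iNaCa = INaCamax_ *
                 (coef_naca1(V) * Nai * Nai * Nai * Cao_ -
                  coef_naca2(V) * Nao_ * Nao_ * Nao_ * Cai) /
                 ((KmNa_ * KmNa_ * KmNa_ + Nao_ * Nao_ * Nao_) * (KmCa_ + Cao_) *
                  (1.0 + ksat_ * coef_naca2(V)));
  double ibNa = gbNa_ * (V - ENa);
  double ibCa = gbCa_ * (V - ECa);
  double ipCa = IpCamax_ * Cai / (0.0005 + Cai);

  double irel = Krel_ * u * u * v * w * (Carel - Cai);
  double itr = (Caup - Carel) / tautr_;
  double iup = Iupmax_ / (1.0 + Kup_ / Cai);
  double iupleak = Iupmax_ * Caup / Caupmax_;

  double Fn = 1e3 * (1e-15 * Vrel_ * irel -
                     1e-15 / (2.0 * F_) * (0.5 * iCaL * Cm_ - 0.4 * iNaCa * Cm_));
  double eu = clampexp(-(Fn - 3.4175e-13) / 13.67e-16);
  double u_inf = 1.0 / (1.0 + eu);
  double tau_v = 1.91 + 2.09 / (1.0 + eu);
  double v_inf = 1.0 - 1.0 / (1.0 + clampexp(-(Fn - 6.835e-14) / 13.67e-16));

  GateVT gm = gate_m(V), gh = gate_h(V), gj = gate_j(V), goa = gate_oa(V),
         goi = gate_oi(V), gua = gate_ua(V), gui = gate_ui(V), gxr = gate_xr(V),
         gxs = gate_xs(V), gd = gate_d(V), gf = gate_f(V), gw = gate_w(V);

  dy[0] = -(iNa + iK1 + ito + iKur + iKr + iKs + iCaL + ipCa + iNaCa + ibNa +
            ibCa + iNaK) - stim;
  dy[1] = (gm.inf - m) / gm.tau;
  dy[2] = (gh.inf - h) / gh.tau;
  dy[3] = (gj.inf - j) / gj.tau;
  dy[4] = (goa.inf - oa) / goa.tau;
  dy[5] = (goi.inf - oi) / goi.tau;
  dy[6] = (gua.inf - ua) / gua.tau;
  dy[7] = (gui.inf - ui) / gui.tau;
  dy[8] = (gxr.inf - xr) / gxr.tau;
  dy[9] = (gxs.inf - xs) / gxs.tau;
  dy[10] = (gd.inf - d) / gd.tau;
  dy[11] = (gf.inf - f) / gf.tau;
  dy[12] = (1.0 / (1.0 + Cai / 0.00035) - fca) / 2.0;
  dy[13] = (u_inf - u) / 8.0;
  dy[14] = (v_inf - v) / tau_v;
  dy[15] = (gw.inf - w) / gw.tau;
  dy[16] = (-3.0 * iNaK - (3.0 * iNaCa + ibNa + iNa)) * Cm_ / (Vi_ * F_);
  dy[17] = (2.0 * iNaK - (iK1 + ito + iKur + iKr + iKs)) * Cm_ / (Vi_ * F_);
  double B1 = (2.0 * iNaCa - (ipCa + iCaL + ibCa)) * Cm_ / (2.0 * Vi_ * F_) +
              (Vup_ * (iupleak - iup) + irel * Vrel_) / Vi_;
  double B2 = 1.0 + TRPNmax_ * KmTrpn_ / ((Cai + KmTrpn_) * (Cai + KmTrpn_)) +
              CMDNmax_ * KmCmdn_ / ((Cai + KmCmdn_) * (Cai + KmCmdn_));
  dy[18] = B1 / B2;
  dy[19] = iup - iupleak - itr * Vrel_ / Vup_;
  dy[20] = (itr - irel) /
           (1.0 + CSQNmax_ * KmCsqn_ / ((Carel + KmCsqn_) * (Carel + KmCsqn_)));
}

// Rush-Larsen update of one cell, exact kinetics (no tables)
static void crn_step_exact(double* y, const double* p, double stim, double dt) {
  const double V = y[0];
  const double Nai = y[16], Ki = y[17], Cai = y[18], Caup = y[19], Carel = y[20];
  const double rtf = R_ * T_ / F_;
  double ENa = rtf * std::log(Nao_ / Nai);
  double EK = rtf * std::log(Ko_ / Ki);
  double ECa = 0.5 * rtf * std::log(Cao_ / Cai);

  double iNa = p[0] * y[1] * y[1] * y[1] * y[2] * y[3] * (V - ENa);
  double iK1 = p[1] * (V - EK) * coef_K1(V);
  double ito = p[2] * y[4] * y[4] * y[4] * y[5] * (V - EK);
  double iKur = p[3] * coef_gKur(V) * y[6] * y[6] * y[6] * y[7] * (V - EK);
  double iKr = p[4] * y[8] * (V - EK) * coef_Kr(V);
  double iKs = p[5] * y[9] * y[9] * (V - EK);
  double iCaL = p[6] * y[10] * y[11] * y[12] * (V - 65.0);
  double iNaK = INaKmax_ * coef_fNaK(V) /
                (1.0 + std::pow(KmNai_ / Nai, 1.5)) * (Ko_ / (Ko_ + KmKo_));
  double e2 = coef_naca2(V);
  double iNaCa = INaCamax_ *
                 (coef_naca1(V) * Nai * Nai * Nai * Cao_ - e2 * Nao_ * Nao_ * Nao_ * Cai) /
                 ((KmNa_ * KmNa_ * KmNa_ + Nao_ * Nao_ * Nao_) * (KmCa_ + Cao_) *
                  (1.0 + ksat_ * e2));
  double ibNa = gbNa_ * (V - ENa);
  double ibCa = gbCa_ * (V - ECa);
  double ipCa = IpCamax_ * Cai / (0.0005 + Cai);
  double irel = Krel_ * y[13] * y[13] * y[14] * y[15] * (Carel - Cai);
  double itr = (Caup - Carel) / tautr_;
  double iup = Iupmax_ / (1.0 + Kup_ / Cai);
  double iupleak = Iupmax_ * Caup / Caupmax_;

  double Fn = 1e3 * (1e-15 * Vrel_ * irel -
                     1e-15 / (2.0 * F_) * (0.5 * iCaL * Cm_ - 0.4 * iNaCa * Cm_));
  double eu = clampexp(-(Fn - 3.4175e-13) / 13.67e-16);
  double u_inf = 1.0 / (1.0 + eu);
  double tau_v = 1.91 + 2.09 / (1.0 + eu);
  double v_inf = 1.0 - 1.0 / (1.0 + clampexp(-(Fn - 6.835e-14) / 13.67e-16));

  GateVT g;
  g = gate_m(V);  y[1] = g.inf + (y[1] - g.inf) * std::exp(-dt / g.tau);
  g = gate_h(V);  y[2] = g.inf + (y[2] - g.inf) * std::exp(-dt / g.tau);
  g = gate_j(V);  y[3] = g.inf + (y[3] - g.inf) * std::exp(-dt / g.tau);
  g = gate_oa(V); y[4] = g.inf + (y[4] - g.inf) * std::exp(-dt / g.tau);
  g = gate_oi(V); y[5] = g.inf + (y[5] - g.inf) * std::exp(-dt / g.tau);
  g = gate_ua(V); y[6] = g.inf + (y[6] - g.inf) * std::exp(-dt / g.tau);
  g = gate_ui(V); y[7] = g.inf + (y[7] - g.inf) * std::exp(-dt / g.tau);
  g = gate_xr(V); y[8] = g.inf + (y[8] - g.inf) * std::exp(-dt / g.tau);
  g = gate_xs(V); y[9] = g.inf + (y[9] - g.inf) * std::exp(-dt / g.tau);
  g = gate_d(V);  y[10] = g.inf + (y[10] - g.inf) * std::exp(-dt / g.tau);
  g = gate_f(V);  y[11] = g.inf + (y[11] - g.inf) * std::exp(-dt / g.tau);
  double fca_inf = 1.0 / (1.0 + Cai / 0.00035);
  y[12] = fca_inf + (y[12] - fca_inf) * std::exp(-dt / 2.0);
  y[13] = u_inf + (y[13] - u_inf) * std::exp(-dt / 8.0);
  y[14] = v_inf + (y[14] - v_inf) * std::exp(-dt / tau_v);
  g = gate_w(V);  y[15] = g.inf + (y[15] - g.inf) * std::exp(-dt / g.tau);

  y[16] += dt * (-3.0 * iNaK - (3.0 * iNaCa + ibNa + iNa)) * Cm_ / (Vi_ * F_);
  y[17] += dt * (2.0 * iNaK - (iK1 + ito + iKur + iKr + iKs)) * Cm_ / (Vi_ * F_);
  double B1 = (2.0 * iNaCa - (ipCa + iCaL + ibCa)) * Cm_ / (2.0 * Vi_ * F_) +
              (Vup_ * (iupleak - iup) + irel * Vrel_) / Vi_;
  double B2 = 1.0 + TRPNmax_ * KmTrpn_ / ((Cai + KmTrpn_) * (Cai + KmTrpn_)) +
              CMDNmax_ * KmCmdn_ / ((Cai + KmCmdn_) * (Cai + KmCmdn_));
  y[18] += dt * B1 / B2;
  y[19] += dt * (iup - iupleak - itr * Vrel_ / Vup_);
  y[20] += dt * (itr - irel) /
           (1.0 + CSQNmax_ * KmCsqn_ / ((Carel + KmCsqn_) * (Carel + KmCsqn_)));

  double Iion = iNa + iK1 + ito + iKur + iKr + iKs + iCaL + ipCa + iNaCa +
                ibNa + ibCa + iNaK;
  y[0] = V + dt * (-Iion - stim);
}

// ---- exported: initial state, RHS ----------------------------------------

// [[Rcpp::export]]
NumericVector cpp_crn_initial_state() {
  NumericVector y(NSTATE);
  y[0] = -81.18;  y[1] = 2.908e-3; y[2] = 9.649e-1; y[3] = 9.775e-1;
  y[4] = 3.043e-2; y[5] = 9.992e-1; y[6] = 4.966e-3; y[7] = 9.986e-1;
  y[8] = 3.296e-5; y[9] = 1.869e-2; y[10] = 1.367e-4; y[11] = 9.996e-1;
  y[12] = 7.755e-1; y[13] = 0.0;    y[14] = 1.0;      y[15] = 9.992e-1;
  y[16] = 11.17;   y[17] = 139.0;   y[18] = 1.013e-4; y[19] = 1.488;
  y[20] = 1.488;
  y.attr("names") = CharacterVector::create(
      "V", "m", "h", "j", "oa", "oi", "ua", "ui", "xr", "xs", "d", "f", "fca",
      "u", "v", "w", "Nai", "Ki", "Cai", "Caup", "Carel");
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_crn_rhs(NumericVector state, NumericVector params, double stim) {
  if (state.size() != NSTATE) stop("state must have 21 entries");
  if (params.size() != 7) stop("params must have 7 entries");
  for (int i = 0; i < NSTATE; ++i)
    if (!R_finite(state[i])) stop("non-finite state");
  NumericVector dy(NSTATE);
  crn_derivs(REAL(state), REAL(params), stim, REAL(dy));
  return dy;
}

// ---- exported: single-cell pacing -----------------------------------------

// [[Rcpp::export]]
List cpp_pace_cell(NumericVector state0, NumericVector params, double cl_ms,
                   int n_beats, double dt_ms, double stim_amp, double stim_dur,
                   double record_dt, double tail_ms) {
  if (params.size() != 7) stop("params must have 7 entries");
  std::vector<double> y(REAL(state0), REAL(state0) + NSTATE);
  double total = cl_ms * n_beats + tail_ms;
  int n_steps = (int)std::ceil(total / dt_ms);
  int rec_every = std::max(1, (int)std::round(record_dt / dt_ms));
  int n_rec = n_steps / rec_every + 1;
  NumericVector tv(n_rec), Vv(n_rec);
  tv[0] = 0.0; Vv[0] = y[0];
  int k = 1;
  for (int s = 0; s < n_steps; ++s) {
    double t = s * dt_ms;
    double tb = t - cl_ms * std::floor(t / cl_ms);
    double stim = (t < cl_ms * n_beats && tb < stim_dur) ? stim_amp : 0.0;
    crn_step_exact(y.data(), REAL(params), stim, dt_ms);
    if ((s + 1) % rec_every == 0 && k < n_rec) {
      tv[k] = (s + 1) * dt_ms;
      Vv[k] = y[0];
      ++k;
    }
    if (!R_finite(y[0])) stop("integration diverged at t=%f ms", t);
  }
  NumericVector yout(NSTATE);
  for (int i = 0; i < NSTATE; ++i) yout[i] = y[i];
  yout.attr("names") = cpp_crn_initial_state().attr("names");
  return List::create(_["t"] = tv[Range(0, k - 1)], _["Vm"] = Vv[Range(0, k - 1)],
                      _["state"] = yout);
}

// ---- tabulated kinetics for tissue runs -----------------------------------

struct RateTable {
  double vmin, vmax, inv_dv;
  int n;
  // per gate: inf and exp(-dt/tau); gates: m h j oa oi ua ui xr xs d f w
  std::vector<double> inf[12], rl[12];
  std::vector<double> cK1, cKr, cgKur, cfNaK, cN1, cN2;
  double rl_fca, rl_u;
};

typedef GateVT (*gatefun)(double);
static gatefun GATES[12] = {gate_m, gate_h, gate_j, gate_oa, gate_oi, gate_ua,
                            gate_ui, gate_xr, gate_xs, gate_d, gate_f, gate_w};

static void build_table(RateTable& tb, double dt) {
  tb.vmin = -150.0; tb.vmax = 100.0;
  double dv = 0.02;
  tb.inv_dv = 1.0 / dv;
  tb.n = (int)((tb.vmax - tb.vmin) / dv) + 2;
  for (int g = 0; g < 12; ++g) { tb.inf[g].resize(tb.n); tb.rl[g].resize(tb.n); }
  tb.cK1.resize(tb.n); tb.cKr.resize(tb.n); tb.cgKur.resize(tb.n);
  tb.cfNaK.resize(tb.n); tb.cN1.resize(tb.n); tb.cN2.resize(tb.n);
  for (int i = 0; i < tb.n; ++i) {
    double V = tb.vmin + i * dv;
    for (int g = 0; g < 12; ++g) {
      GateVT gv = GATES[g](V);
      tb.inf[g][i] = gv.inf;
      tb.rl[g][i] = std::exp(-dt / gv.tau);
    }
    tb.cK1[i] = coef_K1(V);
    tb.cKr[i] = coef_Kr(V);
    tb.cgKur[i] = coef_gKur(V);
    tb.cfNaK[i] = coef_fNaK(V);
    tb.cN1[i] = coef_naca1(V);
    tb.cN2[i] = coef_naca2(V);
  }
  tb.rl_fca = std::exp(-dt / 2.0);
  tb.rl_u = std::exp(-dt / 8.0);
}

// erev caches ENa, EK, ECa per node; refreshed every few steps because the
// concentrations they depend on drift slowly (sub-uV error per ms)
static inline void crn_refresh_erev(const double* y, double* erev) {
  const double rtf = R_ * T_ / F_;
  erev[0] = rtf * std::log(Nao_ / y[16]);
  erev[1] = rtf * std::log(Ko_ / y[17]);
  erev[2] = 0.5 * rtf * std::log(Cao_ / y[18]);
}

static inline void crn_step_table(double* y, const double* p, double stim,
                                  double dt, const RateTable& tb,
                                  const double* erev) {
  double V = y[0];
  if (V < tb.vmin) V = tb.vmin;
  if (V > tb.vmax) V = tb.vmax;
  double fi = (V - tb.vmin) * tb.inv_dv;
  int i0 = (int)fi;
  double wq = fi - i0;

#define LERP(arr) ((arr)[i0] + wq * ((arr)[i0 + 1] - (arr)[i0]))

  const double Nai = y[16], Ki = y[17], Cai = y[18], Caup = y[19], Carel = y[20];
  const double ENa = erev[0], EK = erev[1], ECa = erev[2];

  double iNa = p[0] * y[1] * y[1] * y[1] * y[2] * y[3] * (y[0] - ENa);
  double iK1 = p[1] * (y[0] - EK) * LERP(tb.cK1);
  double ito = p[2] * y[4] * y[4] * y[4] * y[5] * (y[0] - EK);
  double iKur = p[3] * LERP(tb.cgKur) * y[6] * y[6] * y[6] * y[7] * (y[0] - EK);
  double iKr = p[4] * y[8] * (y[0] - EK) * LERP(tb.cKr);
  double iKs = p[5] * y[9] * y[9] * (y[0] - EK);
  double iCaL = p[6] * y[10] * y[11] * y[12] * (y[0] - 65.0);
  double nai15 = Nai * std::sqrt(Nai);  // Nai^1.5
  double km15 = KmNai_ * std::sqrt(KmNai_);
  double iNaK = INaKmax_ * LERP(tb.cfNaK) / (1.0 + km15 / nai15) *
                (Ko_ / (Ko_ + KmKo_));
  double e2 = LERP(tb.cN2);
  double iNaCa = INaCamax_ *
                 (LERP(tb.cN1) * Nai * Nai * Nai * Cao_ - e2 * Nao_ * Nao_ * Nao_ * Cai) /
                 ((KmNa_ * KmNa_ * KmNa_ + Nao_ * Nao_ * Nao_) * (KmCa_ + Cao_) *
                  (1.0 + ksat_ * e2));
  double ibNa = gbNa_ * (y[0] - ENa);
  double ibCa = gbCa_ * (y[0] - ECa);
  double ipCa = IpCamax_ * Cai / (0.0005 + Cai);
  double irel = Krel_ * y[13] * y[13] * y[14] * y[15] * (Carel - Cai);
  double itr = (Caup - Carel) / tautr_;
  double iup = Iupmax_ / (1.0 + Kup_ / Cai);
  double iupleak = Iupmax_ * Caup / Caupmax_;

  double Fn = 1e3 * (1e-15 * Vrel_ * irel -
                     1e-15 / (2.0 * F_) * (0.5 * iCaL * Cm_ - 0.4 * iNaCa * Cm_));
  // single precision suffices for the sigmoidal Ca-release gate rates
  float xeu = (float)(-(Fn - 3.4175e-13) / 13.67e-16);
  if (xeu > 60.0f) xeu = 60.0f; if (xeu < -60.0f) xeu = -60.0f;
  double eu = (double)expf(xeu);
  double u_inf = 1.0 / (1.0 + eu);
  double tau_v = 1.91 + 2.09 / (1.0 + eu);
  float xev = (float)(-(Fn - 6.835e-14) / 13.67e-16);
  if (xev > 60.0f) xev = 60.0f; if (xev < -60.0f) xev = -60.0f;
  double v_inf = 1.0 - 1.0 / (1.0 + (double)expf(xev));

  for (int g = 0; g < 12; ++g) {
    double inf = LERP(tb.inf[g]);
    double rl = LERP(tb.rl[g]);
    int idx = (g < 9) ? g + 1 : ((g < 11) ? g + 1 : 15);  // states 1..11 and w=15
    y[idx] = inf + (y[idx] - inf) * rl;
  }
  double fca_inf = 1.0 / (1.0 + Cai / 0.00035);
  y[12] = fca_inf + (y[12] - fca_inf) * tb.rl_fca;
  y[13] = u_inf + (y[13] - u_inf) * tb.rl_u;
  y[14] = v_inf + (y[14] - v_inf) * (double)expf((float)(-dt / tau_v));

  y[16] += dt * (-3.0 * iNaK - (3.0 * iNaCa + ibNa + iNa)) * Cm_ / (Vi_ * F_);
  y[17] += dt * (2.0 * iNaK - (iK1 + ito + iKur + iKr + iKs)) * Cm_ / (Vi_ * F_);
  double B1 = (2.0 * iNaCa - (ipCa + iCaL + ibCa)) * Cm_ / (2.0 * Vi_ * F_) +
              (Vup_ * (iupleak - iup) + irel * Vrel_) / Vi_;
  double B2 = 1.0 + TRPNmax_ * KmTrpn_ / ((Cai + KmTrpn_) * (Cai + KmTrpn_)) +
              CMDNmax_ * KmCmdn_ / ((Cai + KmCmdn_) * (Cai + KmCmdn_));
  y[18] += dt * B1 / B2;
  y[19] += dt * (iup - iupleak - itr * Vrel_ / Vup_);
  y[20] += dt * (itr - irel) /
           (1.0 + CSQNmax_ * KmCsqn_ / ((Carel + KmCsqn_) * (Carel + KmCsqn_)));

  double Iion = iNa + iK1 + ito + iKur + iKr + iKs + iCaL + ipCa + iNaCa +
                ibNa + ibCa + iNaK;
  y[0] += dt * (-Iion - stim);
#undef LERP
}

// ---- exported: monodomain tissue run --------------------------------------
//
// K is the P1 stiffness operator (symmetric, CSC slots) with the diffusion
// tensor in mm^2/ms already folded in; M the lumped mass (mm^2). One step:
// Rush-Larsen ionic update, then explicit diffusion V -= dt * (K V) / M.
// Stimuli are transmembrane current densities (pA/pF, depolarizing < 0).

// [[Rcpp::export]]
List cpp_run_tissue(NumericMatrix state, NumericMatrix params,
                    IntegerVector region, IntegerVector Kp, IntegerVector Kirow,
                    NumericVector Kx, NumericVector Mlump, double dt,
                    double t0, double t_end, NumericMatrix stim_spec,
                    List stim_nodes, double record_dt, bool use_table) {
  const int n = state.nrow();
  if (state.ncol() != NSTATE) stop("state must be n x 21");
  if ((int)region.size() != n || (int)Mlump.size() != n)
    stop("region/Mlump length mismatch");
  const int nreg = params.ncol();
  if (params.nrow() != 7) stop("params must be 7 x n_regions");
  const int n_steps = (int)std::round((t_end - t0) / dt);
  const int rec_every = std::max(1, (int)std::round(record_dt / dt));
  const int n_frames = n_steps / rec_every + 1;

  // copy state into C-contiguous per-node layout
  std::vector<double> Y((size_t)n * NSTATE);
  for (int i = 0; i < n; ++i)
    for (int s = 0; s < NSTATE; ++s) Y[(size_t)i * NSTATE + s] = state(i, s);

  std::vector<const double*> preg(n);
  for (int i = 0; i < n; ++i) {
    int r = region[i];
    if (r < 0 || r >= nreg) stop("region index out of range");
    preg[i] = &params(0, r);
  }

  RateTable tb;
  std::vector<double> erev;
  if (use_table) {
    build_table(tb, dt);
    erev.resize((size_t)n * 3);
    for (int i = 0; i < n; ++i)
      crn_refresh_erev(&Y[(size_t)i * NSTATE], &erev[(size_t)i * 3]);
  }
  const int erev_every = std::max(1, (int)std::round(0.5 / dt));  // 0.5 ms

  // stimulus bookkeeping
  const int n_stim = stim_spec.nrow();
  std::vector<std::vector<int> > snodes(n_stim);
  for (int s = 0; s < n_stim; ++s) {
    IntegerVector v = stim_nodes[s];
    snodes[s].assign(v.begin(), v.end());
    for (size_t k = 0; k < snodes[s].size(); ++k) {
      snodes[s][k] -= 1;  // R 1-based
      if (snodes[s][k] < 0 || snodes[s][k] >= n) stop("stimulus node out of range");
    }
  }

  NumericMatrix frames(n, n_frames);
  NumericVector ftimes(n_frames);
  std::vector<double> stimv(n, 0.0), kv(n, 0.0);

  for (int i = 0; i < n; ++i) frames(i, 0) = Y[(size_t)i * NSTATE];
  ftimes[0] = t0;
  int fk = 1;

  const int* kp = INTEGER(Kp);
  const int* ki = INTEGER(Kirow);
  const double* kx = REAL(Kx);
  const double* mm = REAL(Mlump);

  bool ok = true;
  double t_bad = NA_REAL;

  for (int s = 0; s < n_steps; ++s) {
    double t = t0 + s * dt;
    // stimulus field for this step
    bool any_stim = false;
    for (int q = 0; q < n_stim; ++q)
      if (t >= stim_spec(q, 0) && t < stim_spec(q, 0) + stim_spec(q, 1)) {
        any_stim = true; break;
      }
    if (any_stim) {
      std::fill(stimv.begin(), stimv.end(), 0.0);
      for (int q = 0; q < n_stim; ++q) {
        if (t >= stim_spec(q, 0) && t < stim_spec(q, 0) + stim_spec(q, 1)) {
          double a = stim_spec(q, 2);
          for (size_t k = 0; k < snodes[q].size(); ++k) stimv[snodes[q][k]] += a;
        }
      }
    }

    // ionic update
    if (use_table) {
      if (s % erev_every == 0)
        for (int i = 0; i < n; ++i)
          crn_refresh_erev(&Y[(size_t)i * NSTATE], &erev[(size_t)i * 3]);
      if (any_stim)
        for (int i = 0; i < n; ++i)
          crn_step_table(&Y[(size_t)i * NSTATE], preg[i], stimv[i], dt, tb,
                         &erev[(size_t)i * 3]);
      else
        for (int i = 0; i < n; ++i)
          crn_step_table(&Y[(size_t)i * NSTATE], preg[i], 0.0, dt, tb,
                         &erev[(size_t)i * 3]);
    } else {
      for (int i = 0; i < n; ++i)
        crn_step_exact(&Y[(size_t)i * NSTATE], preg[i], any_stim ? stimv[i] : 0.0, dt);
    }

    // diffusion: V -= dt * (K V) / M  (K symmetric; CSC traversal)
    std::fill(kv.begin(), kv.end(), 0.0);
    for (int col = 0; col < n; ++col) {
      double vc = Y[(size_t)col * NSTATE];
      for (int idx = kp[col]; idx < kp[col + 1]; ++idx)
        kv[ki[idx]] += kx[idx] * vc;
    }
    for (int i = 0; i < n; ++i) Y[(size_t)i * NSTATE] -= dt * kv[i] / mm[i];

    if ((s + 1) % rec_every == 0 && fk < n_frames) {
      ftimes[fk] = t0 + (s + 1) * dt;
      for (int i = 0; i < n; ++i) frames(i, fk) = Y[(size_t)i * NSTATE];
      ++fk;
    }
    if ((s & 255) == 0) {
      for (int i = 0; i < n; i += std::max(1, n / 64))
        if (!R_finite(Y[(size_t)i * NSTATE])) { ok = false; t_bad = t; break; }
      if (!ok) break;
      Rcpp::checkUserInterrupt();
    }
  }

  NumericMatrix out_state(n, NSTATE);
  for (int i = 0; i < n; ++i)
    for (int sv = 0; sv < NSTATE; ++sv) out_state(i, sv) = Y[(size_t)i * NSTATE + sv];

  if (fk < n_frames) {
    frames = frames(Range(0, n - 1), Range(0, std::max(0, fk - 1)));
    ftimes = ftimes[Range(0, std::max(0, fk - 1))];
  }
  return List::create(_["frames"] = frames, _["times"] = ftimes,
                      _["state"] = out_state, _["ok"] = ok,
                      _["t_bad"] = t_bad);
}
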