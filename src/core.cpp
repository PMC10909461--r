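// Compiled core: HGO constitutive kernels, bilinear mixed-mode cohesive
// point law, and global assembly of residual + consistent tangent for
// hexahedral bulk elements (selective reduced integration), zero-thickness
// cohesive interface elements and follower pressure faces.
//
// Units: mm, mN, kPa, mN/mm (energy per area).

#include <RcppArmadillo.h>
using namespace Rcpp;

typedef arma::mat::fixed<3, 3> mat33;
typedef arma::vec::fixed<3> vec3;

struct MatPar {
  double C10, k1, k2, kappa, D;
};

// ---------------------------------------------------------------------------
// HGO constitutive law (second Piola-Kirchhoff stress from C)
// part: 0 = full, 1 = isochoric (deviatoric-projected) part, 2 = volumetric
// ---------------------------------------------------------------------------
static void hgo_S(const mat33& C, const MatPar& mp, const vec3& M,
                  const vec3& N, int part, mat33& S) {
  double J2 = arma::det(C);
  double J = std::sqrt(std::max(J2, 1e-20));
  // explicit symmetric 3x3 inverse (no exceptions on near-singular input;
  // the caller guards det F > 0)
  mat33 Cinv;
  Cinv(0, 0) = C(1, 1) * C(2, 2) - C(1, 2) * C(2, 1);
  Cinv(0, 1) = C(0, 2) * C(2, 1) - C(0, 1) * C(2, 2);
  Cinv(0, 2) = C(0, 1) * C(1, 2) - C(0, 2) * C(1, 1);
  Cinv(1, 0) = C(1, 2) * C(2, 0) - C(1, 0) * C(2, 2);
  Cinv(1, 1) = C(0, 0) * C(2, 2) - C(0, 2) * C(2, 0);
  Cinv(1, 2) = C(0, 2) * C(1, 0) - C(0, 0) * C(1, 2);
  Cinv(2, 0) = C(1, 0) * C(2, 1) - C(1, 1) * C(2, 0);
  Cinv(2, 1) = C(0, 1) * C(2, 0) - C(0, 0) * C(2, 1);
  Cinv(2, 2) = C(0, 0) * C(1, 1) - C(0, 1) * C(1, 0);
  Cinv /= (J2 > 1e-20 ? J2 : 1e-20);
  S.zeros();
  if (part != 2) {
    double Jm23 = std::pow(J, -2.0 / 3.0);
    double I1b = Jm23 * arma::trace(C);
    double I4b = Jm23 * arma::as_scalar(M.t() * C * M);
    double I6b = Jm23 * arma::as_scalar(N.t() * C * N);
    mat33 I3(arma::fill::eye);
    mat33 dI1 = Jm23 * I3 - (I1b / 3.0) * Cinv;
    mat33 dI4 = Jm23 * (M * M.t()) - (I4b / 3.0) * Cinv;
    mat33 dI6 = Jm23 * (N * N.t()) - (I6b / 3.0) * Cinv;
    double e1 = mp.kappa * (I1b - 3.0) + (1.0 - 3.0 * mp.kappa) * (I4b - 1.0);
    double e2 = mp.kappa * (I1b - 3.0) + (1.0 - 3.0 * mp.kappa) * (I6b - 1.0);
    double p1 = (e1 > 0.0) ? mp.k1 * e1 * std::exp(mp.k2 * e1 * e1) : 0.0;
    double p2 = (e2 > 0.0) ? mp.k1 * e2 * std::exp(mp.k2 * e2 * e2) : 0.0;
    S += 2.0 * (mp.C10 * dI1 +
                p1 * (mp.kappa * dI1 + (1.0 - 3.0 * mp.kappa) * dI4) +
                p2 * (mp.kappa * dI1 + (1.0 - 3.0 * mp.kappa) * dI6));
  }
  if (part != 1) {
    S += (1.0 / mp.D) * (J2 - 1.0) * Cinv;
  }
}

static double hgo_W(const mat33& C, const MatPar& mp, const vec3& M,
                    const vec3& N, int part) {
  double J2 = arma::det(C);
  double J = std::sqrt(J2);
  double W = 0.0;
  if (part != 2) {
    double Jm23 = std::pow(J, -2.0 / 3.0);
    double I1b = Jm23 * arma::trace(C);
    double I4b = Jm23 * arma::as_scalar(M.t() * C * M);
    double I6b = Jm23 * arma::as_scalar(N.t() * C * N);
    double e1 = mp.kappa * (I1b - 3.0) + (1.0 - 3.0 * mp.kappa) * (I4b - 1.0);
    double e2 = mp.kappa * (I1b - 3.0) + (1.0 - 3.0 * mp.kappa) * (I6b - 1.0);
    W += mp.C10 * (I1b - 3.0);
    if (e1 > 0.0) W += mp.k1 / (2.0 * mp.k2) * (std::exp(mp.k2 * e1 * e1) - 1.0);
    if (e2 > 0.0) W += mp.k1 / (2.0 * mp.k2) * (std::exp(mp.k2 * e2 * e2) - 1.0);
  }
  if (part != 1) {
    W += (1.0 / mp.D) * ((J2 - 1.0) / 2.0 - std::log(J));
  }
  return W;
}

// analytic material tangent CC = 2 dS/dC of the HGO energy
static void hgo_CC(const mat33& C, const MatPar& mp, const vec3& M,
                   const vec3& N, int part, double CC[3][3][3][3]) {
  double J2 = arma::det(C);
  mat33 Cinv;
  Cinv(0, 0) = C(1, 1) * C(2, 2) - C(1, 2) * C(2, 1);
  Cinv(0, 1) = C(0, 2) * C(2, 1) - C(0, 1) * C(2, 2);
  Cinv(0, 2) = C(0, 1) * C(1, 2) - C(0, 2) * C(1, 1);
  Cinv(1, 0) = C(1, 2) * C(2, 0) - C(1, 0) * C(2, 2);
  Cinv(1, 1) = C(0, 0) * C(2, 2) - C(0, 2) * C(2, 0);
  Cinv(1, 2) = C(0, 2) * C(1, 0) - C(0, 0) * C(1, 2);
  Cinv(2, 0) = C(1, 0) * C(2, 1) - C(1, 1) * C(2, 0);
  Cinv(2, 1) = C(0, 1) * C(2, 0) - C(0, 0) * C(2, 1);
  Cinv(2, 2) = C(0, 0) * C(1, 1) - C(0, 1) * C(1, 0);
  Cinv /= (J2 > 1e-20 ? J2 : 1e-20);
  // dCinv_AB/dC_CD = -1/2 (Cinv_AC Cinv_BD + Cinv_AD Cinv_BC)
  double dCi[3][3][3][3];
  for (int A = 0; A < 3; ++A)
    for (int B = 0; B < 3; ++B)
      for (int Cc = 0; Cc < 3; ++Cc)
        for (int D = 0; D < 3; ++D)
          dCi[A][B][Cc][D] = -0.5 * (Cinv(A, Cc) * Cinv(B, D) +
                                     Cinv(A, D) * Cinv(B, Cc));
  for (int A = 0; A < 3; ++A)
    for (int B = 0; B < 3; ++B)
      for (int Cc = 0; Cc < 3; ++Cc)
        for (int D = 0; D < 3; ++D) CC[A][B][Cc][D] = 0.0;

  if (part != 2) {
    double u = std::pow(std::max(J2, 1e-20), -1.0 / 3.0);  // J^(-2/3)
    mat33 X[3];
    X[0].eye();
    X[1] = M * M.t();
    X[2] = N * N.t();
    double Jinv[3] = {arma::trace(C),
                      arma::as_scalar(M.t() * C * M),
                      arma::as_scalar(N.t() * C * N)};
    double I[3] = {u * Jinv[0], u * Jinv[1], u * Jinv[2]};
    mat33 G[3];
    for (int a = 0; a < 3; ++a) G[a] = u * X[a] - (I[a] / 3.0) * Cinv;
    double e1 = mp.kappa * (I[0] - 3.0) + (1.0 - 3.0 * mp.kappa) * (I[1] - 1.0);
    double e2 = mp.kappa * (I[0] - 3.0) + (1.0 - 3.0 * mp.kappa) * (I[2] - 1.0);
    double eps[2] = {e1, e2};
    mat33 Ge[2];
    Ge[0] = mp.kappa * G[0] + (1.0 - 3.0 * mp.kappa) * G[1];
    Ge[1] = mp.kappa * G[0] + (1.0 - 3.0 * mp.kappa) * G[2];
    double psi[2], dpsi[2];
    for (int i = 0; i < 2; ++i) {
      if (eps[i] > 0.0) {
        double ex = std::exp(mp.k2 * eps[i] * eps[i]);
        psi[i] = mp.k1 * eps[i] * ex;
        dpsi[i] = mp.k1 * (1.0 + 2.0 * mp.k2 * eps[i] * eps[i]) * ex;
      } else {
        psi[i] = dpsi[i] = 0.0;
      }
    }
    // dG_a/dC = -(1/3)[u X_a (x) Cinv + Cinv (x) G_a] - (I_a/3) dCi ... with
    // the last term +(I_a/3)*(-dCi) sign folded below
    // coefficient in front of each structural piece:
    //   w_a for dG_a/dC :  c10 on a=0, psi_i*(kappa or 1-3kappa) on a=1,2
    double wa[3];
    wa[0] = mp.C10 + (psi[0] + psi[1]) * mp.kappa;
    wa[1] = psi[0] * (1.0 - 3.0 * mp.kappa);
    wa[2] = psi[1] * (1.0 - 3.0 * mp.kappa);
    for (int A = 0; A < 3; ++A)
      for (int B = 0; B < 3; ++B)
        for (int Cc = 0; Cc < 3; ++Cc)
          for (int D = 0; D < 3; ++D) {
            double s = 0.0;
            for (int a = 0; a < 3; ++a) {
              if (wa[a] == 0.0) continue;
              s += wa[a] * (-(u / 3.0) * X[a](A, B) * Cinv(Cc, D)
                            - (1.0 / 3.0) * Cinv(A, B) * G[a](Cc, D)
                            - (I[a] / 3.0) * dCi[A][B][Cc][D]);
            }
            for (int i = 0; i < 2; ++i) {
              if (dpsi[i] != 0.0)
                s += dpsi[i] * Ge[i](A, B) * Ge[i](Cc, D);
            }
            CC[A][B][Cc][D] += 4.0 * s;  // CC = 2 dS/dC, S carries factor 2
          }
  }
  if (part != 1) {
    for (int A = 0; A < 3; ++A)
      for (int B = 0; B < 3; ++B)
        for (int Cc = 0; Cc < 3; ++Cc)
          for (int D = 0; D < 3; ++D)
            CC[A][B][Cc][D] += (2.0 / mp.D) *
              (J2 * Cinv(Cc, D) * Cinv(A, B) +
               (J2 - 1.0) * dCi[A][B][Cc][D]);
  }
}

// ---------------------------------------------------------------------------
// Hexahedral element (8-node, trilinear) with selective reduced integration:
// isochoric part at 2x2x2 Gauss points, volumetric part at the centroid.
// ---------------------------------------------------------------------------
static const double GP1 = 0.577350269189625764509148780502;

static void hex_shape(double xi, double eta, double zeta,
                      double Nf[8], double dN[8][3]) {
  static const double sg[8][3] = {
      {-1, -1, -1}, {1, -1, -1}, {1, 1, -1}, {-1, 1, -1},
      {-1, -1, 1},  {1, -1, 1},  {1, 1, 1},  {-1, 1, 1}};
  for (int I = 0; I < 8; ++I) {
    double a = sg[I][0], b = sg[I][1], c = sg[I][2];
    Nf[I] = 0.125 * (1 + a * xi) * (1 + b * eta) * (1 + c * zeta);
    dN[I][0] = 0.125 * a * (1 + b * eta) * (1 + c * zeta);
    dN[I][1] = 0.125 * b * (1 + a * xi) * (1 + c * zeta);
    dN[I][2] = 0.125 * c * (1 + a * xi) * (1 + b * eta);
  }
}

// one integration point contribution (stress + optionally stiffness)
static bool hex_point(const mat33& Fpre, const double G[8][3],
                      const double ue[8][3], const MatPar& mp,
                      const vec3& M, const vec3& N, int part, double w,
                      bool wantK, double fe[24], double* Ke,
                      double* Wacc, double* minJ) {
  // modified gradients Gt_I = Fpre^T G_I ; F = Fpre + sum u_I (x) Gt_I
  double Gt[8][3];
  for (int I = 0; I < 8; ++I)
    for (int A = 0; A < 3; ++A) {
      double s = 0.0;
      for (int B = 0; B < 3; ++B) s += Fpre(B, A) * G[I][B];
      Gt[I][A] = s;
    }
  mat33 F = Fpre;
  for (int I = 0; I < 8; ++I)
    for (int i = 0; i < 3; ++i)
      for (int A = 0; A < 3; ++A) F(i, A) += ue[I][i] * Gt[I][A];
  double J = arma::det(F);
  if (J < *minJ) *minJ = J;
  if (J <= 1e-10) return false;
  mat33 C = F.t() * F;
  mat33 S;
  hgo_S(C, mp, M, N, part, S);
  if (Wacc) *Wacc += w * hgo_W(C, mp, M, N, part);
  mat33 P = F * S;
  for (int I = 0; I < 8; ++I)
    for (int i = 0; i < 3; ++i) {
      double s = 0.0;
      for (int A = 0; A < 3; ++A) s += P(i, A) * Gt[I][A];
      fe[3 * I + i] += w * s;
    }
  if (wantK) {
    double CC[3][3][3][3];
    hgo_CC(C, mp, M, N, part, CC);
    // Voigt 6x6 material matrix (order 11,22,33,12,13,23; engineering
    // shear convention) and the Green-Lagrange B operator
    static const int VA[6] = {0, 1, 2, 0, 0, 1};
    static const int VB[6] = {0, 1, 2, 1, 2, 2};
    double D6[6][6];
    for (int a = 0; a < 6; ++a)
      for (int b = 0; b < 6; ++b)
        D6[a][b] = CC[VA[a]][VB[a]][VA[b]][VB[b]];
    double Bm[6][24];
    for (int J = 0; J < 8; ++J)
      for (int j = 0; j < 3; ++j) {
        int col = 3 * J + j;
        Bm[0][col] = F(j, 0) * Gt[J][0];
        Bm[1][col] = F(j, 1) * Gt[J][1];
        Bm[2][col] = F(j, 2) * Gt[J][2];
        Bm[3][col] = F(j, 0) * Gt[J][1] + F(j, 1) * Gt[J][0];
        Bm[4][col] = F(j, 0) * Gt[J][2] + F(j, 2) * Gt[J][0];
        Bm[5][col] = F(j, 1) * Gt[J][2] + F(j, 2) * Gt[J][1];
      }
    double DB[6][24];
    for (int a = 0; a < 6; ++a)
      for (int c = 0; c < 24; ++c) {
        double s = 0.0;
        for (int b = 0; b < 6; ++b) s += D6[a][b] * Bm[b][c];
        DB[a][c] = s;
      }
    for (int r = 0; r < 24; ++r)
      for (int c = 0; c < 24; ++c) {
        double s = 0.0;
        for (int a = 0; a < 6; ++a) s += Bm[a][r] * DB[a][c];
        Ke[r * 24 + c] += w * s;
      }
    // geometric part: delta_ij G_I . S . G_J
    double SG[8][3];
    for (int J = 0; J < 8; ++J)
      for (int A = 0; A < 3; ++A) {
        double s = 0.0;
        for (int B = 0; B < 3; ++B) s += S(A, B) * Gt[J][B];
        SG[J][A] = s;
      }
    for (int I = 0; I < 8; ++I)
      for (int J = 0; J < 8; ++J) {
        double g = Gt[I][0] * SG[J][0] + Gt[I][1] * SG[J][1] +
                   Gt[I][2] * SG[J][2];
        for (int i = 0; i < 3; ++i)
          Ke[(3 * I + i) * 24 + (3 * J + i)] += w * g;
      }
  }
  return true;
}

// ---------------------------------------------------------------------------
// Bilinear mixed-mode cohesive point law.
//
// Effective-separation damage with the mode mix evaluated instantaneously;
// initiation from the quadratic nominal stress criterion, final failure
// from the power-law criterion on dissipated energies. Per-mode energies
// are integrated incrementally (work minus change of recoverable energy).
//
// state (length 10): d, delmax, GI, GII, GIII, failed, Gstab, dn0, ds0, dt0
// par   (length 12): Kn, Ks, Kt, TnC, TsC, TtC, GIC, GIIC, GIIIC, alpha,
//                    Kc (contact penalty), mu (viscous regularization)
// ---------------------------------------------------------------------------
struct CohPar {
  double Kn, Ks, Kt, TnC, TsC, TtC, GIC, GIIC, GIIIC, alpha, Kc, mu;
};

// contact penalty for failed/torn faces, C1-smoothed near zero gap
// (quadratic blend over a small depth dc)
// Exponential contact backstop: a smooth, adhesion-free penalty that
// resists interpenetration of every interface point (alive or removed).
// T = -A exp(-dn/w): negligible at open gaps, stiffening exponentially
// under penetration. Smoothness (no active set, no kinks) keeps Newton
// quadratic; the price is a small penetration depth ~ w ln(p/A).
static inline double contact_w(const CohPar& p) {
  return 0.025 * p.TnC / p.Kn;     // ~2e-3 mm for the bundled mode-I set
}
static inline double contact_A(const CohPar& p) {
  return 5e-4 * p.TnC;             // ~0.07 kPa bias at zero gap
}
static inline double contact_traction(double dn, const CohPar& p) {
  double ex = -dn / contact_w(p);
  if (ex > 60.0) ex = 60.0;        // cap: ~1e26 would overflow the solve
  return -contact_A(p) * std::exp(ex);
}
static inline double contact_slope(double dn, const CohPar& p) {
  return -contact_traction(dn, p) / contact_w(p);
}

static void czm_tractions(const double d, const double sep[3],
                          const CohPar& p, bool dead, double T[3]) {
  double dn = sep[0];
  double Tc = contact_traction(dn, p);
  if (dead) {
    T[0] = Tc;
    T[1] = 0.0;
    T[2] = 0.0;
    return;
  }
  // secant stiffness through the origin in the normal direction as well:
  // compression neither damages nor dissipates (Macaulay brackets in the
  // criteria and the energy bookkeeping), and the contact backstop
  // carries deep compression of damaged points
  T[0] = (1.0 - d) * p.Kn * dn + Tc;
  T[1] = (1.0 - d) * p.Ks * sep[1];
  T[2] = (1.0 - d) * p.Kt * sep[2];
}

// Dt (optional, 3x3 row-major): branch-consistent local tangent
// dT/dsep, including the damage-evolution coupling while damage grows.
static void czm_update(const double st[10], const double sep[3],
                       const CohPar& p, bool torn, double dtime,
                       double T[3], double* finit, double* gfail,
                       double nst[10], double* Dt = 0) {
  for (int i = 0; i < 10; ++i) nst[i] = st[i];
  bool failed = torn || st[5] > 0.5;
  double dnp = std::max(sep[0], 0.0);
  double dm = std::sqrt(dnp * dnp + sep[1] * sep[1] + sep[2] * sep[2]);
  double d_new = st[0];
  double dddm = 0.0, beta[3] = {0, 0, 0};
  if (!failed && dm > 1e-14) {
    double bn = dnp / dm, bs = sep[1] / dm, bt = sep[2] / dm;
    double q = std::pow(p.Kn * bn / p.TnC, 2) +
               std::pow(p.Ks * bs / p.TsC, 2) +
               std::pow(p.Kt * bt / p.TtC, 2);
    double dm0 = 1.0 / std::sqrt(q);
    // failure separation from the power law under proportional softening
    double a = p.alpha;
    double ssum = std::pow(0.5 * p.Kn * bn * bn * dm0 / p.GIC, a) +
                  std::pow(0.5 * p.Ks * bs * bs * dm0 / p.GIIC, a) +
                  std::pow(0.5 * p.Kt * bt * bt * dm0 / p.GIIIC, a);
    double dmf = std::pow(ssum, -1.0 / a);
    double dmax = std::max(st[1], dm);
    nst[1] = dmax;
    if (dmax > dm0 && dmf > dm0) {
      double dt_ = dmf * (dmax - dm0) / (dmax * (dmf - dm0));
      bool clamped = dt_ >= 1.0;
      if (dt_ > 1.0) dt_ = 1.0;
      if (dt_ < 0.0) dt_ = 0.0;
      // viscous regularization (Duvaut-Lions on the damage variable)
      double dused = dt_;
      double visc_fac = 1.0;
      if (p.mu > 0.0 && dtime > 0.0) {
        visc_fac = dtime / (p.mu + dtime);
        dused = (p.mu * st[0] + dtime * dt_) / (p.mu + dtime);
      }
      if (dused > d_new) {
        d_new = dused;
        // damage is actively evolving: record the slope wrt the
        // effective separation for the consistent tangent
        if (!clamped && dm >= dmax - 1e-14) {
          dddm = visc_fac * dmf * dm0 / (dm * dm * (dmf - dm0));
          beta[0] = bn; beta[1] = bs; beta[2] = bt;
        }
      }
      if (d_new > 1.0) d_new = 1.0;
      // stabilization energy proxy: extra stored energy held by viscosity
      double el = 0.5 * (p.Kn * dnp * dnp + p.Ks * sep[1] * sep[1] +
                         p.Kt * sep[2] * sep[2]);
      double gs = (dt_ - d_new) * el;
      if (gs > nst[6]) nst[6] = gs;  // track the running maximum
    }
  }
  nst[0] = d_new;
  czm_tractions(d_new, sep, p, failed, T);
  // energy bookkeeping: increment from last committed separations
  double To[3], sold[3] = {st[7], st[8], st[9]};
  czm_tractions(st[0], sold, p, torn || st[5] > 0.5, To);
  double GI = st[2], GII = st[3], GIII = st[4];
  // mode I uses the tensile cohesive part only; contact work (the
  // exponential backstop) is not fracture dissipation
  bool dead0 = torn || st[5] > 0.5;
  double Tn1 = failed ? 0.0 : (1.0 - d_new) * p.Kn * std::max(sep[0], 0.0);
  double Tn0 = dead0 ? 0.0 : (1.0 - st[0]) * p.Kn * std::max(sold[0], 0.0);
  double dn1 = std::max(sep[0], 0.0), dn0 = std::max(sold[0], 0.0);
  double dGI = 0.5 * (Tn0 + Tn1) * (dn1 - dn0) -
               (0.5 * Tn1 * dn1 - 0.5 * Tn0 * dn0);
  double dGII = 0.5 * (To[1] + T[1]) * (sep[1] - sold[1]) -
                (0.5 * T[1] * sep[1] - 0.5 * To[1] * sold[1]);
  double dGIII = 0.5 * (To[2] + T[2]) * (sep[2] - sold[2]) -
                 (0.5 * T[2] * sep[2] - 0.5 * To[2] * sold[2]);
  GI += std::max(dGI, 0.0);
  GII += std::max(dGII, 0.0);
  GIII += std::max(dGIII, 0.0);
  nst[2] = GI; nst[3] = GII; nst[4] = GIII;
  nst[7] = sep[0]; nst[8] = sep[1]; nst[9] = sep[2];
  double g = std::pow(GI / p.GIC, p.alpha) +
             std::pow(GII / p.GIIC, p.alpha) +
             std::pow(GIII / p.GIIIC, p.alpha);
  *gfail = g;
  // complete damage: the power law is met, or the damage variable has
  // exhausted the traction capacity (d = 1, at which the dissipated
  // energies equal their bilinear-triangle asymptotes)
  // a point failing within the current step keeps its (small) softening
  // traction until the step is committed; removal takes effect at the
  // next increment, which keeps the Newton residual continuous
  if (!torn && (g >= 1.0 - 1e-6 || d_new >= 1.0 - 1e-9)) nst[5] = 1.0;
  double Tn = std::max(T[0], 0.0);
  *finit = std::pow(Tn / p.TnC, 2) + std::pow(T[1] / p.TsC, 2) +
           std::pow(T[2] / p.TtC, 2);
  if (Dt) {
    for (int i = 0; i < 9; ++i) Dt[i] = 0.0;
    if (failed) {
      Dt[0] = contact_slope(sep[0], p);
    } else {
      Dt[0] = (1.0 - d_new) * p.Kn + contact_slope(sep[0], p);
      Dt[4] = (1.0 - d_new) * p.Ks;
      Dt[8] = (1.0 - d_new) * p.Kt;
      if (dddm > 0.0) {
        double tv[3] = {(sep[0] > 0.0) ? p.Kn * sep[0] : 0.0,
                        p.Ks * sep[1], p.Kt * sep[2]};
        for (int i = 0; i < 3; ++i)
          for (int j = 0; j < 3; ++j)
            Dt[3 * i + j] -= tv[i] * dddm * beta[j];
      }
    }
  }
}

// [[Rcpp::export(name = ".czm_update_cpp")]]
List czm_update_cpp(NumericVector state, NumericVector sep, NumericVector par,
                    bool torn, double dtime) {
  CohPar p = {par[0], par[1], par[2], par[3], par[4],  par[5],
              par[6], par[7], par[8], par[9], par[10], par[11]};
  double T[3], fi, gf, nst[10];
  double st[10], sp[3];
  for (int i = 0; i < 10; ++i) st[i] = state[i];
  for (int i = 0; i < 3; ++i) sp[i] = sep[i];
  czm_update(st, sp, p, torn, dtime, T, &fi, &gf, nst);
  return List::create(_["state"] = NumericVector(nst, nst + 10),
                      _["traction"] = NumericVector(T, T + 3),
                      _["initiation_value"] = fi, _["failure_value"] = gf);
}

// ---------------------------------------------------------------------------
// Cohesive element (8-node zero-thickness, Newton-Cotes integration at the
// four corner node pairs, co-rotational local frame from the deformed
// mid-surface; e1 follows the xi direction = mode II, e2 = n x e1 = mode III)
// ---------------------------------------------------------------------------
static void coh_residual(const double Xe[8][3], const double ue[8][3],
                         const double stc[4][10], const CohPar& p, bool torn,
                         double dtime, const double area[4],
                         double fe[24], double nst[4][10],
                         double fi[4], double gf[4], double* Ke = 0) {
  static const double xc[4] = {-1, 1, 1, -1};
  static const double ec[4] = {-1, -1, 1, 1};
  for (int i = 0; i < 24; ++i) fe[i] = 0.0;
  if (Ke) for (int i = 0; i < 576; ++i) Ke[i] = 0.0;
  for (int k = 0; k < 4; ++k) {
    // deformed mid-surface tangents at corner k (bilinear on 4 mid-nodes)
    double xm[4][3];
    for (int a = 0; a < 4; ++a)
      for (int i = 0; i < 3; ++i)
        xm[a][i] = 0.5 * (Xe[a][i] + ue[a][i] + Xe[a + 4][i] + ue[a + 4][i]);
    double t1[3], t2[3];
    for (int i = 0; i < 3; ++i) {
      double s1 = 0.0, s2 = 0.0;
      for (int a = 0; a < 4; ++a) {
        s1 += 0.25 * xc[a] * (1 + ec[a] * ec[k]) * xm[a][i];
        s2 += 0.25 * ec[a] * (1 + xc[a] * xc[k]) * xm[a][i];
      }
      t1[i] = s1; t2[i] = s2;
    }
    double n1 = std::sqrt(t1[0] * t1[0] + t1[1] * t1[1] + t1[2] * t1[2]);
    double e1[3] = {t1[0] / n1, t1[1] / n1, t1[2] / n1};
    double nn[3] = {t1[1] * t2[2] - t1[2] * t2[1],
                    t1[2] * t2[0] - t1[0] * t2[2],
                    t1[0] * t2[1] - t1[1] * t2[0]};
    double nl = std::sqrt(nn[0] * nn[0] + nn[1] * nn[1] + nn[2] * nn[2]);
    for (int i = 0; i < 3; ++i) nn[i] /= nl;
    double e2[3] = {nn[1] * e1[2] - nn[2] * e1[1],
                    nn[2] * e1[0] - nn[0] * e1[2],
                    nn[0] * e1[1] - nn[1] * e1[0]};
    // separation of corner pair k
    double Dv[3];
    for (int i = 0; i < 3; ++i)
      Dv[i] = (Xe[k + 4][i] + ue[k + 4][i]) - (Xe[k][i] + ue[k][i]);
    double sep[3] = {Dv[0] * nn[0] + Dv[1] * nn[1] + Dv[2] * nn[2],
                     Dv[0] * e1[0] + Dv[1] * e1[1] + Dv[2] * e1[2],
                     Dv[0] * e2[0] + Dv[1] * e2[1] + Dv[2] * e2[2]};
    double T[3], Dt[9];
    czm_update(stc[k], sep, p, torn, dtime, T, &fi[k], &gf[k], nst[k],
               Ke ? Dt : 0);
    double Tg[3];
    for (int i = 0; i < 3; ++i)
      Tg[i] = T[0] * nn[i] + T[1] * e1[i] + T[2] * e2[i];
    for (int i = 0; i < 3; ++i) {
      fe[3 * (k + 4) + i] += area[k] * Tg[i];
      fe[3 * k + i] -= area[k] * Tg[i];
    }
    if (Ke) {
      // co-rotational tangent: M = area * B D B^T with B = [n e1 e2];
      // frame-rotation and area-change derivatives are neglected
      double B[3][3];
      for (int i = 0; i < 3; ++i) {
        B[i][0] = nn[i]; B[i][1] = e1[i]; B[i][2] = e2[i];
      }
      double M[3][3];
      for (int i = 0; i < 3; ++i)
        for (int j = 0; j < 3; ++j) {
          double acc = 0.0;
          for (int a = 0; a < 3; ++a)
            for (int b = 0; b < 3; ++b)
              acc += B[i][a] * Dt[3 * a + b] * B[j][b];
          M[i][j] = area[k] * acc;
        }
      int tb[2] = {3 * (k + 4), 3 * k};
      double sg[2] = {1.0, -1.0};
      for (int r = 0; r < 2; ++r)
        for (int c = 0; c < 2; ++c) {
          double ss = sg[r] * sg[c];
          for (int i = 0; i < 3; ++i)
            for (int j = 0; j < 3; ++j)
              Ke[(tb[r] + i) * 24 + (tb[c] + j)] += ss * M[i][j];
        }
    }
  }
}

// ---------------------------------------------------------------------------
// Follower pressure on a 4-node quad face: f_I = p int N_I (x_xi x x_eta)
// ---------------------------------------------------------------------------
static void face_pressure(const double xe[4][3], double pval,
                          bool wantK, double fe[12], double Ke[12][12]) {
  for (int i = 0; i < 12; ++i) fe[i] = 0.0;
  if (wantK)
    for (int i = 0; i < 12; ++i)
      for (int j = 0; j < 12; ++j) Ke[i][j] = 0.0;
  static const double sg[4][2] = {{-1, -1}, {1, -1}, {1, 1}, {-1, 1}};
  for (int g = 0; g < 4; ++g) {
    double xi = GP1 * sg[g][0], eta = GP1 * sg[g][1];
    double Nf[4], dNx[4], dNe[4];
    for (int a = 0; a < 4; ++a) {
      Nf[a] = 0.25 * (1 + sg[a][0] * xi) * (1 + sg[a][1] * eta);
      dNx[a] = 0.25 * sg[a][0] * (1 + sg[a][1] * eta);
      dNe[a] = 0.25 * sg[a][1] * (1 + sg[a][0] * xi);
    }
    double t1[3] = {0, 0, 0}, t2[3] = {0, 0, 0};
    for (int a = 0; a < 4; ++a)
      for (int i = 0; i < 3; ++i) {
        t1[i] += dNx[a] * xe[a][i];
        t2[i] += dNe[a] * xe[a][i];
      }
    double cr[3] = {t1[1] * t2[2] - t1[2] * t2[1],
                    t1[2] * t2[0] - t1[0] * t2[2],
                    t1[0] * t2[1] - t1[1] * t2[0]};
    for (int a = 0; a < 4; ++a)
      for (int i = 0; i < 3; ++i) fe[3 * a + i] += pval * Nf[a] * cr[i];
    if (wantK) {
      // d(t1 x t2)/dx_bj
      for (int b = 0; b < 4; ++b)
        for (int j = 0; j < 3; ++j) {
          double dt1[3] = {0, 0, 0}, dt2[3] = {0, 0, 0};
          dt1[j] = dNx[b];
          dt2[j] = dNe[b];
          double dcr[3] = {
              dt1[1] * t2[2] - dt1[2] * t2[1] + t1[1] * dt2[2] - t1[2] * dt2[1],
              dt1[2] * t2[0] - dt1[0] * t2[2] + t1[2] * dt2[0] - t1[0] * dt2[2],
              dt1[0] * t2[1] - dt1[1] * t2[0] + t1[0] * dt2[1] - t1[1] * dt2[0]};
          for (int a = 0; a < 4; ++a)
            for (int i = 0; i < 3; ++i)
              Ke[3 * a + i][3 * b + j] += pval * Nf[a] * dcr[i];
        }
    }
  }
}

// ---------------------------------------------------------------------------
// Global assembly
// ---------------------------------------------------------------------------
// [[Rcpp::export(name = ".assemble_cpp")]]
List assemble_cpp(NumericMatrix coords, NumericVector u,
                  IntegerMatrix hex, IntegerVector hexmat, NumericMatrix matpar,
                  NumericMatrix fibM, NumericMatrix fibN, NumericMatrix Fpre,
                  IntegerMatrix coh, LogicalVector coh_torn,
                  NumericMatrix cohstate, NumericVector cohpar,
                  IntegerMatrix pfaces, NumericVector pvals,
                  double dtime, bool want_matrix) {
  int nn = coords.nrow();
  int ndof = 3 * nn;
  int nhex = hex.nrow();
  int ncoh = coh.nrow();
  int nface = pfaces.nrow();
  bool has_pre = Fpre.nrow() == nhex * 8;
  NumericVector fint(ndof), fext(ndof);
  NumericMatrix nstate(cohstate.nrow(), cohstate.ncol());
  std::vector<int> ti, tj;
  std::vector<double> tx;
  if (want_matrix) {
    ti.reserve((size_t)nhex * 576 + (size_t)ncoh * 576 + (size_t)nface * 144);
    tj.reserve(ti.capacity());
    tx.reserve(ti.capacity());
  }
  double minJ = 1e30, Wbulk = 0.0, maxfi = 0.0, maxgf = 0.0, maxd = 0.0;
  int nfailed = 0, nnewfail = 0;
  bool bad = false;

  // --- bulk hexahedra ------------------------------------------------------
  double Ke[576];
  for (int e = 0; e < nhex && !bad; ++e) {
    double Xe[8][3], ue[8][3];
    int idx[8];
    for (int a = 0; a < 8; ++a) {
      idx[a] = hex(e, a) - 1;
      for (int i = 0; i < 3; ++i) {
        Xe[a][i] = coords(idx[a], i);
        ue[a][i] = u[3 * idx[a] + i];
      }
    }
    MatPar mp = {matpar(hexmat[e] - 1, 0), matpar(hexmat[e] - 1, 1),
                 matpar(hexmat[e] - 1, 2), matpar(hexmat[e] - 1, 3),
                 matpar(hexmat[e] - 1, 4)};
    vec3 M = {fibM(e, 0), fibM(e, 1), fibM(e, 2)};
    vec3 N = {fibN(e, 0), fibN(e, 1), fibN(e, 2)};
    double fe[24];
    for (int i = 0; i < 24; ++i) fe[i] = 0.0;
    if (want_matrix)
      for (int i = 0; i < 576; ++i) Ke[i] = 0.0;
    // 2x2x2 Gauss for the isochoric part
    mat33 FpreC(arma::fill::zeros);
    double Vtot = 0.0;
    int gp = 0;
    for (int gz = 0; gz < 2 && !bad; ++gz)
      for (int gy = 0; gy < 2 && !bad; ++gy)
        for (int gx = 0; gx < 2 && !bad; ++gx, ++gp) {
          double xi = GP1 * (gx ? 1 : -1), eta = GP1 * (gy ? 1 : -1),
                 zeta = GP1 * (gz ? 1 : -1);
          double Nf[8], dN[8][3];
          hex_shape(xi, eta, zeta, Nf, dN);
          mat33 Jac(arma::fill::zeros);
          for (int a = 0; a < 8; ++a)
            for (int i = 0; i < 3; ++i)
              for (int A = 0; A < 3; ++A) Jac(A, i) += dN[a][A] * Xe[a][i];
          double dJ0 = arma::det(Jac);
          if (dJ0 <= 0) { bad = true; break; }
          mat33 Ji = arma::inv(Jac);
          double G[8][3];
          for (int a = 0; a < 8; ++a)
            for (int A = 0; A < 3; ++A) {
              double s = 0.0;
              for (int B = 0; B < 3; ++B) s += Ji(A, B) * dN[a][B];
              G[a][A] = s;
            }
          mat33 Fp(arma::fill::eye);
          if (has_pre) {
            for (int i = 0; i < 3; ++i)
              for (int A = 0; A < 3; ++A) Fp(i, A) = Fpre(e * 8 + gp, 3 * i + A);
          }
          FpreC += Fp / 8.0;
          Vtot += dJ0;
          if (!hex_point(Fp, G, ue, mp, M, N, 1, dJ0, want_matrix, fe,
                         want_matrix ? Ke : nullptr, &Wbulk, &minJ))
            bad = true;
        }
    if (bad) break;
    // centroid point for the volumetric part
    {
      double Nf[8], dN[8][3];
      hex_shape(0.0, 0.0, 0.0, Nf, dN);
      mat33 Jac(arma::fill::zeros);
      for (int a = 0; a < 8; ++a)
        for (int i = 0; i < 3; ++i)
          for (int A = 0; A < 3; ++A) Jac(A, i) += dN[a][A] * Xe[a][i];
      double dJ0 = arma::det(Jac);
      if (dJ0 <= 0) { bad = true; }
      else {
        mat33 Ji = arma::inv(Jac);
        double G[8][3];
        for (int a = 0; a < 8; ++a)
          for (int A = 0; A < 3; ++A) {
            double s = 0.0;
            for (int B = 0; B < 3; ++B) s += Ji(A, B) * dN[a][B];
            G[a][A] = s;
          }
        if (!hex_point(FpreC, G, ue, mp, M, N, 2, Vtot, want_matrix, fe,
                       want_matrix ? Ke : nullptr, &Wbulk, &minJ))
          bad = true;
      }
    }
    if (bad) break;
    for (int a = 0; a < 8; ++a)
      for (int i = 0; i < 3; ++i) fint[3 * idx[a] + i] += fe[3 * a + i];
    if (want_matrix)
      for (int a = 0; a < 8; ++a)
        for (int i = 0; i < 3; ++i)
          for (int b = 0; b < 8; ++b)
            for (int j = 0; j < 3; ++j) {
              ti.push_back(3 * idx[a] + i);
              tj.push_back(3 * idx[b] + j);
              tx.push_back(Ke[(3 * a + i) * 24 + (3 * b + j)]);
            }
  }

  // --- cohesive elements ---------------------------------------------------
  CohPar cp = {cohpar[0], cohpar[1], cohpar[2], cohpar[3],
               cohpar[4], cohpar[5], cohpar[6], cohpar[7],
               cohpar[8], cohpar[9], cohpar[10], cohpar[11]};
  if (!bad)
    for (int e = 0; e < ncoh; ++e) {
      double Xe[8][3], ue[8][3];
      int idx[8];
      for (int a = 0; a < 8; ++a) {
        idx[a] = coh(e, a) - 1;
        for (int i = 0; i < 3; ++i) {
          Xe[a][i] = coords(idx[a], i);
          ue[a][i] = u[3 * idx[a] + i];
        }
      }
      // reference tributary areas of the four corners (Newton-Cotes)
      double area[4];
      {
        static const double xc[4] = {-1, 1, 1, -1};
        static const double ec[4] = {-1, -1, 1, 1};
        for (int k = 0; k < 4; ++k) {
          double t1[3] = {0, 0, 0}, t2[3] = {0, 0, 0};
          for (int a = 0; a < 4; ++a)
            for (int i = 0; i < 3; ++i) {
              double Xm = 0.5 * (Xe[a][i] + Xe[a + 4][i]);
              t1[i] += 0.25 * xc[a] * (1 + ec[a] * ec[k]) * Xm;
              t2[i] += 0.25 * ec[a] * (1 + xc[a] * xc[k]) * Xm;
            }
          double cr[3] = {t1[1] * t2[2] - t1[2] * t2[1],
                          t1[2] * t2[0] - t1[0] * t2[2],
                          t1[0] * t2[1] - t1[1] * t2[0]};
          area[k] = std::sqrt(cr[0] * cr[0] + cr[1] * cr[1] + cr[2] * cr[2]);
        }
      }
      double stc[4][10], nst[4][10], fi[4], gf[4], fe[24];
      for (int k = 0; k < 4; ++k)
        for (int c = 0; c < 10; ++c) stc[k][c] = cohstate(e * 4 + k, c);
      bool torn = coh_torn[e];
      coh_residual(Xe, ue, stc, cp, torn, dtime, area, fe, nst, fi, gf);
      for (int k = 0; k < 4; ++k) {
        for (int c = 0; c < 10; ++c) nstate(e * 4 + k, c) = nst[k][c];
        if (!torn) {
          if (fi[k] > maxfi) maxfi = fi[k];
          if (gf[k] > maxgf) maxgf = gf[k];
          if (nst[k][0] > maxd) maxd = nst[k][0];
          if (nst[k][5] > 0.5) {
            ++nfailed;
            if (stc[k][5] < 0.5) ++nnewfail;
          }
        }
      }
      for (int a = 0; a < 8; ++a)
        for (int i = 0; i < 3; ++i) fint[3 * idx[a] + i] += fe[3 * a + i];
      if (want_matrix) {
        // central-difference element tangent: captures the co-rotational
        // frame coupling between corner pairs exactly; the point law is
        // smooth at the bonded operating state (full compression
        // stiffness), so differencing does not straddle a kink
        double hstep = 1e-6;
        double fp[24], fm[24], n1[4][10], f1[4], g1[4];
        for (int b = 0; b < 8; ++b)
          for (int j = 0; j < 3; ++j) {
            double keep = ue[b][j];
            ue[b][j] = keep + hstep;
            coh_residual(Xe, ue, stc, cp, torn, dtime, area, fp, n1, f1, g1);
            ue[b][j] = keep - hstep;
            coh_residual(Xe, ue, stc, cp, torn, dtime, area, fm, n1, f1, g1);
            ue[b][j] = keep;
            for (int a = 0; a < 8; ++a)
              for (int i = 0; i < 3; ++i) {
                ti.push_back(3 * idx[a] + i);
                tj.push_back(3 * idx[b] + j);
                tx.push_back((fp[3 * a + i] - fm[3 * a + i]) /
                             (2.0 * hstep));
              }
          }
      }
    }

  // --- pressure faces ------------------------------------------------------
  if (!bad)
    for (int f = 0; f < nface; ++f) {
      if (pvals[f] == 0.0) continue;
      double xe[4][3];
      int idx[4];
      for (int a = 0; a < 4; ++a) {
        idx[a] = pfaces(f, a) - 1;
        for (int i = 0; i < 3; ++i)
          xe[a][i] = coords(idx[a], i) + u[3 * idx[a] + i];
      }
      double fe[12], Kf[12][12];
      face_pressure(xe, pvals[f], want_matrix, fe, Kf);
      for (int a = 0; a < 4; ++a)
        for (int i = 0; i < 3; ++i) fext[3 * idx[a] + i] += fe[3 * a + i];
      if (want_matrix)
        for (int a = 0; a < 4; ++a)
          for (int i = 0; i < 3; ++i)
            for (int b = 0; b < 4; ++b)
              for (int j = 0; j < 3; ++j) {
                ti.push_back(3 * idx[a] + i);
                tj.push_back(3 * idx[b] + j);
                tx.push_back(-Kf[3 * a + i][3 * b + j]);  // r = fint - fext
              }
    }

  List out = List::create(
      _["fint"] = fint, _["fext"] = fext, _["bad"] = bad,
      _["cohstate"] = nstate, _["minJ"] = minJ, _["W_bulk"] = Wbulk,
      _["max_f"] = maxfi, _["max_g"] = maxgf, _["max_d"] = maxd,
      _["n_failed"] = nfailed, _["n_new_failed"] = nnewfail);
  if (want_matrix) {
    out["Ti"] = IntegerVector(ti.begin(), ti.end());
    out["Tj"] = IntegerVector(tj.begin(), tj.end());
    out["Tx"] = NumericVector(tx.begin(), tx.end());
  }
  return out;
}

// ---------------------------------------------------------------------------
// Per-element centroid Cauchy stress recovery (deformed centroid + stress)
// ---------------------------------------------------------------------------
// [[Rcpp::export(name = ".hex_stress_cpp")]]
NumericMatrix hex_stress_cpp(NumericMatrix coords, NumericVector u,
                             IntegerMatrix hex, IntegerVector hexmat,
                             NumericMatrix matpar, NumericMatrix fibM,
                             NumericMatrix fibN, NumericMatrix Fpre) {
  int nhex = hex.nrow();
  bool has_pre = Fpre.nrow() == nhex * 8;
  NumericMatrix out(nhex, 10);  // x,y,z (deformed centroid), 6 stress, J
  for (int e = 0; e < nhex; ++e) {
    double Xe[8][3], ue[8][3];
    for (int a = 0; a < 8; ++a) {
      int id = hex(e, a) - 1;
      for (int i = 0; i < 3; ++i) {
        Xe[a][i] = coords(id, i);
        ue[a][i] = u[3 * id + i];
      }
    }
    MatPar mp = {matpar(hexmat[e] - 1, 0), matpar(hexmat[e] - 1, 1),
                 matpar(hexmat[e] - 1, 2), matpar(hexmat[e] - 1, 3),
                 matpar(hexmat[e] - 1, 4)};
    vec3 M = {fibM(e, 0), fibM(e, 1), fibM(e, 2)};
    vec3 N = {fibN(e, 0), fibN(e, 1), fibN(e, 2)};
    double Nf[8], dN[8][3];
    hex_shape(0, 0, 0, Nf, dN);
    mat33 Jac(arma::fill::zeros);
    for (int a = 0; a < 8; ++a)
      for (int i = 0; i < 3; ++i)
        for (int A = 0; A < 3; ++A) Jac(A, i) += dN[a][A] * Xe[a][i];
    mat33 Ji = arma::inv(Jac);
    double G[8][3];
    for (int a = 0; a < 8; ++a)
      for (int A = 0; A < 3; ++A) {
        double s = 0.0;
        for (int B = 0; B < 3; ++B) s += Ji(A, B) * dN[a][B];
        G[a][A] = s;
      }
    mat33 Fp(arma::fill::eye);
    if (has_pre) {
      Fp.zeros();
      for (int g = 0; g < 8; ++g)
        for (int i = 0; i < 3; ++i)
          for (int A = 0; A < 3; ++A)
            Fp(i, A) += Fpre(e * 8 + g, 3 * i + A) / 8.0;
    }
    double Gt[8][3];
    for (int I = 0; I < 8; ++I)
      for (int A = 0; A < 3; ++A) {
        double s = 0.0;
        for (int B = 0; B < 3; ++B) s += Fp(B, A) * G[I][B];
        Gt[I][A] = s;
      }
    mat33 F = Fp;
    for (int I = 0; I < 8; ++I)
      for (int i = 0; i < 3; ++i)
        for (int A = 0; A < 3; ++A) F(i, A) += ue[I][i] * Gt[I][A];
    mat33 C = F.t() * F;
    mat33 S;
    hgo_S(C, mp, M, N, 0, S);
    double J = arma::det(F);
    mat33 sig = (F * S * F.t()) / J;
    double cx = 0, cy = 0, cz = 0;
    for (int a = 0; a < 8; ++a) {
      cx += (Xe[a][0] + ue[a][0]) / 8.0;
      cy += (Xe[a][1] + ue[a][1]) / 8.0;
      cz += (Xe[a][2] + ue[a][2]) / 8.0;
    }
    out(e, 0) = cx; out(e, 1) = cy; out(e, 2) = cz;
    out(e, 3) = sig(0, 0); out(e, 4) = sig(1, 1); out(e, 5) = sig(2, 2);
    out(e, 6) = sig(0, 1); out(e, 7) = sig(0, 2); out(e, 8) = sig(1, 2);
    out(e, 9) = J;
  }
  return out;
}
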