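#ifndef CRYSTALHOP_H
#define CRYSTALHOP_H

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <array>

namespace chop {

typedef std::array<double, 3> Vec3;
typedef std::array<std::array<double, 3>, 3> Mat3;

// Coulomb constant e^2/(4 pi eps0) in kJ mol^-1 Angstrom e^-2
const double COULOMB_K = 1389.35457644382;

inline Vec3 vzero() { return Vec3{{0.0, 0.0, 0.0}}; }
inline Mat3 mzero() {
  Mat3 m;
  for (int i = 0; i < 3; ++i) for (int j = 0; j < 3; ++j) m[i][j] = 0.0;
  return m;
}
inline Mat3 meye() {
  Mat3 m = mzero();
  m[0][0] = m[1][1] = m[2][2] = 1.0;
  return m;
}
inline double dot(const Vec3& a, const Vec3& b) {
  return a[0]*b[0] + a[1]*b[1] + a[2]*b[2];
}
inline double norm(const Vec3& a) { return std::sqrt(dot(a, a)); }
inline Vec3 add(const Vec3& a, const Vec3& b) {
  return Vec3{{a[0]+b[0], a[1]+b[1], a[2]+b[2]}};
}
inline Vec3 sub(const Vec3& a, const Vec3& b) {
  return Vec3{{a[0]-b[0], a[1]-b[1], a[2]-b[2]}};
}
inline Vec3 scale(const Vec3& a, double s) {
  return Vec3{{a[0]*s, a[1]*s, a[2]*s}};
}
inline Vec3 cross(const Vec3& a, const Vec3& b) {
  return Vec3{{a[1]*b[2]-a[2]*b[1], a[2]*b[0]-a[0]*b[2], a[0]*b[1]-a[1]*b[0]}};
}
inline Vec3 matvec(const Mat3& M, const Vec3& v) {
  Vec3 r;
  for (int i = 0; i < 3; ++i)
    r[i] = M[i][0]*v[0] + M[i][1]*v[1] + M[i][2]*v[2];
  return r;
}
inline Vec3 tmatvec(const Mat3& M, const Vec3& v) {  // M^T v
  Vec3 r;
  for (int i = 0; i < 3; ++i)
    r[i] = M[0][i]*v[0] + M[1][i]*v[1] + M[2][i]*v[2];
  return r;
}
inline Mat3 matmul(const Mat3& A, const Mat3& B) {
  Mat3 C = mzero();
  for (int i = 0; i < 3; ++i)
    for (int k = 0; k < 3; ++k)
      for (int j = 0; j < 3; ++j)
        C[i][j] += A[i][k]*B[k][j];
  return C;
}
inline double det3(const Mat3& M) {
  return M[0][0]*(M[1][1]*M[2][2]-M[1][2]*M[2][1])
       - M[0][1]*(M[1][0]*M[2][2]-M[1][2]*M[2][0])
       + M[0][2]*(M[1][0]*M[2][1]-M[1][1]*M[2][0]);
}
inline Mat3 inv3(const Mat3& M) {
  double d = det3(M);
  Mat3 I;
  I[0][0] =  (M[1][1]*M[2][2]-M[1][2]*M[2][1])/d;
  I[0][1] = -(M[0][1]*M[2][2]-M[0][2]*M[2][1])/d;
  I[0][2] =  (M[0][1]*M[1][2]-M[0][2]*M[1][1])/d;
  I[1][0] = -(M[1][0]*M[2][2]-M[1][2]*M[2][0])/d;
  I[1][1] =  (M[0][0]*M[2][2]-M[0][2]*M[2][0])/d;
  I[1][2] = -(M[0][0]*M[1][2]-M[0][2]*M[1][0])/d;
  I[2][0] =  (M[1][0]*M[2][1]-M[1][1]*M[2][0])/d;
  I[2][1] = -(M[0][0]*M[2][1]-M[0][1]*M[2][0])/d;
  I[2][2] =  (M[0][0]*M[1][1]-M[0][1]*M[1][0])/d;
  return I;
}
inline Mat3 skew(const Vec3& v) {
  Mat3 K = mzero();
  K[0][1] = -v[2]; K[0][2] =  v[1];
  K[1][0] =  v[2]; K[1][2] = -v[0];
  K[2][0] = -v[1]; K[2][1] =  v[0];
  return K;
}

// ---------------------------------------------------------------------------
// Unit cell: parameters (a, b, c, alpha, beta, gamma; lengths in Angstrom,
// angles in radians) -> cell matrix H whose COLUMNS are the cell vectors,
// with a along +x and b in the xy-plane (positive y component).
// ---------------------------------------------------------------------------

// angular volume factor P; returns P^2 (may be <= 0 for degenerate input)
inline double p_factor_sq(double ca, double cb, double cg) {
  return 1.0 - ca*ca - cb*cb - cg*cg + 2.0*ca*cb*cg;
}

inline Mat3 build_H(const double* cp) {
  double a = cp[0], b = cp[1], c = cp[2];
  double ca = std::cos(cp[3]), cb = std::cos(cp[4]);
  double cg = std::cos(cp[5]), sg = std::sin(cp[5]);
  double P2 = p_factor_sq(ca, cb, cg);
  if (P2 <= 0.0 || sg <= 0.0)
    Rcpp::stop("degenerate cell: angular volume factor P is not real and positive");
  double P = std::sqrt(P2);
  Mat3 H = mzero();
  H[0][0] = a;
  H[0][1] = b*cg; H[1][1] = b*sg;
  H[0][2] = c*cb;
  H[1][2] = c*(ca - cb*cg)/sg;
  H[2][2] = c*P/sg;
  return H;
}

// analytic dH/dtheta for theta in {a, b, c, alpha, beta, gamma}
inline void build_dH(const double* cp, Mat3 dH[6]) {
  double a = cp[0], b = cp[1], c = cp[2];
  (void)a;
  double al = cp[3], be = cp[4], ga = cp[5];
  double ca = std::cos(al), sa = std::sin(al);
  double cb = std::cos(be), sb = std::sin(be);
  double cg = std::cos(ga), sg = std::sin(ga);
  double P2 = p_factor_sq(ca, cb, cg);
  if (P2 <= 0.0 || sg <= 0.0)
    Rcpp::stop("degenerate cell: angular volume factor P is not real and positive");
  double P = std::sqrt(P2);
  for (int t = 0; t < 6; ++t) dH[t] = mzero();
  // lengths
  dH[0][0][0] = 1.0;
  dH[1][0][1] = cg; dH[1][1][1] = sg;
  dH[2][0][2] = cb; dH[2][1][2] = (ca - cb*cg)/sg; dH[2][2][2] = P/sg;
  // dP/d(cos) terms: P^2 = 1 - ca^2 - cb^2 - cg^2 + 2 ca cb cg
  double dP_dca = (cb*cg - ca)/P;
  double dP_dcb = (ca*cg - cb)/P;
  double dP_dcg = (ca*cb - cg)/P;
  // alpha: only column c entries depend on alpha (via ca)
  dH[3][1][2] = c*(-sa)/sg;
  dH[3][2][2] = c*dP_dca*(-sa)/sg;
  // beta
  dH[4][0][2] = c*(-sb);
  dH[4][1][2] = c*(-(-sb)*cg)/sg;           // d/dbe[(ca - cb cg)/sg] = (sb cg)/sg
  dH[4][1][2] = c*(sb*cg)/sg;
  dH[4][2][2] = c*dP_dcb*(-sb)/sg;
  // gamma
  dH[5][0][1] = -b*sg; dH[5][1][1] = b*cg;
  // d/dga[(ca - cb cg)/sg] = (cb sg * sg - (ca - cb cg) * cg)/sg^2
  dH[5][1][2] = c*((cb*sg)*sg - (ca - cb*cg)*cg)/(sg*sg);
  // d/dga[P/sg] = (dP/dcg * (-sg) * sg - P cg)/sg^2
  dH[5][2][2] = c*(dP_dcg*(-sg)*sg - P*cg)/(sg*sg);
}

// ---------------------------------------------------------------------------
// Angle-axis rotations (Rodrigues), with analytic derivatives dR/dp_k.
// Small-|p| limits handled by series.
// ---------------------------------------------------------------------------

inline Mat3 rotmat(const Vec3& p) {
  double th2 = dot(p, p);
  Mat3 K = skew(p);
  Mat3 K2 = matmul(K, K);
  double A, B;  // R = I + A K + B K^2 with K built from the UNnormalized p
  if (th2 < 1e-12) {
    A = 1.0 - th2/6.0 + th2*th2/120.0;
    B = 0.5 - th2/24.0 + th2*th2/720.0;
  } else {
    double th = std::sqrt(th2);
    A = std::sin(th)/th;
    B = (1.0 - std::cos(th))/th2;
  }
  Mat3 R = meye();
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j)
      R[i][j] += A*K[i][j] + B*K2[i][j];
  return R;
}

// dR/dp_k via Gallego & Yezzi (2015): for |p| > 0,
//   dR/dp_k = ( p_k [p]_x + [ p x ((I - R) e_k) ]_x ) / |p|^2 * R
// with a series form at the origin.
inline void rotmat_derivs(const Vec3& p, const Mat3& R, Mat3 dR[3]) {
  double th2 = dot(p, p);
  if (th2 < 1e-12) {
    // dR/dp_k ~ [e_k]_x + 1/2 ([e_k]_x [p]_x + [p]_x [e_k]_x), error O(|p|^2)
    Mat3 Kp = skew(p);
    for (int k = 0; k < 3; ++k) {
      Vec3 e = vzero(); e[k] = 1.0;
      Mat3 Ke = skew(e);
      Mat3 t1 = matmul(Ke, Kp), t2 = matmul(Kp, Ke);
      dR[k] = mzero();
      for (int i = 0; i < 3; ++i)
        for (int j = 0; j < 3; ++j)
          dR[k][i][j] = Ke[i][j] + 0.5*(t1[i][j] + t2[i][j]);
    }
    return;
  }
  Mat3 Kp = skew(p);
  for (int k = 0; k < 3; ++k) {
    Vec3 e = vzero(); e[k] = 1.0;
    Vec3 ImRe;  // (I - R) e_k  == e_k - R e_k
    Vec3 Re = matvec(R, e);
    ImRe = sub(e, Re);
    Vec3 pc = cross(p, ImRe);
    Mat3 M = mzero();
    Mat3 Kc = skew(pc);
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j)
        M[i][j] = (p[k]*Kp[i][j] + Kc[i][j])/th2;
    dR[k] = matmul(M, R);
  }
}

// ---------------------------------------------------------------------------
// Pair-potential parameters (per site-type pair, symmetric).
// Repulsion: A_ij exp( -B_ij (r - rho(Omega)) ),
//   rho(Omega) = d1_i (z_i . rhat)^2 + d1_j (z_j . rhat)^2
//   (z_m: unit normal of molecule m; d1: per-type anisotropic range shift, Angstrom)
// Dispersion: - f6(B_ij r) C6_ij / r^6, f6 = Tang-Toennies order-6 damping (optional)
// ---------------------------------------------------------------------------

struct PairParams {
  int ntype;
  std::vector<double> A, B, C6;  // ntype x ntype, row-major
  std::vector<double> Ushift;    // pair energy at r_c (subtracted when shifting)
  std::vector<double> d1;        // per type
  bool damp;
  double at(const std::vector<double>& m, int i, int j) const { return m[i*ntype + j]; }
};

inline double tt_f6(double x, double* dfdx) {
  // f6(x) = 1 - exp(-x) * sum_{k=0}^{6} x^k / k!
  double s = 0.0, term = 1.0;
  for (int k = 0; k <= 6; ++k) {
    if (k > 0) term *= x/k;
    s += term;
  }
  double ex = std::exp(-x);
  double f = 1.0 - ex*s;
  if (dfdx) *dfdx = ex*term;  // term = x^6/720 here
  return f;
}

// ---------------------------------------------------------------------------
// Full periodic system: reference geometry + parameters + summation settings.
// ---------------------------------------------------------------------------

struct Settings {
  double r_c;        // site-site cutoff, Angstrom
  double alpha;      // Ewald splitting, 1/Angstrom (<=0: 5.6/r_c)
  double k_cutoff;   // reciprocal cutoff, 1/Angstrom (<=0: from k_eps)
  double k_eps;      // target reciprocal truncation factor
  double eps_P;      // WCA cell penalty strength, kJ/mol
  double sigma_P;    // WCA cell penalty range (dimensionless)
  bool do_short, do_elec, do_penalty;
  bool shift_cutoff; // subtract the pair energy at r_c (continuous sum)
};

struct System {
  int N;                     // molecules in the cell
  int S;                     // sites per molecule
  std::vector<Vec3> x0;      // body-frame site positions
  std::vector<double> q;     // site charges (e), S x N laid out [m*S + s]
  std::vector<int> type;     // 0-based site type
  PairParams pp;
  Settings st;
  double rbody;              // max |x0|
  bool has_charge;
};

struct EnergyResult {
  bool ok;
  double e_total, e_short, e_real, e_recip, e_self, e_excl, e_pen;
  std::vector<double> gcom;   // 3N, w.r.t. fractional COMs
  std::vector<double> gp;     // 3N, w.r.t. angle-axis vectors
  std::vector<double> gcell;  // 6, w.r.t. (a,b,c,alpha,beta,gamma)
};

System make_system(Rcpp::NumericMatrix sites, Rcpp::NumericMatrix charges,
                   Rcpp::IntegerVector stype, Rcpp::List params, Rcpp::List settings,
                   int n_mol);

void energy_core(const System& sys, const double* com, const double* p,
                 const double* cellpar, bool want_grad, EnergyResult& res);

}  // namespace chop

#endif
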