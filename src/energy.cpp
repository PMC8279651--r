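// Periodic lattice energy and analytic gradients for rigid molecules in a
// dynamically varying triclinic cell.
//
// Variables: fractional molecular COMs (X), absolute angle-axis orientations
// (p), and the six cell parameters. Site positions: x_i^m = H X^m + R(p^m) x_i^0.
//
// Terms:
//  * short-range site-site model (anisotropic Born-Mayer repulsion + damped
//    -C6/r^6 dispersion), summed over periodic images within the cutoff r_c
//    using limits M = floor(2 r_c a*) + 1 per lattice direction;
//  * Ewald electrostatics (real + reciprocal + self + rigid intramolecular
//    exclusion, the last a constant for rigid bodies);
//  * WCA-style penalty on the angular volume factor P.
//
// Cell-parameter gradients are assembled as dU/dtheta = sum_ab dU/dH_ab dH_ab/dtheta,
// where dU/dH collects the explicit dependence through image vectors, COM
// positions, reciprocal vectors and the cell volume.
#include "crystalhop.h"
using namespace Rcpp;

namespace chop {

// orientation-dependent site-site model term (no electrostatics)
// d: separation vector (site j minus site i), zi/zj: unit molecular normals
inline double pair_model(const Vec3& d, double r, const Vec3& zi, const Vec3& zj,
                         double A, double B, double C6, double d1i, double d1j,
                         bool damp, bool want_grad,
                         Vec3& dUdd, Vec3& dUdzi, Vec3& dUdzj) {
  Vec3 rhat = scale(d, 1.0/r);
  double ci = dot(zi, rhat), cj = dot(zj, rhat);
  double rho = d1i*ci*ci + d1j*cj*cj;
  double Urep = A*std::exp(-B*(r - rho));
  double inv_r6 = 1.0/(r*r*r*r*r*r);
  double f6 = 1.0, df6 = 0.0;
  if (damp) f6 = tt_f6(B*r, &df6);
  double Udisp = -f6*C6*inv_r6;
  if (want_grad) {
    // d r/dd = rhat ; d ci/dd = (zi - ci rhat)/r
    double drep_dr = -B*Urep;
    double drep_dci = Urep*B*d1i*2.0*ci;
    double drep_dcj = Urep*B*d1j*2.0*cj;
    double ddisp_dr = -C6*(damp ? df6*B : 0.0)*inv_r6 + 6.0*f6*C6*inv_r6/r;
    for (int a = 0; a < 3; ++a) {
      dUdd[a] = (drep_dr + ddisp_dr)*rhat[a]
              + drep_dci*(zi[a] - ci*rhat[a])/r
              + drep_dcj*(zj[a] - cj*rhat[a])/r;
      dUdzi[a] = drep_dci*rhat[a];
      dUdzj[a] = drep_dcj*rhat[a];
    }
  }
  return Urep + Udisp;
}

System make_system(NumericMatrix sites, NumericMatrix charges,
                   IntegerVector stype, List params, List settings, int n_mol) {
  System sys;
  sys.N = n_mol;
  sys.S = sites.ncol();
  sys.x0.resize(sys.S);
  sys.type.resize(sys.S);
  sys.rbody = 0.0;
  sys.has_charge = false;
  for (int s = 0; s < sys.S; ++s) {
    sys.x0[s] = Vec3{{sites(0, s), sites(1, s), sites(2, s)}};
    sys.type[s] = stype[s] - 1;  // R side is 1-based
    sys.rbody = std::max(sys.rbody, norm(sys.x0[s]));
  }
  sys.q.resize(sys.S*sys.N);
  for (int m = 0; m < sys.N; ++m)
    for (int s = 0; s < sys.S; ++s) {
      sys.q[m*sys.S + s] = charges(s, m);
      if (sys.q[m*sys.S + s] != 0.0) sys.has_charge = true;
    }
  NumericMatrix A = params["A"], B = params["B"], C6 = params["C6"];
  NumericVector d1 = params["d1"];
  sys.pp.ntype = A.nrow();
  sys.pp.A.assign(A.begin(), A.end());
  sys.pp.B.assign(B.begin(), B.end());
  sys.pp.C6.assign(C6.begin(), C6.end());
  sys.pp.d1.assign(d1.begin(), d1.end());
  sys.pp.damp = as<bool>(params["damp"]);
  sys.st.r_c = as<double>(settings["r_c"]);
  sys.st.alpha = as<double>(settings["alpha"]);
  if (sys.st.alpha <= 0) sys.st.alpha = 5.6/sys.st.r_c;
  sys.st.k_eps = as<double>(settings["k_eps"]);
  sys.st.k_cutoff = as<double>(settings["k_cutoff"]);
  if (sys.st.k_cutoff <= 0)
    sys.st.k_cutoff = 2.0*sys.st.alpha*std::sqrt(-std::log(sys.st.k_eps));
  sys.st.eps_P = as<double>(settings["eps_P"]);
  sys.st.sigma_P = as<double>(settings["sigma_P"]);
  sys.st.do_short = as<bool>(settings["do_short"]);
  sys.st.do_elec = as<bool>(settings["do_elec"]);
  sys.st.do_penalty = as<bool>(settings["do_penalty"]);
  sys.st.shift_cutoff = as<bool>(settings["shift_cutoff"]);
  // isotropic pair energy at the cutoff; subtracting it makes the truncated
  // lattice sum continuous when pairs cross r_c (the orientation-dependent
  // range shift is a rho(Omega) offset inside the exponential, whose value
  // at r_c is negligible next to the dispersion term and is not included)
  int nt = sys.pp.ntype;
  sys.pp.Ushift.assign(nt*nt, 0.0);
  if (sys.st.shift_cutoff) {
    double rc = sys.st.r_c;
    for (int i = 0; i < nt*nt; ++i) {
      double f6 = 1.0;
      if (sys.pp.damp) f6 = tt_f6(sys.pp.B[i]*rc, nullptr);
      sys.pp.Ushift[i] = sys.pp.A[i]*std::exp(-sys.pp.B[i]*rc)
                       - f6*sys.pp.C6[i]/std::pow(rc, 6.0);
    }
  }
  return sys;
}

void energy_core(const System& sys, const double* com, const double* p,
                 const double* cellpar, bool want_grad, EnergyResult& res) {
  const int N = sys.N, S = sys.S;
  res.ok = false;
  res.e_short = res.e_real = res.e_recip = res.e_self = res.e_excl = res.e_pen = 0.0;
  res.gcom.assign(3*N, 0.0);
  res.gp.assign(3*N, 0.0);
  res.gcell.assign(6, 0.0);

  // cell validity barrier (finite, so line searches simply back off)
  double ca = std::cos(cellpar[3]), cb = std::cos(cellpar[4]), cg = std::cos(cellpar[5]);
  double P2 = p_factor_sq(ca, cb, cg);
  if (cellpar[0] <= 0.5 || cellpar[1] <= 0.5 || cellpar[2] <= 0.5 ||
      cellpar[3] <= 0.02 || cellpar[3] >= M_PI - 0.02 ||
      cellpar[4] <= 0.02 || cellpar[4] >= M_PI - 0.02 ||
      cellpar[5] <= 0.02 || cellpar[5] >= M_PI - 0.02 ||
      P2 <= 1e-12) {
    res.e_total = 1e12;
    return;
  }
  double P = std::sqrt(P2);

  Mat3 H = build_H(cellpar);
  Mat3 Hinv = inv3(H);
  double V = det3(H);
  Mat3 dH[6];
  if (want_grad) build_dH(cellpar, dH);

  // per-molecule rotations, site offsets and derivatives
  std::vector<Mat3> Rm(N);
  std::vector<std::array<Mat3, 3> > dRm(N);
  std::vector<Vec3> zm(N), cm(N);
  std::vector<Vec3> u(N*S);                 // rotated body-frame offsets
  std::vector<Vec3> Ds;                     // dR_k x0_s, laid out [(m*3+k)*S + s]
  std::vector<Vec3> dz(N*3);                // d z_m / d p_k
  if (want_grad) Ds.resize(N*3*S);
  for (int m = 0; m < N; ++m) {
    Vec3 pm{{p[3*m], p[3*m+1], p[3*m+2]}};
    Rm[m] = rotmat(pm);
    zm[m] = Vec3{{Rm[m][0][2], Rm[m][1][2], Rm[m][2][2]}};
    Vec3 Xm{{com[3*m], com[3*m+1], com[3*m+2]}};
    cm[m] = matvec(H, Xm);
    for (int s = 0; s < S; ++s) u[m*S + s] = matvec(Rm[m], sys.x0[s]);
    if (want_grad) {
      rotmat_derivs(pm, Rm[m], dRm[m].data());
      for (int k = 0; k < 3; ++k) {
        dz[m*3 + k] = Vec3{{dRm[m][k][0][2], dRm[m][k][1][2], dRm[m][k][2][2]}};
        for (int s = 0; s < S; ++s) Ds[(m*3 + k)*S + s] = matvec(dRm[m][k], sys.x0[s]);
      }
    }
  }

  std::vector<Vec3> gabs(N, vzero());   // dU/d(absolute COM)
  std::vector<Vec3> gfrac(N, vzero());  // direct fractional contributions (reciprocal)
  Mat3 dUdH = mzero();

  const double r_c = sys.st.r_c, rc2 = r_c*r_c;
  const double alpha = sys.st.alpha;
  const double two_over_sqrtpi = 2.0/std::sqrt(M_PI);
  const bool do_elec = sys.st.do_elec && sys.has_charge;

  if (sys.st.do_short || do_elec) {
    // image limits M = floor(2 r_c a*) + 1; reciprocal lengths are the row
    // norms of H^-1
    int M[3];
    for (int d = 0; d < 3; ++d) {
      double rl = std::sqrt(Hinv[d][0]*Hinv[d][0] + Hinv[d][1]*Hinv[d][1] +
                            Hinv[d][2]*Hinv[d][2]);
      M[d] = (int)std::floor(2.0*r_c*rl + 1e-9) + 1;
    }
    double com_cut = r_c + 2.0*sys.rbody + 1e-9;
    double com_cut2 = com_cut*com_cut;

    Vec3 dUdd, dUdzi, dUdzj;
    for (int m = 0; m < N; ++m) {
      for (int m2 = m; m2 < N; ++m2) {
        Vec3 fbase{{com[3*m2] - com[3*m], com[3*m2+1] - com[3*m+1],
                    com[3*m2+2] - com[3*m+2]}};
        for (int n1 = -M[0]; n1 <= M[0]; ++n1)
        for (int n2 = -M[1]; n2 <= M[1]; ++n2)
        for (int n3 = -M[2]; n3 <= M[2]; ++n3) {
          if (m == m2 && n1 == 0 && n2 == 0 && n3 == 0) continue;
          double w = (m == m2) ? 0.5 : 1.0;
          Vec3 f{{fbase[0] + n1, fbase[1] + n2, fbase[2] + n3}};
          Vec3 dcom = matvec(H, f);
          if (dot(dcom, dcom) > com_cut2) continue;
          for (int si = 0; si < S; ++si) {
            const Vec3& ui = u[m*S + si];
            Vec3 base = sub(dcom, ui);
            for (int sj = 0; sj < S; ++sj) {
              Vec3 d3 = add(base, u[m2*S + sj]);
              double r2 = dot(d3, d3);
              if (r2 > rc2) continue;
              double r = std::sqrt(r2);
              Vec3 gpair = vzero();
              if (sys.st.do_short) {
                int ti = sys.type[si], tj = sys.type[sj];
                double Umod = pair_model(
                    d3, r, zm[m], zm[m2],
                    sys.pp.at(sys.pp.A, ti, tj), sys.pp.at(sys.pp.B, ti, tj),
                    sys.pp.at(sys.pp.C6, ti, tj), sys.pp.d1[ti], sys.pp.d1[tj],
                    sys.pp.damp, want_grad, dUdd, dUdzi, dUdzj);
                res.e_short += w*(Umod - sys.pp.at(sys.pp.Ushift, ti, tj));
                if (want_grad) {
                  for (int a = 0; a < 3; ++a) gpair[a] += w*dUdd[a];
                  for (int k = 0; k < 3; ++k) {
                    res.gp[3*m + k]  += w*dot(dUdzi, dz[m*3 + k]);
                    res.gp[3*m2 + k] += w*dot(dUdzj, dz[m2*3 + k]);
                  }
                }
              }
              if (do_elec) {
                double qq = sys.q[m*S + si]*sys.q[m2*S + sj];
                if (qq != 0.0) {
                  double er = std::erfc(alpha*r);
                  double Ureal = COULOMB_K*qq*er/r;
                  res.e_real += w*Ureal;
                  if (want_grad) {
                    double dUr = COULOMB_K*qq*(-er/r2
                        - alpha*two_over_sqrtpi*std::exp(-alpha*alpha*r2)/r);
                    for (int a = 0; a < 3; ++a) gpair[a] += w*dUr*d3[a]/r;
                  }
                }
              }
              if (want_grad && (gpair[0] != 0.0 || gpair[1] != 0.0 || gpair[2] != 0.0)) {
                for (int a = 0; a < 3; ++a) {
                  gabs[m][a] -= gpair[a];
                  gabs[m2][a] += gpair[a];
                  for (int b = 0; b < 3; ++b) dUdH[a][b] += gpair[a]*f[b];
                }
                for (int k = 0; k < 3; ++k) {
                  res.gp[3*m + k]  -= dot(gpair, Ds[(m*3 + k)*S + si]);
                  res.gp[3*m2 + k] += dot(gpair, Ds[(m2*3 + k)*S + sj]);
                }
              }
            }
          }
        }
      }
    }
  }

  if (do_elec) {
    // reciprocal-space sum over half space, weight 2
    double kcut = sys.st.k_cutoff, kcut2 = kcut*kcut;
    double pref = COULOMB_K*2.0*M_PI/V;
    int Mk[3];
    for (int d = 0; d < 3; ++d) {
      double len = std::sqrt(H[0][d]*H[0][d] + H[1][d]*H[1][d] + H[2][d]*H[2][d]);
      // one index beyond the floor bound: the spherical |k| <= kcut test
      // alone then decides inclusion, so tiny cell changes that move the
      // integer bound cannot flip the included k-set discontinuously
      Mk[d] = (int)std::floor(kcut*len/(2.0*M_PI)) + 1;
    }
    std::vector<double> cph(N*S), sph(N*S), dUdphi(N*S);
    for (int m1 = -Mk[0]; m1 <= Mk[0]; ++m1)
    for (int m2v = -Mk[1]; m2v <= Mk[1]; ++m2v)
    for (int m3 = -Mk[2]; m3 <= Mk[2]; ++m3) {
      if (!(m1 > 0 || (m1 == 0 && m2v > 0) || (m1 == 0 && m2v == 0 && m3 > 0)))
        continue;
      Vec3 mm{{(double)m1, (double)m2v, (double)m3}};
      Vec3 k = scale(tmatvec(Hinv, mm), 2.0*M_PI);  // 2 pi H^-T m
      double k2 = dot(k, k);
      if (k2 > kcut2) continue;
      double gk = std::exp(-k2/(4.0*alpha*alpha))/k2;
      double Cc = 0.0, Ss = 0.0;
      for (int m = 0; m < N; ++m) {
        double base = 2.0*M_PI*(mm[0]*com[3*m] + mm[1]*com[3*m+1] + mm[2]*com[3*m+2]);
        for (int s = 0; s < S; ++s) {
          double phi = base + dot(k, u[m*S + s]);
          double cp = std::cos(phi), sp = std::sin(phi);
          cph[m*S + s] = cp; sph[m*S + s] = sp;
          Cc += sys.q[m*S + s]*cp; Ss += sys.q[m*S + s]*sp;
        }
      }
      double S2 = Cc*Cc + Ss*Ss;
      double term = 2.0*pref*gk*S2;
      res.e_recip += term;
      if (want_grad && S2 > 0.0) {
        double common = 2.0*pref*gk;
        Vec3 wvec = vzero();
        for (int m = 0; m < N; ++m) {
          Vec3 gp_phi = vzero();
          for (int s = 0; s < S; ++s) {
            double dphi = common*2.0*sys.q[m*S + s]*(-Cc*sph[m*S + s] + Ss*cph[m*S + s]);
            dUdphi[m*S + s] = dphi;
            // fractional COM part of the phase: 2 pi m . X
            for (int a = 0; a < 3; ++a) gfrac[m][a] += dphi*2.0*M_PI*mm[a];
            for (int a = 0; a < 3; ++a) wvec[a] += dphi*u[m*S + s][a];
            for (int kk = 0; kk < 3; ++kk)
              gp_phi[kk] += dphi*dot(k, Ds[(m*3 + kk)*S + s]);
          }
          for (int kk = 0; kk < 3; ++kk) res.gp[3*m + kk] += gp_phi[kk];
        }
        // dU/dH: volume factor, k^2 dependence, and phase (k . u) dependence
        double dterm_dk2 = term*(-1.0/(4.0*alpha*alpha) - 1.0/k2);
        Vec3 t = matvec(Hinv, k);
        Vec3 hw = matvec(Hinv, wvec);
        for (int a = 0; a < 3; ++a)
          for (int b = 0; b < 3; ++b)
            dUdH[a][b] += -term*Hinv[b][a] - 2.0*dterm_dk2*k[a]*t[b] - k[a]*hw[b];
      }
    }
    // self-interaction
    double sumq2 = 0.0;
    for (int i = 0; i < N*S; ++i) sumq2 += sys.q[i]*sys.q[i];
    res.e_self = -COULOMB_K*alpha/std::sqrt(M_PI)*sumq2;
    // rigid intramolecular exclusion: constant for a rigid reference geometry
    double excl = 0.0;
    for (int m = 0; m < N; ++m)
      for (int si = 0; si < S; ++si)
        for (int sj = si + 1; sj < S; ++sj) {
          double qq = sys.q[m*S + si]*sys.q[m*S + sj];
          if (qq == 0.0) continue;
          double r0 = norm(sub(sys.x0[sj], sys.x0[si]));
          excl += -COULOMB_K*qq*std::erf(alpha*r0)/r0;
        }
    res.e_excl = excl;
  }

  if (sys.st.do_penalty) {
    double sp = sys.st.sigma_P, ep = sys.st.eps_P;
    double P6 = P2*P2*P2;
    if (P6 < sp) {
      double x = sp/P6 - 1.0;
      res.e_pen = ep*x*x;
      if (want_grad) {
        double dUdP = 2.0*ep*x*(-6.0*sp/(P6*P));
        double dP_dca = (cb*cg - ca)/P, dP_dcb = (ca*cg - cb)/P, dP_dcg = (ca*cb - cg)/P;
        res.gcell[3] += dUdP*dP_dca*(-std::sin(cellpar[3]));
        res.gcell[4] += dUdP*dP_dcb*(-std::sin(cellpar[4]));
        res.gcell[5] += dUdP*dP_dcg*(-std::sin(cellpar[5]));
      }
    }
  }

  if (want_grad) {
    for (int m = 0; m < N; ++m) {
      Vec3 gf = tmatvec(H, gabs[m]);  // Eq.: dU/dXbar = H^T dU/dX
      for (int a = 0; a < 3; ++a) res.gcom[3*m + a] = gf[a] + gfrac[m][a];
    }
    for (int t = 0; t < 6; ++t) {
      double g = res.gcell[t];  // penalty part already there
      for (int a = 0; a < 3; ++a)
        for (int b = 0; b < 3; ++b)
          g += dUdH[a][b]*dH[t][a][b];
      res.gcell[t] = g;
    }
  }

  res.e_total = res.e_short + res.e_real + res.e_recip + res.e_self + res.e_excl +
                res.e_pen;
  res.ok = true;
}

}  // namespace chop

using namespace chop;

// [[Rcpp::export(name = ".cpp_energy")]]
List cpp_energy(NumericMatrix com, NumericMatrix pmat, NumericVector cellpar,
                NumericMatrix sites, NumericMatrix charges, IntegerVector stype,
                List params, List settings, bool want_grad) {
  int N = com.ncol();
  System sys = make_system(sites, charges, stype, params, settings, N);
  EnergyResult res;
  energy_core(sys, com.begin(), pmat.begin(), cellpar.begin(), want_grad, res);
  if (!res.ok) stop("degenerate cell: energy evaluation rejected the cell parameters");
  NumericMatrix gcom(3, N), gp(3, N);
  NumericVector gcell(6);
  if (want_grad) {
    std::copy(res.gcom.begin(), res.gcom.end(), gcom.begin());
    std::copy(res.gp.begin(), res.gp.end(), gp.begin());
    std::copy(res.gcell.begin(), res.gcell.end(), gcell.begin());
  }
  return List::create(
      _["energy"] = res.e_total,
      _["components"] = NumericVector::create(
          _["short_range"] = res.e_short, _["ewald_real"] = res.e_real,
          _["ewald_recip"] = res.e_recip, _["ewald_self"] = res.e_self,
          _["ewald_excl"] = res.e_excl, _["cell_penalty"] = res.e_pen),
      _["grad_com"] = gcom, _["grad_p"] = gp, _["grad_cell"] = gcell);
}

// single site-site model term, exposed for testing the pair contract
// [[Rcpp::export(name = ".cpp_pair_eval")]]
List cpp_pair_eval(NumericVector d, NumericVector zi, NumericVector zj,
                   double A, double B, double C6, double d1i, double d1j,
                   bool damp) {
  Vec3 dv{{d[0], d[1], d[2]}}, zvi{{zi[0], zi[1], zi[2]}}, zvj{{zj[0], zj[1], zj[2]}};
  double r = norm(dv);
  if (r <= 0) stop("zero separation");
  Vec3 dUdd, dUdzi, dUdzj;
  double U = pair_model(dv, r, zvi, zvj, A, B, C6, d1i, d1j, damp, true,
                        dUdd, dUdzi, dUdzj);
  return List::create(
      _["energy"] = U,
      _["dUdd"] = NumericVector::create(dUdd[0], dUdd[1], dUdd[2]),
      _["dUdzi"] = NumericVector::create(dUdzi[0], dUdzi[1], dUdzi[2]),
      _["dUdzj"] = NumericVector::create(dUdzj[0], dUdzj[1], dUdzj[2]));
}
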