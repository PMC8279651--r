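#include "crystalhop.h"
using namespace Rcpp;
using namespace chop;

static NumericMatrix mat3_to_R(const Mat3& M) {
  NumericMatrix out(3, 3);
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j)
      out(i, j) = M[i][j];
  return out;
}

// [[Rcpp::export(name = ".cpp_cell_matrix")]]
NumericMatrix cpp_cell_matrix(NumericVector cellpar) {
  Mat3 H = build_H(cellpar.begin());
  return mat3_to_R(H);
}

// [[Rcpp::export(name = ".cpp_cell_matrix_derivs")]]
List cpp_cell_matrix_derivs(NumericVector cellpar) {
  Mat3 dH[6];
  build_dH(cellpar.begin(), dH);
  List out(6);
  for (int t = 0; t < 6; ++t) out[t] = mat3_to_R(dH[t]);
  out.attr("names") = CharacterVector::create("a", "b", "c", "alpha", "beta", "gamma");
  return out;
}

// [[Rcpp::export(name = ".cpp_p_factor")]]
double cpp_p_factor(NumericVector cellpar) {
  double P2 = p_factor_sq(std::cos(cellpar[3]), std::cos(cellpar[4]),
                          std::cos(cellpar[5]));
  if (P2 <= 0.0) return NA_REAL;
  return std::sqrt(P2);
}

// [[Rcpp::export(name = ".cpp_rotation_matrix")]]
List cpp_rotation_matrix(NumericVector p, bool derivatives) {
  Vec3 pv{{p[0], p[1], p[2]}};
  Mat3 R = rotmat(pv);
  if (!derivatives) return List::create(_["R"] = mat3_to_R(R));
  Mat3 dR[3];
  rotmat_derivs(pv, R, dR);
  return List::create(_["R"] = mat3_to_R(R),
                      _["dR"] = List::create(mat3_to_R(dR[0]), mat3_to_R(dR[1]),
                                             mat3_to_R(dR[2])));
}
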