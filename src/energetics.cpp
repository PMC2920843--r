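#include <Rcpp.h>
using namespace Rcpp;

// CHARMM-convention Coulomb constant, kcal*Angstrom/(mol*e^2)
static const double COULOMB_K = 332.0637;

static inline void min_image(double &dx, double &dy, double &dz,
                             const double *box) {
  if (box) {
    dx -= box[0] * std::round(dx / box[0]);
    dy -= box[1] * std::round(dy / box[1]);
    dz -= box[2] * std::round(dz / box[2]);
  }
}

// Nonbonded energy between two disjoint atom groups (CHARMM functional form,
// no cutoff). Indices are 1-based. Optional minimum-image box, optional
// accumulation into group-pair matrices (ga/gb give a 1-based group id per
// atom of ia/ib; ngrp_a/ngrp_b give matrix extents).
// [[Rcpp::export]]
List cpp_group_energy(const NumericMatrix &coords,
                      const IntegerVector &ia, const IntegerVector &ib,
                      const NumericVector &q, const NumericVector &eps,
                      const NumericVector &rminh, double dielectric,
                      Nullable<NumericVector> box_ = R_NilValue,
                      Nullable<IntegerVector> ga_ = R_NilValue,
                      Nullable<IntegerVector> gb_ = R_NilValue,
                      int ngrp_a = 0, int ngrp_b = 0) {
  const double *box = NULL;
  NumericVector boxv;
  if (box_.isNotNull()) { boxv = box_.get(); box = &boxv[0]; }
  bool grouped = ga_.isNotNull() && gb_.isNotNull() && ngrp_a > 0 && ngrp_b > 0;
  IntegerVector ga, gb;
  if (grouped) { ga = ga_.get(); gb = gb_.get(); }
  NumericMatrix emat_e, emat_v;
  if (grouped) {
    emat_e = NumericMatrix(ngrp_a, ngrp_b);
    emat_v = NumericMatrix(ngrp_a, ngrp_b);
  }
  double elec = 0.0, vdw = 0.0;
  const double kq = COULOMB_K / dielectric;
  for (int a = 0; a < ia.size(); ++a) {
    int i = ia[a] - 1;
    double xi = coords(i, 0), yi = coords(i, 1), zi = coords(i, 2);
    double qi = q[i], ei = eps[i], ri = rminh[i];
    for (int b = 0; b < ib.size(); ++b) {
      int j = ib[b] - 1;
      double dx = coords(j, 0) - xi, dy = coords(j, 1) - yi,
             dz = coords(j, 2) - zi;
      min_image(dx, dy, dz, box);
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 < 1e-8)
        stop("near-singular contact between atoms %d and %d (r < 1e-4 A)",
             i + 1, j + 1);
      double r = std::sqrt(r2);
      double ee = kq * qi * q[j] / r;
      double vv = 0.0;
      double epsij = std::sqrt(ei * eps[j]);
      if (epsij > 0.0) {
        double rmin = ri + rminh[j];
        double s2 = (rmin * rmin) / r2;
        double s6 = s2 * s2 * s2;
        vv = epsij * (s6 * s6 - 2.0 * s6);
      }
      elec += ee;
      vdw += vv;
      if (grouped) {
        emat_e(ga[a] - 1, gb[b] - 1) += ee;
        emat_v(ga[a] - 1, gb[b] - 1) += vv;
      }
    }
  }
  List out = List::create(_["elec"] = elec, _["vdw"] = vdw);
  if (grouped) { out["elec_by_group"] = emat_e; out["vdw_by_group"] = emat_v; }
  return out;
}

// Nonbonded energy over an explicit pair list with per-pair scale factors
// (0 for excluded 1-2/1-3 pairs, the 1-4 factor for 1-4 pairs, 1 otherwise).
// [[Rcpp::export]]
List cpp_pairlist_energy(const NumericMatrix &coords,
                         const IntegerVector &pi, const IntegerVector &pj,
                         const NumericVector &scale,
                         const NumericVector &q, const NumericVector &eps,
                         const NumericVector &rminh, double dielectric) {
  double elec = 0.0, vdw = 0.0;
  const double kq = COULOMB_K / dielectric;
  for (int p = 0; p < pi.size(); ++p) {
    double s = scale[p];
    if (s == 0.0) continue;
    int i = pi[p] - 1, j = pj[p] - 1;
    double dx = coords(j, 0) - coords(i, 0);
    double dy = coords(j, 1) - coords(i, 1);
    double dz = coords(j, 2) - coords(i, 2);
    double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 < 1e-8)
      stop("near-singular contact between atoms %d and %d (r < 1e-4 A)",
           i + 1, j + 1);
    double r = std::sqrt(r2);
    elec += s * kq * q[i] * q[j] / r;
    double epsij = std::sqrt(eps[i] * eps[j]);
    if (epsij > 0.0) {
      double rmin = rminh[i] + rminh[j];
      double s2 = (rmin * rmin) / r2;
      double s6 = s2 * s2 * s2;
      vdw += s * epsij * (s6 * s6 - 2.0 * s6);
    }
  }
  return List::create(_["elec"] = elec, _["vdw"] = vdw);
}
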