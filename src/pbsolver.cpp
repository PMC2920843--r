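#include <Rcpp.h>
using namespace Rcpp;

static const double COULOMB_K = 332.0637;

static inline long idx3(int i, int j, int k, int n) {
  return (long)i + (long)n * ((long)j + (long)n * (long)k);
}

// 1D squared Euclidean distance transform (lower envelope of parabolas).
static void edt1d(const std::vector<double> &f, std::vector<double> &d, int n,
                  std::vector<int> &v, std::vector<double> &z) {
  int k = 0;
  v[0] = 0;
  z[0] = -1e20;
  z[1] = 1e20;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = 1e20;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    d[q] = (q - v[k]) * (double)(q - v[k]) + f[v[k]];
  }
}

// Squared distance (grid units) from every node to the nearest node where
// mask == 0, computed with the separable exact EDT.
static std::vector<double> edt3(const std::vector<int> &mask, int n) {
  long n3 = (long)n * n * n;
  std::vector<double> g(n3);
  for (long i = 0; i < n3; ++i) g[i] = mask[i] ? 1e18 : 0.0;
  std::vector<double> f(n), d(n), z(n + 1);
  std::vector<int> v(n);
  // x pass
  for (int k = 0; k < n; ++k)
    for (int j = 0; j < n; ++j) {
      for (int i = 0; i < n; ++i) f[i] = g[idx3(i, j, k, n)];
      edt1d(f, d, n, v, z);
      for (int i = 0; i < n; ++i) g[idx3(i, j, k, n)] = d[i];
    }
  // y pass
  for (int k = 0; k < n; ++k)
    for (int i = 0; i < n; ++i) {
      for (int j = 0; j < n; ++j) f[j] = g[idx3(i, j, k, n)];
      edt1d(f, d, n, v, z);
      for (int j = 0; j < n; ++j) g[idx3(i, j, k, n)] = d[j];
    }
  // z pass
  for (int j = 0; j < n; ++j)
    for (int i = 0; i < n; ++i) {
      for (int k = 0; k < n; ++k) f[k] = g[idx3(i, j, k, n)];
      edt1d(f, d, n, v, z);
      for (int k = 0; k < n; ++k) g[idx3(i, j, k, n)] = d[k];
    }
  return g;
}

// Build the finite-difference maps for the linearized PB equation on a cubic
// grid of n^3 nodes with spacing h centred at `center`.
//
// The dielectric boundary is the molecular (solvent-excluded) surface,
// realised as a signed level field: a node is interior when the distance from
// the node to the solvent-accessible complement is at least `probe`
// (grid morphological closing of the probe-inflated van der Waals volume).
// The level combines an analytic per-atom depth (exact for convex patches)
// with a lattice Euclidean distance transform that seals reentrant volume.
// Link dielectrics are harmonically averaged with the linear-interpolation
// crossing fraction, which restores sub-grid boundary placement.
// [[Rcpp::export]]
List cpp_pb_maps(const NumericMatrix &coords, const NumericVector &q,
                 const NumericVector &radius, int n, double h,
                 const NumericVector &center, double eps_in, double eps_out,
                 double kappa2bar, double stern, double probe) {
  long n3 = (long)n * n * n;
  double half = (n - 1) / 2.0;
  double x0 = center[0] - half * h, y0 = center[1] - half * h,
         z0 = center[2] - half * h;
  int m = coords.nrow();

  // analytic SAS depth, computed locally around each atom
  std::vector<double> level(n3, -1e9);
  std::vector<int> stern_block(n3, 0);
  for (int a = 0; a < m; ++a) {
    double ra = radius[a];
    if (ra <= 0.0 && q[a] == 0.0) continue;
    double reach = ra + probe + 4.0 * h;
    double reach_st = ra + stern;
    double rmax = std::max(reach, reach_st);
    double ax = coords(a, 0), ay = coords(a, 1), az = coords(a, 2);
    int i0 = std::max(0, (int)std::floor((ax - rmax - x0) / h));
    int i1 = std::min(n - 1, (int)std::ceil((ax + rmax - x0) / h));
    int j0 = std::max(0, (int)std::floor((ay - rmax - y0) / h));
    int j1 = std::min(n - 1, (int)std::ceil((ay + rmax - y0) / h));
    int k0 = std::max(0, (int)std::floor((az - rmax - z0) / h));
    int k1 = std::min(n - 1, (int)std::ceil((az + rmax - z0) / h));
    for (int k = k0; k <= k1; ++k)
      for (int j = j0; j <= j1; ++j)
        for (int i = i0; i <= i1; ++i) {
          double dx = x0 + i * h - ax, dy = y0 + j * h - ay,
                 dz = z0 + k * h - az;
          double r = std::sqrt(dx * dx + dy * dy + dz * dz);
          long id = idx3(i, j, k, n);
          double depth = ra + probe - r;
          if (depth > level[id]) level[id] = depth;
          if (r < reach_st) stern_block[id] = 1;
        }
  }
  // lattice closing: distance to the SAS complement seals reentrant pockets
  std::vector<int> sas(n3);
  for (long i = 0; i < n3; ++i) sas[i] = level[i] > 0.0 ? 1 : 0;
  std::vector<double> d2 = edt3(sas, n);
  const double lattice_bias = 0.8660254 * h; // node-offset safety margin
  for (long i = 0; i < n3; ++i) {
    if (sas[i]) {
      double dl = std::sqrt(d2[i]) * h - lattice_bias;
      if (dl > level[i]) level[i] = dl;
    }
    level[i] -= probe; // > 0 => inside the molecular surface
  }

  // harmonic link dielectrics with linear crossing fraction
  NumericVector epsx(n3), epsy(n3), epsz(n3);
  auto link_eps = [&](double lu, double lv) {
    bool iu = lu > 0.0, iv = lv > 0.0;
    if (iu && iv) return eps_in;
    if (!iu && !iv) return eps_out;
    double f = lu / (lu - lv); // fraction of link on the u side of crossing
    double f_in = iu ? f : 1.0 - f;
    return 1.0 / (f_in / eps_in + (1.0 - f_in) / eps_out);
  };
  for (int k = 0; k < n; ++k)
    for (int j = 0; j < n; ++j)
      for (int i = 0; i < n; ++i) {
        long id = idx3(i, j, k, n);
        if (i < n - 1) epsx[id] = link_eps(level[id], level[idx3(i + 1, j, k, n)]);
        if (j < n - 1) epsy[id] = link_eps(level[id], level[idx3(i, j + 1, k, n)]);
        if (k < n - 1) epsz[id] = link_eps(level[id], level[idx3(i, j, k + 1, n)]);
      }

  NumericVector k2(n3);
  for (long i = 0; i < n3; ++i)
    k2[i] = (level[i] <= 0.0 && !stern_block[i]) ? kappa2bar : 0.0;

  // trilinear charge spreading
  NumericVector rho(n3);
  for (int a = 0; a < m; ++a) {
    if (q[a] == 0.0) continue;
    double gx = (coords(a, 0) - x0) / h, gy = (coords(a, 1) - y0) / h,
           gz = (coords(a, 2) - z0) / h;
    int i = (int)std::floor(gx), j = (int)std::floor(gy),
        k = (int)std::floor(gz);
    if (i < 0 || j < 0 || k < 0 || i > n - 2 || j > n - 2 || k > n - 2)
      stop("solute charge outside the PB grid; enlarge the coarse grid");
    double fx = gx - i, fy = gy - j, fz = gz - k;
    for (int di = 0; di < 2; ++di)
      for (int dj = 0; dj < 2; ++dj)
        for (int dk = 0; dk < 2; ++dk) {
          double w = (di ? fx : 1 - fx) * (dj ? fy : 1 - fy) *
                     (dk ? fz : 1 - fz);
          rho[idx3(i + di, j + dj, k + dk, n)] += w * q[a];
        }
  }

  NumericVector lev(n3);
  for (long i = 0; i < n3; ++i) lev[i] = level[i];
  return List::create(_["epsx"] = epsx, _["epsy"] = epsy, _["epsz"] = epsz,
                      _["k2"] = k2, _["rho"] = rho, _["level"] = lev);
}

// Fill the six boundary faces of phi with screened-Coulomb (Debye-Hueckel)
// potentials of the solute charges in uniform solvent dielectric.
// [[Rcpp::export]]
NumericVector cpp_pb_boundary(NumericVector phi, int n, double h,
                              const NumericVector &center,
                              const NumericMatrix &coords,
                              const NumericVector &q, double eps_solv,
                              double kappa) {
  double half = (n - 1) / 2.0;
  double x0 = center[0] - half * h, y0 = center[1] - half * h,
         z0 = center[2] - half * h;
  int m = coords.nrow();
  auto fill = [&](int i, int j, int k) {
    double px = x0 + i * h, py = y0 + j * h, pz = z0 + k * h;
    double v = 0.0;
    for (int a = 0; a < m; ++a) {
      if (q[a] == 0.0) continue;
      double dx = px - coords(a, 0), dy = py - coords(a, 1),
             dz = pz - coords(a, 2);
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (r < 1e-6) r = 1e-6;
      v += COULOMB_K * q[a] * std::exp(-kappa * r) / (eps_solv * r);
    }
    phi[idx3(i, j, k, n)] = v;
  };
  for (int j = 0; j < n; ++j)
    for (int i = 0; i < n; ++i) { fill(i, j, 0); fill(i, j, n - 1); }
  for (int k = 0; k < n; ++k)
    for (int i = 0; i < n; ++i) { fill(i, 0, k); fill(i, n - 1, k); }
  for (int k = 0; k < n; ++k)
    for (int j = 0; j < n; ++j) { fill(0, j, k); fill(n - 1, j, k); }
  return phi;
}

// Successive over-relaxation for the linearized PB equation.
// Node equation: sum_links eps_l (phi_nb - phi_0) * h - k2 h^3 phi_0
//                + 4 pi K q_0 / ... collapses (dividing by h) to
//   phi_0 = (sum eps_l phi_nb + 4 pi K q_0 / h) / (sum eps_l + k2 h^2)
// [[Rcpp::export]]
List cpp_pb_sor(const NumericVector &epsx, const NumericVector &epsy,
                const NumericVector &epsz, const NumericVector &k2,
                const NumericVector &rho, NumericVector phi, int n, double h,
                double omega, double tol, int max_iter) {
  const double fourpiK = 4.0 * M_PI * COULOMB_K;
  double resid = 1e30;
  int it = 0;
  for (it = 1; it <= max_iter; ++it) {
    double max_upd = 0.0, max_phi = 1e-30;
    for (int k = 1; k < n - 1; ++k)
      for (int j = 1; j < n - 1; ++j)
        for (int i = 1; i < n - 1; ++i) {
          long id = idx3(i, j, k, n);
          double exm = epsx[idx3(i - 1, j, k, n)], exp_ = epsx[id];
          double eym = epsy[idx3(i, j - 1, k, n)], eyp = epsy[id];
          double ezm = epsz[idx3(i, j, k - 1, n)], ezp = epsz[id];
          double num = exm * phi[id - 1] + exp_ * phi[id + 1] +
                       eym * phi[id - n] + eyp * phi[id + n] +
                       ezm * phi[id - (long)n * n] + ezp * phi[id + (long)n * n] +
                       fourpiK * rho[id] / h;
          double den = exm + exp_ + eym + eyp + ezm + ezp + k2[id] * h * h;
          double gs = num / den;
          double upd = gs - phi[id];
          phi[id] += omega * upd;
          double au = std::fabs(upd);
          if (au > max_upd) max_upd = au;
          double ap = std::fabs(phi[id]);
          if (ap > max_phi) max_phi = ap;
        }
    resid = max_upd / max_phi;
    if (resid < tol) break;
  }
  if (resid >= tol)
    stop("PB solver did not converge: relative residual %g after %d iterations",
         resid, max_iter);
  return List::create(_["phi"] = phi, _["iterations"] = it,
                      _["residual"] = resid);
}

// Trilinear interpolation of a grid field at arbitrary points.
// [[Rcpp::export]]
NumericVector cpp_trilinear(const NumericVector &phi, int n, double h,
                            const NumericVector &center,
                            const NumericMatrix &points) {
  double half = (n - 1) / 2.0;
  double x0 = center[0] - half * h, y0 = center[1] - half * h,
         z0 = center[2] - half * h;
  int m = points.nrow();
  NumericVector out(m);
  for (int a = 0; a < m; ++a) {
    double gx = (points(a, 0) - x0) / h, gy = (points(a, 1) - y0) / h,
           gz = (points(a, 2) - z0) / h;
    int i = (int)std::floor(gx), j = (int)std::floor(gy),
        k = (int)std::floor(gz);
    if (i < 0 || j < 0 || k < 0 || i > n - 2 || j > n - 2 || k > n - 2)
      stop("interpolation point outside the grid");
    double fx = gx - i, fy = gy - j, fz = gz - k;
    double v = 0.0;
    for (int di = 0; di < 2; ++di)
      for (int dj = 0; dj < 2; ++dj)
        for (int dk = 0; dk < 2; ++dk) {
          double w = (di ? fx : 1 - fx) * (dj ? fy : 1 - fy) *
                     (dk ? fz : 1 - fz);
          v += w * phi[idx3(i + di, j + dj, k + dk, n)];
        }
    out[a] = v;
  }
  return out;
}
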