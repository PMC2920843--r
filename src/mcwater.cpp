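#include <Rcpp.h>
using namespace Rcpp;

static const double COULOMB_K = 332.0637;

// Interaction energy of rigid 3-site water `m` with all other waters.
// Molecule-based minimum image and cutoff: the O-O displacement picks the
// image, the whole partner molecule is shifted with it (keeps dipoles whole).
static double mol_energy(const std::vector<double> &x, int m, int n_waters,
                         double L, double cut2,
                         const double *qs, const double *epss,
                         const double *rminhs) {
  double e = 0.0;
  const double *pm = &x[9 * m];
  for (int k = 0; k < n_waters; ++k) {
    if (k == m) continue;
    const double *pk = &x[9 * k];
    double dx = pk[0] - pm[0], dy = pk[1] - pm[1], dz = pk[2] - pm[2];
    double sx = -L * std::round(dx / L), sy = -L * std::round(dy / L),
           sz = -L * std::round(dz / L);
    dx += sx; dy += sy; dz += sz;
    double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 > cut2) continue;
    for (int a = 0; a < 3; ++a) {
      for (int b = 0; b < 3; ++b) {
        double ddx = pk[3 * b] + sx - pm[3 * a];
        double ddy = pk[3 * b + 1] + sy - pm[3 * a + 1];
        double ddz = pk[3 * b + 2] + sz - pm[3 * a + 2];
        double rr2 = ddx * ddx + ddy * ddy + ddz * ddz;
        double r = std::sqrt(rr2);
        e += COULOMB_K * qs[a] * qs[b] / r;
        double epsij = std::sqrt(epss[a] * epss[b]);
        if (epsij > 0.0) {
          double rmin = rminhs[a] + rminhs[b];
          double s2 = rmin * rmin / rr2;
          double s6 = s2 * s2 * s2;
          e += epsij * (s6 * s6 - 2.0 * s6);
        }
      }
    }
  }
  return e;
}

static void rotate_about(double *p, const double *o, const double *axis,
                         double ang) {
  double ux = axis[0], uy = axis[1], uz = axis[2];
  double c = std::cos(ang), s = std::sin(ang);
  double vx = p[0] - o[0], vy = p[1] - o[1], vz = p[2] - o[2];
  double dot = ux * vx + uy * vy + uz * vz;
  double rx = vx * c + (uy * vz - uz * vy) * s + ux * dot * (1 - c);
  double ry = vy * c + (uz * vx - ux * vz) * s + uy * dot * (1 - c);
  double rz = vz * c + (ux * vy - uy * vx) * s + uz * dot * (1 - c);
  p[0] = o[0] + rx; p[1] = o[1] + ry; p[2] = o[2] + rz;
}

// Metropolis Monte Carlo of rigid 3-site waters in a cubic periodic box.
// coords0: (3*n_waters) x 3 matrix, O/H1/H2 per molecule. site_q/site_eps/
// site_rminh: per-site (O,H1,H2) parameters. Snapshots are taken every
// `spacing_attempts` attempted moves once at least `min_accept` moves have
// been accepted since the previous snapshot. Uses R's RNG.
// [[Rcpp::export]]
List cpp_mc_water(const NumericMatrix &coords0, double L, double temperature,
                  double cutoff, int n_equil_moves, int n_snapshots,
                  int spacing_attempts, int min_accept,
                  double dtrans, double drot,
                  const NumericVector &site_q, const NumericVector &site_eps,
                  const NumericVector &site_rminh) {
  int n_waters = coords0.nrow() / 3;
  std::vector<double> x(9 * n_waters);
  for (int i = 0; i < 3 * n_waters; ++i)
    for (int d = 0; d < 3; ++d) x[3 * i + d] = coords0(i, d);
  double cut2 = cutoff * cutoff;
  double kT = 0.0019872041 * temperature;
  const double *qs = &site_q[0], *epss = &site_eps[0],
               *rminhs = &site_rminh[0];

  long accepted = 0, attempted = 0;
  NumericVector frames(Dimension(3 * n_waters, 3, n_snapshots));
  NumericVector snap_energy(n_snapshots);
  std::vector<double> trial(9);

  int snap = 0;
  long since_attempt = 0, since_accept = 0;
  long total_moves = (long)n_equil_moves +
                     (long)n_snapshots * (long)spacing_attempts * 4L + 1000000L;
  bool production = false;
  for (long step = 0; step < total_moves && snap < n_snapshots; ++step) {
    if (!production && step >= n_equil_moves) {
      production = true;
      since_attempt = 0;
      since_accept = 0;
    }
    int m = (int)std::floor(R::runif(0.0, 1.0) * n_waters);
    if (m >= n_waters) m = n_waters - 1;
    double e_old = mol_energy(x, m, n_waters, L, cut2, qs, epss, rminhs);
    for (int d = 0; d < 9; ++d) trial[d] = x[9 * m + d];
    // translation
    double tx = R::runif(-dtrans, dtrans), ty = R::runif(-dtrans, dtrans),
           tz = R::runif(-dtrans, dtrans);
    for (int a = 0; a < 3; ++a) {
      trial[3 * a] += tx; trial[3 * a + 1] += ty; trial[3 * a + 2] += tz;
    }
    // rotation about the oxygen, random axis
    double ax[3];
    double norm = 0.0;
    do {
      ax[0] = R::norm_rand(); ax[1] = R::norm_rand(); ax[2] = R::norm_rand();
      norm = std::sqrt(ax[0] * ax[0] + ax[1] * ax[1] + ax[2] * ax[2]);
    } while (norm < 1e-12);
    for (int d = 0; d < 3; ++d) ax[d] /= norm;
    double ang = R::runif(-drot, drot);
    rotate_about(&trial[3], &trial[0], ax, ang);
    rotate_about(&trial[6], &trial[0], ax, ang);
    // wrap oxygen into the box, moving the whole molecule
    for (int d = 0; d < 3; ++d) {
      double shift = -L * std::floor(trial[d] / L);
      trial[d] += shift; trial[3 + d] += shift; trial[6 + d] += shift;
    }
    std::vector<double> saved(9);
    for (int d = 0; d < 9; ++d) saved[d] = x[9 * m + d];
    for (int d = 0; d < 9; ++d) x[9 * m + d] = trial[d];
    double e_new = mol_energy(x, m, n_waters, L, cut2, qs, epss, rminhs);
    double dE = e_new - e_old;
    bool acc = dE <= 0.0 || R::runif(0.0, 1.0) < std::exp(-dE / kT);
    if (!acc) {
      for (int d = 0; d < 9; ++d) x[9 * m + d] = saved[d];
    }
    ++attempted;
    if (acc) ++accepted;
    if (production) {
      ++since_attempt;
      if (acc) ++since_accept;
      if (since_attempt >= spacing_attempts && since_accept >= min_accept) {
        for (int i = 0; i < 3 * n_waters; ++i)
          for (int d = 0; d < 3; ++d)
            frames[i + (long)3 * n_waters * (d + 3L * snap)] = x[3 * i + d];
        double etot = 0.0;
        for (int k = 0; k < n_waters; ++k)
          etot += mol_energy(x, k, n_waters, L, cut2, qs, epss, rminhs);
        snap_energy[snap] = 0.5 * etot;
        ++snap;
        since_attempt = 0;
        since_accept = 0;
      }
    }
  }
  if (snap < n_snapshots)
    stop("Monte Carlo sampler did not reach the requested snapshot count");
  return List::create(_["frames"] = frames,
                      _["acceptance"] = (double)accepted / (double)attempted,
                      _["snapshot_energy"] = snap_energy);
}
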