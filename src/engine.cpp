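// Coarse-grained chain energy engine and Metropolis Monte Carlo sampler.
//
// Units: nm, kJ/mol, elementary charges, K.  The electrostatic prefactor
// e^2/(4 pi eps0) = 138.935458 kJ mol^-1 nm e^-2 (interior dielectric 1).
//
// Generalized Born flavour: Still-style pairwise f_GB with effective Born
// radii from a Coulomb-field-approximation pairwise descreening integral
// (exact for non-overlapping spheres; overlapping pairs are evaluated at the
// contact distance, which caps the descreening smoothly).  The nonpolar term
// is a per-bead solvent-accessible surface area from pairwise spherical-cap
// burial, scaled by a per-bead surface-tension coefficient.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double KE = 138.935458;   // kJ mol^-1 nm e^-2
static const double PROBE = 0.14;      // nm, water probe radius
static const double INV_RADIUS_FLOOR = 1e-3; // caps effective radii at 1000 nm

struct Topo {
  int n;
  IntegerMatrix bonds;          // m x 2, 0-based
  NumericVector br0, bk;
  IntegerMatrix angles;         // a x 3, 0-based
  NumericVector at0, ak;
  NumericVector q, rho, sig, eps, gam;
  int t1, t2;                   // terminal bead indices, 0-based
  std::vector<char> excl;       // n*n, 1-2 exclusions for nonbonded terms
};

static Topo parse_topo(const List& tl) {
  Topo t;
  t.n = as<int>(tl["n"]);
  t.bonds = as<IntegerMatrix>(tl["bonds"]);
  t.br0 = as<NumericVector>(tl["bond_r0"]);
  t.bk = as<NumericVector>(tl["bond_k"]);
  t.angles = as<IntegerMatrix>(tl["angles"]);
  t.at0 = as<NumericVector>(tl["angle_theta0"]);
  t.ak = as<NumericVector>(tl["angle_k"]);
  t.q = as<NumericVector>(tl["charge"]);
  t.rho = as<NumericVector>(tl["born_radius"]);
  t.sig = as<NumericVector>(tl["lj_sigma"]);
  t.eps = as<NumericVector>(tl["lj_eps"]);
  t.gam = as<NumericVector>(tl["gamma"]);
  IntegerVector term = as<IntegerVector>(tl["terminals"]);
  t.t1 = term[0]; t.t2 = term[1];
  t.excl.assign((size_t)t.n * t.n, 0);
  for (int b = 0; b < t.bonds.nrow(); ++b) {
    int i = t.bonds(b, 0), j = t.bonds(b, 1);
    t.excl[(size_t)i * t.n + j] = 1;
    t.excl[(size_t)j * t.n + i] = 1;
  }
  return t;
}

static inline double dist3(const double* x, int i, int j, int n) {
  double dx = x[i] - x[j];
  double dy = x[i + n] - x[j + n];
  double dz = x[i + 2 * n] - x[j + 2 * n];
  return std::sqrt(dx * dx + dy * dy + dz * dz);
}

static double e_bonded(const Topo& t, const double* x) {
  double e = 0.0;
  int n = t.n;
  for (int b = 0; b < t.bonds.nrow(); ++b) {
    double r = dist3(x, t.bonds(b, 0), t.bonds(b, 1), n);
    double d = r - t.br0[b];
    e += 0.5 * t.bk[b] * d * d;
  }
  for (int a = 0; a < t.angles.nrow(); ++a) {
    int i = t.angles(a, 0), j = t.angles(a, 1), k = t.angles(a, 2);
    double v1x = x[i] - x[j], v1y = x[i + n] - x[j + n], v1z = x[i + 2 * n] - x[j + 2 * n];
    double v2x = x[k] - x[j], v2y = x[k + n] - x[j + n], v2z = x[k + 2 * n] - x[j + 2 * n];
    double c = (v1x * v2x + v1y * v2y + v1z * v2z) /
      (std::sqrt(v1x * v1x + v1y * v1y + v1z * v1z) *
       std::sqrt(v2x * v2x + v2y * v2y + v2z * v2z));
    c = std::max(-1.0, std::min(1.0, c));
    double d = std::acos(c) - t.at0[a];
    e += 0.5 * t.ak[a] * d * d;
  }
  return e;
}

// LJ + Coulomb over non-excluded pairs (1-2 bonded pairs excluded)
static void e_nonbonded(const Topo& t, const double* x, double* lj, double* coul) {
  *lj = 0.0; *coul = 0.0;
  int n = t.n;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      if (t.excl[(size_t)i * n + j]) continue;
      double r = dist3(x, i, j, n);
      double epsij = std::sqrt(t.eps[i] * t.eps[j]);
      if (epsij > 0.0) {
        double s = 0.5 * (t.sig[i] + t.sig[j]);
        double sr6 = std::pow(s / r, 6.0);
        *lj += 4.0 * epsij * (sr6 * sr6 - sr6);
      }
      if (t.q[i] != 0.0 && t.q[j] != 0.0) *coul += KE * t.q[i] * t.q[j] / r;
    }
  }
}

// CFA descreening integral of a sphere radius rho at centre distance r (>= contact)
static inline double descreen(double r, double rho) {
  return 0.5 * (rho / (r * r - rho * rho) + (0.5 / r) * std::log((r - rho) / (r + rho)));
}

static void born_radii(const Topo& t, const double* x, std::vector<double>& R) {
  int n = t.n;
  R.resize(n);
  for (int i = 0; i < n; ++i) {
    double inv = 1.0 / t.rho[i];
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double r = dist3(x, i, j, n);
      double contact = t.rho[i] + t.rho[j];
      if (r < contact) r = contact;
      inv -= descreen(r, t.rho[j]);
    }
    if (inv < INV_RADIUS_FLOOR) inv = INV_RADIUS_FLOOR;
    R[i] = 1.0 / inv;
  }
}

static double e_gb(const Topo& t, const double* x, double eps_r) {
  if (eps_r <= 1.0) return 0.0;
  int n = t.n;
  std::vector<double> R;
  born_radii(t, x, R);
  double s = 0.0;
  for (int i = 0; i < n; ++i) {
    if (t.q[i] == 0.0) continue;
    s += t.q[i] * t.q[i] / R[i];
    for (int j = i + 1; j < n; ++j) {
      if (t.q[j] == 0.0) continue;
      double r = dist3(x, i, j, n);
      double rr = R[i] * R[j];
      double f = std::sqrt(r * r + rr * std::exp(-r * r / (4.0 * rr)));
      s += 2.0 * t.q[i] * t.q[j] / f;
    }
  }
  return -0.5 * KE * (1.0 - 1.0 / eps_r) * s;
}

static void sasa(const Topo& t, const double* x, std::vector<double>& A) {
  int n = t.n;
  A.resize(n);
  for (int i = 0; i < n; ++i) {
    double ai = t.rho[i] + PROBE;
    double area = 4.0 * M_PI * ai * ai;
    double buried = 0.0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double aj = t.rho[j] + PROBE;
      double r = dist3(x, i, j, n);
      if (r >= ai + aj) continue;
      if (r + ai <= aj) { buried = area; break; }   // engulfed
      double h = ai - (r * r + ai * ai - aj * aj) / (2.0 * r);
      if (h > 0.0) buried += 2.0 * M_PI * ai * h;
    }
    A[i] = std::max(0.0, area - buried);
  }
}

static double e_sa(const Topo& t, const double* x) {
  std::vector<double> A;
  sasa(t, x, A);
  double e = 0.0;
  for (int i = 0; i < t.n; ++i) e += t.gam[i] * A[i];
  return e;
}

static double e_solv(const Topo& t, const double* x, double eps_r, bool sa_on) {
  double e = e_gb(t, x, eps_r);
  if (sa_on) e += e_sa(t, x);
  return e;
}

static double e_intra(const Topo& t, const double* x) {
  double lj, coul;
  e_nonbonded(t, x, &lj, &coul);
  return e_bonded(t, x) + lj + coul;
}

// [[Rcpp::export]]
List cpp_energy_terms(NumericMatrix coords, List topo, double eps_r, bool sa_on) {
  Topo t = parse_topo(topo);
  if (coords.nrow() != t.n || coords.ncol() != 3)
    stop("conformation has %d x %d coordinates but topology has %d beads",
         coords.nrow(), coords.ncol(), t.n);
  const double* x = coords.begin();
  double lj, coul;
  e_nonbonded(t, x, &lj, &coul);
  double bonded_only = e_bonded(t, x);
  std::vector<double> R, A;
  born_radii(t, x, R);
  sasa(t, x, A);
  return List::create(
    _["bonded"] = bonded_only,
    _["lj"] = lj,
    _["coulomb"] = coul,
    _["gb"] = e_gb(t, x, eps_r),
    _["sa"] = sa_on ? e_sa(t, x) : 0.0,
    _["born_radii"] = NumericVector(R.begin(), R.end()),
    _["sasa"] = NumericVector(A.begin(), A.end()));
}

// Per-frame energies over an n x 3 x F array.
// what: 0 = solvation, 1 = intramolecular, 2 = effective, 3 = total SASA
// [[Rcpp::export]]
NumericVector cpp_eval_frames(NumericVector frames, List topo, double eps_r,
                              bool sa_on, int what) {
  Topo t = parse_topo(topo);
  IntegerVector dim = frames.attr("dim");
  if (dim.size() != 3 || dim[0] != t.n || dim[1] != 3)
    stop("frames array must be n_beads x 3 x n_frames");
  int nf = dim[2];
  size_t stride = (size_t)t.n * 3;
  NumericVector out(nf);
  for (int f = 0; f < nf; ++f) {
    const double* x = frames.begin() + stride * f;
    double v;
    if (what == 0) v = e_solv(t, x, eps_r, sa_on);
    else if (what == 1) v = e_intra(t, x);
    else if (what == 2) v = e_intra(t, x) + e_solv(t, x, eps_r, sa_on);
    else {
      std::vector<double> A;
      sasa(t, x, A);
      v = 0.0;
      for (int i = 0; i < t.n; ++i) v += A[i];
    }
    out[f] = v;
  }
  return out;
}

// Metropolis Monte Carlo with single-bead Gaussian displacements.
// bias_mode: 0 none; 1 harmonic restraint 0.5*k*(R - R0)^2 on the end-to-end
// distance; 2 exact fixed-R (terminal beads frozen, no restraint energy).
// Uses R's RNG so set.seed() gives bit-identical trajectories.
// [[Rcpp::export]]
List cpp_mc_sample(NumericMatrix coords0, List topo, double eps_r, bool sa_on,
                   double beta, int n_equil, int n_frames, int stride,
                   double step_sd, int bias_mode, double bias_k, double bias_r0) {
  Topo t = parse_topo(topo);
  int n = t.n;
  if (coords0.nrow() != n || coords0.ncol() != 3)
    stop("initial conformation has %d x %d coordinates but topology has %d beads",
         coords0.nrow(), coords0.ncol(), n);
  std::vector<double> x(coords0.begin(), coords0.end());
  std::vector<int> movable;
  for (int i = 0; i < n; ++i)
    if (bias_mode != 2 || (i != t.t1 && i != t.t2)) movable.push_back(i);

  auto energy = [&](const double* xx) {
    double e = e_intra(t, xx) + e_solv(t, xx, eps_r, sa_on);
    if (bias_mode == 1) {
      double R = dist3(xx, t.t1, t.t2, n);
      double d = R - bias_r0;
      e += 0.5 * bias_k * d * d;
    }
    return e;
  };

  double e_cur = energy(x.data());
  if (!std::isfinite(e_cur)) stop("non-finite energy for the initial conformation");

  long n_acc = 0, n_try = 0;
  NumericVector frames((size_t)n * 3 * n_frames);
  frames.attr("dim") = IntegerVector::create(n, 3, n_frames);
  NumericVector Rvec(n_frames);
  long total = (long)n_equil + (long)n_frames * stride;
  long saved = 0;

  for (long s = 0; s < total; ++s) {
    if (!movable.empty()) {
      int b = movable[(int)std::floor(R::unif_rand() * movable.size())];
      double old0 = x[b], old1 = x[b + n], old2 = x[b + 2 * n];
      x[b]         = old0 + step_sd * R::norm_rand();
      x[b + n]     = old1 + step_sd * R::norm_rand();
      x[b + 2 * n] = old2 + step_sd * R::norm_rand();
      double e_new = energy(x.data());
      if (!std::isfinite(e_new))
        stop("non-finite energy encountered during sampling (step %ld)", s);
      ++n_try;
      if (e_new <= e_cur || R::unif_rand() < std::exp(-beta * (e_new - e_cur))) {
        e_cur = e_new; ++n_acc;
      } else {
        x[b] = old0; x[b + n] = old1; x[b + 2 * n] = old2;
      }
    }
    if (s >= n_equil && ((s - n_equil + 1) % stride == 0)) {
      std::copy(x.begin(), x.end(), frames.begin() + (size_t)n * 3 * saved);
      Rvec[saved] = dist3(x.data(), t.t1, t.t2, n);
      ++saved;
      if (saved == n_frames) break;
    }
  }
  if (saved != n_frames) stop("sampler produced %ld of %d frames", saved, n_frames);

  NumericMatrix final_coords(n, 3);
  std::copy(x.begin(), x.end(), final_coords.begin());
  return List::create(
    _["frames"] = frames,
    _["R"] = Rvec,
    _["acceptance"] = n_try > 0 ? (double)n_acc / n_try : NA_REAL,
    _["final"] = final_coords);
}
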