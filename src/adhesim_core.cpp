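// Compiled core of the hybrid CPM / focal-adhesion simulator.
//
// Conventions shared with the R layer:
//  * lattices are R matrices (column-major), nrow = ny, ncol = nx;
//    linear index k = (ix-1)*ny + (iy-1) for 1-based (ix, iy)
//  * spin: 0 = medium, 1 = cell (single cell)
//  * units: length um, force nN, per-bond force pN (1 nN = 1000 pN),
//    stiffness kPa, time s
//  * all randomness goes through R's RNG (unif_rand) so that runs are
//    reproducible from set.seed() and the R-level seed plumbing
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double koff_rate(double f, double k_s, double k_c,
                               double F_slip, double F_catch) {
  return k_s * std::exp(f / F_slip) + k_c * std::exp(-f / F_catch);
}

//' @noRd
// [[Rcpp::export]]
double cpp_koff(double f, double k_s, double k_c, double F_slip, double F_catch) {
  if (f < 0) stop("per-bond force must be non-negative");
  return koff_rate(f, k_s, k_c, F_slip, F_catch);
}

// Binding runs at the constant rate gamma while free integrins are
// plentiful and is linearly limited once the free fraction drops below
// the reserve fraction `pool_sat`.
static inline double bind_rate(double gamma, int N_free, double N_total,
                               double pool_sat) {
  double frac = (double)N_free / N_total;
  return (frac >= pool_sat) ? gamma : gamma * frac / pool_sat;
}

// One tau-leap substep of a single cluster with integer bookkeeping:
// bond gains ~ Poisson(bind_rate * dt) clamped by the pool,
// bond losses ~ Binomial(N, 1 - exp(-koff(F/N) * dt)).
// Returns (N_new, N_free_new).
// [[Rcpp::export]]
IntegerVector cpp_cluster_step(int N, double F, int N_free, double N_total,
                               double dt, double gamma,
                               double k_s, double k_c, double F_slip, double F_catch,
                               double pool_sat = 0.4) {
  if (N < 0 || N_free < 0) stop("bond counts must be non-negative");
  if (N == 0) return IntegerVector::create(0, N_free);
  double f = 1000.0 * F / (double)N; // nN -> pN per bond
  double koff = koff_rate(f, k_s, k_c, F_slip, F_catch);
  int gain = (int)R::rpois(bind_rate(gamma, N_free, N_total, pool_sat) * dt);
  if (gain > N_free) gain = N_free; // pool exhaustion clamps binding
  int loss = (int)R::rbinom((double)N, 1.0 - std::exp(-koff * dt));
  N += gain - loss;
  N_free += loss - gain;
  return IntegerVector::create(N, N_free);
}

// Integrate force build-up and tau-leap cluster kinetics on every
// adhesion-bearing site for one inter-MCS window of t_fa seconds.
//
// occ:    0-based linear indices of sites that carry a cluster (N > 0)
// F, N:   full-lattice vectors, modified copies are returned
// Fs_eff: stall force per occ site (already feedback-scaled for model 2.2)
// E_occ:  local Young's modulus per occ site (kPa)
// [[Rcpp::export]]
List cpp_fa_window(IntegerVector occ, IntegerVector N_in, NumericVector F_in,
                   NumericVector Fs_eff, NumericVector E_occ,
                   double ell, double v0, double t_fa, double dt,
                   double gamma, double N_total, int N_free,
                   double k_s, double k_c, double F_slip, double F_catch,
                   double pool_sat = 0.4, double E_series = 150.0) {
  IntegerVector N = clone(N_in);
  NumericVector F = clone(F_in);
  int nsub = (int)std::lround(t_fa / dt);
  if (nsub < 1) stop("t_fa/dt must be a positive integer");
  int nocc = occ.size();
  for (int s = 0; s < nocc; ++s) {
    int k = occ[s];
    int Nk = N[k];
    if (Nk <= 0) continue;
    double Fs = Fs_eff[s];
    double Fk = F[k];
    if (Fk > Fs) Fk = Fs; // stall force dropped since last MCS: clip
    double decay = 0.0;
    if (Fs > 0.0) {
      // substrate spring in series with the intracellular linkage
      double E_eff = E_occ[s] * E_series / (E_occ[s] + E_series);
      double tau = Fs / (E_eff * ell * v0); // s
      decay = std::exp(-dt / tau);
    } else {
      Fk = 0.0;
    }
    for (int i = 0; i < nsub; ++i) {
      if (Fs > 0.0) Fk = Fs + (Fk - Fs) * decay; // exact linear build-up
      double f = 1000.0 * Fk / (double)Nk;
      double koff = koff_rate(f, k_s, k_c, F_slip, F_catch);
      int gain = (int)R::rpois(bind_rate(gamma, N_free, N_total, pool_sat) * dt);
      if (gain > N_free) gain = N_free;
      int loss = (int)R::rbinom((double)Nk, 1.0 - std::exp(-koff * dt));
      Nk += gain - loss;
      N_free += loss - gain;
      if (Nk == 0) { Fk = 0.0; break; }
    }
    N[k] = Nk;
    F[k] = Fk;
  }
  return List::create(_["N"] = N, _["F"] = F, _["N_free"] = N_free);
}

// ---- CPM machinery ---------------------------------------------------------

static inline int spin_at(const IntegerMatrix &spin, int ix, int iy) {
  // outside the domain counts as medium
  if (ix < 0 || iy < 0 || ix >= spin.ncol() || iy >= spin.nrow()) return 0;
  return spin(iy, ix);
}

// von Neumann interface energy change of setting site (ix,iy) to s_new
static inline double dH_interface(const IntegerMatrix &spin, int ix, int iy,
                                  int s_new, double J) {
  static const int dx4[4] = {1, -1, 0, 0};
  static const int dy4[4] = {0, 0, 1, -1};
  int s_old = spin(iy, ix);
  int d = 0;
  for (int n = 0; n < 4; ++n) {
    int sn = spin_at(spin, ix + dx4[n], iy + dy4[n]);
    d += ((s_new != sn) ? 1 : 0) - ((s_old != sn) ? 1 : 0);
  }
  return J * (double)d;
}

// Local connectivity of the 8-ring around (ix,iy) after its removal from the
// cell: retraction is allowed only if the cell sites on the ring form one
// cyclically contiguous block (a local simple-point condition; consecutive
// ring positions are always 4-adjacent on the lattice).
static bool ring_stays_connected(const IntegerMatrix &spin, int ix, int iy) {
  static const int rx[8] = {1, 1, 0, -1, -1, -1, 0, 1};
  static const int ry[8] = {0, 1, 1, 1, 0, -1, -1, -1};
  int ring[8];
  int ncell = 0;
  for (int i = 0; i < 8; ++i) {
    ring[i] = spin_at(spin, ix + rx[i], iy + ry[i]);
    ncell += ring[i];
  }
  if (ncell == 0) return false; // last site of an arm: keep
  if (ncell == 8) return true;
  int blocks = 0;
  for (int i = 0; i < 8; ++i) {
    int prev = ring[(i + 7) % 8];
    if (ring[i] == 1 && prev == 0) ++blocks;
  }
  return blocks == 1;
}

// [[Rcpp::export]]
int cpp_interface_count(IntegerMatrix spin) {
  static const int mx[8] = {1, 1, 0, -1, -1, -1, 0, 1};
  static const int my[8] = {0, 1, 1, 1, 0, -1, -1, -1};
  int nx = spin.ncol(), ny = spin.nrow(), count = 0;
  for (int ix = 0; ix < nx; ++ix)
    for (int iy = 0; iy < ny; ++iy) {
      int s = spin(iy, ix);
      for (int n = 0; n < 8; ++n) {
        if (spin_at(spin, ix + mx[n], iy + my[n]) != s) { ++count; break; }
      }
    }
  return count;
}

// Energy change of copying s_src into the target site (0-based coords).
// Positive eps_bond * N * w acts only on retraction (cell -> medium) and
// only for load-bearing adhesions past the nascent threshold (F > 0 and
// N > N0): an unloaded or still-nascent cluster has no tension-reinforced
// bond network and detaches without a barrier.
// [[Rcpp::export]]
double cpp_delta_h(IntegerMatrix spin, NumericVector N, NumericVector F,
                   NumericVector w, int tx, int ty, int s_src,
                   double J, double lambda_area, double A_target,
                   double lambda_C, double eps_bond, double dx,
                   double area, int N0 = 50) {
  int s_tgt = spin(ty, tx);
  if (s_src == s_tgt) stop("source and target spins must differ");
  double a = dx * dx;
  double dH = dH_interface(spin, tx, ty, s_src, J);
  double dA = (s_src == 1) ? a : -a;
  dH += lambda_area * ((area + dA - A_target) * (area + dA - A_target) -
                       (area - A_target) * (area - A_target));
  dH += -lambda_C * ((s_src == 1) ? 1.0 : -1.0);
  if (s_src == 0) { // retraction pays the adhesion detachment barrier
    int k = tx * spin.nrow() + ty;
    if (F[k] > 0.0 && N[k] > (double)N0) dH += eps_bond * N[k] * w[k];
  }
  return dH;
}

// One Monte Carlo Step. Performs as many copy attempts as there are
// interface sites at the start of the MCS, sampling source-target Moore
// pairs by rejection from the whole lattice. Accepted extensions seed a
// nascent cluster from the free-integrin pool; accepted retractions return
// the site's bonds to the pool.
// [[Rcpp::export]]
List cpp_run_mcs(IntegerMatrix spin_in, IntegerVector N_in, NumericVector F_in,
                 NumericVector w, double Tcell, double J,
                 double lambda_area, double A_target, double lambda_C,
                 double eps_bond, double dx, int N_seed, int N_free,
                 int N0, bool record_attempts) {
  static const int mx[8] = {1, 1, 0, -1, -1, -1, 0, 1};
  static const int my[8] = {0, 1, 1, 1, 0, -1, -1, -1};
  IntegerMatrix spin = clone(spin_in);
  IntegerVector N = clone(N_in);
  NumericVector F = clone(F_in);
  int nx = spin.ncol(), ny = spin.nrow();
  double a = dx * dx;
  long ncellsites = 0;
  for (int k = 0; k < nx * ny; ++k) ncellsites += spin[k];
  double area = (double)ncellsites * a;

  int attempts = (ncellsites > 0) ? cpp_interface_count(spin) : 0;
  int n_ext = 0, n_ret = 0;
  std::vector<double> rec_dH;
  std::vector<int> rec_acc;

  for (int att = 0; att < attempts; ++att) {
    // rejection-sample an interface pair
    int sx, sy, tx, ty, s_src, s_tgt;
    int guard = 0;
    do {
      sx = (int)(unif_rand() * nx); if (sx == nx) sx = nx - 1;
      sy = (int)(unif_rand() * ny); if (sy == ny) sy = ny - 1;
      int n = (int)(unif_rand() * 8); if (n == 8) n = 7;
      tx = sx + mx[n]; ty = sy + my[n];
      if (tx < 0 || ty < 0 || tx >= nx || ty >= ny) { s_src = s_tgt = -1; continue; }
      s_src = spin(sy, sx);
      s_tgt = spin(ty, tx);
      if (++guard > 2000000) stop("no interface pair found (cell lost?)");
    } while (s_src == s_tgt || s_src < 0);

    if (s_src == 0 && !ring_stays_connected(spin, tx, ty)) {
      // counted as an attempt; the energy was never evaluated
      if (record_attempts) { rec_dH.push_back(NA_REAL); rec_acc.push_back(0); }
      continue;
    }

    double dH = dH_interface(spin, tx, ty, s_src, J);
    double dA = (s_src == 1) ? a : -a;
    dH += lambda_area * ((area + dA - A_target) * (area + dA - A_target) -
                         (area - A_target) * (area - A_target));
    dH += -lambda_C * ((s_src == 1) ? 1.0 : -1.0);
    int k = tx * ny + ty;
    if (s_src == 0 && F[k] > 0.0 && N[k] > N0)
      dH += eps_bond * (double)N[k] * w[k];

    bool accept = (dH <= 0.0) || (unif_rand() < std::exp(-dH / Tcell));
    if (record_attempts) {
      rec_dH.push_back(dH);
      rec_acc.push_back(accept ? 1 : 0);
    }
    if (!accept) continue;

    spin(ty, tx) = s_src;
    area += dA;
    if (s_src == 1) { // extension: nascent adhesion from the pool
      int seed = (N_seed <= N_free) ? N_seed : N_free;
      N[k] = seed;
      N_free -= seed;
      F[k] = 0.0;
      ++n_ext;
    } else {          // retraction: adhesion destroyed, bonds returned
      N_free += N[k];
      N[k] = 0;
      F[k] = 0.0;
      ++n_ret;
    }
    if (area <= 0.0) break; // extinction; R layer aborts the run
  }

  List out = List::create(
    _["spin"] = spin, _["N"] = N, _["F"] = F, _["N_free"] = N_free,
    _["area"] = area, _["attempts"] = attempts,
    _["n_ext"] = n_ext, _["n_ret"] = n_ret);
  if (record_attempts) {
    out["attempt_dH"] = wrap(rec_dH);
    out["attempt_accept"] = wrap(rec_acc);
  }
  return out;
}
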