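#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Linear interpolation of a tabulated curve against log10(energy),
// clamped at both ends. Curves are short (~10 rows), linear scan is fine.
static double interp_curve(double e_keV,
                           const std::vector<double> &loge,
                           const std::vector<double> &val) {
  const double x = std::log10(e_keV);
  const int n = (int)loge.size();
  if (x <= loge[0]) return val[0];
  if (x >= loge[n - 1]) return val[n - 1];
  int i = 1;
  while (loge[i] < x) ++i;
  const double t = (x - loge[i - 1]) / (loge[i] - loge[i - 1]);
  return val[i - 1] + t * (val[i] - val[i - 1]);
}

struct TrackBuf {
  std::vector<double> x, y, z, dep; // nm, eV
  std::vector<int> ion;             // 1 = ionization, 0 = excitation
};

// Compound cluster process: cluster centres along a randomly scattered
// polyline with exponential spacings; within-cluster isotropic Gaussian
// displacements; exponential per-event deposits. All model curves are
// evaluated at the electron's current (residual) energy so a track
// carries its own slowing-down end. The final event absorbs the exact
// energy remainder. Consumes R's global RNG; callers seed it.
static void generate_track(double e_in_keV,
                           const std::vector<double> &loge,
                           const std::vector<double> &w_ev,
                           const std::vector<double> &sigma_nm,
                           const std::vector<double> &spacing_nm,
                           double lambda_extra, double cutoff_keV,
                           double ion_prob, TrackBuf &buf) {
  if (e_in_keV < cutoff_keV) {
    // below the tracking cut-off all energy is deposited locally
    buf.x.push_back(0.0); buf.y.push_back(0.0); buf.z.push_back(0.0);
    buf.dep.push_back(e_in_keV * 1000.0);
    buf.ion.push_back(unif_rand() < ion_prob ? 1 : 0);
    return;
  }
  double e_rem = e_in_keV * 1000.0; // eV
  double px = 0.0, py = 0.0, pz = 0.0;
  while (e_rem > 0.0) {
    const double e_cur = e_rem / 1000.0; // keV
    const double spacing = interp_curve(e_cur, loge, spacing_nm);
    const double sigma = interp_curve(e_cur, loge, sigma_nm);
    const double wbar = interp_curve(e_cur, loge, w_ev);

    // isotropic step to the next cluster centre
    const double cz = 2.0 * unif_rand() - 1.0;
    const double phi = 2.0 * M_PI * unif_rand();
    const double s = std::sqrt(std::max(0.0, 1.0 - cz * cz));
    const double len = R::rexp(spacing);
    px += len * s * std::cos(phi);
    py += len * s * std::sin(phi);
    pz += len * cz;

    const int k = 1 + (int)R::rpois(lambda_extra);
    for (int j = 0; j < k && e_rem > 0.0; ++j) {
      double d = R::rexp(wbar);
      if (d >= e_rem) d = e_rem; // last event absorbs the remainder
      buf.x.push_back(px + sigma * norm_rand());
      buf.y.push_back(py + sigma * norm_rand());
      buf.z.push_back(pz + sigma * norm_rand());
      buf.dep.push_back(d);
      buf.ion.push_back(unif_rand() < ion_prob ? 1 : 0);
      e_rem -= d;
    }
  }
}

// Cell-list (spatial hash) pair count: unordered event pairs with
// Euclidean separation <= r (inclusive). Exact.
static double count_pairs_cell(const std::vector<double> &x,
                               const std::vector<double> &y,
                               const std::vector<double> &z, double r) {
  const int n = (int)x.size();
  if (n < 2) return 0.0;
  const double r2 = r * r;
  const double inv = 1.0 / r;
  std::unordered_map<long long, std::vector<int> > cells;
  cells.reserve((size_t)n * 2);
  std::vector<long long> key(n);
  const long long M = 1 << 21, H = M / 2; // 21-bit signed packing per axis
  for (int i = 0; i < n; ++i) {
    long long ix = (long long)std::floor(x[i] * inv) + H;
    long long iy = (long long)std::floor(y[i] * inv) + H;
    long long iz = (long long)std::floor(z[i] * inv) + H;
    key[i] = (ix * M + iy) * M + iz;
  }
  double cnt = 0.0;
  for (int i = 0; i < n; ++i) {
    const long long ix = key[i] / (M * M);
    const long long iy = (key[i] / M) % M;
    const long long iz = key[i] % M;
    for (long long dx = -1; dx <= 1; ++dx)
      for (long long dy = -1; dy <= 1; ++dy)
        for (long long dz = -1; dz <= 1; ++dz) {
          const long long k = ((ix + dx) * M + (iy + dy)) * M + (iz + dz);
          std::unordered_map<long long, std::vector<int> >::const_iterator
              it = cells.find(k);
          if (it == cells.end()) continue;
          const std::vector<int> &v = it->second;
          for (size_t m = 0; m < v.size(); ++m) {
            const int j = v[m];
            const double ddx = x[i] - x[j], ddy = y[i] - y[j],
                         ddz = z[i] - z[j];
            if (ddx * ddx + ddy * ddy + ddz * ddz <= r2) cnt += 1.0;
          }
        }
    cells[key[i]].push_back(i); // insert after scan: pairs j < i only
  }
  return cnt;
}

static std::vector<double> as_std(const NumericVector &v) {
  return std::vector<double>(v.begin(), v.end());
}

// [[Rcpp::export]]
List cpp_simulate_track(double e_in_keV, NumericVector log10_e,
                        NumericVector w_ev, NumericVector sigma_nm,
                        NumericVector spacing_nm, double lambda_extra,
                        double cutoff_keV, double ion_prob) {
  TrackBuf buf;
  generate_track(e_in_keV, as_std(log10_e), as_std(w_ev), as_std(sigma_nm),
                 as_std(spacing_nm), lambda_extra, cutoff_keV, ion_prob, buf);
  return List::create(_["x_nm"] = wrap(buf.x), _["y_nm"] = wrap(buf.y),
                      _["z_nm"] = wrap(buf.z), _["deposit_eV"] = wrap(buf.dep),
                      _["ion"] = wrap(buf.ion));
}

// Fused generate-and-count path: identical RNG consumption to
// cpp_simulate_track, but only (N_event, N_link) leave C++.
// [[Rcpp::export]]
NumericVector cpp_track_counts(double e_in_keV, NumericVector log10_e,
                               NumericVector w_ev, NumericVector sigma_nm,
                               NumericVector spacing_nm, double lambda_extra,
                               double cutoff_keV, double ion_prob,
                               double r_link_nm) {
  TrackBuf buf;
  generate_track(e_in_keV, as_std(log10_e), as_std(w_ev), as_std(sigma_nm),
                 as_std(spacing_nm), lambda_extra, cutoff_keV, ion_prob, buf);
  NumericVector out(2);
  out[0] = (double)buf.x.size();
  out[1] = count_pairs_cell(buf.x, buf.y, buf.z, r_link_nm);
  return out;
}

// [[Rcpp::export]]
double cpp_count_pairs(NumericVector x, NumericVector y, NumericVector z,
                       double r) {
  return count_pairs_cell(as_std(x), as_std(y), as_std(z), r);
}

// Sum of deposits within `radius` of each centre (spherical scoring
// sites), via the same cell-list with cell edge = radius.
// [[Rcpp::export]]
NumericVector cpp_score_spheres(NumericVector x, NumericVector y,
                                NumericVector z, NumericVector dep,
                                NumericVector cx, NumericVector cy,
                                NumericVector cz, double radius) {
  const int n = x.size(), m = cx.size();
  const double r2 = radius * radius, inv = 1.0 / radius;
  const long long M = 1 << 21, H = M / 2;
  std::unordered_map<long long, std::vector<int> > cells;
  cells.reserve((size_t)n * 2);
  for (int i = 0; i < n; ++i) {
    long long ix = (long long)std::floor(x[i] * inv) + H;
    long long iy = (long long)std::floor(y[i] * inv) + H;
    long long iz = (long long)std::floor(z[i] * inv) + H;
    cells[(ix * M + iy) * M + iz].push_back(i);
  }
  NumericVector eps(m);
  for (int c = 0; c < m; ++c) {
    const long long ix = (long long)std::floor(cx[c] * inv) + H;
    const long long iy = (long long)std::floor(cy[c] * inv) + H;
    const long long iz = (long long)std::floor(cz[c] * inv) + H;
    double acc = 0.0;
    for (long long dx = -1; dx <= 1; ++dx)
      for (long long dy = -1; dy <= 1; ++dy)
        for (long long dz = -1; dz <= 1; ++dz) {
          std::unordered_map<long long, std::vector<int> >::const_iterator
              it = cells.find(((ix + dx) * M + (iy + dy)) * M + (iz + dz));
          if (it == cells.end()) continue;
          const std::vector<int> &v = it->second;
          for (size_t q = 0; q < v.size(); ++q) {
            const int j = v[q];
            const double ddx = x[j] - cx[c], ddy = y[j] - cy[c],
                         ddz = z[j] - cz[c];
            if (ddx * ddx + ddy * ddy + ddz * ddz <= r2) acc += dep[j];
          }
        }
    eps[c] = acc;
  }
  return eps;
}

// Number of events within Chebyshev (cube) half-width h of each centre;
// used to undo the importance-sampling density of site placement.
// [[Rcpp::export]]
NumericVector cpp_count_in_cube(NumericVector x, NumericVector y,
                                NumericVector z, NumericVector cx,
                                NumericVector cy, NumericVector cz,
                                double h) {
  const int n = x.size(), m = cx.size();
  const double inv = 1.0 / h;
  const long long M = 1 << 21, H = M / 2;
  std::unordered_map<long long, std::vector<int> > cells;
  cells.reserve((size_t)n * 2);
  for (int i = 0; i < n; ++i) {
    long long ix = (long long)std::floor(x[i] * inv) + H;
    long long iy = (long long)std::floor(y[i] * inv) + H;
    long long iz = (long long)std::floor(z[i] * inv) + H;
    cells[(ix * M + iy) * M + iz].push_back(i);
  }
  NumericVector cnt(m);
  for (int c = 0; c < m; ++c) {
    const long long ix = (long long)std::floor(cx[c] * inv) + H;
    const long long iy = (long long)std::floor(cy[c] * inv) + H;
    const long long iz = (long long)std::floor(cz[c] * inv) + H;
    double acc = 0.0;
    for (long long dx = -1; dx <= 1; ++dx)
      for (long long dy = -1; dy <= 1; ++dy)
        for (long long dz = -1; dz <= 1; ++dz) {
          std::unordered_map<long long, std::vector<int> >::const_iterator
              it = cells.find(((ix + dx) * M + (iy + dy)) * M + (iz + dz));
          if (it == cells.end()) continue;
          const std::vector<int> &v = it->second;
          for (size_t q = 0; q < v.size(); ++q) {
            const int j = v[q];
            if (std::fabs(x[j] - cx[c]) <= h && std::fabs(y[j] - cy[c]) <= h &&
                std::fabs(z[j] - cz[c]) <= h)
              acc += 1.0;
          }
        }
    cnt[c] = acc;
  }
  return cnt;
}
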