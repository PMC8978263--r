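// Voxel Monte Carlo photon transport with a track-length fluence estimator.
// Weighted photons, continuous absorption along sub-steps, Henyey-Greenstein
// scattering, Russian roulette, matched (absorbing) grid boundary.
// All lengths in mm; mua/mus in mm^-1; fluence normalized per launched photon
// and per voxel volume (mm^-2).
#include <Rcpp.h>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

namespace {

// xoshiro256+ with splitmix64 seeding: deterministic, independent of R's RNG.
struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9e3779b97f4a7c15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    uint64_t result = s[0] + s[3];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform in [0, 1)
  double unif() { return (next() >> 11) * 0x1.0p-53; }
  // uniform in (0, 1] (safe for log())
  double unif_pos() { return 1.0 - unif(); }
};

inline double hg_cos(double g, double u) {
  if (std::fabs(g) < 1e-8) return 2.0 * u - 1.0;
  double s = (1.0 - g * g) / (1.0 - g + 2.0 * g * u);
  double c = (1.0 + g * g - s * s) / (2.0 * g);
  if (c > 1.0) c = 1.0;
  if (c < -1.0) c = -1.0;
  return c;
}

inline void rotate_direction(double &ux, double &uy, double &uz,
                             double cost, double phi) {
  double sint = std::sqrt(std::max(0.0, 1.0 - cost * cost));
  double cosp = std::cos(phi), sinp = std::sin(phi);
  if (std::fabs(uz) > 0.999999) {
    ux = sint * cosp;
    uy = sint * sinp;
    uz = cost * (uz >= 0 ? 1.0 : -1.0);
  } else {
    double tmp = std::sqrt(1.0 - uz * uz);
    double nx = sint * (ux * uz * cosp - uy * sinp) / tmp + ux * cost;
    double ny = sint * (uy * uz * cosp + ux * sinp) / tmp + uy * cost;
    double nz = -sint * cosp * tmp + uz * cost;
    ux = nx; uy = ny; uz = nz;
  }
  double nrm = std::sqrt(ux * ux + uy * uy + uz * uz);
  ux /= nrm; uy /= nrm; uz /= nrm;
}

} // namespace

//' @noRd
// [[Rcpp::export(name = ".mc_fluence")]]
List mc_fluence(NumericVector mua, NumericVector mus, NumericVector g,
                IntegerVector dims, double spacing, NumericVector origin,
                NumericMatrix launch_pos, NumericMatrix launch_dir,
                double seed, bool roulette,
                double roulette_threshold = 1e-4,
                double roulette_survive = 0.1) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  if (mua.size() != nvox || mus.size() != nvox || g.size() != nvox)
    stop("property grids do not match the grid dimensions");
  const int nph = launch_pos.nrow();
  if (nph < 1) stop("n_photons must be >= 1");

  NumericVector phi(nvox);
  double absorbed = 0.0, escaped = 0.0, killed = 0.0, boosted = 0.0;
  const double vvox = spacing * spacing * spacing;
  const double ox = origin[0], oy = origin[1], oz = origin[2];
  const double xmax = ox + nx * spacing, ymax = oy + ny * spacing,
               zmax = oz + nz * spacing;
  const double eps = spacing * 1e-9;
  Xoshiro rng((uint64_t)seed);

  for (int p = 0; p < nph; ++p) {
    double px = launch_pos(p, 0), py = launch_pos(p, 1), pz = launch_pos(p, 2);
    double ux = launch_dir(p, 0), uy = launch_dir(p, 1), uz = launch_dir(p, 2);
    double nrm = std::sqrt(ux * ux + uy * uy + uz * uz);
    ux /= nrm; uy /= nrm; uz /= nrm;
    double w = 1.0;
    double tau = -std::log(rng.unif_pos()); // dimensionless scattering length

    for (;;) {
      // locate voxel; photons outside the grid are terminated (matched boundary)
      if (px < ox || px >= xmax || py < oy || py >= ymax ||
          pz < oz || pz >= zmax) {
        escaped += w;
        break;
      }
      int ix = (int)std::floor((px - ox) / spacing);
      int iy = (int)std::floor((py - oy) / spacing);
      int iz = (int)std::floor((pz - oz) / spacing);
      if (ix < 0) ix = 0; if (ix >= nx) ix = nx - 1;
      if (iy < 0) iy = 0; if (iy >= ny) iy = ny - 1;
      if (iz < 0) iz = 0; if (iz >= nz) iz = nz - 1;
      R_xlen_t idx = (R_xlen_t)ix + (R_xlen_t)nx * (iy + (R_xlen_t)ny * iz);
      double ma = mua[idx], ms = mus[idx];

      // distance to scattering event and to the voxel boundary
      double dscat = (ms > 0.0) ? tau / ms : R_PosInf;
      double db = R_PosInf, d;
      if (ux > 0) { d = (ox + (ix + 1) * spacing - px) / ux; if (d < db) db = d; }
      else if (ux < 0) { d = (ox + ix * spacing - px) / ux; if (d < db) db = d; }
      if (uy > 0) { d = (oy + (iy + 1) * spacing - py) / uy; if (d < db) db = d; }
      else if (uy < 0) { d = (oy + iy * spacing - py) / uy; if (d < db) db = d; }
      if (uz > 0) { d = (oz + (iz + 1) * spacing - pz) / uz; if (d < db) db = d; }
      else if (uz < 0) { d = (oz + iz * spacing - pz) / uz; if (d < db) db = d; }
      if (db < 0) db = 0;
      bool scatter = dscat <= db;
      double ell = scatter ? dscat : db;

      // track-length deposit with continuous absorption:
      //   integral of w(l) dl over the sub-step; exact decrement of w
      if (ma > 0.0) {
        double att = std::exp(-ma * ell);
        phi[idx] += w * (1.0 - att) / ma;
        absorbed += w * (1.0 - att);
        w *= att;
      } else {
        phi[idx] += w * ell;
      }
      tau -= ell * ms;

      px += ux * ell; py += uy * ell; pz += uz * ell;
      if (scatter) {
        double cost = hg_cos(g[idx], rng.unif());
        double phi_ang = 2.0 * M_PI * rng.unif();
        rotate_direction(ux, uy, uz, cost, phi_ang);
        tau = -std::log(rng.unif_pos());
      } else {
        // nudge across the voxel face
        px += ux * eps; py += uy * eps; pz += uz * eps;
      }

      if (roulette && w < roulette_threshold) {
        if (rng.unif() < roulette_survive) {
          boosted += w * (1.0 / roulette_survive - 1.0);
          w /= roulette_survive;
        } else {
          killed += w;
          break;
        }
      }
    }
  }

  double norm = vvox * (double)nph;
  for (R_xlen_t i = 0; i < nvox; ++i) phi[i] /= norm;
  return List::create(_["phi"] = phi,
                      _["absorbed"] = absorbed / nph,
                      _["escaped"] = escaped / nph,
                      _["roulette_killed"] = killed / nph,
                      _["roulette_boosted"] = boosted / nph);
}

//' @noRd
// [[Rcpp::export(name = ".hg_sample_cpp")]]
NumericVector hg_sample_cpp(int n, double g, double seed) {
  if (std::fabs(g) >= 1.0) stop("anisotropy g must lie in (-1, 1)");
  Xoshiro rng((uint64_t)seed);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = hg_cos(g, rng.unif());
  return out;
}
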