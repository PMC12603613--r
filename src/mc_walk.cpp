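#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

// xoshiro256+ generator, seeded from R's RNG stream so that set.seed()
// controls reproducibility without paying the R API cost per deviate
struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    // splitmix64 expansion
    for (int i = 0; i < 4; ++i) {
      seed += 0x9e3779b97f4a7c15ULL;
      uint64_t z = seed;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    uint64_t r = s[0] + s[3];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3]; s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return r;
  }
  double runif() {  // uniform in (0,1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
};

// unpolarized Fresnel reflectance, tissue (index n) -> exterior (index 1)
static double fresnel_refl(double ci, double n) {
  double st2 = n * n * (1.0 - ci * ci);  // sin^2 of transmitted angle
  if (st2 >= 1.0) return 1.0;            // total internal reflection
  double ct = std::sqrt(1.0 - st2);
  double rs = (n * ci - ct) / (n * ci + ct);
  double rp = (n * ct - ci) / (n * ct + ci);
  return 0.5 * (rs * rs + rp * rp);
}

// Random walk of photons in a laterally infinite layered slab with isotropic
// scattering (mu_s = mu_s'), no absorption during the walk (white Monte
// Carlo; absorption applied afterwards by pathlength rescaling). Fresnel
// reflection at the top surface is sampled probabilistically, so recorded
// weights are all 1. Photons crossing z_cutoff are terminated.
//
// thickness: per-layer thickness, mm (last entry ignored, treated as
// extending to z_cutoff); mus: per-layer scattering coefficient, mm^-1.
// Uses R's RNG: seed with set.seed() before calling.
// [[Rcpp::export]]
List mc_walk_slab(NumericVector thickness, NumericVector mus, double n_rel,
                  int n_photons, double z_cutoff) {
  const int L = mus.size();
  std::vector<double> zb(L + 1);
  zb[0] = 0.0;
  for (int i = 0; i < L; ++i) {
    double t = thickness[i];
    if (i == L - 1 || !R_finite(t) || zb[i] + t > z_cutoff)
      t = z_cutoff - zb[i];
    zb[i + 1] = zb[i] + t;
  }
  zb[L] = z_cutoff;

  std::vector<double> out_r, out_L;
  out_r.reserve(n_photons);
  out_L.reserve((size_t)n_photons * L);
  long n_deep = 0;
  std::vector<double> lp(L);

  uint64_t sd = (uint64_t)(unif_rand() * 4294967296.0) << 32 |
                (uint64_t)(unif_rand() * 4294967296.0);
  Xoshiro rng(sd);

  for (int p = 0; p < n_photons; ++p) {
    double x = 0, y = 0, z = 0, ux = 0, uy = 0, uz = 1;
    int li = 0;
    std::fill(lp.begin(), lp.end(), 0.0);
    bool alive = true, escaped = false;
    while (alive) {
      double tau = -std::log(rng.runif());
      while (tau > 0.0 && alive) {
        double mu = mus[li];
        double step = tau / mu;
        // distance to the layer boundary along uz
        double db = R_PosInf;
        int next = li;
        if (uz > 0) { db = (zb[li + 1] - z) / uz; next = li + 1; }
        else if (uz < 0) { db = (zb[li] - z) / uz; next = li - 1; }
        if (step < db) {
          x += step * ux; y += step * uy; z += step * uz;
          lp[li] += step;
          tau = 0.0;
        } else {
          x += db * ux; y += db * uy;
          lp[li] += db;
          tau -= db * mu;
          if (next > li) {               // moving down
            if (next >= L) { alive = false; ++n_deep; }
            else { li = next; z = zb[li]; }
          } else {                       // moving up
            if (next < 0) {              // at the top surface
              double ci = -uz;
              if (rng.runif() < fresnel_refl(ci, n_rel)) {
                uz = -uz; z = 0.0;       // internally reflected
              } else {
                alive = false; escaped = true;
              }
            } else { li = next; z = zb[li + 1]; }  // enter layer above at its bottom
          }
        }
      }
      if (!alive) break;
      // isotropic scattering; Marsaglia polar sampling avoids trig calls
      double u, v, ss;
      do {
        u = 2.0 * rng.runif() - 1.0;
        v = 2.0 * rng.runif() - 1.0;
        ss = u * u + v * v;
      } while (ss >= 1.0 || ss == 0.0);
      uz = 2.0 * rng.runif() - 1.0;
      double sz = std::sqrt(std::max(0.0, 1.0 - uz * uz)) / ss;
      ux = sz * (u * u - v * v);
      uy = sz * 2.0 * u * v;
    }
    if (escaped) {
      out_r.push_back(std::sqrt(x * x + y * y));
      for (int i = 0; i < L; ++i) out_L.push_back(lp[i]);
    }
  }

  const int nd = (int)out_r.size();
  NumericMatrix rec(nd, L + 1);
  for (int j = 0; j < nd; ++j) {
    rec(j, 0) = out_r[j];
    for (int i = 0; i < L; ++i) rec(j, i + 1) = out_L[(size_t)j * L + i];
  }
  return List::create(_["records"] = rec,
                      _["launched"] = n_photons,
                      _["n_deep"] = (double)n_deep);
}
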