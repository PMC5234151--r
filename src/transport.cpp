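// Weighted Monte Carlo photon transport through a plane-parallel layer stack.
//
// Scheme: flight lengths are sampled from the scattering coefficient alone and
// packet weight is attenuated continuously by exp(-mua * s) along each segment
// (the attenuated fraction is tallied as absorbed).  This makes the unscattered
// (ballistic) transmission of an absorbing slab exactly Beer-Lambert per packet
// and keeps the energy balance exact when Russian roulette is disabled.
// Scattering is isotropic (g = 0).  Interfaces use the unpolarized Fresnel
// average with Snell refraction; total internal reflection reflects fully.
//
// Determinism: every photon owns an RNG stream seeded from (master seed,
// photon index) via splitmix64 -> xoshiro256++, so tallies are bit-identical
// for a given seed regardless of how launches are batched.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

namespace {

constexpr double kEps = 1e-9;        // boundary nudge, mm
constexpr double kKillRadius2 = 100.0 * 100.0;  // lateral kill radius^2, mm^2
constexpr double kRouletteW = 1e-4;  // roulette trigger weight
constexpr double kRouletteP = 0.1;   // survival probability
constexpr long kMaxSteps = 2000000L; // hard per-photon step cap

struct Rng {
  uint64_t s[4];

  void seed(uint64_t x) {
    for (int i = 0; i < 4; ++i) {
      x += 0x9E3779B97F4A7C15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    const uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return r;
  }
  // uniform in the open interval (0, 1)
  inline double unif() {
    return (static_cast<double>(next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
};

inline uint64_t photon_stream(uint64_t master, uint64_t index) {
  return master ^ (0x9E3779B97F4A7C15ULL * (index + 1ULL));
}

// unpolarized Fresnel reflectance; returns 1 under total internal reflection
inline double fresnel(double n1, double n2, double ci, double& ct_out) {
  ci = std::min(1.0, std::max(0.0, ci));
  if (n1 == n2) { ct_out = ci; return 0.0; }
  const double si2 = 1.0 - ci * ci;
  const double st2 = (n1 / n2) * (n1 / n2) * si2;
  if (st2 >= 1.0) { ct_out = 0.0; return 1.0; }
  const double ct = std::sqrt(1.0 - st2);
  ct_out = ct;
  const double rs = (n1 * ci - n2 * ct) / (n1 * ci + n2 * ct);
  const double rp = (n1 * ct - n2 * ci) / (n1 * ct + n2 * ci);
  return 0.5 * (rs * rs + rp * rp);
}

struct Source {
  double radius;   // core radius, mm
  double na;       // numerical aperture
  double tilt;     // radians from the surface plane
  double ax, az;   // axis direction (in the x-z plane, az > 0 into tissue)
};

struct Detector {
  double radius2;     // collection-zone radius^2, mm^2
  double na;
  double cx;          // zone centre x (= separation), mm
  double ax, az;      // acceptance axis (upward: az < 0)
  double cos_half;    // cos of acceptance half-angle asin(na)
  bool accept_all;    // na >= 1: footprint-only test
};

struct Stack {
  int nl;
  const double* mua;  // mm^-1
  const double* mus;  // mm^-1
  const double* n;
  const double* z0;   // top of layer, mm
  const double* z1;   // bottom of layer, mm
  double n_above, n_below;
};

struct Tally {
  double specular = 0, diffuse = 0, detected = 0, transmitted = 0, absorbed = 0;
  long n_roulette_killed = 0, n_truncated = 0;
};

// Launch one photon: position on the elliptical footprint of the fibre core
// projected along the tilted axis onto the surface, direction uniform in solid
// angle within the NA cone about the axis, then Fresnel/Snell entry into
// layer 0.  Returns false if the packet is entirely specularly reflected.
inline bool launch_one(const Source& src, double n_above, double n0, Rng& rng,
                       double& x, double& y, double& z,
                       double& ux, double& uy, double& uz,
                       double& w, double& specular) {
  // orthonormal basis about the axis (axis lies in the x-z plane)
  const double e1x = src.az, e1z = -src.ax;  // in-plane perpendicular
  // e2 = (0, 1, 0)

  // point on the fibre face (disk perpendicular to the axis through origin)
  const double rr = src.radius * std::sqrt(rng.unif());
  const double ph = 2.0 * M_PI * rng.unif();
  const double a = rr * std::cos(ph), b = rr * std::sin(ph);
  double px = a * e1x, py = b, pz = a * e1z;
  // project along the axis onto the surface z = 0
  const double tproj = -pz / src.az;
  x = px + tproj * src.ax;
  y = py;
  z = 0.0;

  // direction within the cone
  const double half = std::asin(std::min(1.0, src.na));
  const double cmin = std::cos(half);
  const double cpsi = cmin + (1.0 - cmin) * rng.unif();
  const double spsi = std::sqrt(std::max(0.0, 1.0 - cpsi * cpsi));
  const double phi = 2.0 * M_PI * rng.unif();
  const double c1 = spsi * std::cos(phi), c2 = spsi * std::sin(phi);
  ux = src.ax * cpsi + e1x * c1;
  uy = c2;
  uz = src.az * cpsi + e1z * c1;

  // entry refraction at the air / layer-0 interface (normal = z)
  double ct;
  const double R = fresnel(n_above, n0, uz, ct);
  specular += w * R;
  w *= (1.0 - R);
  if (w <= 0.0 || R >= 1.0) return false;
  const double scale = n_above / n0;
  ux *= scale; uy *= scale;
  uz = ct;
  z = kEps;
  return true;
}

}  // namespace

// [[Rcpp::export]]
List cpp_run_simulation(NumericVector mua, NumericVector mus, NumericVector nidx,
                        NumericVector thickness,
                        double n_above, double n_below,
                        double src_radius, double src_na, double src_tilt_deg,
                        double det_radius, double det_na, double det_tilt_deg,
                        double separation,
                        double n_photons, double seed,
                        bool roulette, bool detect_all, int keep_exits) {
  const int nl = mua.size();
  if (nl < 1) stop("stack must have at least one layer");
  std::vector<double> z0(nl), z1(nl);
  double zc = 0.0;
  for (int i = 0; i < nl; ++i) {
    if (thickness[i] <= 0) stop("layer thickness must be positive");
    z0[i] = zc; zc += thickness[i]; z1[i] = zc;
  }
  Stack st{nl, mua.begin(), mus.begin(), nidx.begin(), z0.data(), z1.data(),
           n_above, n_below};

  Source src;
  src.radius = src_radius;
  src.na = src_na;
  src.tilt = src_tilt_deg * M_PI / 180.0;
  src.ax = std::cos(src.tilt);
  src.az = std::sin(src.tilt);
  if (src.az <= 0) stop("source tilt must point into the tissue (0 < tilt <= 90)");

  Detector det;
  det.radius2 = det_radius * det_radius;
  det.na = det_na;
  det.cx = separation;
  const double dt = std::fabs(det_tilt_deg) * M_PI / 180.0;
  det.ax = std::cos(dt);
  det.az = -std::sin(dt);
  det.accept_all = (det_na >= 1.0) || detect_all;
  det.cos_half = std::cos(std::asin(std::min(1.0, det_na)));

  const long np = static_cast<long>(n_photons);
  const uint64_t master = static_cast<uint64_t>(seed);

  Tally tl;
  const int ne_max = keep_exits > 0 ? keep_exits : 0;
  NumericMatrix exits(ne_max, 6);
  int ne = 0;

  Rng rng;
  for (long ip = 0; ip < np; ++ip) {
    rng.seed(photon_stream(master, static_cast<uint64_t>(ip)));
    double x, y, z, ux, uy, uz, w = 1.0;
    if (!launch_one(src, n_above, st.n[0], rng, x, y, z, ux, uy, uz, w,
                    tl.specular))
      continue;
    int L = 0;
    bool alive = true;
    long steps = 0;
    while (alive) {
      if (++steps > kMaxSteps) { tl.absorbed += w; tl.n_truncated++; break; }
      const double musL = st.mus[L];
      const double s = musL > 0 ? -std::log(rng.unif()) / musL
                                : std::numeric_limits<double>::infinity();
      double db;
      bool down;
      if (uz > 0)      { db = (st.z1[L] - z) / uz;  down = true; }
      else if (uz < 0) { db = (st.z0[L] - z) / uz;  down = false; }
      else             { db = std::numeric_limits<double>::infinity(); down = false; }
      if (db < 0) db = 0;

      const double t = std::min(s, db);
      if (std::isfinite(t)) {
        const double att = std::exp(-st.mua[L] * t);
        tl.absorbed += w * (1.0 - att);
        w *= att;
        x += ux * t; y += uy * t; z += uz * t;
      } else {
        // non-scattering, non-bounded flight cannot happen in a finite stack
        stop("photon escaped to infinity inside the stack");
      }

      if (s < db) {
        // scatter isotropically
        const double cz = 2.0 * rng.unif() - 1.0;
        const double sz = std::sqrt(std::max(0.0, 1.0 - cz * cz));
        const double phi = 2.0 * M_PI * rng.unif();
        ux = sz * std::cos(phi); uy = sz * std::sin(phi); uz = cz;
        if (x * x + y * y > kKillRadius2) { tl.absorbed += w; break; }
        if (roulette && w < kRouletteW) {
          if (rng.unif() < kRouletteP) w /= kRouletteP;
          else { tl.n_roulette_killed++; break; }
        }
      } else {
        // boundary interaction
        const double ci = std::fabs(uz);
        const double n1 = st.n[L];
        double n2;
        if (down) n2 = (L == nl - 1) ? st.n_below : st.n[L + 1];
        else      n2 = (L == 0)      ? st.n_above : st.n[L - 1];
        double ct;
        const double R = fresnel(n1, n2, ci, ct);
        if (rng.unif() < R) {
          uz = -uz;
          z = down ? st.z1[L] - kEps : st.z0[L] + kEps;
        } else {
          const double scale = n1 / n2;
          ux *= scale; uy *= scale;
          uz = down ? ct : -ct;
          if (down) {
            if (L == nl - 1) { tl.transmitted += w; break; }
            ++L; z = st.z0[L] + kEps;
          } else {
            if (L == 0) {
              tl.diffuse += w;
              bool ok = (x - det.cx) * (x - det.cx) + y * y <= det.radius2;
              if (ok && !det.accept_all) {
                const double cang = ux * det.ax + uz * det.az;
                ok = cang >= det.cos_half;
              }
              if (detect_all) ok = true;
              if (ok) tl.detected += w;
              if (ne < ne_max) {
                exits(ne, 0) = x; exits(ne, 1) = y;
                exits(ne, 2) = ux; exits(ne, 3) = uy; exits(ne, 4) = uz;
                exits(ne, 5) = w;
                ++ne;
              }
              break;
            }
            --L; z = st.z1[L] - kEps;
          }
        }
      }
      if (!std::isfinite(x + y + z + ux + uy + uz + w))
        stop("non-finite photon state (layer %d, step %ld)", L, steps);
    }
  }

  List out = List::create(
      _["n_launched"] = static_cast<double>(np),
      _["w_specular"] = tl.specular,
      _["w_diffuse_reflected"] = tl.diffuse,
      _["w_detected"] = tl.detected,
      _["w_transmitted"] = tl.transmitted,
      _["w_absorbed"] = tl.absorbed,
      _["n_roulette_killed"] = static_cast<double>(tl.n_roulette_killed),
      _["n_truncated"] = static_cast<double>(tl.n_truncated));
  if (ne_max > 0) {
    out["exits"] = ne > 0 ? NumericMatrix(exits(Range(0, ne - 1), _))
                          : NumericMatrix(0, 6);
    out["n_exits_kept"] = ne;
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_launch(int n, double src_radius, double src_na,
                         double src_tilt_deg, double n_above, double n0,
                         double seed) {
  Source src;
  src.radius = src_radius;
  src.na = src_na;
  src.tilt = src_tilt_deg * M_PI / 180.0;
  src.ax = std::cos(src.tilt);
  src.az = std::sin(src.tilt);
  if (src.az <= 0) stop("source tilt must point into the tissue (0 < tilt <= 90)");
  NumericMatrix out(n, 8);  // x y z ux uy uz weight specular
  Rng rng;
  const uint64_t master = static_cast<uint64_t>(seed);
  for (int i = 0; i < n; ++i) {
    rng.seed(photon_stream(master, static_cast<uint64_t>(i)));
    double x, y, z, ux, uy, uz, w = 1.0, spec = 0.0;
    const bool entered =
        launch_one(src, n_above, n0, rng, x, y, z, ux, uy, uz, w, spec);
    out(i, 0) = x; out(i, 1) = y; out(i, 2) = z;
    out(i, 3) = ux; out(i, 4) = uy; out(i, 5) = uz;
    out(i, 6) = entered ? w : 0.0;
    out(i, 7) = spec;
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_sample_directions(int n, double seed) {
  NumericMatrix out(n, 3);
  Rng rng;
  rng.seed(static_cast<uint64_t>(seed));
  for (int i = 0; i < n; ++i) {
    const double cz = 2.0 * rng.unif() - 1.0;
    const double sz = std::sqrt(std::max(0.0, 1.0 - cz * cz));
    const double phi = 2.0 * M_PI * rng.unif();
    out(i, 0) = sz * std::cos(phi);
    out(i, 1) = sz * std::sin(phi);
    out(i, 2) = cz;
  }
  return out;
}
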