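// Monte Carlo photon transport in layered turbid media probed by tilted,
// beveled fibers. White-MC scheme: no absorption during transport; per-layer
// partial path lengths of collected photons are stored so Beer-Lambert
// weights can be applied afterwards. An analog-absorption mode (absorption
// events sampled during transport) is kept as an independent cross-check.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

// xoshiro256++ with splitmix64 seeding; explicit, R-independent stream so
// runs are bit-reproducible and per-illumination-fiber substreams are cheap.
struct Xoshiro {
  uint64_t s[4];
  static uint64_t splitmix(uint64_t &x) {
    x += 0x9E3779B97F4A7C15ULL;
    uint64_t z = x;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  void seed(uint64_t v) {
    uint64_t x = v;
    for (int i = 0; i < 4; i++) s[i] = splitmix(x);
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
  inline double unif() { return (next() >> 11) * 0x1.0p-53; }
};

// Modified Henyey-Greenstein deviate: HG component with probability beta,
// else the cos^2 (Rayleigh-like) component with inverse CDF mu = cbrt(2u-1).
inline double sample_mhg_mu(Xoshiro &rng, double g, double beta) {
  if (rng.unif() < beta) {
    if (std::fabs(g) < 1e-9) return 2.0 * rng.unif() - 1.0;
    double f = (1.0 - g * g) / (1.0 - g + 2.0 * g * rng.unif());
    double mu = (1.0 + g * g - f * f) / (2.0 * g);
    if (mu < -1.0) mu = -1.0;
    if (mu > 1.0) mu = 1.0;
    return mu;
  }
  return std::cbrt(2.0 * rng.unif() - 1.0);
}

// Fiber face on the probe plane: ellipse (semi-minor a across the tilt
// azimuth, semi-major b = a/cos(tilt) along it) plus the effective photon
// axis (tilt + bevel refraction) and the in-medium acceptance cone cosine.
struct Face {
  double cx, cy, tx, ty, sinb, cosb, a, b, ccone, nf;
  double ax, ay, az;          // effective axis, pointing into the medium
  double e1x, e1y, e1z, e2x, e2y, e2z; // orthonormal frame around the axis
};

Face make_face(const NumericMatrix &M, int i) {
  Face f;
  f.cx = M(i, 0); f.cy = M(i, 1); f.tx = M(i, 2); f.ty = M(i, 3);
  f.sinb = M(i, 4); f.cosb = M(i, 5);
  f.a = M(i, 6); f.b = M(i, 7); f.ccone = M(i, 8); f.nf = M(i, 9);
  f.ax = f.sinb * f.tx; f.ay = f.sinb * f.ty; f.az = f.cosb;
  if (f.sinb < 1e-12) {
    f.e1x = 1; f.e1y = 0; f.e1z = 0;
    f.e2x = 0; f.e2y = 1; f.e2z = 0;
  } else {
    double nrm = std::sqrt(f.ax * f.ax + f.ay * f.ay);
    f.e1x = f.ay / nrm; f.e1y = -f.ax / nrm; f.e1z = 0.0;
    f.e2x = f.ay * f.e1z - f.az * f.e1y;
    f.e2y = f.az * f.e1x - f.ax * f.e1z;
    f.e2z = f.ax * f.e1y - f.ay * f.e1x;
  }
  return f;
}

inline bool in_face(const Face &f, double x, double y) {
  double dx = x - f.cx, dy = y - f.cy;
  if (dx * dx + dy * dy > f.b * f.b * (1.0 + 1e-12)) return false;
  double al = dx * f.tx + dy * f.ty;
  double ap = -dx * f.ty + dy * f.tx;
  double q = (al * al) / (f.b * f.b) + (ap * ap) / (f.a * f.a);
  return q <= 1.0 + 1e-12;
}

// Uniform azimuth as (cos, sin) via rejection on the unit disc (no trig).
inline void rand_azimuth(Xoshiro &rng, double &cp, double &sp) {
  double a, b, r2;
  do {
    a = 2.0 * rng.unif() - 1.0;
    b = 2.0 * rng.unif() - 1.0;
    r2 = a * a + b * b;
  } while (r2 >= 1.0 || r2 < 1e-300);
  double inv = 1.0 / std::sqrt(r2);
  cp = a * inv; sp = b * inv;
}

// Scatter the direction by cos(theta)=ct about itself, azimuth (cp, sp).
inline void spin(double &ux, double &uy, double &uz, double ct, double cp,
                 double sp) {
  double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
  if (std::fabs(uz) > 0.99999) {
    ux = st * cp; uy = st * sp; uz = ct * (uz >= 0 ? 1.0 : -1.0);
  } else {
    double d = std::sqrt(1.0 - uz * uz);
    double nx = st * (ux * uz * cp - uy * sp) / d + ux * ct;
    double ny = st * (uy * uz * cp + ux * sp) / d + uy * ct;
    double nz = -st * cp * d + uz * ct;
    ux = nx; uy = ny; uz = nz;
  }
  double inv = 1.0 / std::sqrt(ux * ux + uy * uy + uz * uz);
  ux *= inv; uy *= inv; uz *= inv;
}

// Unpolarized Fresnel reflectance; returns 1 for total internal reflection.
// On transmission fills the refracted cos(theta_t).
inline double fresnel(double n1, double n2, double ci, double &ct) {
  if (n1 == n2) { ct = ci; return 0.0; }
  double r = n1 / n2;
  double s2 = r * r * (1.0 - ci * ci);
  if (s2 >= 1.0) return 1.0;
  ct = std::sqrt(1.0 - s2);
  double rs = (n1 * ci - n2 * ct) / (n1 * ci + n2 * ct);
  double rp = (n1 * ct - n2 * ci) / (n1 * ct + n2 * ci);
  return 0.5 * (rs * rs + rp * rp);
}

} // namespace

// Sample n scattering-angle cosines from the modified HG mixture.
// [[Rcpp::export]]
NumericVector cpp_sample_mhg(int n, double g, double beta, double seed) {
  Xoshiro rng;
  rng.seed(static_cast<uint64_t>(seed));
  NumericVector out(n);
  for (int i = 0; i < n; i++) out[i] = sample_mhg_mu(rng, g, beta);
  return out;
}

// Layered-medium photon transport for one probe.
//
// med: list(d_oil, n_oil, z_top, d_deep, n_above, n_below,
//           mus = c(top, deep), g = c(top, deep), beta = c(top, deep),
//           n = c(top, deep), mua = c(top, deep))
// ill, det: one row per fiber with columns
//   cx, cy, tx, ty, sin_beff, cos_beff, a, b, cos_cone, n_fiber
// Directions use z pointing down into the medium; the surface is z = 0.
// [[Rcpp::export]]
List cpp_run_forward(List med, NumericMatrix ill, NumericMatrix det,
                     int n_photons, double seed, double max_path,
                     double max_lateral, bool analog, bool store_records) {
  const double d_oil = as<double>(med["d_oil"]);
  const double n_oil = as<double>(med["n_oil"]);
  const double z_top = as<double>(med["z_top"]);
  double d_deep = as<double>(med["d_deep"]);
  const double n_above = as<double>(med["n_above"]);
  const double n_below = as<double>(med["n_below"]);
  NumericVector mus2 = med["mus"], g2 = med["g"], be2 = med["beta"],
                nn2 = med["n"], mua2 = med["mua"];
  if (!R_FINITE(d_deep)) d_deep = 1e12;

  // region 0 = oil (non-scattering), 1 = top, 2 = deep
  double zb[4] = {0.0, d_oil, d_oil + z_top, d_oil + z_top + d_deep};
  double mus[3] = {0.0, mus2[0], mus2[1]};
  double mua[3] = {0.0, analog ? mua2[0] : 0.0, analog ? mua2[1] : 0.0};
  double mut[3] = {0.0, mus[1] + mua[1], mus[2] + mua[2]};
  double gg[3] = {0.0, g2[0], g2[1]};
  double bb[3] = {1.0, be2[0], be2[1]};
  double nr[3] = {n_oil, nn2[0], nn2[1]};

  const int n_ill = ill.nrow(), n_det = det.nrow();
  std::vector<Face> illf, detf;
  for (int i = 0; i < n_ill; i++) illf.push_back(make_face(ill, i));
  for (int i = 0; i < n_det; i++) detf.push_back(make_face(det, i));
  double face_r2 = 0.0; // quick-reject radius for surface face lookup
  for (int i = 0; i < n_ill; i++) {
    double r = std::hypot(illf[i].cx, illf[i].cy) + illf[i].b;
    face_r2 = std::max(face_r2, r * r);
  }
  for (int i = 0; i < n_det; i++) {
    double r = std::hypot(detf[i].cx, detf[i].cy) + detf[i].b;
    face_r2 = std::max(face_r2, r * r);
  }

  // Cell grid over the probe face so each surface hit tests at most a few
  // candidate fiber faces instead of all of them. Encoding: det j -> j + 1,
  // ill j -> -(j + 1).
  const int NG = 64;
  const double gext = std::sqrt(face_r2) + 1e-6;
  const double cell = 2.0 * gext / NG;
  std::vector<std::vector<int>> fgrid(NG * NG);
  {
    auto add_face = [&](const Face &f, int code) {
      int i0 = std::max(0, (int)((f.cx - f.b + gext) / cell));
      int i1 = std::min(NG - 1, (int)((f.cx + f.b + gext) / cell));
      int j0 = std::max(0, (int)((f.cy - f.b + gext) / cell));
      int j1 = std::min(NG - 1, (int)((f.cy + f.b + gext) / cell));
      for (int jj = j0; jj <= j1; jj++)
        for (int ii = i0; ii <= i1; ii++)
          fgrid[jj * NG + ii].push_back(code);
    };
    for (int j = 0; j < n_det; j++) add_face(detf[j], j + 1);
    for (int j = 0; j < n_ill; j++) add_face(illf[j], -(j + 1));
  }
  // find the face under (x, y): hit_det / hit_ill set to the face index or -1
  auto face_at = [&](double x, double y, int &hit_det, int &hit_ill) {
    hit_det = -1; hit_ill = -1;
    int ii = (int)((x + gext) / cell), jj = (int)((y + gext) / cell);
    if (ii < 0 || ii >= NG || jj < 0 || jj >= NG) return;
    for (int code : fgrid[jj * NG + ii]) {
      if (code > 0) {
        if (in_face(detf[code - 1], x, y)) { hit_det = code - 1; return; }
      } else {
        if (in_face(illf[-code - 1], x, y)) { hit_ill = -code - 1; return; }
      }
    }
  };

  const double maxlat2 = max_lateral * max_lateral;
  const double TWOPI = 6.283185307179586;

  std::vector<int> rec_ill, rec_det;
  std::vector<double> rl_top, rl_deep, rex, rey, rux, ruy, ruz, rmaxd;

  double top_exit = 0.0, bottom_exit = 0.0, truncated = 0.0, absorbed = 0.0;
  double n_surface = 0.0, n_events = 0.0;
  const int surf_reg = (d_oil > 0.0) ? 0 : 1;
  const double tir_air = 1.0 - (n_above / nr[surf_reg]) * (n_above / nr[surf_reg]);

  Xoshiro rng;
  for (int k = 0; k < n_ill; k++) {
    rng.seed(static_cast<uint64_t>(seed) ^
             (0x9E3779B97F4A7C15ULL * static_cast<uint64_t>(k + 1)));
    const Face &src = illf[k];

    for (int ip = 0; ip < n_photons; ip++) {
      // launch: uniform over the beveled elliptical footprint, direction in
      // the in-medium acceptance cone around the effective (tilt+bevel) axis
      double r = std::sqrt(rng.unif());
      double th = TWOPI * rng.unif();
      double al = src.b * r * std::cos(th), ap = src.a * r * std::sin(th);
      double x = src.cx + al * src.tx - ap * src.ty;
      double y = src.cy + al * src.ty + ap * src.tx;
      double z = 0.0;
      double ux = 0, uy = 0, uz = 0;
      for (int tries = 0; tries < 100; tries++) {
        double cd = 1.0 - rng.unif() * (1.0 - src.ccone);
        double sd = std::sqrt(std::max(0.0, 1.0 - cd * cd));
        double psi = TWOPI * rng.unif();
        double c1 = sd * std::cos(psi), c2 = sd * std::sin(psi);
        ux = cd * src.ax + c1 * src.e1x + c2 * src.e2x;
        uy = cd * src.ay + c1 * src.e1y + c2 * src.e2y;
        uz = cd * src.az + c1 * src.e1z + c2 * src.e2z;
        if (uz > 1e-9) break; // grazing launches re-drawn
      }
      if (uz <= 1e-9) { ux = src.ax; uy = src.ay; uz = src.az; }

      int reg = (d_oil > 0.0) ? 0 : 1;
      double l_top = 0.0, l_deep = 0.0, path = 0.0, maxd = 0.0;
      double xi = -std::log(1.0 - rng.unif());
      bool alive = true;

      while (alive) {
        if (path > max_path || x * x + y * y > maxlat2) {
          truncated += 1.0;
          break;
        }
        // distance to the next z-boundary of the current region
        int bnd;
        double db;
        if (uz > 0.0) { bnd = reg + 1; db = (zb[bnd] - z) / uz; }
        else if (uz < 0.0) { bnd = reg; db = (zb[bnd] - z) / uz; }
        else { bnd = -1; db = 1e30; }

        bool to_boundary;
        double step;
        if (mut[reg] <= 0.0) {
          if (bnd < 0) { truncated += 1.0; break; } // horizontal in oil
          to_boundary = true; step = db;
        } else {
          double s = xi / mut[reg];
          if (db <= s) { to_boundary = true; step = db; xi -= db * mut[reg]; }
          else { to_boundary = false; step = s; }
        }

        x += ux * step; y += uy * step; z += uz * step;
        path += step;
        if (reg == 1) l_top += step; else if (reg == 2) l_deep += step;
        if (z > maxd) maxd = z;

        if (!to_boundary) {
          // collision: analog absorption branch, else scatter
          if (mua[reg] > 0.0 && rng.unif() * mut[reg] < mua[reg]) {
            absorbed += 1.0;
            break;
          }
          n_events += 1.0;
          double ct = sample_mhg_mu(rng, gg[reg], bb[reg]);
          double cp, sp;
          rand_azimuth(rng, cp, sp);
          spin(ux, uy, uz, ct, cp, sp);
          xi = -std::log(1.0 - rng.unif());
          continue;
        }

        z = zb[bnd]; // land exactly on the boundary
        double ci = std::fabs(uz), ct;

        if (bnd >= 1 && bnd <= 2 && !(uz < 0.0 && zb[bnd] == 0.0)) {
          // internal interface (skips zero-thickness oil automatically)
          int nreg = (uz > 0.0) ? bnd : bnd - 1;
          if (nreg == reg) { reg = (uz > 0.0) ? reg + 1 : reg - 1; continue; }
          double R = fresnel(nr[reg], nr[nreg], ci, ct);
          if (rng.unif() < R) { uz = -uz; }
          else {
            double sc = nr[reg] / nr[nreg];
            ux *= sc; uy *= sc; uz = (uz > 0 ? 1.0 : -1.0) * ct;
            reg = nreg;
          }
          continue;
        }

        if (uz < 0.0 && zb[bnd] == 0.0) {
          // top surface: outside index depends on what sits above (x, y)
          n_surface += 1.0;
          int hit_det = -1, hit_ill = -1;
          double n2 = n_above;
          if (x * x + y * y <= face_r2) {
            face_at(x, y, hit_det, hit_ill);
            if (hit_det >= 0) n2 = detf[hit_det].nf;
            else if (hit_ill >= 0) n2 = illf[hit_ill].nf;
            else if (ci * ci < tir_air) { uz = -uz; continue; }
          } else if (ci * ci < tir_air) {
            // guaranteed total internal reflection against the outside medium
            uz = -uz;
            continue;
          }
          double R = fresnel(nr[reg], n2, ci, ct);
          if (rng.unif() < R) { uz = -uz; continue; }
          top_exit += 1.0;
          if (store_records && hit_det >= 0) {
            const Face &f = detf[hit_det];
            // acceptance cone evaluated in-medium against the reversed axis
            double dot = -(ux * f.ax + uy * f.ay + uz * f.az);
            if (dot >= f.ccone) {
              rec_ill.push_back(k + 1);
              rec_det.push_back(hit_det + 1);
              rl_top.push_back(l_top);
              rl_deep.push_back(l_deep);
              rex.push_back(x); rey.push_back(y);
              rux.push_back(ux); ruy.push_back(uy); ruz.push_back(uz);
              rmaxd.push_back(maxd);
            }
          }
          break;
        }

        if (uz > 0.0 && bnd == 3) {
          // finite bottom: transmit or reflect against n_below
          double R = fresnel(nr[reg], n_below, ci, ct);
          if (rng.unif() < R) { uz = -uz; continue; }
          bottom_exit += 1.0;
          break;
        }

        // unreachable; defensive
        truncated += 1.0;
        break;
      }
    }
  }

  return List::create(
      _["ill"] = wrap(rec_ill), _["det"] = wrap(rec_det),
      _["l_top"] = wrap(rl_top), _["l_deep"] = wrap(rl_deep),
      _["x"] = wrap(rex), _["y"] = wrap(rey),
      _["ux"] = wrap(rux), _["uy"] = wrap(ruy), _["uz"] = wrap(ruz),
      _["max_depth"] = wrap(rmaxd),
      _["n_launched"] = static_cast<double>(n_photons) * n_ill,
      _["top_exit"] = top_exit, _["bottom_exit"] = bottom_exit,
      _["truncated"] = truncated, _["absorbed"] = absorbed,
      _["n_scatter"] = n_events, _["n_surface_hits"] = n_surface);
}

// Beer-Lambert reweighting of a white-MC path set over a (mua_top, mua_deep)
// grid. Returns, per fiber combination and mua pair, the reflectance
// sum(w)/n_launched and the relative MC uncertainty sd(w)/(mean(w) sqrt(n)).
// combo: 0-based combination index per record; n_launched: photons per
// illumination fiber (denominator of each combination).
// [[Rcpp::export]]
List cpp_reweight(NumericVector l_top, NumericVector l_deep,
                  IntegerVector combo, int n_combo,
                  NumericVector mua_top, NumericVector mua_deep,
                  double n_launched) {
  const int nrec = l_top.size();
  const int na1 = mua_top.size(), na2 = mua_deep.size();
  const int npair = na1 * na2;
  NumericMatrix Rm(npair, n_combo), Wm(npair, n_combo);
  std::vector<double> sum1(static_cast<size_t>(npair) * n_combo, 0.0);
  std::vector<double> sum2(static_cast<size_t>(npair) * n_combo, 0.0);
  std::vector<double> ncol(n_combo, 0.0);
  std::vector<double> w1(na1), w2(na2);

  for (int i = 0; i < nrec; i++) {
    int c = combo[i];
    ncol[c] += 1.0;
    for (int a = 0; a < na1; a++) w1[a] = std::exp(-mua_top[a] * l_top[i]);
    for (int b = 0; b < na2; b++) w2[b] = std::exp(-mua_deep[b] * l_deep[i]);
    size_t base = static_cast<size_t>(c) * npair;
    for (int b = 0; b < na2; b++) {
      double wb = w2[b];
      size_t off = base + static_cast<size_t>(b) * na1;
      for (int a = 0; a < na1; a++) {
        double w = w1[a] * wb;
        sum1[off + a] += w;
        sum2[off + a] += w * w;
      }
    }
  }
  for (int c = 0; c < n_combo; c++) {
    size_t base = static_cast<size_t>(c) * npair;
    for (int p = 0; p < npair; p++) {
      double s1 = sum1[base + p], s2 = sum2[base + p], nc = ncol[c];
      Rm(p, c) = s1 / n_launched;
      if (nc >= 1.0 && s1 > 0.0) {
        double mean = s1 / nc;
        double var = std::max(0.0, s2 / nc - mean * mean);
        Wm(p, c) = std::sqrt(var) / (mean * std::sqrt(nc));
      } else {
        Wm(p, c) = NA_REAL;
      }
    }
  }
  NumericVector ncolv(n_combo);
  for (int c = 0; c < n_combo; c++) ncolv[c] = ncol[c];
  return List::create(_["R"] = Rm, _["wnum"] = Wm, _["n_col"] = ncolv);
}

// Relative-difference cost over all LUT nodes:
//   F(node) = mean over combinations of w_c * |R_sim - R_meas| / R_sim.
// Empty Monte Carlo bins (R_sim = 0) are handled by support:
//   - R_sim = 0 and R_meas = 0: uninformative, dropped from the node mean;
//   - R_sim = 0 and R_meas > 0: the node cannot explain observed signal;
//     strict mode marks it ineligible (F = Inf), lenient mode charges a
//     unit relative misfit (used as a fallback when strictness would
//     disqualify every node, e.g. for measurements from an independent
//     run).
// [[Rcpp::export]]
List cpp_cost(NumericMatrix table, NumericVector r_meas, NumericVector w,
              bool strict_support) {
  const int nn = table.nrow(), nc = table.ncol();
  NumericVector F(nn);
  int n_partial = 0, n_empty = 0;
  for (int i = 0; i < nn; i++) {
    double acc = 0.0;
    int nv = 0;
    bool conflict = false;
    for (int c = 0; c < nc; c++) {
      double t = table(i, c);
      if (t > 0.0) {
        acc += w[c] * std::fabs(t - r_meas[c]) / t;
        nv++;
      } else if (r_meas[c] > 0.0) {
        if (strict_support) { conflict = true; break; }
        acc += w[c]; // lenient: unit relative misfit
        nv++;
      } // both zero: uninformative, dropped
    }
    if (conflict || nv == 0) { F[i] = R_PosInf; n_empty++; }
    else {
      F[i] = acc / nv;
      if (nv < nc) n_partial++;
    }
  }
  return List::create(_["F"] = F, _["n_partial"] = n_partial,
                      _["n_empty"] = n_empty);
}
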