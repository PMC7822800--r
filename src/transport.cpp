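// Monte Carlo photon transport on a voxel grid.
//
// Woodcock delta-tracking against the volume's majorant attenuation, with a
// kerma approximation: the energy transferred to secondary electrons is
// deposited at the interaction voxel (no electron transport).  Interaction
// channels are photoelectric absorption (full local deposit), Compton
// scattering (Klein-Nishina via Kahn's rejection method, electron energy
// deposited locally) and Rayleigh scattering (Thomson angular shape, no
// deposit).  A photon counts as "primary" until its first Compton or
// Rayleigh event.  Free-in-air collision kerma is scored at the reference
// point with a track-length estimator over a small spherical air cell.
//
// Randomness is a counter-based splitmix64 stream seeded per history, so
// the result is independent of batch decomposition and bit-reproducible.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

namespace {

const double ELECTRON_REST_KEV = 510.99895;

struct SplitMix {
  uint64_t state;
  explicit SplitMix(uint64_t s) : state(s) {}
  uint64_t next_u64() {
    uint64_t z = (state += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  // uniform in (0, 1)
  double next() { return ((next_u64() >> 11) + 0.5) * (1.0 / 9007199254740992.0); }
};

struct Grid {
  int nx, ny, nz;
  double sx, sy, sz;      // spacing, mm
  double ox, oy, oz;      // corner origin, mm
  double hx, hy, hz;      // upper corner
  const int* labels;

  bool inside(const double p[3]) const {
    return p[0] > ox && p[0] < hx && p[1] > oy && p[1] < hy &&
           p[2] > oz && p[2] < hz;
  }
  int voxel(const double p[3]) const {
    int i = (int)std::floor((p[0] - ox) / sx);
    int j = (int)std::floor((p[1] - oy) / sy);
    int k = (int)std::floor((p[2] - oz) / sz);
    if (i < 0) i = 0; if (i >= nx) i = nx - 1;
    if (j < 0) j = 0; if (j >= ny) j = ny - 1;
    if (k < 0) k = 0; if (k >= nz) k = nz - 1;
    return i + nx * (j + ny * k);
  }
  // slab intersection of the ray p + t*d with the box; returns false if the
  // ray misses, else [t0, t1] clipped to t >= 0
  bool clip(const double p[3], const double d[3], double& t0,
            double& t1) const {
    t0 = 0.0;
    t1 = 1e30;
    const double lo[3] = {ox, oy, oz}, hi[3] = {hx, hy, hz};
    for (int a = 0; a < 3; ++a) {
      if (std::fabs(d[a]) < 1e-15) {
        if (p[a] <= lo[a] || p[a] >= hi[a]) return false;
      } else {
        double u = (lo[a] - p[a]) / d[a];
        double v = (hi[a] - p[a]) / d[a];
        if (u > v) std::swap(u, v);
        if (u > t0) t0 = u;
        if (v < t1) t1 = v;
        if (t0 >= t1) return false;
      }
    }
    return t1 > 0.0;
  }
};

// linear interpolation on the uniform energy grid
struct Interp {
  double e0, de;
  int n;
  double at(const double* col, double e) const {
    double x = (e - e0) / de;
    if (x <= 0.0) return col[0];
    int i = (int)x;
    if (i >= n - 1) return col[n - 1];
    double f = x - i;
    return col[i] * (1.0 - f) + col[i + 1] * f;
  }
};

void rotate_direction(double d[3], double cos_t, double phi) {
  double sin_t = std::sqrt(std::max(0.0, 1.0 - cos_t * cos_t));
  // orthonormal basis around d
  double e1[3];
  if (std::fabs(d[2]) < 0.99) {
    e1[0] = -d[1]; e1[1] = d[0]; e1[2] = 0.0;
  } else {
    e1[0] = 0.0; e1[1] = -d[2]; e1[2] = d[1];
  }
  double n1 = std::sqrt(e1[0] * e1[0] + e1[1] * e1[1] + e1[2] * e1[2]);
  for (int a = 0; a < 3; ++a) e1[a] /= n1;
  double e2[3] = {d[1] * e1[2] - d[2] * e1[1],
                  d[2] * e1[0] - d[0] * e1[2],
                  d[0] * e1[1] - d[1] * e1[0]};
  double cp = std::cos(phi), sp = std::sin(phi);
  double nd[3];
  for (int a = 0; a < 3; ++a) {
    nd[a] = sin_t * (cp * e1[a] + sp * e2[a]) + cos_t * d[a];
  }
  double nn = std::sqrt(nd[0] * nd[0] + nd[1] * nd[1] + nd[2] * nd[2]);
  for (int a = 0; a < 3; ++a) d[a] = nd[a] / nn;
}

// Kahn's rejection sampling of the Klein-Nishina distribution; returns the
// scattered photon energy and sets cos_t
double kahn_compton(double e_kev, SplitMix& rng, double& cos_t) {
  double alpha = e_kev / ELECTRON_REST_KEV;
  double x;  // E / E'
  for (;;) {
    double r1 = rng.next(), r2 = rng.next(), r3 = rng.next();
    if (r1 <= (1.0 + 2.0 * alpha) / (9.0 + 2.0 * alpha)) {
      x = 1.0 + 2.0 * alpha * r2;
      if (r3 <= 4.0 * (1.0 / x - 1.0 / (x * x))) {
        cos_t = 1.0 - (x - 1.0) / alpha;
        break;
      }
    } else {
      x = (1.0 + 2.0 * alpha) / (1.0 + 2.0 * alpha * r2);
      cos_t = 1.0 - (x - 1.0) / alpha;
      if (r3 <= 0.5 * (cos_t * cos_t + 1.0 / x)) break;
    }
  }
  return e_kev / x;
}

double thomson_cosine(SplitMix& rng) {
  for (;;) {
    double ct = 2.0 * rng.next() - 1.0;
    if (rng.next() <= 0.5 * (1.0 + ct * ct)) return ct;
  }
}

// chord length of segment p0 -> p0 + len*d inside a sphere
double sphere_chord(const double p0[3], const double d[3], double len,
                    const double c[3], double radius) {
  double f[3] = {p0[0] - c[0], p0[1] - c[1], p0[2] - c[2]};
  double b = f[0] * d[0] + f[1] * d[1] + f[2] * d[2];
  double cc = f[0] * f[0] + f[1] * f[1] + f[2] * f[2] - radius * radius;
  double disc = b * b - cc;
  if (disc <= 0.0) return 0.0;
  double sq = std::sqrt(disc);
  double t0 = std::max(-b - sq, 0.0);
  double t1 = std::min(-b + sq, len);
  return t1 > t0 ? t1 - t0 : 0.0;
}

}  // namespace

// [[Rcpp::export(name = ".mc_transport")]]
List mc_transport(IntegerVector labels, IntegerVector dims,
                  NumericVector spacing, NumericVector origin,
                  NumericMatrix mu_lin, NumericMatrix f_photo,
                  NumericMatrix f_compton, NumericVector muen_air,
                  double egrid_start, double egrid_step,
                  NumericVector src, NumericVector e_u, NumericVector e_v,
                  NumericVector e_c, double tan_phi, double tan_theta,
                  NumericVector spec_energy, NumericVector spec_cdf,
                  NumericVector ref_point, double ref_radius,
                  double n_histories, int n_batches, double seed,
                  double e_cutoff) {
  const int n_energy = mu_lin.nrow();
  const int n_label = mu_lin.ncol();
  const R_xlen_t n_vox = labels.size();

  Grid grid;
  grid.nx = dims[0]; grid.ny = dims[1]; grid.nz = dims[2];
  grid.sx = spacing[0]; grid.sy = spacing[1]; grid.sz = spacing[2];
  grid.ox = origin[0]; grid.oy = origin[1]; grid.oz = origin[2];
  grid.hx = grid.ox + grid.nx * grid.sx;
  grid.hy = grid.oy + grid.ny * grid.sy;
  grid.hz = grid.oz + grid.nz * grid.sz;
  grid.labels = INTEGER(labels);

  Interp ip;
  ip.e0 = egrid_start; ip.de = egrid_step; ip.n = n_energy;

  // flat copies of the coefficient tables and the per-energy majorant
  std::vector<double> mu(n_energy * n_label), fp(n_energy * n_label),
      fc(n_energy * n_label), maj(n_energy), muen_a(n_energy);
  for (int l = 0; l < n_label; ++l) {
    for (int e = 0; e < n_energy; ++e) {
      mu[l * n_energy + e] = mu_lin(e, l);
      fp[l * n_energy + e] = f_photo(e, l);
      fc[l * n_energy + e] = f_compton(e, l);
    }
  }
  for (int e = 0; e < n_energy; ++e) {
    double m = 0.0;
    for (int l = 0; l < n_label; ++l) m = std::max(m, mu[l * n_energy + e]);
    maj[e] = m;
    muen_a[e] = muen_air[e];
  }
  double maj_floor = *std::min_element(maj.begin(), maj.end());
  if (maj_floor <= 0.0) stop("majorant attenuation must be positive");

  const double S[3] = {src[0], src[1], src[2]};
  const double EU[3] = {e_u[0], e_u[1], e_u[2]};
  const double EV[3] = {e_v[0], e_v[1], e_v[2]};
  const double EC[3] = {e_c[0], e_c[1], e_c[2]};
  const double RC[3] = {ref_point[0], ref_point[1], ref_point[2]};
  const int n_spec = spec_energy.size();

  std::vector<double> primary(n_vox, 0.0), scatter(n_vox, 0.0),
      batch_buf(n_vox, 0.0), batch_sumsq(n_vox, 0.0);
  double emitted = 0.0, deposited = 0.0, escaped = 0.0, ref_raw = 0.0;

  const long long n_hist = (long long)n_histories;
  const uint64_t seed_u = (uint64_t)seed;
  long long done = 0;

  for (int b = 0; b < n_batches; ++b) {
    long long batch_n = n_hist / n_batches + (b < n_hist % n_batches ? 1 : 0);
    std::fill(batch_buf.begin(), batch_buf.end(), 0.0);
    for (long long h = 0; h < batch_n; ++h, ++done) {
      SplitMix rng(seed_u ^ (0x9E3779B97F4A7C15ULL * (uint64_t)(done + 1)));
      rng.next_u64();

      // source energy and direction within the collimation pyramid
      double e_kev;
      if (n_spec == 1) {
        e_kev = spec_energy[0];
      } else {
        double u = rng.next();
        int lo = 0, hi = n_spec - 1;
        while (lo < hi) {
          int mid = (lo + hi) / 2;
          if (spec_cdf[mid] < u) lo = mid + 1; else hi = mid;
        }
        e_kev = spec_energy[lo];
      }
      emitted += e_kev;
      double uu = (2.0 * rng.next() - 1.0) * tan_phi;
      double vv = (2.0 * rng.next() - 1.0) * tan_theta;
      double dir[3];
      double nn = 0.0;
      for (int a = 0; a < 3; ++a) {
        dir[a] = EC[a] + uu * EU[a] + vv * EV[a];
        nn += dir[a] * dir[a];
      }
      nn = std::sqrt(nn);
      for (int a = 0; a < 3; ++a) dir[a] /= nn;

      double pos[3] = {S[0], S[1], S[2]};
      double seg[3] = {S[0], S[1], S[2]};  // start of the current straight leg
      bool is_primary = true;
      bool alive = true;

      while (alive) {
        if (!grid.inside(pos)) {
          double t0, t1;
          if (!grid.clip(pos, dir, t0, t1)) {
            // misses (or has left) the volume; fly off through the air cell
            if (is_primary) {
              double chord = sphere_chord(seg, dir, 1e7, RC, ref_radius);
              if (chord > 0.0)
                ref_raw += e_kev * chord * ip.at(muen_a.data(), e_kev);
            }
            escaped += e_kev;
            alive = false;
            break;
          }
          double step_in = t0 + 1e-9;
          for (int a = 0; a < 3; ++a) pos[a] += step_in * dir[a];
          if (!grid.inside(pos)) {  // grazing corner: treat as a miss
            if (is_primary) {
              double chord = sphere_chord(seg, dir, 1e7, RC, ref_radius);
              if (chord > 0.0)
                ref_raw += e_kev * chord * ip.at(muen_a.data(), e_kev);
            }
            escaped += e_kev;
            alive = false;
            break;
          }
        }
        double mu_maj = ip.at(maj.data(), e_kev);
        // Woodcock flight inside the volume
        for (;;) {
          double l = -std::log(rng.next()) / mu_maj;
          for (int a = 0; a < 3; ++a) pos[a] += l * dir[a];
          if (!grid.inside(pos)) {
            if (is_primary) {
              double chord = sphere_chord(seg, dir, 1e7, RC, ref_radius);
              if (chord > 0.0)
                ref_raw += e_kev * chord * ip.at(muen_a.data(), e_kev);
            }
            escaped += e_kev;
            alive = false;
            break;
          }
          int vox = grid.voxel(pos);
          int lab = grid.labels[vox];
          double mu_here = ip.at(mu.data() + (size_t)lab * n_energy, e_kev);
          if (rng.next() * mu_maj > mu_here) continue;  // fictitious

          // real interaction: close the straight leg for the kerma cell
          if (is_primary) {
            double seg_len = std::sqrt(
                (pos[0] - seg[0]) * (pos[0] - seg[0]) +
                (pos[1] - seg[1]) * (pos[1] - seg[1]) +
                (pos[2] - seg[2]) * (pos[2] - seg[2]));
            double chord = sphere_chord(seg, dir, seg_len, RC, ref_radius);
            if (chord > 0.0)
              ref_raw += e_kev * chord * ip.at(muen_a.data(), e_kev);
          }
          double u = rng.next();
          double f_ph = ip.at(fp.data() + (size_t)lab * n_energy, e_kev);
          double f_co = ip.at(fc.data() + (size_t)lab * n_energy, e_kev);
          if (u < f_ph) {
            // photoelectric: full local absorption
            (is_primary ? primary : scatter)[vox] += e_kev;
            batch_buf[vox] += e_kev;
            deposited += e_kev;
            alive = false;
          } else if (u < f_ph + f_co) {
            double cos_t;
            double e_out = kahn_compton(e_kev, rng, cos_t);
            double e_dep = e_kev - e_out;
            (is_primary ? primary : scatter)[vox] += e_dep;
            batch_buf[vox] += e_dep;
            deposited += e_dep;
            rotate_direction(dir, cos_t, 2.0 * M_PI * rng.next());
            is_primary = false;
            for (int a = 0; a < 3; ++a) seg[a] = pos[a];
            if (e_out < e_cutoff) {
              scatter[vox] += e_out;
              batch_buf[vox] += e_out;
              deposited += e_out;
              alive = false;
            } else {
              e_kev = e_out;
              mu_maj = ip.at(maj.data(), e_kev);
            }
          } else {
            // Rayleigh: elastic, direction change only
            rotate_direction(dir, thomson_cosine(rng), 2.0 * M_PI * rng.next());
            is_primary = false;
            for (int a = 0; a < 3; ++a) seg[a] = pos[a];
          }
          if (!alive) break;
        }
      }
    }
    for (R_xlen_t v = 0; v < n_vox; ++v) {
      batch_sumsq[v] += batch_buf[v] * batch_buf[v];
    }
  }

  return List::create(
      _["primary"] = NumericVector(primary.begin(), primary.end()),
      _["scatter"] = NumericVector(scatter.begin(), scatter.end()),
      _["batch_sumsq"] = NumericVector(batch_sumsq.begin(), batch_sumsq.end()),
      _["emitted"] = emitted, _["deposited"] = deposited,
      _["escaped"] = escaped, _["ref_raw"] = ref_raw);
}
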