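// Monte Carlo photon/electron transport core for nanoscintillator
// assemblies.  Geometry: (1) "satellite" -- one SiO2 sphere decorated with
// ZnO nanoparticles inside an air-filled world sphere; (2) "powder" -- many
// ZnO-shelled SiO2 spheres inside an air-filled micro-cylinder.  Photons:
// analog or forced-first-interaction free-path sampling per ray segment;
// photoelectric events with K-shell/outer-shell split and single-step
// atomic relaxation (K-alpha fluorescence or one Auger electron);
// Klein-Nishina Compton on free electrons; Thomson-law Rayleigh.
// Electrons: condensed-history stepping (fixed step in solids, safety-
// distance steps in air) with Gaussian small-angle multiple scattering.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
#include <algorithm>
using namespace Rcpp;

static const double TWO_PI = 6.283185307179586;
static const double MEC2 = 510.99895; // keV

// ---------------------------------------------------------------- RNG ----
struct XRng {
  uint64_t s[4];
  bool has_cache = false;
  double cache = 0.0;
  static uint64_t splitmix(uint64_t &x) {
    uint64_t z = (x += 0x9e3779b97f4a7c15ULL);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }
  XRng(uint64_t seed, uint64_t stream) {
    uint64_t x = seed ^ (0x632be59bd9b4e019ULL * (stream + 1));
    for (int i = 0; i < 4; ++i) s[i] = splitmix(x);
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t res = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return res;
  }
  inline double unif() { return (next() >> 11) * 1.1102230246251565e-16; }
  inline double unif_pos() {
    double u;
    do { u = unif(); } while (u <= 0.0);
    return u;
  }
  double norm() {
    if (has_cache) { has_cache = false; return cache; }
    double u1 = unif_pos(), u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1)), a = TWO_PI * u2;
    cache = r * std::sin(a);
    has_cache = true;
    return r * std::cos(a);
  }
};

// ------------------------------------------------------- material tables --
struct MatTab {
  std::vector<double> logE, lpe, lin, lco, lstop, lrange;
  int nelem = 0;
  std::vector<double> cumshare; // grid-major: g * nelem + j
  std::vector<double> k_edge, jump, omega, kalpha, lmean;
  double density = 0.0;

  inline double interp(const std::vector<double> &ly, double E) const {
    double le = std::log(std::max(E, 1e-12));
    size_t n = logE.size();
    if (le <= logE[0]) le = logE[0];
    if (le >= logE[n - 1]) le = logE[n - 1];
    size_t hi = std::upper_bound(logE.begin(), logE.end(), le) - logE.begin();
    if (hi == 0) hi = 1;
    if (hi >= n) hi = n - 1;
    size_t lo = hi - 1;
    double w = (le - logE[lo]) / std::max(logE[hi] - logE[lo], 1e-300);
    double v = (1.0 - w) * ly[lo] + w * ly[hi];
    return v < -600.0 ? 0.0 : std::exp(v);
  }
  inline double mu_pe(double E) const { return interp(lpe, E); }
  inline double mu_in(double E) const { return interp(lin, E); }
  inline double mu_co(double E) const { return interp(lco, E); }
  inline double mu_tot(double E) const { return mu_pe(E) + mu_in(E) + mu_co(E); }
  inline double stop(double E) const { return interp(lstop, E); }
  inline double range(double E) const { return interp(lrange, E); }

  int sample_element(double E, double u) const {
    if (nelem == 1) return 0;
    double le = std::log(std::max(E, 1e-12));
    size_t n = logE.size();
    if (le <= logE[0]) le = logE[0];
    if (le >= logE[n - 1]) le = logE[n - 1];
    size_t hi = std::upper_bound(logE.begin(), logE.end(), le) - logE.begin();
    if (hi == 0) hi = 1;
    if (hi >= n) hi = n - 1;
    size_t lo = hi - 1;
    double w = (le - logE[lo]) / std::max(logE[hi] - logE[lo], 1e-300);
    for (int j = 0; j < nelem; ++j) {
      double c = (1.0 - w) * cumshare[lo * nelem + j] +
                 w * cumshare[hi * nelem + j];
      if (u <= c) return j;
    }
    return nelem - 1;
  }
};

static MatTab mat_from_list(const List &m) {
  MatTab t;
  t.logE = as<std::vector<double>>(m["logE"]);
  t.lpe = as<std::vector<double>>(m["lpe"]);
  t.lin = as<std::vector<double>>(m["lin"]);
  t.lco = as<std::vector<double>>(m["lco"]);
  t.lstop = as<std::vector<double>>(m["lstop"]);
  t.lrange = as<std::vector<double>>(m["lrange"]);
  t.density = as<double>(m["density"]);
  NumericMatrix cs = m["cumshare"];
  t.nelem = cs.ncol();
  t.cumshare.resize((size_t)cs.nrow() * cs.ncol());
  for (int g = 0; g < cs.nrow(); ++g)
    for (int j = 0; j < cs.ncol(); ++j)
      t.cumshare[(size_t)g * cs.ncol() + j] = cs(g, j);
  t.k_edge = as<std::vector<double>>(m["k_edge"]);
  t.jump = as<std::vector<double>>(m["jump"]);
  t.omega = as<std::vector<double>>(m["omega"]);
  t.kalpha = as<std::vector<double>>(m["kalpha"]);
  t.lmean = as<std::vector<double>>(m["lmean"]);
  return t;
}

// --------------------------------------------------------------- geometry --
struct Seg { double t0, t1; int medium, body; };

struct Geom {
  int kind = 1; // 1 satellite, 2 powder
  // satellite
  double world_r = 0, host_r = 0, np_r = 0;
  std::vector<double> npx, npy, npz;
  int m_world = 0, m_host = 1, m_np = 2;
  // powder
  double cyl_r = 0, cyl_hz = 0, core_r = 0, shell_r = 0;
  std::vector<double> cx, cy, cz;
  int m_core = 1, m_shell = 2;
  // cell grid (powder)
  double cell = 1, ox = 0, oy = 0, oz = 0;
  int ngx = 1, ngy = 1, ngz = 1;
  std::vector<int> cell_start, cell_items;

  void build_grid() {
    if (kind != 2) return;
    cell = 2.0 * shell_r + 1.0;
    ox = -cyl_r; oy = -cyl_r; oz = -cyl_hz;
    ngx = std::max(1, (int)std::ceil(2.0 * cyl_r / cell));
    ngy = ngx;
    ngz = std::max(1, (int)std::ceil(2.0 * cyl_hz / cell));
    size_t nc = (size_t)ngx * ngy * ngz, n = cx.size();
    std::vector<int> cnt(nc + 1, 0);
    std::vector<int> ci(n);
    for (size_t i = 0; i < n; ++i) {
      int ix = std::min(ngx - 1, std::max(0, (int)((cx[i] - ox) / cell)));
      int iy = std::min(ngy - 1, std::max(0, (int)((cy[i] - oy) / cell)));
      int iz = std::min(ngz - 1, std::max(0, (int)((cz[i] - oz) / cell)));
      ci[i] = ix + ngx * (iy + ngy * iz);
      cnt[ci[i] + 1]++;
    }
    for (size_t c = 1; c <= nc; ++c) cnt[c] += cnt[c - 1];
    cell_start = cnt;
    cell_items.resize(n);
    std::vector<int> fill(cell_start.begin(), cell_start.end());
    for (size_t i = 0; i < n; ++i) cell_items[fill[ci[i]]++] = i;
  }

  inline bool in_world(const double *p) const {
    if (kind == 1)
      return p[0] * p[0] + p[1] * p[1] + p[2] * p[2] <= world_r * world_r;
    double rho2 = p[0] * p[0] + p[1] * p[1];
    return rho2 <= cyl_r * cyl_r && std::fabs(p[2]) <= cyl_hz;
  }

  // medium index, body id via pointer (-1 world/outside, 0 host, i>=1 NP or
  // powder sphere index).  Returns -1 when outside the world.
  int locate(const double *p, int *body) const {
    *body = -1;
    if (!in_world(p)) return -1;
    if (kind == 1) {
      double r2 = p[0] * p[0] + p[1] * p[1] + p[2] * p[2];
      if (r2 <= host_r * host_r) { *body = 0; return m_host; }
      double r = std::sqrt(r2);
      if (r <= host_r + 2.0 * np_r + 1e-9) {
        for (size_t i = 0; i < npx.size(); ++i) {
          double dx = p[0] - npx[i], dy = p[1] - npy[i], dz = p[2] - npz[i];
          if (dx * dx + dy * dy + dz * dz <= np_r * np_r) {
            *body = (int)i + 1;
            return m_np;
          }
        }
      }
      return m_world;
    }
    // powder: 27-cell search
    int ix = std::min(ngx - 1, std::max(0, (int)((p[0] - ox) / cell)));
    int iy = std::min(ngy - 1, std::max(0, (int)((p[1] - oy) / cell)));
    int iz = std::min(ngz - 1, std::max(0, (int)((p[2] - oz) / cell)));
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          int jx = ix + dx, jy = iy + dy, jz = iz + dz;
          if (jx < 0 || jy < 0 || jz < 0 || jx >= ngx || jy >= ngy || jz >= ngz)
            continue;
          int c = jx + ngx * (jy + ngy * jz);
          for (int k = cell_start[c]; k < cell_start[c + 1]; ++k) {
            int i = cell_items[k];
            double ddx = p[0] - cx[i], ddy = p[1] - cy[i], ddz = p[2] - cz[i];
            double d2 = ddx * ddx + ddy * ddy + ddz * ddz;
            if (d2 <= core_r * core_r) { *body = i + 1; return m_core; }
            if (d2 <= shell_r * shell_r) { *body = i + 1; return m_shell; }
          }
        }
    return m_world;
  }

  // conservative distance from an air point to the nearest solid surface
  double safety(const double *p) const {
    if (kind == 1) {
      double r = std::sqrt(p[0] * p[0] + p[1] * p[1] + p[2] * p[2]);
      double s = r - host_r;
      for (size_t i = 0; i < npx.size(); ++i) {
        double dx = p[0] - npx[i], dy = p[1] - npy[i], dz = p[2] - npz[i];
        double d = std::sqrt(dx * dx + dy * dy + dz * dz) - np_r;
        if (d < s) s = d;
      }
      return std::max(s, 0.0);
    }
    int ix = std::min(ngx - 1, std::max(0, (int)((p[0] - ox) / cell)));
    int iy = std::min(ngy - 1, std::max(0, (int)((p[1] - oy) / cell)));
    int iz = std::min(ngz - 1, std::max(0, (int)((p[2] - oz) / cell)));
    double s = cell - shell_r; // nearest center outside the 27-block
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          int jx = ix + dx, jy = iy + dy, jz = iz + dz;
          if (jx < 0 || jy < 0 || jz < 0 || jx >= ngx || jy >= ngy || jz >= ngz)
            continue;
          int c = jx + ngx * (jy + ngy * jz);
          for (int k = cell_start[c]; k < cell_start[c + 1]; ++k) {
            int i = cell_items[k];
            double ddx = p[0] - cx[i], ddy = p[1] - cy[i], ddz = p[2] - cz[i];
            double d = std::sqrt(ddx * ddx + ddy * ddy + ddz * ddz) - shell_r;
            if (d < s) s = d;
          }
        }
    return std::max(s, 0.0);
  }

  // nearest sphere center to a point (powder radial anchoring); returns
  // index or -1 when no center lies within the 27-cell neighbourhood.
  int nearest_center(const double *p) const {
    int ix = std::min(ngx - 1, std::max(0, (int)((p[0] - ox) / cell)));
    int iy = std::min(ngy - 1, std::max(0, (int)((p[1] - oy) / cell)));
    int iz = std::min(ngz - 1, std::max(0, (int)((p[2] - oz) / cell)));
    int best = -1;
    double bd = 1e300;
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          int jx = ix + dx, jy = iy + dy, jz = iz + dz;
          if (jx < 0 || jy < 0 || jz < 0 || jx >= ngx || jy >= ngy || jz >= ngz)
            continue;
          int c = jx + ngx * (jy + ngy * jz);
          for (int k = cell_start[c]; k < cell_start[c + 1]; ++k) {
            int i = cell_items[k];
            double ddx = p[0] - cx[i], ddy = p[1] - cy[i], ddz = p[2] - cz[i];
            double d2 = ddx * ddx + ddy * ddy + ddz * ddz;
            if (d2 < bd) { bd = d2; best = i; }
          }
        }
    return best;
  }

  // closed-form sphere intersection: interval of t with |p + t d - c| <= R
  static bool sphere_hit(const double *p, const double *d, double cx_, double cy_,
                         double cz_, double R, double &t0, double &t1) {
    double ox_ = p[0] - cx_, oy_ = p[1] - cy_, oz_ = p[2] - cz_;
    double b = ox_ * d[0] + oy_ * d[1] + oz_ * d[2];
    double c = ox_ * ox_ + oy_ * oy_ + oz_ * oz_ - R * R;
    double disc = b * b - c;
    if (disc <= 0) return false;
    double sq = std::sqrt(disc);
    t0 = -b - sq;
    t1 = -b + sq;
    return t1 > 0;
  }

  // ordered segments from (possibly outside) origin to world exit
  void ray_segments(const double *p, const double *d, std::vector<Seg> &out) const {
    out.clear();
    double tw0, tw1;
    if (kind == 1) {
      if (!sphere_hit(p, d, 0, 0, 0, world_r, tw0, tw1)) return;
      tw0 = std::max(tw0, 0.0);
      if (tw1 <= tw0) return;
      std::vector<Seg> solids;
      double a0, a1;
      if (sphere_hit(p, d, 0, 0, 0, host_r, a0, a1)) {
        a0 = std::max(a0, tw0); a1 = std::min(a1, tw1);
        if (a1 > a0) solids.push_back({a0, a1, m_host, 0});
      }
      for (size_t i = 0; i < npx.size(); ++i)
        if (sphere_hit(p, d, npx[i], npy[i], npz[i], np_r, a0, a1)) {
          a0 = std::max(a0, tw0); a1 = std::min(a1, tw1);
          if (a1 > a0) solids.push_back({a0, a1, m_np, (int)i + 1});
        }
      std::sort(solids.begin(), solids.end(),
                [](const Seg &x, const Seg &y) { return x.t0 < y.t0; });
      double t = tw0;
      for (const Seg &s : solids) {
        if (s.t0 > t + 1e-12) out.push_back({t, s.t0, m_world, -1});
        out.push_back(s);
        t = s.t1;
      }
      if (tw1 > t + 1e-12) out.push_back({t, tw1, m_world, -1});
      return;
    }
    // powder: cylinder world
    double a = d[0] * d[0] + d[1] * d[1];
    double tr0 = -1e300, tr1 = 1e300;
    if (a > 1e-14) {
      double b = p[0] * d[0] + p[1] * d[1];
      double c = p[0] * p[0] + p[1] * p[1] - cyl_r * cyl_r;
      double disc = b * b - a * c;
      if (disc <= 0) return;
      double sq = std::sqrt(disc);
      tr0 = (-b - sq) / a;
      tr1 = (-b + sq) / a;
    } else if (p[0] * p[0] + p[1] * p[1] > cyl_r * cyl_r) return;
    double tz0 = -1e300, tz1 = 1e300;
    if (std::fabs(d[2]) > 1e-14) {
      tz0 = (-cyl_hz - p[2]) / d[2];
      tz1 = (cyl_hz - p[2]) / d[2];
      if (tz0 > tz1) std::swap(tz0, tz1);
    } else if (std::fabs(p[2]) > cyl_hz) return;
    tw0 = std::max(0.0, std::max(tr0, tz0));
    tw1 = std::min(tr1, tz1);
    if (tw1 <= tw0) return;
    std::vector<Seg> solids;
    for (size_t i = 0; i < cx.size(); ++i) {
      double s0, s1;
      if (!sphere_hit(p, d, cx[i], cy[i], cz[i], shell_r, s0, s1)) continue;
      s0 = std::max(s0, tw0);
      s1 = std::min(s1, tw1);
      if (s1 <= s0) continue;
      double c0, c1;
      bool core = sphere_hit(p, d, cx[i], cy[i], cz[i], core_r, c0, c1);
      if (core) {
        c0 = std::max(c0, s0);
        c1 = std::min(c1, s1);
        core = c1 > c0;
      }
      if (core) {
        if (c0 > s0) solids.push_back({s0, c0, m_shell, (int)i + 1});
        solids.push_back({c0, c1, m_core, (int)i + 1});
        if (s1 > c1) solids.push_back({c1, s1, m_shell, (int)i + 1});
      } else {
        solids.push_back({s0, s1, m_shell, (int)i + 1});
      }
    }
    std::sort(solids.begin(), solids.end(),
              [](const Seg &x, const Seg &y) { return x.t0 < y.t0; });
    double t = tw0;
    for (const Seg &s : solids) {
      if (s.t0 > t + 1e-12) out.push_back({t, s.t0, m_world, -1});
      out.push_back(s);
      t = std::max(t, s.t1);
    }
    if (tw1 > t + 1e-12) out.push_back({t, tw1, m_world, -1});
  }

  void anchor_of(int medium, int body, const double *at, double *anchor) const {
    if (kind == 1) {
      if (medium == m_host) { anchor[0] = anchor[1] = anchor[2] = 0; return; }
      if (medium == m_np && body >= 1) {
        anchor[0] = npx[body - 1]; anchor[1] = npy[body - 1];
        anchor[2] = npz[body - 1];
        return;
      }
    } else if (body >= 1) {
      anchor[0] = cx[body - 1]; anchor[1] = cy[body - 1]; anchor[2] = cz[body - 1];
      return;
    }
    anchor[0] = at[0]; anchor[1] = at[1]; anchor[2] = at[2];
  }
};

static Geom geom_from_list(const List &g) {
  Geom G;
  G.kind = as<int>(g["kind"]);
  G.m_world = as<int>(g["m_world"]);
  if (G.kind == 1) {
    G.world_r = as<double>(g["world_r"]);
    G.host_r = as<double>(g["host_r"]);
    G.np_r = as<double>(g["np_r"]);
    G.m_host = as<int>(g["m_host"]);
    G.m_np = as<int>(g["m_np"]);
    NumericMatrix c = g["np_centers"];
    for (int i = 0; i < c.nrow(); ++i) {
      G.npx.push_back(c(i, 0));
      G.npy.push_back(c(i, 1));
      G.npz.push_back(c(i, 2));
    }
  } else {
    G.cyl_r = as<double>(g["cyl_r"]);
    G.cyl_hz = as<double>(g["cyl_hz"]);
    G.core_r = as<double>(g["core_r"]);
    G.shell_r = as<double>(g["shell_r"]);
    G.m_core = as<int>(g["m_core"]);
    G.m_shell = as<int>(g["m_shell"]);
    NumericMatrix c = g["centers"];
    for (int i = 0; i < c.nrow(); ++i) {
      G.cx.push_back(c(i, 0));
      G.cy.push_back(c(i, 1));
      G.cz.push_back(c(i, 2));
    }
    G.build_grid();
  }
  return G;
}

// ------------------------------------------------------------- samplers ---
// Klein-Nishina cos(theta) by rejection; returns scattered photon energy too
static inline void sample_compton(XRng &rng, double E, double &ct, double &Eout) {
  double k = E / MEC2;
  for (;;) {
    double c = 2.0 * rng.unif() - 1.0;
    double ratio = 1.0 / (1.0 + k * (1.0 - c));
    double s2 = 1.0 - c * c;
    double f = ratio * ratio * (ratio + 1.0 / ratio - s2);
    if (rng.unif() * 2.0 <= f) { ct = c; Eout = E * ratio; return; }
  }
}

static inline double sample_thomson(XRng &rng) {
  for (;;) {
    double c = 2.0 * rng.unif() - 1.0;
    if (rng.unif() * 2.0 <= 1.0 + c * c) return c;
  }
}

// rotate unit vector d by polar angle theta (cos ct) and uniform azimuth
static inline void rotate_dir(XRng &rng, double *d, double ct) {
  double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
  double phi = TWO_PI * rng.unif();
  double u[3], v[3];
  if (std::fabs(d[2]) < 0.99) {
    u[0] = -d[1]; u[1] = d[0]; u[2] = 0;
  } else {
    u[0] = 0; u[1] = -d[2]; u[2] = d[1];
  }
  double un = std::sqrt(u[0] * u[0] + u[1] * u[1] + u[2] * u[2]);
  for (int i = 0; i < 3; ++i) u[i] /= un;
  v[0] = d[1] * u[2] - d[2] * u[1];
  v[1] = d[2] * u[0] - d[0] * u[2];
  v[2] = d[0] * u[1] - d[1] * u[0];
  double cp = std::cos(phi), sp = std::sin(phi);
  for (int i = 0; i < 3; ++i)
    d[i] = ct * d[i] + st * (cp * u[i] + sp * v[i]);
  double n = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
  for (int i = 0; i < 3; ++i) d[i] /= n;
}

static inline void iso_dir(XRng &rng, double *d) {
  double c = 2.0 * rng.unif() - 1.0;
  double s = std::sqrt(std::max(0.0, 1.0 - c * c));
  double phi = TWO_PI * rng.unif();
  d[0] = s * std::cos(phi);
  d[1] = s * std::sin(phi);
  d[2] = c;
}

// ------------------------------------------------------------ transport ---
struct Evt { double p[3]; double E; int medium; };

struct Particle { int kind; double p[3], d[3], E; }; // 0 photon, 1 electron

struct HistScore {
  std::vector<Evt> evts;
  double escaped = 0;
  int first_medium = -1, first_body = -1, first_channel = -1;
  double first_anchor[3] = {0, 0, 0};
  bool has_first = false;
  int n_secondaries = 0;
  bool excluded = false;
  void reset() {
    evts.clear();
    escaped = 0;
    first_medium = first_body = first_channel = -1;
    has_first = false;
    n_secondaries = 0;
    excluded = false;
  }
  double dep_total() const {
    double s = 0;
    for (const Evt &e : evts) s += e.E;
    return s;
  }
};

struct Engine {
  Geom G;
  std::vector<MatTab> mats;
  double cutoff = 0.25, estep = 1.0, ms_k = 2.2;
  int max_secondaries = 10000;
  bool tag_rayleigh = true;
  // non-radiative relaxation: deposit the K binding locally (the reference
  // Livermore configuration, Auger generation off) or emit one KLL-like
  // Auger electron
  bool auger_electron = false;
  std::vector<Particle> stack;

  void deposit(HistScore &hs, const double *p, double E, int medium) {
    if (E <= 0) return;
    if (medium < 0) { hs.escaped += E; return; }
    hs.evts.push_back({{p[0], p[1], p[2]}, E, medium});
  }

  int sample_channel(XRng &rng, int medium, double E) {
    const MatTab &m = mats[medium];
    double pe = m.mu_pe(E), in = m.mu_in(E), co = m.mu_co(E);
    double u = rng.unif() * (pe + in + co);
    if (u <= pe) return 0;
    if (u <= pe + in) return 1;
    return 2;
  }

  // photoelectric absorption at p in `medium`; pushes secondaries
  void do_photoelectric(XRng &rng, HistScore &hs, const double *p, double E,
                        int medium) {
    const MatTab &m = mats[medium];
    int j = m.sample_element(E, rng.unif());
    double ke = m.k_edge[j], om = m.omega[j], ka = m.kalpha[j], lm = m.lmean[j];
    double local = 0;
    double p_k = (E >= ke) ? 1.0 - 1.0 / m.jump[j] : 0.0;
    if (rng.unif() < p_k) {
      double Eel = E - ke;
      push_electron(rng, hs, p, Eel, medium);
      if (rng.unif() < om) {
        // K-alpha fluorescence; residual L binding deposited locally
        if (ka > cutoff) {
          Particle ph;
          ph.kind = 0; ph.E = ka;
          for (int i = 0; i < 3; ++i) ph.p[i] = p[i];
          iso_dir(rng, ph.d);
          stack.push_back(ph);
          hs.n_secondaries++;
          local += ke - ka;
        } else local += ke;
      } else if (auger_electron) {
        double Ea = ke - 2.0 * lm;
        if (Ea > cutoff) {
          push_electron(rng, hs, p, Ea, medium);
          local += ke - Ea;
        } else local += ke;
      } else {
        local += ke;
      }
    } else {
      double b = std::min(lm, E);
      push_electron(rng, hs, p, E - b, medium);
      local += b;
    }
    if (local > 0) deposit(hs, p, local, medium);
  }

  void push_electron(XRng &rng, HistScore &hs, const double *p, double E,
                     int medium) {
    if (E <= 0) return;
    if (E <= cutoff) { deposit(hs, p, E, medium); return; }
    Particle el;
    el.kind = 1; el.E = E;
    for (int i = 0; i < 3; ++i) el.p[i] = p[i];
    iso_dir(rng, el.d);
    stack.push_back(el);
    hs.n_secondaries++;
  }

  // condensed-history electron walk; returns path length (for oracles)
  double walk_electron(XRng &rng, HistScore &hs, Particle e) {
    double path = 0;
    int body;
    for (;;) {
      int med = G.locate(e.p, &body);
      if (med < 0) { hs.escaped += e.E; break; }
      double step;
      bool in_air = (med == G.m_world);
      if (in_air) step = std::min(std::max(0.9 * G.safety(e.p), estep), 1000.0);
      else step = estep;
      double S = mats[med].stop(e.E);
      double mid[3];
      if (S <= 1e-12) { // transparent medium: drift without loss
        for (int i = 0; i < 3; ++i) e.p[i] += step * e.d[i];
        path += step;
        continue;
      }
      // the step's energy loss is scored to the medium whose stopping
      // power was applied (the medium at the step start), at the midpoint
      double dE = S * step;
      if (dE >= e.E - cutoff) { // terminal (partial) step
        double s2 = std::min(step, (e.E - cutoff) / S + 1e-12);
        for (int i = 0; i < 3; ++i) mid[i] = e.p[i] + 0.5 * s2 * e.d[i];
        deposit(hs, mid, e.E, med);
        path += s2;
        break;
      }
      for (int i = 0; i < 3; ++i) mid[i] = e.p[i] + 0.5 * step * e.d[i];
      deposit(hs, mid, dE, med);
      for (int i = 0; i < 3; ++i) e.p[i] += step * e.d[i];
      e.E -= dE;
      path += step;
      // Gaussian small-angle multiple scattering; variance chosen so the
      // straight-line/path detour factor over a full range is ~0.6
      double R = mats[med].range(e.E);
      if (R > 0 && !in_air) {
        double s2ang = ms_k * step / std::max(R, step);
        rotate_dir(rng, e.d, std::cos(rng.norm() * std::sqrt(s2ang)));
      }
    }
    return path;
  }

  // analog photon tracking from current position; records first interaction
  // if not yet recorded
  void track_photon(XRng &rng, HistScore &hs, Particle ph) {
    std::vector<Seg> segs;
    for (;;) {
      if (ph.E <= cutoff) {
        int b, med = G.locate(ph.p, &b);
        deposit(hs, ph.p, ph.E, med);
        return;
      }
      G.ray_segments(ph.p, ph.d, segs);
      double target = -std::log(rng.unif_pos());
      double cum = 0, tint = -1;
      int imed = -1, ibody = -1;
      for (const Seg &s : segs) {
        double mu = mats[s.medium].mu_tot(ph.E);
        double tau = mu * (s.t1 - s.t0);
        if (cum + tau >= target && mu > 0) {
          tint = s.t0 + (target - cum) / mu;
          imed = s.medium;
          ibody = s.body;
          break;
        }
        cum += tau;
      }
      if (tint < 0) { hs.escaped += ph.E; return; }
      double ip[3];
      for (int i = 0; i < 3; ++i) ip[i] = ph.p[i] + tint * ph.d[i];
      int chan = sample_channel(rng, imed, ph.E);
      if (!hs.has_first && (chan != 2 || tag_rayleigh)) {
        hs.has_first = true;
        hs.first_medium = imed;
        hs.first_body = ibody;
        hs.first_channel = chan;
        G.anchor_of(imed, ibody, ip, hs.first_anchor);
      }
      if (chan == 0) {
        do_photoelectric(rng, hs, ip, ph.E, imed);
        return;
      } else if (chan == 1) {
        double ct, Eout;
        sample_compton(rng, ph.E, ct, Eout);
        double Eel = ph.E - Eout;
        if (Eel > 0) {
          Particle el;
          el.kind = 1;
          el.E = Eel;
          for (int i = 0; i < 3; ++i) el.p[i] = ip[i];
          // recoil direction from Compton kinematics
          double k = ph.E / MEC2;
          double tan_half = std::sqrt(std::max(0.0, (1 - ct) / (1 + ct)));
          double phie = std::atan(1.0 / std::max(1e-12, (1 + k) * tan_half));
          for (int i = 0; i < 3; ++i) el.d[i] = ph.d[i];
          rotate_dir(rng, el.d, std::cos(phie));
          if (el.E > cutoff) {
            stack.push_back(el);
            hs.n_secondaries++;
          } else deposit(hs, ip, el.E, imed);
        }
        for (int i = 0; i < 3; ++i) ph.p[i] = ip[i];
        rotate_dir(rng, ph.d, ct);
        ph.E = Eout;
      } else {
        for (int i = 0; i < 3; ++i) ph.p[i] = ip[i];
        rotate_dir(rng, ph.d, sample_thomson(rng));
      }
    }
  }

  void drain_stack(XRng &rng, HistScore &hs) {
    while (!stack.empty()) {
      if (hs.n_secondaries > max_secondaries) {
        hs.excluded = true;
        stack.clear();
        return;
      }
      Particle p = stack.back();
      stack.pop_back();
      if (p.kind == 0) track_photon(rng, hs, p);
      else walk_electron(rng, hs, p);
    }
  }
};

// ------------------------------------------------------------- exports ----

// [[Rcpp::export]]
List cpp_locate(List geom, NumericMatrix pts) {
  Geom G = geom_from_list(geom);
  int n = pts.nrow();
  IntegerVector med(n), body(n);
  for (int i = 0; i < n; ++i) {
    double p[3] = {pts(i, 0), pts(i, 1), pts(i, 2)};
    int b;
    med[i] = G.locate(p, &b);
    body[i] = b;
  }
  return List::create(_["medium"] = med, _["body"] = body);
}

// [[Rcpp::export]]
DataFrame cpp_ray_segments(List geom, NumericVector origin, NumericVector dir) {
  Geom G = geom_from_list(geom);
  double p[3] = {origin[0], origin[1], origin[2]};
  double d[3] = {dir[0], dir[1], dir[2]};
  std::vector<Seg> segs;
  G.ray_segments(p, d, segs);
  int n = segs.size();
  NumericVector t0(n), t1(n), len(n);
  IntegerVector med(n), body(n);
  for (int i = 0; i < n; ++i) {
    t0[i] = segs[i].t0;
    t1[i] = segs[i].t1;
    len[i] = segs[i].t1 - segs[i].t0;
    med[i] = segs[i].medium;
    body[i] = segs[i].body;
  }
  return DataFrame::create(_["t0"] = t0, _["t1"] = t1, _["length"] = len,
                           _["medium"] = med, _["body"] = body);
}

// [[Rcpp::export]]
DataFrame cpp_sample_compton(int n, double energy, double seed) {
  XRng rng((uint64_t)seed, 0xC0317ULL);
  NumericVector ct(n), eo(n);
  for (int i = 0; i < n; ++i) sample_compton(rng, energy, ct[i], eo[i]);
  return DataFrame::create(_["cos_theta"] = ct, _["energy_out"] = eo);
}

// [[Rcpp::export]]
NumericVector cpp_sample_thomson(int n, double seed) {
  XRng rng((uint64_t)seed, 0x7103ULL);
  NumericVector ct(n);
  for (int i = 0; i < n; ++i) ct[i] = sample_thomson(rng);
  return ct;
}

// [[Rcpp::export]]
List cpp_transport_electron(List geom, List mats, NumericVector start,
                            NumericVector dir, double energy, List run,
                            double seed) {
  Engine eng;
  eng.G = geom_from_list(geom);
  for (R_xlen_t i = 0; i < mats.size(); ++i)
    eng.mats.push_back(mat_from_list(mats[i]));
  eng.cutoff = as<double>(run["cutoff"]);
  eng.estep = as<double>(run["electron_step"]);
  eng.ms_k = as<double>(run["ms_k"]);
  XRng rng((uint64_t)seed, 0xE1ECULL);
  HistScore hs;
  Particle e;
  e.kind = 1;
  e.E = energy;
  for (int i = 0; i < 3; ++i) {
    e.p[i] = start[i];
    e.d[i] = dir[i];
  }
  double path = eng.walk_electron(rng, hs, e);
  int n = hs.evts.size();
  NumericVector x(n), y(n), z(n), E(n);
  IntegerVector med(n);
  for (int i = 0; i < n; ++i) {
    x[i] = hs.evts[i].p[0];
    y[i] = hs.evts[i].p[1];
    z[i] = hs.evts[i].p[2];
    E[i] = hs.evts[i].E;
    med[i] = hs.evts[i].medium;
  }
  return List::create(
      _["deposits"] = DataFrame::create(_["x"] = x, _["y"] = y, _["z"] = z,
                                        _["energy_keV"] = E, _["medium"] = med),
      _["path_length"] = path, _["escaped"] = hs.escaped);
}

// [[Rcpp::export]]
List cpp_run_transport(List geom, List mats, List beam, List run) {
  Engine eng;
  eng.G = geom_from_list(geom);
  int nmat = mats.size();
  for (int i = 0; i < nmat; ++i) eng.mats.push_back(mat_from_list(mats[i]));
  eng.cutoff = as<double>(run["cutoff"]);
  eng.estep = as<double>(run["electron_step"]);
  eng.ms_k = as<double>(run["ms_k"]);
  eng.max_secondaries = as<int>(run["max_secondaries"]);
  eng.tag_rayleigh = as<bool>(run["tag_rayleigh"]);
  eng.auger_electron = as<std::string>(run["relaxation"]) == "single-auger";

  int n_hist = as<int>(run["n_histories"]);
  uint64_t seed = (uint64_t)as<double>(run["seed"]);
  bool forced = as<std::string>(run["mode"]) == "forced";
  bool rec_hist = as<bool>(run["record_histories"]);
  int rec_events = as<int>(run["record_events"]);
  int nbatch = as<int>(run["nbatch"]);
  double rbin = as<double>(run["r_bin_width"]);
  double rmax = as<double>(run["r_max"]);
  int powder_anchor_first = as<int>(run["powder_anchor_first"]);
  int nbin = (int)std::ceil(rmax / rbin) + 1; // last bin = overflow

  double E0 = as<double>(beam["energy"]);
  NumericVector bdir = beam["direction"];
  double beam_r = as<double>(beam["radius"]);
  double backoff = as<double>(beam["backoff"]);
  bool air_column = as<bool>(beam["air_column"]);
  double tau_column = as<double>(beam["tau_column"]); // 15 cm air optical depth
  double dir0[3] = {bdir[0], bdir[1], bdir[2]};
  // beam frame
  double e1[3], e2[3];
  {
    double tmp[3] = {dir0[0], dir0[1], dir0[2]};
    if (std::fabs(tmp[2]) < 0.99) { e1[0] = -tmp[1]; e1[1] = tmp[0]; e1[2] = 0; }
    else { e1[0] = 0; e1[1] = -tmp[2]; e1[2] = tmp[1]; }
    double n1 = std::sqrt(e1[0] * e1[0] + e1[1] * e1[1] + e1[2] * e1[2]);
    for (int i = 0; i < 3; ++i) e1[i] /= n1;
    e2[0] = tmp[1] * e1[2] - tmp[2] * e1[1];
    e2[1] = tmp[2] * e1[0] - tmp[0] * e1[2];
    e2[2] = tmp[0] * e1[1] - tmp[1] * e1[0];
  }

  // media indices for partition: engine media are material indices
  std::vector<double> edep_w(nmat, 0.0);
  double escaped_w = 0, sum_w = 0, sum_w_int = 0;
  long n_int = 0, n_excluded = 0, n_noncons = 0;
  NumericMatrix batch_dep(nbatch, nmat);
  std::vector<double> batch_w(nbatch, 0.0);
  // radial histograms: row 0 = first in host/core medium, row 1 = first in
  // NP/shell medium
  NumericMatrix radial(2, nbin);
  // optional per-history table
  std::vector<double> h_w, h_esc;
  std::vector<int> h_fm, h_fb, h_fc;
  std::vector<std::vector<double>> h_dep(nmat);
  // optional events
  std::vector<double> ev_x, ev_y, ev_z, ev_E, ev_w, ev_fx, ev_fy, ev_fz;
  std::vector<int> ev_med, ev_fm;

  int m_sio2 = (eng.G.kind == 1) ? eng.G.m_host : eng.G.m_core;
  int m_zno = (eng.G.kind == 1) ? eng.G.m_np : eng.G.m_shell;

  HistScore hs;
  std::vector<Seg> segs;
  for (int h = 0; h < n_hist; ++h) {
    if (h % 8192 == 0) Rcpp::checkUserInterrupt();
    XRng rng(seed, (uint64_t)h);
    hs.reset();
    eng.stack.clear();
    double w = 1.0;
    bool interacted = false;
    // sample ray
    double r = beam_r * std::sqrt(rng.unif());
    double phi = TWO_PI * rng.unif();
    double p0[3], d[3] = {dir0[0], dir0[1], dir0[2]};
    for (int i = 0; i < 3; ++i)
      p0[i] = r * (std::cos(phi) * e1[i] + std::sin(phi) * e2[i]) -
              backoff * dir0[i];
    eng.G.ray_segments(p0, d, segs);

    if (forced) {
      double T = 0, tau_pre = 0;
      bool seen_solid = false;
      for (const Seg &s : segs) {
        double tau = eng.mats[s.medium].mu_tot(E0) * (s.t1 - s.t0);
        if (s.medium == eng.G.m_world) {
          if (!seen_solid) tau_pre += tau;
        } else {
          seen_solid = true;
          T += tau;
        }
      }
      if (T <= 0) {
        w = 0; // ray misses every solid: zero-weight history, no events
      } else {
        w = 1.0 - std::exp(-T);
        if (air_column) w *= std::exp(-(tau_pre + tau_column));
        double target = -std::log(1.0 - rng.unif() * (1.0 - std::exp(-T)));
        double cum = 0, tint = -1;
        int imed = -1, ibody = -1;
        for (const Seg &s : segs) {
          if (s.medium == eng.G.m_world) continue;
          double mu = eng.mats[s.medium].mu_tot(E0);
          double tau = mu * (s.t1 - s.t0);
          if (cum + tau >= target && mu > 0) {
            tint = s.t0 + (target - cum) / mu;
            imed = s.medium;
            ibody = s.body;
            break;
          }
          cum += tau;
        }
        if (tint < 0) { // numerical tail: force into last solid segment
          for (auto it = segs.rbegin(); it != segs.rend(); ++it)
            if (it->medium != eng.G.m_world) {
              tint = it->t1;
              imed = it->medium;
              ibody = it->body;
              break;
            }
        }
        interacted = true;
        double ip[3];
        for (int i = 0; i < 3; ++i) ip[i] = p0[i] + tint * d[i];
        int chan = eng.sample_channel(rng, imed, E0);
        if (chan != 2 || eng.tag_rayleigh) {
          hs.has_first = true;
          hs.first_medium = imed;
          hs.first_body = ibody;
          hs.first_channel = chan;
          eng.G.anchor_of(imed, ibody, ip, hs.first_anchor);
        }
        if (chan == 0) {
          eng.do_photoelectric(rng, hs, ip, E0, imed);
        } else if (chan == 1) {
          double ct, Eout;
          sample_compton(rng, E0, ct, Eout);
          double Eel = E0 - Eout;
          Particle el;
          el.kind = 1;
          el.E = Eel;
          for (int i = 0; i < 3; ++i) el.p[i] = ip[i];
          double k = E0 / MEC2;
          double tan_half = std::sqrt(std::max(0.0, (1 - ct) / (1 + ct)));
          double phie = std::atan(1.0 / std::max(1e-12, (1 + k) * tan_half));
          for (int i = 0; i < 3; ++i) el.d[i] = d[i];
          rotate_dir(rng, el.d, std::cos(phie));
          if (el.E > eng.cutoff) {
            eng.stack.push_back(el);
            hs.n_secondaries++;
          } else eng.deposit(hs, ip, el.E, imed);
          Particle ph;
          ph.kind = 0;
          ph.E = Eout;
          for (int i = 0; i < 3; ++i) { ph.p[i] = ip[i]; ph.d[i] = d[i]; }
          rotate_dir(rng, ph.d, ct);
          if (ph.E > eng.cutoff) {
            eng.stack.push_back(ph);
          } else eng.deposit(hs, ip, ph.E, imed);
        } else {
          Particle ph;
          ph.kind = 0;
          ph.E = E0;
          for (int i = 0; i < 3; ++i) { ph.p[i] = ip[i]; ph.d[i] = d[i]; }
          rotate_dir(rng, ph.d, sample_thomson(rng));
          eng.stack.push_back(ph);
        }
        eng.drain_stack(rng, hs);
      }
    } else { // analog
      bool absorbed_upstream = false;
      if (air_column && rng.unif() > std::exp(-tau_column))
        absorbed_upstream = true;
      if (absorbed_upstream) {
        hs.escaped = E0;
      } else {
        Particle ph;
        ph.kind = 0;
        ph.E = E0;
        for (int i = 0; i < 3; ++i) { ph.p[i] = p0[i]; ph.d[i] = d[i]; }
        eng.track_photon(rng, hs, ph);
        eng.drain_stack(rng, hs);
        interacted = hs.has_first && hs.first_medium != eng.G.m_world &&
                     hs.first_medium >= 0;
      }
    }

    // conservation bookkeeping (unweighted, interacting branch)
    if (!hs.excluded && (interacted || !forced) && w > 0) {
      double tot = hs.dep_total() + hs.escaped;
      double expect = E0;
      if (std::fabs(tot - expect) > 1e-9 * expect) n_noncons++;
    }
    if (hs.excluded) {
      n_excluded++;
      // excluded histories contribute nothing
      hs.evts.clear();
      hs.escaped = 0;
      w = forced ? 0.0 : w;
    }

    sum_w += w;
    if (interacted && w > 0) {
      sum_w_int += w;
      n_int++;
    }
    int b = (int)(((long long)h * nbatch) / n_hist);
    batch_w[b] += w;
    // commit events
    for (const Evt &e : hs.evts) {
      edep_w[e.medium] += w * e.E;
      batch_dep(b, e.medium) += w * e.E;
      if (hs.has_first) {
        int row = -1;
        if (hs.first_medium == m_sio2) row = 0;
        else if (hs.first_medium == m_zno) row = 1;
        if (row >= 0) {
          double ax = hs.first_anchor[0], ay = hs.first_anchor[1],
                 az = hs.first_anchor[2];
          if (eng.G.kind == 2 && !powder_anchor_first) {
            int nc = eng.G.nearest_center(e.p);
            if (nc >= 0) { ax = eng.G.cx[nc]; ay = eng.G.cy[nc]; az = eng.G.cz[nc]; }
          }
          double dx = e.p[0] - ax, dy = e.p[1] - ay, dz = e.p[2] - az;
          double rr = std::sqrt(dx * dx + dy * dy + dz * dz);
          int bin = (int)(rr / rbin);
          if (bin >= nbin - 1) bin = nbin - 1;
          radial(row, bin) += w * e.E;
        }
      }
      if ((int)ev_x.size() < rec_events && w > 0) {
        ev_x.push_back(e.p[0]); ev_y.push_back(e.p[1]); ev_z.push_back(e.p[2]);
        ev_E.push_back(e.E); ev_med.push_back(e.medium);
        ev_fm.push_back(hs.first_medium); ev_w.push_back(w);
        ev_fx.push_back(hs.first_anchor[0]); ev_fy.push_back(hs.first_anchor[1]);
        ev_fz.push_back(hs.first_anchor[2]);
      }
    }
    escaped_w += w * hs.escaped;
    if (rec_hist) {
      h_w.push_back(w);
      h_esc.push_back(w * hs.escaped);
      h_fm.push_back(hs.first_medium);
      h_fb.push_back(hs.first_body);
      h_fc.push_back(hs.first_channel);
      std::vector<double> dep(nmat, 0.0);
      for (const Evt &e : hs.evts) dep[e.medium] += w * e.E;
      for (int mIdx = 0; mIdx < nmat; ++mIdx) h_dep[mIdx].push_back(dep[mIdx]);
    }
  }

  List out = List::create(
      _["n_histories"] = n_hist, _["sum_weight"] = sum_w,
      _["sum_weight_interacting"] = sum_w_int, _["n_interacting"] = (double)n_int,
      _["n_excluded"] = (double)n_excluded,
      _["n_conservation_fail"] = (double)n_noncons,
      _["edep_weighted"] = NumericVector(edep_w.begin(), edep_w.end()),
      _["escaped_weighted"] = escaped_w, _["radial"] = radial,
      _["batch_dep"] = batch_dep,
      _["batch_w"] = NumericVector(batch_w.begin(), batch_w.end()));
  if (rec_hist) {
    List hd = List::create(
        _["weight"] = NumericVector(h_w.begin(), h_w.end()),
        _["first_medium"] = IntegerVector(h_fm.begin(), h_fm.end()),
        _["first_body"] = IntegerVector(h_fb.begin(), h_fb.end()),
        _["first_channel"] = IntegerVector(h_fc.begin(), h_fc.end()),
        _["escaped"] = NumericVector(h_esc.begin(), h_esc.end()));
    for (int mIdx = 0; mIdx < nmat; ++mIdx)
      hd.push_back(NumericVector(h_dep[mIdx].begin(), h_dep[mIdx].end()),
                   std::string("edep_m") + std::to_string(mIdx));
    out["histories"] = hd;
  }
  if (rec_events > 0) {
    out["events"] = DataFrame::create(
        _["x"] = NumericVector(ev_x.begin(), ev_x.end()),
        _["y"] = NumericVector(ev_y.begin(), ev_y.end()),
        _["z"] = NumericVector(ev_z.begin(), ev_z.end()),
        _["energy_keV"] = NumericVector(ev_E.begin(), ev_E.end()),
        _["medium"] = IntegerVector(ev_med.begin(), ev_med.end()),
        _["first_medium"] = IntegerVector(ev_fm.begin(), ev_fm.end()),
        _["anchor_x"] = NumericVector(ev_fx.begin(), ev_fx.end()),
        _["anchor_y"] = NumericVector(ev_fy.begin(), ev_fy.end()),
        _["anchor_z"] = NumericVector(ev_fz.begin(), ev_fz.end()),
        _["weight"] = NumericVector(ev_w.begin(), ev_w.end()));
  }
  return out;
}
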