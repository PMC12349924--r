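// Core molecular-dynamics engine for the solvent-free three-bead lipid model.
//
// Bead kinds (integer codes shared with R):
//   0 HEAD, 1 TAIL1, 2 TAIL2, 3 CARGO, 4 ROBOT_CORE, 5 ROBOT_SPIKE,
//   6 RECEPTOR_HEAD
// Bond types: 1 FENE, 2 harmonic head--tail2 straightening spring.
//
// Positions are kept unwrapped; periodic images enter only through
// minimum-image distances and cell binning.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
#include <algorithm>
#include <chrono>

using namespace Rcpp;

static const int N_KINDS = 7;

enum PairType { PT_NONE = 0, PT_WCA = 1, PT_WCA_COS = 2, PT_LJ = 3 };

struct PairRuleC {
  int type;
  double b2;       // squared length parameter
  double eps;
  double wca_rc2;  // squared repulsive cutoff (2^(1/3) b2)
  double wca_shift;
  double lj_rc2;
  double lj_shift;
  double cut2;     // outermost interaction cutoff, squared
};

struct FFParams {
  double b_hh, b_ht, b_tt;
  double eps_rep;
  bool   rep_shifted;
  double eps_cos, rc, wc;
  double k_fene, r_inf;
  double k_bend, r0_bend;
  double eps_np, b_np, rcut_np;
  double eps_receptor;
  double b_cargo;
};

static inline bool is_robot(int k) { return k == 4 || k == 5; }
static inline bool is_big(int k)   { return k >= 3 && k <= 5; }
static inline bool is_lipid(int k) { return k == 0 || k == 1 || k == 2 || k == 6; }
static inline bool is_headlike(int k) { return k == 0 || k == 6; }
static inline bool is_tail(int k)  { return k == 1 || k == 2; }

static FFParams parse_ff(const List& p) {
  FFParams f;
  f.b_hh = as<double>(p["b_head_head"]);
  f.b_ht = as<double>(p["b_head_tail"]);
  f.b_tt = as<double>(p["b_tail_tail"]);
  f.eps_rep = as<double>(p["eps_rep"]);
  f.rep_shifted = as<bool>(p["rep_shifted"]);
  f.eps_cos = as<double>(p["eps_cos"]);
  f.rc = as<double>(p["rc"]);
  f.wc = as<double>(p["wc"]);
  f.k_fene = as<double>(p["k_fene"]);
  f.r_inf = as<double>(p["r_inf"]);
  f.k_bend = as<double>(p["k_bend"]);
  f.r0_bend = as<double>(p["r0_bend"]);
  f.eps_np = as<double>(p["eps_np"]);
  f.b_np = as<double>(p["b_np"]);
  f.rcut_np = as<double>(p["rcut_np"]);
  f.eps_receptor = as<double>(p["eps_receptor"]);
  f.b_cargo = as<double>(p["b_cargo"]);
  return f;
}

static void set_wca(PairRuleC& r, double b, double eps, bool shifted) {
  r.type = PT_WCA;
  r.b2 = b * b;
  r.eps = eps;
  r.wca_rc2 = std::cbrt(2.0) * r.b2;       // (2^(1/6) b)^2
  r.wca_shift = shifted ? eps : 0.0;
}

static void set_lj(PairRuleC& r, double b, double eps, double rcut) {
  r.type = PT_LJ;
  r.b2 = b * b;
  r.eps = eps;
  r.lj_rc2 = rcut * rcut;
  double s2 = r.b2 / r.lj_rc2, s6 = s2 * s2 * s2;
  r.lj_shift = 4.0 * eps * (s6 * s6 - s6);  // value at the cutoff, removed
}

// Build the symmetric kind-pair rule table.
static std::vector<PairRuleC> build_rules(const FFParams& f) {
  std::vector<PairRuleC> rules(N_KINDS * N_KINDS);
  for (auto& r : rules) { r.type = PT_NONE; r.b2 = r.eps = 0; r.wca_rc2 = r.lj_rc2 = 0; r.wca_shift = r.lj_shift = 0; r.cut2 = 0; }
  for (int a = 0; a < N_KINDS; ++a) {
    for (int b = a; b < N_KINDS; ++b) {
      PairRuleC r; r.type = PT_NONE; r.b2 = 0; r.eps = 0; r.wca_rc2 = 0; r.wca_shift = 0; r.lj_rc2 = 0; r.lj_shift = 0; r.cut2 = 0;
      bool la = is_lipid(a), lb = is_lipid(b);
      if (la && lb) {
        if (is_tail(a) && is_tail(b)) {
          set_wca(r, f.b_tt, f.eps_rep, f.rep_shifted);
          r.type = PT_WCA_COS;
        } else if (is_headlike(a) && is_headlike(b)) {
          set_wca(r, f.b_hh, f.eps_rep, f.rep_shifted);
        } else {
          set_wca(r, f.b_ht, f.eps_rep, f.rep_shifted);
        }
      } else if ((a == 3 && lb) || (la && b == 3)) {
        set_lj(r, f.b_np, f.eps_np, f.rcut_np);           // cargo--membrane
      } else if ((is_robot(a) && lb) || (la && is_robot(b))) {
        int rob = is_robot(a) ? a : b;
        int lip = is_robot(a) ? b : a;
        if (rob == 5 && lip == 6)
          set_lj(r, f.b_np, f.eps_receptor, f.rcut_np);   // receptor--spike adhesion
        else
          set_lj(r, f.b_np, f.eps_np, f.rcut_np);         // robot--membrane
      } else if (a == 3 && b == 3) {
        set_wca(r, f.b_cargo, f.eps_rep, true);           // cargo--cargo, always shifted
      } else if ((a == 3 && is_robot(b)) || (is_robot(a) && b == 3)) {
        set_wca(r, f.b_np, f.eps_rep, true);              // cargo--robot excluded volume
      } // robot--robot: none (rigid body)
      if (r.type == PT_LJ) r.cut2 = r.lj_rc2;
      else if (r.type == PT_WCA_COS) { double ro = f.rc + f.wc; r.cut2 = ro * ro; }
      else if (r.type == PT_WCA) r.cut2 = r.wca_rc2;
      rules[a * N_KINDS + b] = r;
      rules[b * N_KINDS + a] = r;
    }
  }
  return rules;
}

// ---------------------------------------------------------------------------
// deterministic counter-based gaussians (splitmix64 + Box-Muller)

static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

static inline double u01(uint64_t z) {
  return (double)((z >> 11) + 1) * (1.0 / 9007199254740993.0); // (0,1)
}

// three standard normals for (seed, step, bead)
static inline void gauss3(uint64_t seed, uint64_t step, uint64_t bead, double* g) {
  uint64_t base = seed ^ (step * 0x9E3779B97F4A7C15ULL) ^ ((bead + 1) * 0xC2B2AE3D27D4EB4FULL);
  double u1 = u01(splitmix64(base));
  double u2 = u01(splitmix64(base ^ 0x94D049BB133111EBULL));
  double u3 = u01(splitmix64(base ^ 0xD6E8FEB86659FD93ULL));
  double u4 = u01(splitmix64(base ^ 0xA0761D6478BD642FULL));
  double r1 = std::sqrt(-2.0 * std::log(u1));
  double r2 = std::sqrt(-2.0 * std::log(u3));
  g[0] = r1 * std::cos(2.0 * M_PI * u2);
  g[1] = r1 * std::sin(2.0 * M_PI * u2);
  g[2] = r2 * std::cos(2.0 * M_PI * u4);
}

static inline double gauss1(uint64_t seed, uint64_t step, uint64_t salt) {
  uint64_t base = seed ^ (step * 0xD1342543DE82EF95ULL) ^ (salt * 0x9E3779B97F4A7C15ULL);
  double u1 = u01(splitmix64(base));
  double u2 = u01(splitmix64(base ^ 0x94D049BB133111EBULL));
  return std::sqrt(-2.0 * std::log(u1)) * std::cos(2.0 * M_PI * u2);
}

// ---------------------------------------------------------------------------
// pair kernel: energy + fr such that force_on_i = fr * (ri - rj)

static inline void eval_pair(const PairRuleC& rule, const FFParams& ff,
                             double r2, double& u, double& fr) {
  u = 0.0; fr = 0.0;
  if (rule.type == PT_NONE) return;
  if (rule.type == PT_LJ) {
    if (r2 < rule.lj_rc2) {
      double s2 = rule.b2 / r2, s6 = s2 * s2 * s2, s12 = s6 * s6;
      u = 4.0 * rule.eps * (s12 - s6) - rule.lj_shift;
      fr = 24.0 * rule.eps * (2.0 * s12 - s6) / r2;
    }
    return;
  }
  // WCA part
  if (r2 < rule.wca_rc2) {
    double s2 = rule.b2 / r2, s6 = s2 * s2 * s2, s12 = s6 * s6;
    u = 4.0 * rule.eps * (s12 - s6) + rule.wca_shift;
    fr = 24.0 * rule.eps * (2.0 * s12 - s6) / r2;
  }
  if (rule.type == PT_WCA_COS) {
    double rc = ff.rc, wc = ff.wc;
    double rout = rc + wc;
    if (r2 < rc * rc) {
      u += -ff.eps_cos;
    } else if (r2 < rout * rout) {
      double r = std::sqrt(r2);
      double x = M_PI * (r - rc) / (2.0 * wc);
      double c = std::cos(x);
      u += -ff.eps_cos * c * c;
      // dU/dr = eps * (pi/(2 wc)) * sin(2x); force_i = -dU/dr * rhat
      fr += -ff.eps_cos * (M_PI / (2.0 * wc)) * std::sin(2.0 * x) / r;
    }
  }
}

// ---------------------------------------------------------------------------
// tabulated pair kernel: cubic Hermite interpolation of u(r2) and du/d(r2)
// on a uniform r2 grid per distinct rule; exact analytic evaluation below
// a safety floor (never visited in practice) and for table construction.

struct PairTable {
  double tmin, h, inv_h, cut2;
  int n;
  std::vector<double> ug;     // interleaved (u, g) at knots; g = dU/d(r2)
};

static const int TABLE_N = 4096;

static PairTable build_table(const PairRuleC& rule, const FFParams& ff) {
  PairTable t;
  t.cut2 = rule.cut2;
  t.tmin = 0.3 * rule.b2;
  t.n = TABLE_N;
  t.h = (t.cut2 - t.tmin) / t.n;
  t.inv_h = 1.0 / t.h;
  t.ug.resize(2 * (t.n + 1));
  for (int k = 0; k <= t.n; ++k) {
    double r2 = t.tmin + k * t.h;
    double uu, fr;
    eval_pair(rule, ff, r2, uu, fr);
    t.ug[2 * k] = uu;
    t.ug[2 * k + 1] = -0.5 * fr;             // dU/d(r2) = -fr/2
  }
  return t;
}

// energy and fr (= -2 dU/d(r2)) from the table
static inline void eval_table(const PairTable& t, double r2, double& u, double& fr) {
  int k = (int)((r2 - t.tmin) * t.inv_h);
  if (k < 0) k = 0; else if (k >= t.n) k = t.n - 1;
  double x = (r2 - (t.tmin + k * t.h)) * t.inv_h;  // in [0,1]
  double x2 = x * x, x3 = x2 * x;
  double h00 = 2 * x3 - 3 * x2 + 1, h10 = x3 - 2 * x2 + x;
  double h01 = -2 * x3 + 3 * x2,    h11 = x3 - x2;
  const double* p0 = &t.ug[2 * k];
  double u0 = p0[0], u1 = p0[2];
  double g0 = p0[1] * t.h, g1 = p0[3] * t.h;
  u = h00 * u0 + h10 * g0 + h01 * u1 + h11 * g1;
  double du = (6 * x2 - 6 * x) * u0 + (3 * x2 - 4 * x + 1) * g0 +
              (-6 * x2 + 6 * x) * u1 + (3 * x2 - 2 * x) * g1;
  fr = -2.0 * du * t.inv_h;
}

// ---------------------------------------------------------------------------
// simulation state

struct Sim {
  int N;
  std::vector<double> x, v, fbuf;      // 3N, unwrapped positions
  std::vector<double> w;               // 3N, wrapped shadow of x (force path)
  std::vector<int> kind;
  std::vector<int> bond_i, bond_j, bond_t;
  double box[3];
  FFParams ff;
  std::vector<PairRuleC> rules;
  std::vector<PairTable> tables;
  std::vector<int> table_of;          // rule index -> table id (-1 none)

  void build_tables() {
    table_of.assign(rules.size(), -1);
    std::vector<int> src_rule;
    for (size_t r = 0; r < rules.size(); ++r) {
      if (rules[r].type == PT_NONE) continue;
      int found = -1;
      for (size_t t = 0; t < src_rule.size(); ++t) {
        const PairRuleC& a = rules[src_rule[t]];
        const PairRuleC& b = rules[r];
        if (a.type == b.type && a.b2 == b.b2 && a.eps == b.eps &&
            a.wca_shift == b.wca_shift && a.lj_rc2 == b.lj_rc2 &&
            a.cut2 == b.cut2) { found = (int)t; break; }
      }
      if (found < 0) {
        tables.push_back(build_table(rules[r], ff));
        src_rule.push_back((int)r);
        found = (int)tables.size() - 1;
      }
      table_of[r] = found;
    }
  }

  // rigid robot
  std::vector<int> rob_idx;            // 0-based
  std::vector<double> rob_ref;         // body-frame coords, 3 * nrob
  double rob_center[3];
  double rob_axis[3];

  // neighbor lists
  double cut_small, cut_big, skin;
  double b_hh_len, b_ht_len;
  std::vector<int> small_tt;           // flattened (i,j), tail-tail rule
  std::vector<int> small_other;        // flattened (i,j), other lipid pairs
  std::vector<int> big_pairs;
  std::vector<double> x_at_build;
  std::vector<int> small_idx, big_idx; // bead index subsets

  // bookkeeping
  double pe, wxx, wyy, wzz;
  int n_mobile;

  bool overstretch;
  int bad_bond_i, bad_bond_j; long bad_step;

  Sim() : overstretch(false), bad_bond_i(-1), bad_bond_j(-1), bad_step(-1) {}

  // minimum image for differences of wrapped coordinates (|d| < L)
  inline void minimg(double& dx, double& dy, double& dz) const {
    const double hx = 0.5 * box[0], hy = 0.5 * box[1], hz = 0.5 * box[2];
    if (dx > hx) dx -= box[0]; else if (dx < -hx) dx += box[0];
    if (dy > hy) dy -= box[1]; else if (dy < -hy) dy += box[1];
    if (dz > hz) dz -= box[2]; else if (dz < -hz) dz += box[2];
  }

  inline void rewrap_bead(int i) {
    for (int k = 0; k < 3; ++k) {
      double& c = w[3 * i + k];
      c -= box[k] * std::floor(c / box[k]);
    }
  }
  void rewrap_all() { for (int i = 0; i < N; ++i) rewrap_bead(i); }

  void classify() {
    small_idx.clear(); big_idx.clear();
    for (int i = 0; i < N; ++i) (is_big(kind[i]) ? big_idx : small_idx).push_back(i);
    n_mobile = 0;
    for (int i = 0; i < N; ++i) if (!is_robot(kind[i])) ++n_mobile;
  }

  void build_lists() {
    small_tt.clear(); small_other.clear(); big_pairs.clear();
    const double rl_s = cut_small + skin, rl_b = cut_big + skin;
    const double rl_s2 = rl_s * rl_s, rl_b2 = rl_b * rl_b;
    // head-involving lipid pairs interact only through the short WCA core
    double bmax_h = std::max(b_hh_len, b_ht_len);
    double rl_h = std::pow(2.0, 1.0 / 6.0) * bmax_h + skin;
    const double rl_h2 = rl_h * rl_h;

    // cell list over all beads at the small cutoff scale
    int ncx = std::max(1, (int)std::floor(box[0] / rl_s));
    int ncy = std::max(1, (int)std::floor(box[1] / rl_s));
    int ncz = std::max(1, (int)std::floor(box[2] / rl_s));
    // avoid degenerate duplicated neighbor cells in tiny boxes
    if (ncx < 3) ncx = 1;
    if (ncy < 3) ncy = 1;
    if (ncz < 3) ncz = 1;
    int ncells = ncx * ncy * ncz;
    std::vector<int> head(ncells, -1), nxt(N, -1);
    std::vector<int> occupied; occupied.reserve(256);
    for (int i = 0; i < N; ++i) {
      int cx = std::min(ncx - 1, std::max(0, (int)(w[3 * i] / box[0] * ncx)));
      int cy = std::min(ncy - 1, std::max(0, (int)(w[3 * i + 1] / box[1] * ncy)));
      int cz = std::min(ncz - 1, std::max(0, (int)(w[3 * i + 2] / box[2] * ncz)));
      int c = (cz * ncy + cy) * ncx + cx;
      if (head[c] < 0) occupied.push_back(c);
      nxt[i] = head[c]; head[c] = i;
    }
    // small-small pairs via cells; deduplicate neighbor cells (wrapped offsets
    // collide when a dimension has fewer than 3 cells)
    small_tt.reserve(60 * small_idx.size());
    for (size_t oc = 0; oc < occupied.size(); ++oc) {
      int c = occupied[oc];
      int cx = c % ncx, cy = (c / ncx) % ncy, cz = c / (ncx * ncy);
      int seen[27]; int nseen = 0;
      for (int dz = -1; dz <= 1; ++dz) for (int dy = -1; dy <= 1; ++dy) for (int dx = -1; dx <= 1; ++dx) {
        int ox = (cx + dx + ncx) % ncx, oy = (cy + dy + ncy) % ncy, oz = (cz + dz + ncz) % ncz;
        int c2 = (oz * ncy + oy) * ncx + ox;
        if (c2 < c) continue;
        bool dup = false;
        for (int q = 0; q < nseen; ++q) if (seen[q] == c2) { dup = true; break; }
        if (dup) continue;
        seen[nseen++] = c2;
        for (int i = head[c]; i >= 0; i = nxt[i]) {
          if (is_big(kind[i])) continue;
          for (int j = (c2 == c ? nxt[i] : head[c2]); j >= 0; j = nxt[j]) {
            if (is_big(kind[j])) continue;
            double ddx = w[3 * i] - w[3 * j], ddy = w[3 * i + 1] - w[3 * j + 1], ddz = w[3 * i + 2] - w[3 * j + 2];
            minimg(ddx, ddy, ddz);
            bool tt = is_tail(kind[i]) && is_tail(kind[j]);
            double lim2 = tt ? rl_s2 : rl_h2;
            if (ddx * ddx + ddy * ddy + ddz * ddz < lim2) {
              if (tt) { small_tt.push_back(i); small_tt.push_back(j); }
              else { small_other.push_back(i); small_other.push_back(j); }
            }
          }
        }
      }
    }
    // big-involving pairs: brute force over big x all
    for (size_t a = 0; a < big_idx.size(); ++a) {
      int i = big_idx[a];
      for (int j = 0; j < N; ++j) {
        if (j == i) continue;
        if (is_big(kind[j]) && j < i) continue;          // count big-big once
        if (is_robot(kind[i]) && is_robot(kind[j])) continue;
        double ddx = w[3 * i] - w[3 * j], ddy = w[3 * i + 1] - w[3 * j + 1], ddz = w[3 * i + 2] - w[3 * j + 2];
        minimg(ddx, ddy, ddz);
        if (ddx * ddx + ddy * ddy + ddz * ddz < rl_b2) {
          big_pairs.push_back(i); big_pairs.push_back(j);
        }
      }
    }
    x_at_build = x;
  }

  bool need_rebuild() const {
    // rebuild when the two largest displacements can close the skin gap
    double m1 = 0, m2 = 0;
    for (int i = 0; i < N; ++i) {
      double dx = x[3 * i] - x_at_build[3 * i];
      double dy = x[3 * i + 1] - x_at_build[3 * i + 1];
      double dz = x[3 * i + 2] - x_at_build[3 * i + 2];
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 > m1) { m2 = m1; m1 = d2; }
      else if (d2 > m2) m2 = d2;
    }
    return std::sqrt(m1) + std::sqrt(m2) > skin;
  }

  // forces from a pair index list sharing one rule (hot path: tail-tail)
  inline void accum_pairs_rule(const std::vector<int>& pairs,
                               const PairRuleC& rule, const PairTable& tab,
                               double* f) {
    const size_t np = pairs.size() / 2;
    const double cut2 = rule.cut2, tmin = tab.tmin;
    const double hx = 0.5 * box[0], hy = 0.5 * box[1], hz = 0.5 * box[2];
    for (size_t k = 0; k < np; ++k) {
      int i = pairs[2 * k], j = pairs[2 * k + 1];
      double dx = w[3 * i] - w[3 * j], dy = w[3 * i + 1] - w[3 * j + 1], dz = w[3 * i + 2] - w[3 * j + 2];
      if (dx > hx) dx -= box[0]; else if (dx < -hx) dx += box[0];
      if (dy > hy) dy -= box[1]; else if (dy < -hy) dy += box[1];
      if (dz > hz) dz -= box[2]; else if (dz < -hz) dz += box[2];
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 >= cut2) continue;
      double u, fr;
      if (r2 >= tmin) eval_table(tab, r2, u, fr);
      else eval_pair(rule, ff, r2, u, fr);
      pe += u;
      double fx = fr * dx, fy = fr * dy, fz = fr * dz;
      f[3 * i] += fx; f[3 * i + 1] += fy; f[3 * i + 2] += fz;
      f[3 * j] -= fx; f[3 * j + 1] -= fy; f[3 * j + 2] -= fz;
      wxx += fx * dx; wyy += fy * dy; wzz += fz * dz;
    }
  }

  // generic path: rule resolved per pair
  inline void accum_pairs(const std::vector<int>& pairs, double* f) {
    const size_t np = pairs.size() / 2;
    for (size_t k = 0; k < np; ++k) {
      int i = pairs[2 * k], j = pairs[2 * k + 1];
      int rid = kind[i] * N_KINDS + kind[j];
      const PairRuleC& rule = rules[rid];
      if (rule.type == PT_NONE) continue;
      double dx = w[3 * i] - w[3 * j], dy = w[3 * i + 1] - w[3 * j + 1], dz = w[3 * i + 2] - w[3 * j + 2];
      minimg(dx, dy, dz);
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 >= rule.cut2) continue;
      double u, fr;
      const PairTable& tab = tables[table_of[rid]];
      if (r2 >= tab.tmin) eval_table(tab, r2, u, fr);
      else eval_pair(rule, ff, r2, u, fr);
      pe += u;
      double fx = fr * dx, fy = fr * dy, fz = fr * dz;
      f[3 * i] += fx; f[3 * i + 1] += fy; f[3 * i + 2] += fz;
      f[3 * j] -= fx; f[3 * j + 1] -= fy; f[3 * j + 2] -= fz;
      wxx += fx * dx; wyy += fy * dy; wzz += fz * dz;
    }
  }

  void accum_bonds(double* f, long step) {
    const double ri2 = ff.r_inf * ff.r_inf;
    for (size_t k = 0; k < bond_i.size(); ++k) {
      int i = bond_i[k], j = bond_j[k];
      double dx = w[3 * i] - w[3 * j], dy = w[3 * i + 1] - w[3 * j + 1], dz = w[3 * i + 2] - w[3 * j + 2];
      minimg(dx, dy, dz);
      double r2 = dx * dx + dy * dy + dz * dz;
      double fr;
      if (bond_t[k] == 1) {                     // FENE
        if (r2 >= ri2) {
          overstretch = true; bad_bond_i = i; bad_bond_j = j; bad_step = step;
          return;
        }
        double q = 1.0 - r2 / ri2;
        pe += -0.5 * ff.k_fene * ri2 * std::log(q);
        fr = -ff.k_fene / q;
      } else {                                  // harmonic straightening spring
        double r = std::sqrt(r2);
        double d = r - ff.r0_bend;
        pe += 0.5 * ff.k_bend * d * d;
        fr = (r > 0) ? -ff.k_bend * d / r : 0.0;
      }
      double fx = fr * dx, fy = fr * dy, fz = fr * dz;
      f[3 * i] += fx; f[3 * i + 1] += fy; f[3 * i + 2] += fz;
      f[3 * j] -= fx; f[3 * j + 1] -= fy; f[3 * j + 2] -= fz;
      wxx += fx * dx; wyy += fy * dy; wzz += fz * dz;
    }
  }

  void compute_forces(double* f, long step) {
    std::fill(f, f + 3 * N, 0.0);
    pe = 0.0; wxx = wyy = wzz = 0.0;
    const PairRuleC& tt_rule = rules[1 * N_KINDS + 2];  // TAIL1-TAIL2
    accum_pairs_rule(small_tt, tt_rule, tables[table_of[1 * N_KINDS + 2]], f);
    accum_pairs(small_other, f);
    accum_pairs(big_pairs, f);
    accum_bonds(f, step);
  }

  // brute-force all-pairs reference path (testing)
  void compute_forces_brute(double* f, long step) {
    std::fill(f, f + 3 * N, 0.0);
    pe = 0.0; wxx = wyy = wzz = 0.0;
    std::vector<int> pairs;
    for (int i = 0; i < N; ++i)
      for (int j = i + 1; j < N; ++j) {
        if (is_robot(kind[i]) && is_robot(kind[j])) continue;
        pairs.push_back(i); pairs.push_back(j);
      }
    accum_pairs(pairs, f);
    accum_bonds(f, step);
  }

  double rob_vel[3] = {0, 0, 0};

  void place_robot(double angle, double dt_trans = 0.0) {
    if (rob_idx.empty()) return;
    double cx = rob_center[0] + rob_vel[0] * dt_trans;
    double cy = rob_center[1] + rob_vel[1] * dt_trans;
    double cz = rob_center[2] + rob_vel[2] * dt_trans;
    double ux = rob_axis[0], uy = rob_axis[1], uz = rob_axis[2];
    double c = std::cos(angle), s = std::sin(angle), C = 1.0 - c;
    double R[9] = {
      c + ux * ux * C,      ux * uy * C - uz * s, ux * uz * C + uy * s,
      uy * ux * C + uz * s, c + uy * uy * C,      uy * uz * C - ux * s,
      uz * ux * C - uy * s, uz * uy * C + ux * s, c + uz * uz * C };
    for (size_t a = 0; a < rob_idx.size(); ++a) {
      int i = rob_idx[a];
      double px = rob_ref[3 * a], py = rob_ref[3 * a + 1], pz = rob_ref[3 * a + 2];
      x[3 * i]     = cx + R[0] * px + R[1] * py + R[2] * pz;
      x[3 * i + 1] = cy + R[3] * px + R[4] * py + R[5] * pz;
      x[3 * i + 2] = cz + R[6] * px + R[7] * py + R[8] * pz;
      w[3 * i] = x[3 * i]; w[3 * i + 1] = x[3 * i + 1]; w[3 * i + 2] = x[3 * i + 2];
      rewrap_bead(i);
    }
  }
};

static Sim make_sim(NumericMatrix pos, IntegerVector kinds, IntegerMatrix bonds,
                    NumericVector box, List ff_params, double skin) {
  Sim s;
  s.N = pos.nrow();
  s.x.resize(3 * s.N); s.v.assign(3 * s.N, 0.0);
  for (int i = 0; i < s.N; ++i) {
    s.x[3 * i] = pos(i, 0); s.x[3 * i + 1] = pos(i, 1); s.x[3 * i + 2] = pos(i, 2);
  }
  s.kind.assign(kinds.begin(), kinds.end());
  for (int k = 0; k < bonds.nrow(); ++k) {
    s.bond_i.push_back(bonds(k, 0) - 1);
    s.bond_j.push_back(bonds(k, 1) - 1);
    s.bond_t.push_back(bonds(k, 2));
  }
  s.box[0] = box[0]; s.box[1] = box[1]; s.box[2] = box[2];
  s.w = s.x;
  s.ff = parse_ff(ff_params);
  s.rewrap_all();
  s.rules = build_rules(s.ff);
  s.build_tables();
  s.skin = skin;
  double bmax = std::max(s.ff.b_hh, std::max(s.ff.b_ht, s.ff.b_tt));
  s.b_hh_len = s.ff.b_hh; s.b_ht_len = s.ff.b_ht;
  s.cut_small = std::max(s.ff.rc + s.ff.wc, std::pow(2.0, 1.0 / 6.0) * bmax);
  s.cut_big = std::max(s.ff.rcut_np, std::pow(2.0, 1.0 / 6.0) * std::max(s.ff.b_cargo, s.ff.b_np));
  s.classify();
  return s;
}

// [[Rcpp::export]]
List cpp_energy_forces(NumericMatrix pos, IntegerVector kinds, IntegerMatrix bonds,
                       NumericVector box, List ff_params, bool brute = false,
                       double skin = 0.4) {
  Sim s = make_sim(pos, kinds, bonds, box, ff_params, skin);
  std::vector<double> f(3 * s.N, 0.0);
  if (brute) {
    s.compute_forces_brute(f.data(), 0);
  } else {
    s.build_lists();
    s.compute_forces(f.data(), 0);
  }
  if (s.overstretch)
    stop("FENE bond overstretched between beads %d and %d", s.bad_bond_i + 1, s.bad_bond_j + 1);
  NumericMatrix fm(s.N, 3);
  for (int i = 0; i < s.N; ++i) { fm(i, 0) = f[3 * i]; fm(i, 1) = f[3 * i + 1]; fm(i, 2) = f[3 * i + 2]; }
  return List::create(_["energy"] = s.pe, _["forces"] = fm,
                      _["virial"] = NumericVector::create(s.wxx, s.wyy, s.wzz),
                      _["n_small_pairs"] = (double)((s.small_tt.size() + s.small_other.size()) / 2),
                      _["n_big_pairs"] = (double)(s.big_pairs.size() / 2));
}

// [[Rcpp::export]]
List cpp_run(NumericMatrix pos, NumericMatrix vel, IntegerVector kinds,
             IntegerMatrix bonds, NumericVector box, List ff_params, List opts) {
  Sim s = make_sim(pos, kinds, bonds, box, ff_params, as<double>(opts["skin"]));
  for (int i = 0; i < s.N; ++i) {
    s.v[3 * i] = vel(i, 0); s.v[3 * i + 1] = vel(i, 1); s.v[3 * i + 2] = vel(i, 2);
  }

  const long   n_steps      = as<long>(opts["n_steps"]);
  const double dt           = as<double>(opts["dt"]);
  const bool   thermo       = as<bool>(opts["thermostat"]);
  const double tc_t         = as<double>(opts["thermostat_tc"]);
  const double kT           = as<double>(opts["temperature"]);
  const bool   baro         = as<bool>(opts["barostat"]);
  const double tc_p         = as<double>(opts["barostat_tc"]);
  const double betaT        = as<double>(opts["baro_compressibility"]);
  const bool   baro_stoch   = as<bool>(opts["baro_stochastic"]);
  const double p_target     = as<double>(opts["baro_target"]);
  const double baro_max     = as<double>(opts["baro_max_step"]);
  const bool   fix_mem_com  = as<bool>(opts["fix_membrane_com_z"]);
  const long   sample_every = as<long>(opts["sample_every"]);
  const long   frame_every  = as<long>(opts["frame_every"]);
  const uint64_t seed       = (uint64_t)as<double>(opts["seed"]);
  const double f_rot        = as<double>(opts["rotation_frequency"]);
  const double t0           = as<double>(opts["t0"]);
  const double angle0       = as<double>(opts["robot_angle0"]);
  const bool   use_brute    = as<bool>(opts["brute_neighbors"]);

  // rigid robot setup
  IntegerVector rob_idx_r = opts["robot_indices"];     // 1-based, may be empty
  if (rob_idx_r.size() > 0) {
    NumericMatrix ref = opts["robot_reference"];
    NumericVector ctr = opts["robot_center"];
    NumericVector axs = opts["robot_axis"];
    double nn = std::sqrt(axs[0] * axs[0] + axs[1] * axs[1] + axs[2] * axs[2]);
    if (nn <= 0) stop("robot rotation axis has zero length");
    NumericVector rvel = opts["robot_center_velocity"];
    for (int k = 0; k < 3; ++k) {
      s.rob_center[k] = ctr[k]; s.rob_axis[k] = axs[k] / nn;
      s.rob_vel[k] = rvel[k];
    }
    for (int a = 0; a < rob_idx_r.size(); ++a) {
      s.rob_idx.push_back(rob_idx_r[a] - 1);
      s.rob_ref.push_back(ref(a, 0)); s.rob_ref.push_back(ref(a, 1)); s.rob_ref.push_back(ref(a, 2));
    }
  }

  const double c1 = thermo ? std::exp(-dt / tc_t) : 1.0;
  const double c2 = thermo ? std::sqrt((1.0 - c1 * c1) * kT) : 0.0;

  std::vector<char> mobile(s.N);
  for (int i = 0; i < s.N; ++i) mobile[i] = !is_robot(s.kind[i]);

  // output containers
  long n_frames = (frame_every > 0) ? (n_steps / frame_every + 1) : 1;
  NumericVector frames(3 * (R_xlen_t)s.N * n_frames);
  NumericMatrix frame_box(n_frames, 3);
  NumericVector frame_time(n_frames);
  IntegerVector frame_step(n_frames);
  std::vector<double> st_time, st_T, st_pe, st_area, st_plat, st_tension, st_fx, st_fy, st_fz;

  double* f = new double[3 * s.N];
  std::vector<double>& X = s.x; std::vector<double>& V = s.v;

  s.place_robot(angle0, 0.0);
  if (!use_brute) s.build_lists();

  double t_force = 0, t_list = 0, t_integ = 0; long n_rebuild = 0;
  auto tick = []() { return std::chrono::high_resolution_clock::now(); };
  auto tock = [](std::chrono::high_resolution_clock::time_point a) {
    return std::chrono::duration<double>(std::chrono::high_resolution_clock::now() - a).count(); };
  auto forces_now = [&](long step) {
    if (use_brute) s.compute_forces_brute(f, step);
    else {
      auto a = tick();
      if (s.need_rebuild()) { s.build_lists(); ++n_rebuild; }
      t_list += tock(a);
      auto b = tick();
      s.compute_forces(f, step);
      t_force += tock(b);
    }
  };
  forces_now(0);

  long nf = 0;
  auto snap_frame = [&](long step, double tnow) {
    double* dst = REAL(frames) + 3 * (R_xlen_t)s.N * nf;
    std::copy(X.begin(), X.end(), dst);
    frame_box(nf, 0) = s.box[0]; frame_box(nf, 1) = s.box[1]; frame_box(nf, 2) = s.box[2];
    frame_time[nf] = tnow; frame_step[nf] = (int)step;
    ++nf;
  };
  auto sample_series = [&](double tnow) {
    double ke = 0.0, kxx = 0.0, kyy = 0.0;
    for (int i = 0; i < s.N; ++i) if (mobile[i]) {
      double vx = V[3 * i], vy = V[3 * i + 1], vz = V[3 * i + 2];
      ke += vx * vx + vy * vy + vz * vz;
      kxx += vx * vx; kyy += vy * vy;
    }
    double Vol = s.box[0] * s.box[1] * s.box[2];
    double pxx = (kxx + s.wxx) / Vol, pyy = (kyy + s.wyy) / Vol;
    double plat = 0.5 * (pxx + pyy);
    st_time.push_back(tnow);
    st_T.push_back(ke / (3.0 * s.n_mobile));
    st_pe.push_back(s.pe);
    st_area.push_back(s.box[0] * s.box[1]);
    st_plat.push_back(plat);
    st_tension.push_back(-plat * s.box[2]);
    double rfx = 0, rfy = 0, rfz = 0;
    for (size_t a = 0; a < s.rob_idx.size(); ++a) {
      int i = s.rob_idx[a];
      rfx += f[3 * i]; rfy += f[3 * i + 1]; rfz += f[3 * i + 2];
    }
    st_fx.push_back(rfx); st_fy.push_back(rfy); st_fz.push_back(rfz);
  };

  snap_frame(0, t0);
  sample_series(t0);

  std::string status = "ok";
  long step;
  for (step = 0; step < n_steps; ++step) {
    const double tnow = t0 + (step + 1) * dt;

    // B: half kick
    for (int i = 0; i < s.N; ++i) if (mobile[i]) {
      V[3 * i]     += 0.5 * dt * f[3 * i];
      V[3 * i + 1] += 0.5 * dt * f[3 * i + 1];
      V[3 * i + 2] += 0.5 * dt * f[3 * i + 2];
    }
    // A: half drift (unwrapped and wrapped shadow; per-step moves << box)
    for (int i = 0; i < s.N; ++i) if (mobile[i]) {
      double ddx = 0.5 * dt * V[3 * i], ddy = 0.5 * dt * V[3 * i + 1], ddz = 0.5 * dt * V[3 * i + 2];
      X[3 * i] += ddx; X[3 * i + 1] += ddy; X[3 * i + 2] += ddz;
      double& wx = s.w[3 * i]; double& wy = s.w[3 * i + 1]; double& wz = s.w[3 * i + 2];
      wx += ddx; wy += ddy; wz += ddz;
      if (wx >= s.box[0]) wx -= s.box[0]; else if (wx < 0) wx += s.box[0];
      if (wy >= s.box[1]) wy -= s.box[1]; else if (wy < 0) wy += s.box[1];
      if (wz >= s.box[2]) wz -= s.box[2]; else if (wz < 0) wz += s.box[2];
    }
    // O: Ornstein-Uhlenbeck
    if (thermo) {
      double g[3];
      for (int i = 0; i < s.N; ++i) if (mobile[i]) {
        gauss3(seed, (uint64_t)(step + 1), (uint64_t)i, g);
        V[3 * i]     = c1 * V[3 * i]     + c2 * g[0];
        V[3 * i + 1] = c1 * V[3 * i + 1] + c2 * g[1];
        V[3 * i + 2] = c1 * V[3 * i + 2] + c2 * g[2];
      }
    }
    // A: half drift (unwrapped and wrapped shadow; per-step moves << box)
    for (int i = 0; i < s.N; ++i) if (mobile[i]) {
      double ddx = 0.5 * dt * V[3 * i], ddy = 0.5 * dt * V[3 * i + 1], ddz = 0.5 * dt * V[3 * i + 2];
      X[3 * i] += ddx; X[3 * i + 1] += ddy; X[3 * i + 2] += ddz;
      double& wx = s.w[3 * i]; double& wy = s.w[3 * i + 1]; double& wz = s.w[3 * i + 2];
      wx += ddx; wy += ddy; wz += ddz;
      if (wx >= s.box[0]) wx -= s.box[0]; else if (wx < 0) wx += s.box[0];
      if (wy >= s.box[1]) wy -= s.box[1]; else if (wy < 0) wy += s.box[1];
      if (wz >= s.box[2]) wz -= s.box[2]; else if (wz < 0) wz += s.box[2];
    }

    // in-plane barostat (weak coupling, optional stochastic rescale term)
    if (baro) {
      double kxx = 0.0, kyy = 0.0;
      for (int i = 0; i < s.N; ++i) if (mobile[i]) {
        kxx += V[3 * i] * V[3 * i]; kyy += V[3 * i + 1] * V[3 * i + 1];
      }
      double Vol = s.box[0] * s.box[1] * s.box[2];
      double plat = 0.5 * ((kxx + s.wxx) + (kyy + s.wyy)) / Vol;
      double dlnA = (betaT / tc_p) * (plat - p_target) * dt;
      if (baro_stoch)
        dlnA += std::sqrt(2.0 * kT * betaT * dt / (Vol * tc_p)) * gauss1(seed, (uint64_t)(step + 1), 0xBA50BA50ULL);
      // rate limit: virial spikes (e.g. a rigid body driven through the
      // membrane) must not translate into large single-step rescales
      if (dlnA > baro_max) dlnA = baro_max; else if (dlnA < -baro_max) dlnA = -baro_max;
      double mu = std::exp(0.5 * dlnA);
      if (mu < 0.9 || mu > 1.1) { status = "barostat_instability"; break; }
      s.box[0] *= mu; s.box[1] *= mu;
      for (int i = 0; i < s.N; ++i) if (mobile[i]) {
        X[3 * i] *= mu; X[3 * i + 1] *= mu;
        s.w[3 * i] *= mu; s.w[3 * i + 1] *= mu;
        V[3 * i] *= mu; V[3 * i + 1] *= mu;
      }
    }

    // prescribed robot kinematics: angle = angle0 + 2 pi f (t - t0),
    // exact; optional constant-velocity center translation (indentation)
    if (!s.rob_idx.empty()) s.place_robot(angle0 + 2.0 * M_PI * f_rot * (tnow - t0), tnow - t0);

    forces_now(step + 1);
    if (s.overstretch) { status = "fene_overstretch"; break; }

    // B: half kick
    for (int i = 0; i < s.N; ++i) if (mobile[i]) {
      V[3 * i]     += 0.5 * dt * f[3 * i];
      V[3 * i + 1] += 0.5 * dt * f[3 * i + 1];
      V[3 * i + 2] += 0.5 * dt * f[3 * i + 2];
    }

    // membrane-anchor constraint: remove the net z drift of the lipid
    // subsystem (a desk-scale patch otherwise translates with a driven
    // body instead of being pierced by it; emulates embedding in a
    // macroscopic membrane)
    if (fix_mem_com) {
      double vz = 0; int nl = 0;
      for (int i = 0; i < s.N; ++i) if (is_lipid(s.kind[i])) { vz += V[3 * i + 2]; ++nl; }
      if (nl > 0) {
        vz /= nl;
        for (int i = 0; i < s.N; ++i) if (is_lipid(s.kind[i])) V[3 * i + 2] -= vz;
      }
    }

    if (sample_every > 0 && (step + 1) % sample_every == 0) sample_series(tnow);
    if (frame_every > 0 && (step + 1) % frame_every == 0 && nf < n_frames) snap_frame(step + 1, tnow);
    if ((step & 1023) == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix pos_out(s.N, 3), vel_out(s.N, 3);
  for (int i = 0; i < s.N; ++i) {
    pos_out(i, 0) = X[3 * i]; pos_out(i, 1) = X[3 * i + 1]; pos_out(i, 2) = X[3 * i + 2];
    vel_out(i, 0) = V[3 * i]; vel_out(i, 1) = V[3 * i + 1]; vel_out(i, 2) = V[3 * i + 2];
  }
  delete[] f;

  frames.attr("dim") = IntegerVector::create(3, s.N, n_frames);
  List series = List::create(
    _["time"] = wrap(st_time), _["T_kin"] = wrap(st_T), _["pe"] = wrap(st_pe),
    _["area"] = wrap(st_area), _["p_lateral"] = wrap(st_plat),
    _["tension"] = wrap(st_tension),
    _["robot_fx"] = wrap(st_fx), _["robot_fy"] = wrap(st_fy), _["robot_fz"] = wrap(st_fz));

  return List::create(
    _["status"] = status,
    _["steps_done"] = (double)step,
    _["positions"] = pos_out, _["velocities"] = vel_out,
    _["box"] = NumericVector::create(s.box[0], s.box[1], s.box[2]),
    _["frames"] = frames, _["frame_box"] = frame_box,
    _["frame_time"] = frame_time, _["frame_step"] = frame_step,
    _["n_frames"] = (double)nf,
    _["series"] = series,
    _["bad_bond"] = IntegerVector::create(s.bad_bond_i + 1, s.bad_bond_j + 1),
    _["bad_step"] = (double)s.bad_step,
    _["timing"] = NumericVector::create(_["force"] = t_force, _["list"] = t_list,
                                        _["rebuilds"] = (double)n_rebuild));
}

// Rotate reference coordinates by angle about a unit axis (kinematic oracle
// support and robot placement outside the run loop).
// [[Rcpp::export]]
NumericMatrix cpp_rotate_about_axis(NumericMatrix ref, NumericVector center,
                                    NumericVector axis, double angle) {
  double nn = std::sqrt(axis[0] * axis[0] + axis[1] * axis[1] + axis[2] * axis[2]);
  if (nn <= 0) stop("rotation axis has zero length");
  double ux = axis[0] / nn, uy = axis[1] / nn, uz = axis[2] / nn;
  double c = std::cos(angle), s = std::sin(angle), C = 1.0 - c;
  double R[9] = {
    c + ux * ux * C,      ux * uy * C - uz * s, ux * uz * C + uy * s,
    uy * ux * C + uz * s, c + uy * uy * C,      uy * uz * C - ux * s,
    uz * ux * C - uy * s, uz * uy * C + ux * s, c + uz * uz * C };
  NumericMatrix out(ref.nrow(), 3);
  for (int i = 0; i < ref.nrow(); ++i) {
    double px = ref(i, 0), py = ref(i, 1), pz = ref(i, 2);
    out(i, 0) = center[0] + R[0] * px + R[1] * py + R[2] * pz;
    out(i, 1) = center[1] + R[3] * px + R[4] * py + R[5] * pz;
    out(i, 2) = center[2] + R[6] * px + R[7] * py + R[8] * pz;
  }
  return out;
}
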