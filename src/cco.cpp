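// Constrained constructive optimization growth: one stage of terminal
// insertions into an existing branching tree.
//
// Tree representation (segment-indexed, 0-based, distal = (x1,y1)):
//   parent  index of parent segment (-1 for the root segment)
//   c1,c2   children at the distal node (-1 if absent); c1 set, c2 == -1
//           marks a chain (pass-through) node
//   radius  current derived radius (terminals: rbase; internal: Murray)
//   gbif    Murray exponent frozen at the distal bifurcation's creation
//
// Radii are Murray-consistent at all times: r_p^g = r_1^g + r_2^g with the
// per-bifurcation exponent, so the post-hoc Murray residual is exactly zero.
// Uses R's RNG (unif_rand/norm_rand) so growth is reproducible via set.seed.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

namespace {

struct Tree {
  std::vector<double> x0, y0, x1, y1, radius, rbase, gbif;
  std::vector<int> parent, c1, c2, is_term, stage;
  size_t n() const { return x0.size(); }
};

inline double seglen(const Tree &T, int i) {
  double dx = T.x1[i] - T.x0[i], dy = T.y1[i] - T.y0[i];
  return std::sqrt(dx * dx + dy * dy);
}

// distance from point p to segment a-b
inline double pt_seg_dist(double px, double py, double ax, double ay,
                          double bx, double by) {
  double vx = bx - ax, vy = by - ay;
  double wx = px - ax, wy = py - ay;
  double vv = vx * vx + vy * vy;
  double t = vv > 0 ? (wx * vx + wy * vy) / vv : 0.0;
  t = std::max(0.0, std::min(1.0, t));
  double dx = wx - t * vx, dy = wy - t * vy;
  return std::sqrt(dx * dx + dy * dy);
}

// minimum distance from the FAZ center (origin) to segment a-b
inline double seg_origin_dist(double ax, double ay, double bx, double by) {
  return pt_seg_dist(0.0, 0.0, ax, ay, bx, by);
}

// recompute radius of segment i from its children (no-op for terminals)
inline double derived_radius(const Tree &T, int i, double rc1, double rc2) {
  if (T.c1[i] < 0) return T.rbase[i];
  if (T.c2[i] < 0) return rc1;
  double g = T.gbif[i];
  return std::pow(std::pow(rc1, g) + std::pow(rc2, g), 1.0 / g);
}

// Walk ancestors of segment j assuming j's radius becomes r_new; returns the
// added volume (pi * l * (r'^2 - r^2)) accumulated over ancestors. Read-only.
double ancestor_volume_delta(const Tree &T, int j, double r_new) {
  double dv = 0.0;
  int child = j;
  double rc = r_new;
  int a = T.parent[j];
  while (a >= 0) {
    double r_old = T.radius[a], r_upd;
    if (T.c2[a] < 0) {
      r_upd = rc;
    } else {
      int sib = (T.c1[a] == child) ? T.c2[a] : T.c1[a];
      double g = T.gbif[a];
      r_upd = std::pow(std::pow(rc, g) + std::pow(T.radius[sib], g), 1.0 / g);
    }
    if (std::fabs(r_upd - r_old) < 1e-14) break;  // no further change upstream
    dv += M_PI * seglen(T, a) * (r_upd * r_upd - r_old * r_old);
    child = a; rc = r_upd; a = T.parent[a];
  }
  return dv;
}

// Propagate radii up from segment j after commit.
void update_ancestors(Tree &T, int j) {
  int a = T.parent[j];
  while (a >= 0) {
    double r_upd = derived_radius(T, a, T.c1[a] >= 0 ? T.radius[T.c1[a]] : 0.0,
                                  T.c2[a] >= 0 ? T.radius[T.c2[a]] : 0.0);
    if (std::fabs(r_upd - T.radius[a]) < 1e-15) break;
    T.radius[a] = r_upd;
    a = T.parent[a];
  }
}

struct Candidate {
  int host = -1;
  double bx = 0, by = 0, dvol = 0;
  bool ok = false;
};

// Evaluate attaching terminal at (xn,yn) to host j with bifurcation at (bx,by).
// Returns volume delta, or NA if inadmissible.
double eval_bif(const Tree &T, int j, double bx, double by, double xn,
                double yn, double rt, double delta, double cos_thmin,
                double gamma, double r_faz, double min_len) {
  double p0x = T.x0[j], p0y = T.y0[j], p1x = T.x1[j], p1y = T.y1[j];
  double lp = std::hypot(bx - p0x, by - p0y);
  double lc = std::hypot(p1x - bx, p1y - by);
  double ln = std::hypot(xn - bx, yn - by);
  if (lp < min_len || lc < min_len || ln < min_len) return NA_REAL;
  // bifurcation angle between the two daughters
  double ux = (p1x - bx) / lc, uy = (p1y - by) / lc;
  double vx = (xn - bx) / ln, vy = (yn - by) / ln;
  double cth = ux * vx + uy * vy;
  if (cth >= cos_thmin) return NA_REAL;  // theta <= theta_min
  double rc = T.radius[j];
  double ratio = std::min(rc, rt) / std::max(rc, rt);
  if (!(ratio > delta)) return NA_REAL;
  // FAZ clearance for the three new pieces
  if (seg_origin_dist(p0x, p0y, bx, by) < r_faz) return NA_REAL;
  if (seg_origin_dist(bx, by, p1x, p1y) < r_faz) return NA_REAL;
  if (seg_origin_dist(bx, by, xn, yn) < r_faz) return NA_REAL;
  double rp = std::pow(std::pow(rc, gamma) + std::pow(rt, gamma), 1.0 / gamma);
  double lj = seglen(T, j);
  double dv = M_PI * (lp * rp * rp + lc * rc * rc + ln * rt * rt -
                      lj * rc * rc);
  dv += ancestor_volume_delta(T, j, rp);
  return dv;
}

}  // namespace

// [[Rcpp::export(name = ".cco_grow_stage")]]
List cco_grow_stage(List tree, List stage_pars) {
  Tree T;
  {
    NumericVector x0 = tree["x0"], y0 = tree["y0"], x1 = tree["x1"],
                  y1 = tree["y1"], radius = tree["radius"],
                  rbase = tree["rbase"], gbif = tree["gbif"];
    IntegerVector parent = tree["parent"], c1 = tree["c1"], c2 = tree["c2"],
                  is_term = tree["is_term"], stg = tree["stage"];
    T.x0 = as<std::vector<double>>(x0);
    T.y0 = as<std::vector<double>>(y0);
    T.x1 = as<std::vector<double>>(x1);
    T.y1 = as<std::vector<double>>(y1);
    T.radius = as<std::vector<double>>(radius);
    T.rbase = as<std::vector<double>>(rbase);
    T.gbif = as<std::vector<double>>(gbif);
    T.parent = as<std::vector<int>>(parent);
    T.c1 = as<std::vector<int>>(c1);
    T.c2 = as<std::vector<int>>(c2);
    T.is_term = as<std::vector<int>>(is_term);
    T.stage = as<std::vector<int>>(stg);
  }

  const int n_add = as<int>(stage_pars["n_terms"]);
  const int stage_id = as<int>(stage_pars["stage_id"]);
  const double r_in = as<double>(stage_pars["r_in"]);
  const double r_out = as<double>(stage_pars["r_out"]);
  const double r_faz = as<double>(stage_pars["r_faz"]);
  const double side = as<double>(stage_pars["side"]);      // +1 sup, -1 inf
  const double x_min = as<double>(stage_pars["x_min"]);
  const double mu = as<double>(stage_pars["mu"]);
  const double sigma = as<double>(stage_pars["sigma"]);
  const double r0 = as<double>(stage_pars["r0"]);
  const double delta = as<double>(stage_pars["delta"]);
  const double theta_min = as<double>(stage_pars["theta_min"]);  // degrees
  const double gamma = as<double>(stage_pars["gamma"]);
  const double nu = as<double>(stage_pars["nu"]);
  const double f_n = as<double>(stage_pars["f_n"]);
  const double area = as<double>(stage_pars["area"]);
  const double rt_new = as<double>(stage_pars["rt_new"]);
  const int n_cand = as<int>(stage_pars["n_candidates"]);
  const int max_attempts = as<int>(stage_pars["max_attempts"]);

  const double cos_thmin = std::cos(theta_min * M_PI / 180.0);
  const double cand_radius = f_n * std::sqrt(area);
  const double min_len = 1e-4;  // mm; guards degenerate splits

  int n_term_cur = 0;
  for (size_t i = 0; i < T.n(); ++i) n_term_cur += T.is_term[i];

  double lmin_red = 1.0;  // cumulative l_fr reduction, persists within stage
  const double l_fr = as<double>(stage_pars["l_fr"]);

  // audit logs
  std::vector<double> bif_ratio, bif_angle;
  std::vector<int> bif_stage_v;
  std::vector<int> log_ins, log_host;
  std::vector<double> log_vol, log_chosen;

  std::vector<int> cand_idx;
  std::vector<double> dist_buf;

  RNGScope rng;

  for (int add = 0; add < n_add; ++add) {
    int eq2_fails = 0, attempts = 0, region_rejects = 0;
    bool placed = false;
    while (!placed) {
      if (++attempts > max_attempts)
        stop("cco_grow_stage: no admissible site/connection after %d attempts "
             "(stage %d, %d of %d terminals placed, l_min reduction %.3g)",
             max_attempts, stage_id, add, n_add, lmin_red);
      // --- sample a site -------------------------------------------------
      double r = r0 + std::exp(mu + sigma * norm_rand());
      double th = 2.0 * M_PI * unif_rand();
      double xn = r * std::cos(th), yn = r * std::sin(th);
      double rad = std::hypot(xn, yn);
      if (rad < r_in || rad > r_out || rad <= r_faz || yn * side <= 0.0 ||
          xn < x_min) {
        if (++region_rejects > max_attempts)
          stop("cco_grow_stage: >%d consecutive rejections sampling the stage "
               "region (stage %d); region/parameter mismatch", max_attempts,
               stage_id);
        continue;
      }
      region_rejects = 0;
      // --- minimum separation (Eq. 2 style) -------------------------------
      double lmin = std::sqrt(nu * area / (M_PI * (n_term_cur + 1))) * lmin_red;
      if (lmin < 1e-3 && nu > 0)
        stop("cco_grow_stage: l_min exhausted (<1 um) in stage %d", stage_id);
      dist_buf.resize(T.n());
      double dmin = R_PosInf;
      for (size_t i = 0; i < T.n(); ++i) {
        dist_buf[i] = pt_seg_dist(xn, yn, T.x0[i], T.y0[i], T.x1[i], T.y1[i]);
        if (dist_buf[i] < dmin) dmin = dist_buf[i];
      }
      if (dmin < lmin) {
        if (++eq2_fails >= 20) { lmin_red *= l_fr; eq2_fails = 0; }
        continue;
      }
      // --- candidate hosts: nearest segments within f_n * sqrt(area) ------
      cand_idx.clear();
      for (size_t i = 0; i < T.n(); ++i)
        if (dist_buf[i] <= cand_radius) cand_idx.push_back((int)i);
      if (cand_idx.empty()) continue;
      std::sort(cand_idx.begin(), cand_idx.end(),
                [&](int a, int b) { return dist_buf[a] < dist_buf[b]; });
      if ((int)cand_idx.size() > n_cand) cand_idx.resize(n_cand);

      Candidate best;
      std::vector<Candidate> per_host;
      const int nd = 6;  // barycentric grid divisions (21 interior points)
      for (int j : cand_idx) {
        Candidate bh; bh.host = j;
        double p0x = T.x0[j], p0y = T.y0[j], p1x = T.x1[j], p1y = T.y1[j];
        // coarse grid over the triangle (p0, p1, xnew)
        double bw0 = -1, bw1 = -1;
        for (int a = 1; a < nd; ++a) {
          for (int b = 1; b < nd - a; ++b) {
            double w0 = (double)a / nd, w1 = (double)b / nd,
                   w2 = 1.0 - w0 - w1;
            double bx = w0 * p0x + w1 * p1x + w2 * xn;
            double by = w0 * p0y + w1 * p1y + w2 * yn;
            double dv = eval_bif(T, j, bx, by, xn, yn, rt_new, delta,
                                 cos_thmin, gamma, r_faz, min_len);
            if (!ISNA(dv) && (!bh.ok || dv < bh.dvol)) {
              bh.ok = true; bh.dvol = dv; bh.bx = bx; bh.by = by;
              bw0 = w0; bw1 = w1;
            }
          }
        }
        // one local refinement around the best grid point
        if (bh.ok) {
          double step = 1.0 / (2.0 * nd);
          for (int a = -1; a <= 1; ++a) {
            for (int b = -1; b <= 1; ++b) {
              if (a == 0 && b == 0) continue;
              double w0 = bw0 + a * step, w1 = bw1 + b * step,
                     w2 = 1.0 - w0 - w1;
              if (w0 <= 0.02 || w1 <= 0.02 || w2 <= 0.02) continue;
              double bx = w0 * p0x + w1 * p1x + w2 * xn;
              double by = w0 * p0y + w1 * p1y + w2 * yn;
              double dv = eval_bif(T, j, bx, by, xn, yn, rt_new, delta,
                                   cos_thmin, gamma, r_faz, min_len);
              if (!ISNA(dv) && dv < bh.dvol) {
                bh.dvol = dv; bh.bx = bx; bh.by = by;
              }
            }
          }
          per_host.push_back(bh);
          if (!best.ok || bh.dvol < best.dvol) best = bh;
        }
      }
      if (!best.ok) continue;  // no admissible connection; resample site

      // --- commit ---------------------------------------------------------
      for (const Candidate &c : per_host) {
        log_ins.push_back(add); log_host.push_back(c.host);
        log_vol.push_back(c.dvol);
        log_chosen.push_back(best.dvol);
      }
      int j = best.host;
      int jc = (int)T.n();   // distal continuation of the host
      int k = jc + 1;        // new terminal
      // continuation inherits the host's distal state
      T.x0.push_back(best.bx); T.y0.push_back(best.by);
      T.x1.push_back(T.x1[j]); T.y1.push_back(T.y1[j]);
      T.radius.push_back(T.radius[j]); T.rbase.push_back(T.rbase[j]);
      T.gbif.push_back(T.gbif[j]); T.parent.push_back(j);
      T.c1.push_back(T.c1[j]); T.c2.push_back(T.c2[j]);
      T.is_term.push_back(T.is_term[j]); T.stage.push_back(T.stage[j]);
      if (T.c1[j] >= 0) T.parent[T.c1[j]] = jc;
      if (T.c2[j] >= 0) T.parent[T.c2[j]] = jc;
      // new terminal
      T.x0.push_back(best.bx); T.y0.push_back(best.by);
      T.x1.push_back(xn); T.y1.push_back(yn);
      T.radius.push_back(rt_new); T.rbase.push_back(rt_new);
      T.gbif.push_back(0.0); T.parent.push_back(j);
      T.c1.push_back(-1); T.c2.push_back(-1);
      T.is_term.push_back(1); T.stage.push_back(stage_id);
      // host becomes the proximal piece with the new bifurcation
      T.x1[j] = best.bx; T.y1[j] = best.by;
      T.c1[j] = jc; T.c2[j] = k; T.is_term[j] = 0; T.gbif[j] = gamma;
      double rc = T.radius[jc];
      T.radius[j] =
          std::pow(std::pow(rc, gamma) + std::pow(rt_new, gamma), 1.0 / gamma);
      update_ancestors(T, j);

      // audit of the new bifurcation (creation-time constraint values)
      double lc = seglen(T, jc), ln = seglen(T, k);
      double ux = (T.x1[jc] - best.bx) / lc, uy = (T.y1[jc] - best.by) / lc;
      double vx = (xn - best.bx) / ln, vy = (yn - best.by) / ln;
      double ang = std::acos(std::max(-1.0, std::min(1.0, ux * vx + uy * vy)));
      bif_ratio.push_back(std::min(rc, rt_new) / std::max(rc, rt_new));
      bif_angle.push_back(ang * 180.0 / M_PI);
      bif_stage_v.push_back(stage_id);

      ++n_term_cur;
      placed = true;
    }
  }

  return List::create(
      _["x0"] = wrap(T.x0), _["y0"] = wrap(T.y0), _["x1"] = wrap(T.x1),
      _["y1"] = wrap(T.y1), _["radius"] = wrap(T.radius),
      _["rbase"] = wrap(T.rbase), _["gbif"] = wrap(T.gbif),
      _["parent"] = wrap(T.parent), _["c1"] = wrap(T.c1),
      _["c2"] = wrap(T.c2), _["is_term"] = wrap(T.is_term),
      _["stage"] = wrap(T.stage),
      _["audit"] = List::create(_["ratio"] = wrap(bif_ratio),
                                _["angle_deg"] = wrap(bif_angle),
                                _["stage"] = wrap(bif_stage_v)),
      _["candidate_log"] = List::create(
          _["insertion"] = wrap(log_ins), _["host"] = wrap(log_host),
          _["volume_delta"] = wrap(log_vol),
          _["chosen_delta"] = wrap(log_chosen)));
}
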