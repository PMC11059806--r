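// Geometry kernels: segment-segment clearance (capillary pruning against
// dilated macro vessels), mask/skeleton rasterization.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

namespace {

inline double clamp01(double t) { return std::max(0.0, std::min(1.0, t)); }

// minimum distance between segments p0-p1 and q0-q1 in 2D
double seg_seg_dist(double p0x, double p0y, double p1x, double p1y,
                    double q0x, double q0y, double q1x, double q1y) {
  double ux = p1x - p0x, uy = p1y - p0y;
  double vx = q1x - q0x, vy = q1y - q0y;
  double wx = p0x - q0x, wy = p0y - q0y;
  double a = ux * ux + uy * uy, b = ux * vx + uy * vy, c = vx * vx + vy * vy;
  double d = ux * wx + uy * wy, e = vx * wx + vy * wy;
  double D = a * c - b * b;
  double sc, tc;
  if (D < 1e-14) {  // nearly parallel
    sc = 0.0;
    tc = (c > 1e-14) ? clamp01(e / c) : 0.0;
  } else {
    sc = clamp01((b * e - c * d) / D);
    tc = clamp01((a * e - b * d) / D);
    // re-clamp pass for the boxed minimum
    tc = (c > 1e-14) ? clamp01((e + b * sc) / c) : 0.0;
    sc = (a > 1e-14) ? clamp01((b * tc - d) / a) : 0.0;
  }
  double dx = wx + sc * ux - tc * vx, dy = wy + sc * uy - tc * vy;
  // proper crossing check: distance is 0 if the segments intersect
  double d1 = ux * (q0y - p0y) - uy * (q0x - p0x);
  double d2 = ux * (q1y - p0y) - uy * (q1x - p0x);
  double d3 = vx * (p0y - q0y) - vy * (p0x - q0x);
  double d4 = vx * (p1y - q0y) - vy * (p1x - q0x);
  if (((d1 > 0) != (d2 > 0)) && ((d3 > 0) != (d4 > 0))) return 0.0;
  return std::sqrt(dx * dx + dy * dy);
}

}  // namespace

// For each query segment (capillary edge), TRUE if it comes within the
// dilation radius of any reference segment (macro vessel stadium test).
// Uses a uniform grid over reference segment bounding boxes.
// [[Rcpp::export(name = ".segments_hit_stadia")]]
LogicalVector segments_hit_stadia(NumericMatrix qseg, NumericMatrix rseg,
                                  NumericVector rdil) {
  const int nq = qseg.nrow(), nr = rseg.nrow();
  LogicalVector hit(nq, false);
  if (nr == 0 || nq == 0) return hit;
  double xmin = R_PosInf, xmax = R_NegInf, ymin = R_PosInf, ymax = R_NegInf;
  double rmax = 0.0;
  for (int i = 0; i < nr; ++i) {
    xmin = std::min({xmin, rseg(i, 0), rseg(i, 2)});
    xmax = std::max({xmax, rseg(i, 0), rseg(i, 2)});
    ymin = std::min({ymin, rseg(i, 1), rseg(i, 3)});
    ymax = std::max({ymax, rseg(i, 1), rseg(i, 3)});
    rmax = std::max(rmax, rdil[i]);
  }
  const double cell = 0.25;  // mm
  const double pad = rmax + 1e-9;
  xmin -= pad; ymin -= pad; xmax += pad; ymax += pad;
  const int ncx = std::max(1, (int)std::ceil((xmax - xmin) / cell));
  const int ncy = std::max(1, (int)std::ceil((ymax - ymin) / cell));
  std::vector<std::vector<int>> bins((size_t)ncx * ncy);
  auto cx = [&](double x) {
    return std::max(0, std::min(ncx - 1, (int)((x - xmin) / cell)));
  };
  auto cy = [&](double y) {
    return std::max(0, std::min(ncy - 1, (int)((y - ymin) / cell)));
  };
  for (int i = 0; i < nr; ++i) {
    double r = rdil[i];
    int ix0 = cx(std::min(rseg(i, 0), rseg(i, 2)) - r);
    int ix1 = cx(std::max(rseg(i, 0), rseg(i, 2)) + r);
    int iy0 = cy(std::min(rseg(i, 1), rseg(i, 3)) - r);
    int iy1 = cy(std::max(rseg(i, 1), rseg(i, 3)) + r);
    for (int ix = ix0; ix <= ix1; ++ix)
      for (int iy = iy0; iy <= iy1; ++iy)
        bins[(size_t)ix * ncy + iy].push_back(i);
  }
  for (int q = 0; q < nq; ++q) {
    double ax = qseg(q, 0), ay = qseg(q, 1), bx = qseg(q, 2), by = qseg(q, 3);
    if (std::max(ax, bx) < xmin || std::min(ax, bx) > xmax ||
        std::max(ay, by) < ymin || std::min(ay, by) > ymax)
      continue;
    int ix0 = cx(std::min(ax, bx)), ix1 = cx(std::max(ax, bx));
    int iy0 = cy(std::min(ay, by)), iy1 = cy(std::max(ay, by));
    bool h = false;
    for (int ix = ix0; ix <= ix1 && !h; ++ix) {
      for (int iy = iy0; iy <= iy1 && !h; ++iy) {
        for (int i : bins[(size_t)ix * ncy + iy]) {
          if (seg_seg_dist(ax, ay, bx, by, rseg(i, 0), rseg(i, 1), rseg(i, 2),
                           rseg(i, 3)) < rdil[i]) {
            h = true;
            break;
          }
        }
      }
    }
    hit[q] = h;
  }
  return hit;
}

// Rasterize segments onto a square canvas of npx x npx pixels spanning
// [-half, half]^2 mm. Returns list(mask, skeleton) as integer matrices.
// mask: pixels within each segment's radius (full vessel width);
// skeleton: 1-px centerlines (supercover line walk).
// [[Rcpp::export(name = ".rasterize_segments")]]
List rasterize_segments(NumericMatrix seg, NumericVector radius_mm, int npx,
                        double half) {
  IntegerMatrix mask(npx, npx), skel(npx, npx);
  const double px = 2.0 * half / npx;
  auto to_px = [&](double v) { return (v + half) / px - 0.5; };  // center idx
  for (int s = 0; s < seg.nrow(); ++s) {
    double ax = seg(s, 0), ay = seg(s, 1), bx = seg(s, 2), by = seg(s, 3);
    double r = radius_mm[s];
    // --- mask: stadium fill over the bounding box ---
    int i0 = std::max(0, (int)std::floor(to_px(std::min(ax, bx) - r)));
    int i1 = std::min(npx - 1, (int)std::ceil(to_px(std::max(ax, bx) + r)));
    int j0 = std::max(0, (int)std::floor(to_px(std::min(ay, by) - r)));
    int j1 = std::min(npx - 1, (int)std::ceil(to_px(std::max(ay, by) + r)));
    double ux = bx - ax, uy = by - ay;
    double uu = ux * ux + uy * uy;
    for (int i = i0; i <= i1; ++i) {
      double x = -half + (i + 0.5) * px;
      for (int j = j0; j <= j1; ++j) {
        double y = -half + (j + 0.5) * px;
        double t = uu > 0 ? clamp01(((x - ax) * ux + (y - ay) * uy) / uu) : 0;
        double dx = x - (ax + t * ux), dy = y - (ay + t * uy);
        if (dx * dx + dy * dy <= r * r) mask(i, j) = 1;
      }
    }
    // --- skeleton: sampled centerline walk at sub-pixel steps ---
    double len = std::sqrt(uu);
    int nstep = std::max(1, (int)std::ceil(len / (0.5 * px)));
    for (int k = 0; k <= nstep; ++k) {
      double t = (double)k / nstep;
      int i = (int)std::round(to_px(ax + t * ux));
      int j = (int)std::round(to_px(ay + t * uy));
      if (i >= 0 && i < npx && j >= 0 && j < npx) skel(i, j) = 1;
    }
  }
  return List::create(_["mask"] = mask, _["skeleton"] = skel);
}

// Minimum distance from each point to a set of segments (used for audits).
// [[Rcpp::export(name = ".points_min_seg_dist")]]
NumericVector points_min_seg_dist(NumericMatrix pts, NumericMatrix seg) {
  NumericVector out(pts.nrow());
  for (int p = 0; p < pts.nrow(); ++p) {
    double best = R_PosInf;
    double x = pts(p, 0), y = pts(p, 1);
    for (int s = 0; s < seg.nrow(); ++s) {
      double ax = seg(s, 0), ay = seg(s, 1), bx = seg(s, 2), by = seg(s, 3);
      double ux = bx - ax, uy = by - ay;
      double uu = ux * ux + uy * uy;
      double t = uu > 0 ? clamp01(((x - ax) * ux + (y - ay) * uy) / uu) : 0;
      double dx = x - (ax + t * ux), dy = y - (ay + t * uy);
      best = std::min(best, dx * dx + dy * dy);
    }
    out[p] = std::sqrt(best);
  }
  return out;
}
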