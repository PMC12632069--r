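#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Amanatides & Woo incremental grid traversal. Voxel (i,j,k) (0-based here)
// occupies [bmin + idx*sp, bmin + (idx+1)*sp) with bmin = origin - sp/2.
// Walks from p0 along dir, emitting visited voxels and chord lengths.
struct Tracer {
  double bmin[3], sp[3];
  int dims[3];
  Tracer(const NumericVector& origin, const NumericVector& spacing,
         const IntegerVector& d) {
    for (int i = 0; i < 3; ++i) {
      sp[i] = spacing[i];
      bmin[i] = origin[i] - 0.5 * sp[i];
      dims[i] = d[i];
    }
  }
  // visit(i,j,k,chord) called per voxel in ray order
  template <class F>
  void trace(const double p0[3], const double dirin[3], F visit) const {
    double dir[3], norm = 0.0;
    for (int i = 0; i < 3; ++i) norm += dirin[i] * dirin[i];
    norm = std::sqrt(norm);
    if (norm <= 0.0) stop("direction must be non-zero");
    for (int i = 0; i < 3; ++i) dir[i] = dirin[i] / norm;

    const double inf = std::numeric_limits<double>::infinity();
    double tmin = 0.0, tmax = inf;
    for (int i = 0; i < 3; ++i) {
      double lo = bmin[i], hi = bmin[i] + dims[i] * sp[i];
      if (dir[i] == 0.0) {
        if (p0[i] < lo || p0[i] >= hi) return;  // parallel, outside slab
      } else {
        double t1 = (lo - p0[i]) / dir[i], t2 = (hi - p0[i]) / dir[i];
        if (t1 > t2) std::swap(t1, t2);
        if (t1 > tmin) tmin = t1;
        if (t2 < tmax) tmax = t2;
      }
    }
    if (tmin >= tmax) return;

    int idx[3], step[3];
    double tnext[3], tdelta[3];
    for (int i = 0; i < 3; ++i) {
      double p = p0[i] + tmin * dir[i];
      int v = (int)std::floor((p - bmin[i]) / sp[i]);
      if (v < 0) v = 0;
      if (v >= dims[i]) v = dims[i] - 1;
      idx[i] = v;
      if (dir[i] > 0.0) {
        step[i] = 1;
        tnext[i] = (bmin[i] + (v + 1) * sp[i] - p0[i]) / dir[i];
        tdelta[i] = sp[i] / dir[i];
      } else if (dir[i] < 0.0) {
        step[i] = -1;
        tnext[i] = (bmin[i] + v * sp[i] - p0[i]) / dir[i];
        tdelta[i] = -sp[i] / dir[i];
      } else {
        step[i] = 0;
        tnext[i] = inf;
        tdelta[i] = inf;
      }
    }
    double tcur = tmin;
    while (true) {
      int ax = 0;
      if (tnext[1] < tnext[ax]) ax = 1;
      if (tnext[2] < tnext[ax]) ax = 2;
      double texit = tnext[ax] < tmax ? tnext[ax] : tmax;
      double chord = texit - tcur;
      if (chord < 0.0) chord = 0.0;
      visit(idx[0], idx[1], idx[2], chord);
      if (tnext[ax] >= tmax) break;
      tcur = tnext[ax];
      idx[ax] += step[ax];
      if (idx[ax] < 0 || idx[ax] >= dims[ax]) break;
      tnext[ax] += tdelta[ax];
    }
  }
};

// [[Rcpp::export]]
List dda_traverse_cpp(NumericVector entry, NumericVector direction,
                      NumericVector origin, NumericVector spacing,
                      IntegerVector dims) {
  Tracer tr(origin, spacing, dims);
  std::vector<int> vi, vj, vk;
  std::vector<double> chords;
  double p0[3] = {entry[0], entry[1], entry[2]};
  double d[3] = {direction[0], direction[1], direction[2]};
  tr.trace(p0, d, [&](int i, int j, int k, double c) {
    vi.push_back(i + 1); vj.push_back(j + 1); vk.push_back(k + 1);
    chords.push_back(c);
  });
  int n = (int)chords.size();
  IntegerMatrix index(n, 3);
  NumericVector chord(n);
  for (int r = 0; r < n; ++r) {
    index(r, 0) = vi[r]; index(r, 1) = vj[r]; index(r, 2) = vk[r];
    chord[r] = chords[r];
  }
  return List::create(_["index"] = index, _["chord"] = chord);
}

// Cast one ray per (sub)pixel of a fluence map through the voxel grid,
// accumulating w * (sad/d)^2 (optionally times the chord length) into vol.
// px/py are pixel-centre BEV coordinates (cm at the isocenter plane).
// [[Rcpp::export]]
NumericVector project_rays_cpp(NumericMatrix values, NumericVector px,
                               NumericVector py, NumericVector source,
                               NumericVector ex, NumericVector ey,
                               NumericVector iso, double sad,
                               NumericVector origin, NumericVector spacing,
                               IntegerVector dims, bool chord_weight,
                               int supersample, NumericVector vol) {
  Tracer tr(origin, spacing, dims);
  const double s0 = source[0], s1 = source[1], s2 = source[2];
  const double sad2 = sad * sad;
  const int nx = values.nrow(), ny = values.ncol();
  const int ss = supersample < 1 ? 1 : supersample;
  // subpixel offsets in units of pixel spacing
  double dpx = (px.size() > 1) ? (px[1] - px[0]) : 0.0;
  double dpy = (py.size() > 1) ? (py[1] - py[0]) : 0.0;
  const int d0 = dims[0], d1 = dims[1];
  for (int j = 0; j < ny; ++j) {
    for (int i = 0; i < nx; ++i) {
      double w = values(i, j);
      if (w <= 0.0) continue;
      double wsub = w / (double)(ss * ss);
      for (int su = 0; su < ss; ++su) {
        for (int sv = 0; sv < ss; ++sv) {
          double ox = ss == 1 ? 0.0 : ((su + 0.5) / ss - 0.5) * dpx;
          double oy = ss == 1 ? 0.0 : ((sv + 0.5) / ss - 0.5) * dpy;
          double u = px[i] + ox, v = py[j] + oy;
          double p[3] = {iso[0] + u * ex[0] + v * ey[0],
                         iso[1] + u * ex[1] + v * ey[1],
                         iso[2] + u * ex[2] + v * ey[2]};
          double dir[3] = {p[0] - s0, p[1] - s1, p[2] - s2};
          double p0[3] = {s0, s1, s2};
          tr.trace(p0, dir, [&](int a, int b, int c, double chord) {
            double cx = tr.bmin[0] + (a + 0.5) * tr.sp[0] - s0;
            double cy = tr.bmin[1] + (b + 0.5) * tr.sp[1] - s1;
            double cz = tr.bmin[2] + (c + 0.5) * tr.sp[2] - s2;
            double d2 = cx * cx + cy * cy + cz * cz;
            double dep = wsub * sad2 / d2;
            if (chord_weight) dep *= chord;
            vol[a + (R_xlen_t)d0 * (b + (R_xlen_t)d1 * c)] += dep;
          });
        }
      }
    }
  }
  return vol;
}
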