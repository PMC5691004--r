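#include <Rcpp.h>
#include <algorithm>
#include <functional>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Cubic-convolution kernel (Keys, a = -0.5): C1-smooth, interpolates
// cubics exactly on uniform grids.  Used for both Cartesian->polar and
// polar->Cartesian resampling.
static inline double cc_kernel(double t) {
  t = std::fabs(t);
  if (t < 1.0) return 1.5 * t * t * t - 2.5 * t * t + 1.0;
  if (t < 2.0) return -0.5 * t * t * t + 2.5 * t * t - 4.0 * t + 2.0;
  return 0.0;
}

static inline int clampi(int i, int lo, int hi) {
  return i < lo ? lo : (i > hi ? hi : i);
}

// Sample a matrix at continuous 0-based (row, col) positions with cubic
// convolution; edge rows/cols are replicated.  Positions whose center falls
// outside the grid get `fill` and inside = FALSE.
// [[Rcpp::export]]
List cpp_bicubic_sample(NumericMatrix m, NumericVector row, NumericVector col,
                        double fill) {
  const int nr = m.nrow(), nc = m.ncol(), n = row.size();
  NumericVector out(n);
  LogicalVector inside(n);
  for (int k = 0; k < n; ++k) {
    double r = row[k], c = col[k];
    if (!(r >= 0.0 && r <= nr - 1.0 && c >= 0.0 && c <= nc - 1.0)) {
      out[k] = fill;
      inside[k] = false;
      continue;
    }
    inside[k] = true;
    int r0 = (int)std::floor(r), c0 = (int)std::floor(c);
    double fr = r - r0, fc = c - c0;
    double wr[4], wc[4];
    for (int i = 0; i < 4; ++i) {
      wr[i] = cc_kernel(fr - (i - 1));
      wc[i] = cc_kernel(fc - (i - 1));
    }
    double acc = 0.0;
    for (int i = 0; i < 4; ++i) {
      int ri = clampi(r0 + i - 1, 0, nr - 1);
      double rowacc = 0.0;
      for (int j = 0; j < 4; ++j) {
        int cj = clampi(c0 + j - 1, 0, nc - 1);
        rowacc += wc[j] * m(ri, cj);
      }
      acc += wr[i] * rowacc;
    }
    out[k] = acc;
  }
  return List::create(_["values"] = out, _["inside"] = inside);
}

// Sample a polar grid (rows = radial bins, cols = angular bins) at
// continuous 0-based bin coordinates.  Angular axis is periodic; radial
// axis clamps (constant extrapolation beyond the first/last bin).
// [[Rcpp::export]]
NumericVector cpp_polar_sample(NumericMatrix pm, NumericVector rad,
                               NumericVector ang) {
  const int nr = pm.nrow(), na = pm.ncol(), n = rad.size();
  NumericVector out(n);
  for (int k = 0; k < n; ++k) {
    double r = rad[k];
    if (r < 0.0) r = 0.0;
    if (r > nr - 1.0) r = nr - 1.0;
    double a = ang[k];
    a -= na * std::floor(a / na);  // wrap into [0, na)
    int r0 = (int)std::floor(r), a0 = (int)std::floor(a);
    double fr = r - r0, fa = a - a0;
    double wr[4], wa[4];
    for (int i = 0; i < 4; ++i) {
      wr[i] = cc_kernel(fr - (i - 1));
      wa[i] = cc_kernel(fa - (i - 1));
    }
    double acc = 0.0;
    for (int i = 0; i < 4; ++i) {
      int ri = clampi(r0 + i - 1, 0, nr - 1);
      double rowacc = 0.0;
      for (int j = 0; j < 4; ++j) {
        int aj = (a0 + j - 1) % na;
        if (aj < 0) aj += na;
        rowacc += wa[j] * pm(ri, aj);
      }
      acc += wr[i] * rowacc;
    }
    out[k] = acc;
  }
  return out;
}

static inline double median_of(std::vector<double> &buf) {
  size_t n = buf.size();
  size_t h = n / 2;
  std::nth_element(buf.begin(), buf.begin() + h, buf.end());
  double hi = buf[h];
  if (n % 2 == 1) return hi;
  double lo = *std::max_element(buf.begin(), buf.begin() + h);
  return 0.5 * (lo + hi);
}

// Windowed median along the (periodic) angular axis of a polar grid,
// excluding invalid bins.  width is the window size in bins; the window is
// centered (floor(width/2) either side, so even widths use width+1 bins).
// [[Rcpp::export]]
List cpp_angular_median(NumericMatrix pm, LogicalMatrix valid, int width) {
  const int nr = pm.nrow(), na = pm.ncol();
  int half = width / 2;
  // a window covering the whole circle uses every bin exactly once
  if (2 * half + 1 > na) half = na / 2;
  const bool full = (2 * half + 1 >= na);
  NumericMatrix out(nr, na);
  LogicalMatrix vout(nr, na);
  std::vector<double> buf;
  buf.reserve(full ? na : 2 * half + 1);
  for (int r = 0; r < nr; ++r) {
    if (full) {
      // one median per radial row, shared by every angle
      buf.clear();
      for (int a = 0; a < na; ++a)
        if (valid(r, a)) buf.push_back(pm(r, a));
      double med = buf.empty() ? NA_REAL : median_of(buf);
      bool ok = !buf.empty();
      for (int a = 0; a < na; ++a) {
        out(r, a) = med;
        vout(r, a) = ok;
      }
      continue;
    }
    for (int a = 0; a < na; ++a) {
      buf.clear();
      for (int d = -half; d <= half; ++d) {
        int aj = (a + d) % na;
        if (aj < 0) aj += na;
        if (valid(r, aj)) buf.push_back(pm(r, aj));
      }
      if (buf.empty()) {
        out(r, a) = NA_REAL;
        vout(r, a) = false;
      } else {
        out(r, a) = median_of(buf);
        vout(r, a) = true;
      }
    }
  }
  return List::create(_["values"] = out, _["valid"] = vout);
}

// Windowed median along the (non-periodic) radial axis, window clamped at
// the ends, invalid bins excluded.  width = 1 is the identity on valid bins.
// [[Rcpp::export]]
List cpp_radial_median(NumericMatrix pm, LogicalMatrix valid, int width) {
  const int nr = pm.nrow(), na = pm.ncol();
  const int half = width / 2;
  NumericMatrix out(nr, na);
  LogicalMatrix vout(nr, na);
  std::vector<double> buf;
  buf.reserve(2 * half + 1);
  for (int a = 0; a < na; ++a) {
    for (int r = 0; r < nr; ++r) {
      buf.clear();
      int lo = std::max(0, r - half), hi = std::min(nr - 1, r + half);
      for (int i = lo; i <= hi; ++i)
        if (valid(i, a)) buf.push_back(pm(i, a));
      if (buf.empty()) {
        out(r, a) = NA_REAL;
        vout(r, a) = false;
      } else {
        out(r, a) = median_of(buf);
        vout(r, a) = true;
      }
    }
  }
  return List::create(_["values"] = out, _["valid"] = vout);
}

// 3D median filter with edge replication.  arr is a numeric vector holding
// a d1 x d2 x d3 array in column-major order; k1, k2, k3 are odd.
// [[Rcpp::export]]
NumericVector cpp_median3d(NumericVector arr, IntegerVector dims,
                           int k1, int k2, int k3) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const int h1 = k1 / 2, h2 = k2 / 2, h3 = k3 / 2;
  NumericVector out(arr.size());
  std::vector<double> buf;
  buf.reserve((size_t)k1 * k2 * k3);
  for (int z = 0; z < d3; ++z) {
    for (int y = 0; y < d2; ++y) {
      for (int x = 0; x < d1; ++x) {
        buf.clear();
        for (int dz = -h3; dz <= h3; ++dz) {
          int zz = clampi(z + dz, 0, d3 - 1);
          for (int dy = -h2; dy <= h2; ++dy) {
            int yy = clampi(y + dy, 0, d2 - 1);
            size_t base = (size_t)zz * d1 * d2 + (size_t)yy * d1;
            for (int dx = -h1; dx <= h1; ++dx) {
              int xx = clampi(x + dx, 0, d1 - 1);
              buf.push_back(arr[base + xx]);
            }
          }
        }
        out[(size_t)z * d1 * d2 + (size_t)y * d1 + x] = median_of(buf);
      }
    }
  }
  return out;
}

// 4-connected component labelling of a logical matrix (two-pass union-find).
// Returns an integer matrix: 0 = background, 1..n = component id.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(LogicalMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> parent(1, 0);
  std::function<int(int)> find = [&](int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  };
  int next = 1;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c)) continue;
      int up = (r > 0 && mask(r - 1, c)) ? find(lab(r - 1, c)) : 0;
      int lf = (c > 0 && mask(r, c - 1)) ? find(lab(r, c - 1)) : 0;
      if (up == 0 && lf == 0) {
        parent.push_back(next);
        lab(r, c) = next++;
      } else if (up != 0 && lf != 0) {
        int a = std::min(up, lf), b = std::max(up, lf);
        parent[b] = a;
        lab(r, c) = a;
      } else {
        lab(r, c) = up != 0 ? up : lf;
      }
    }
  }
  std::vector<int> remap(next, 0);
  int nfinal = 0;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      if (lab(r, c) != 0) {
        int root = find(lab(r, c));
        if (remap[root] == 0) remap[root] = ++nfinal;
        lab(r, c) = remap[root];
      }
  return lab;
}
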