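#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Voxel coordinates are 1-based throughout, matching R array indexing.

static inline double sample_trilinear(const double *vol, const int *d,
                                      double x, double y, double z,
                                      double fill) {
  // x,y,z are 1-based continuous voxel coordinates into vol (dims d)
  if (x < 1.0 || y < 1.0 || z < 1.0 || x > d[0] || y > d[1] || z > d[2])
    return fill;
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
  if (x0 == d[0]) x0--;
  if (y0 == d[1]) y0--;
  if (z0 == d[2]) z0--;
  double fx = x - x0, fy = y - y0, fz = z - z0;
  const R_xlen_t sx = 1, sy = d[0], sz = (R_xlen_t)d[0] * d[1];
  const double *p = vol + (x0 - 1) + (R_xlen_t)(y0 - 1) * sy + (R_xlen_t)(z0 - 1) * sz;
  double c00 = p[0] * (1 - fx) + p[sx] * fx;
  double c10 = p[sy] * (1 - fx) + p[sy + sx] * fx;
  double c01 = p[sz] * (1 - fx) + p[sz + sx] * fx;
  double c11 = p[sz + sy] * (1 - fx) + p[sz + sy + sx] * fx;
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

static inline double sample_nearest(const double *vol, const int *d,
                                    double x, double y, double z,
                                    double fill) {
  long xi = (long)std::floor(x + 0.5), yi = (long)std::floor(y + 0.5),
       zi = (long)std::floor(z + 0.5);
  if (xi < 1 || yi < 1 || zi < 1 || xi > d[0] || yi > d[1] || zi > d[2])
    return fill;
  return vol[(xi - 1) + (R_xlen_t)(yi - 1) * d[0] +
             (R_xlen_t)(zi - 1) * d[0] * d[1]];
}

// Resample `moving` onto an output grid. For output voxel v (1-based),
// the sampled coordinate is
//   y      = A %*% c(v, 1) + field(v)          (full-resolution space)
//   sample = (y - post_off) / post_scale       (voxel coords of `moving`)
// `field` (optional) holds a displacement per output voxel, one block of
// length prod(odim) per axis.
// [[Rcpp::export]]
NumericVector cpp_warp(NumericVector moving, IntegerVector mdim,
                       IntegerVector odim, NumericMatrix A,
                       Nullable<NumericVector> field,
                       NumericVector post_scale, NumericVector post_off,
                       bool nearest, double fill) {
  int d0 = odim[0], d1 = odim[1], d2 = odim[2];
  int md[3] = {mdim[0], mdim[1], mdim[2]};
  R_xlen_t n = (R_xlen_t)d0 * d1 * d2;
  NumericVector out(n);
  const double *mv = moving.begin();
  const double *fld = nullptr;
  if (field.isNotNull()) fld = NumericVector(field).begin();
  double a[3][4];
  for (int r = 0; r < 3; r++)
    for (int c = 0; c < 4; c++) a[r][c] = A(r, c);
  R_xlen_t idx = 0;
  for (int k = 1; k <= d2; k++) {
    for (int j = 1; j <= d1; j++) {
      double bx = a[0][1] * j + a[0][2] * k + a[0][3];
      double by = a[1][1] * j + a[1][2] * k + a[1][3];
      double bz = a[2][1] * j + a[2][2] * k + a[2][3];
      for (int i = 1; i <= d0; i++, idx++) {
        double x = a[0][0] * i + bx, y = a[1][0] * i + by, z = a[2][0] * i + bz;
        if (fld) {
          x += fld[idx];
          y += fld[idx + n];
          z += fld[idx + 2 * n];
        }
        x = (x - post_off[0]) / post_scale[0];
        y = (y - post_off[1]) / post_scale[1];
        z = (z - post_off[2]) / post_scale[2];
        out[idx] = nearest ? sample_nearest(mv, md, x, y, z, fill)
                           : sample_trilinear(mv, md, x, y, z, fill);
      }
    }
  }
  return out;
}

// Joint histogram of two equal-length vectors over equal-width bins
// spanning [xmin, xmax] x [ymin, ymax]; top edge is inclusive.
// [[Rcpp::export]]
NumericMatrix cpp_joint_hist(NumericVector x, NumericVector y, int bins,
                             double xmin, double xmax, double ymin,
                             double ymax) {
  NumericMatrix h(bins, bins);
  double wx = (xmax - xmin) / bins, wy = (ymax - ymin) / bins;
  R_xlen_t n = x.size();
  for (R_xlen_t t = 0; t < n; t++) {
    int i = (int)((x[t] - xmin) / wx);
    int j = (int)((y[t] - ymin) / wy);
    if (i < 0) i = 0;
    if (i >= bins) i = bins - 1;
    if (j < 0) j = 0;
    if (j >= bins) j = bins - 1;
    h(i, j) += 1.0;
  }
  return h;
}

// 6-connected component labelling of a binary volume; labels 1..K.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dim) {
  int d0 = dim[0], d1 = dim[1], d2 = dim[2];
  R_xlen_t n = (R_xlen_t)d0 * d1 * d2;
  IntegerVector lab(n, 0);
  std::vector<R_xlen_t> stack;
  const R_xlen_t sy = d0, sz = (R_xlen_t)d0 * d1;
  int next = 0;
  for (R_xlen_t s = 0; s < n; s++) {
    if (!mask[s] || lab[s] != 0) continue;
    next++;
    lab[s] = next;
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t v = stack.back();
      stack.pop_back();
      int i = (int)(v % d0), j = (int)((v / d0) % d1), k = (int)(v / sz);
      R_xlen_t nb[6];
      int m = 0;
      if (i > 0) nb[m++] = v - 1;
      if (i < d0 - 1) nb[m++] = v + 1;
      if (j > 0) nb[m++] = v - sy;
      if (j < d1 - 1) nb[m++] = v + sy;
      if (k > 0) nb[m++] = v - sz;
      if (k < d2 - 1) nb[m++] = v + sz;
      for (int t = 0; t < m; t++) {
        R_xlen_t w = nb[t];
        if (mask[w] && lab[w] == 0) {
          lab[w] = next;
          stack.push_back(w);
        }
      }
    }
  }
  lab.attr("n_components") = next;
  return lab;
}

static inline void bspline_w(double t, double *w) {
  double t2 = t * t, t3 = t2 * t;
  w[0] = (1 - 3 * t + 3 * t2 - t3) / 6.0;
  w[1] = (3 * t3 - 6 * t2 + 4) / 6.0;
  w[2] = (-3 * t3 + 3 * t2 + 3 * t + 1) / 6.0;
  w[3] = t3 / 6.0;
}

// Evaluate a cubic B-spline free-form deformation on an output grid.
// Control point m (1-based) along an axis sits at full-resolution voxel
// coordinate (m - 2) * spacing + 1. `coef` holds the three displacement
// component arrays (each of dim cdim) concatenated. Output voxel v maps to
// full-resolution coordinate o2f_scale * v + o2f_off before evaluation.
// Returns the three displacement fields concatenated (length 3 * prod(odim)).
// [[Rcpp::export]]
NumericVector cpp_bspline_field(NumericVector coef, IntegerVector cdim,
                                double spacing, IntegerVector odim,
                                NumericVector o2f_scale,
                                NumericVector o2f_off) {
  int c0 = cdim[0], c1 = cdim[1], c2 = cdim[2];
  R_xlen_t cn = (R_xlen_t)c0 * c1 * c2;
  int d0 = odim[0], d1 = odim[1], d2 = odim[2];
  R_xlen_t n = (R_xlen_t)d0 * d1 * d2;
  NumericVector out(3 * n);
  std::vector<double> wx(4 * d0);
  std::vector<int> ix(d0);
  for (int i = 1; i <= d0; i++) {
    double x = o2f_scale[0] * i + o2f_off[0];
    double u = (x - 1.0) / spacing;
    int iu = (int)std::floor(u);
    ix[i - 1] = iu;
    bspline_w(u - iu, &wx[4 * (i - 1)]);
  }
  R_xlen_t idx = 0;
  for (int k = 1; k <= d2; k++) {
    double z = o2f_scale[2] * k + o2f_off[2];
    double uz = (z - 1.0) / spacing;
    int iz = (int)std::floor(uz);
    double wz[4];
    bspline_w(uz - iz, wz);
    for (int j = 1; j <= d1; j++) {
      double y = o2f_scale[1] * j + o2f_off[1];
      double uy = (y - 1.0) / spacing;
      int iy = (int)std::floor(uy);
      double wy[4];
      bspline_w(uy - iy, wy);
      for (int i = 0; i < d0; i++, idx++) {
        double acc0 = 0, acc1 = 0, acc2 = 0;
        for (int n3 = 0; n3 < 4; n3++) {
          int kk = iz + n3;
          if (kk < 0 || kk >= c2) continue;
          for (int n2 = 0; n2 < 4; n2++) {
            int jj = iy + n2;
            if (jj < 0 || jj >= c1) continue;
            double wyz = wy[n2] * wz[n3];
            R_xlen_t base = (R_xlen_t)jj * c0 + (R_xlen_t)kk * c0 * c1;
            for (int n1 = 0; n1 < 4; n1++) {
              int ii = ix[i] + n1;
              if (ii < 0 || ii >= c0) continue;
              double w = wx[4 * i + n1] * wyz;
              R_xlen_t ci = base + ii;
              acc0 += w * coef[ci];
              acc1 += w * coef[ci + cn];
              acc2 += w * coef[ci + 2 * cn];
            }
          }
        }
        out[idx] = acc0;
        out[idx + n] = acc1;
        out[idx + 2 * n] = acc2;
      }
    }
  }
  return out;
}
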