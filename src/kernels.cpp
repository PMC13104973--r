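#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Per-pixel rolling median over the first array dimension (time), with the
// window truncated at the sequence ends: frame t uses [t-h, t+h] /\ [0, T-1].
// Even-length truncated windows use the midpoint of the two middle order
// statistics (the usual sample median).
// [[Rcpp::export]]
NumericVector cpp_rolling_median_t(NumericVector arr, int h) {
  IntegerVector d = arr.attr("dim");
  int T = d[0];
  if (T < 1) stop("array has zero extent along the first dimension");
  if (h < 1) stop("half window must be >= 1");
  R_xlen_t np = arr.size() / T;
  NumericVector out(no_init(arr.size()));
  out.attr("dim") = d;
  std::vector<double> buf;
  const double* a = REAL(arr);
  double* o = REAL(out);
  for (R_xlen_t p = 0; p < np; ++p) {
    const double* col = a + p * T;
    double* oc = o + p * T;
    for (int t = 0; t < T; ++t) {
      int lo = t - h; if (lo < 0) lo = 0;
      int hi = t + h; if (hi > T - 1) hi = T - 1;
      int n = hi - lo + 1;
      buf.assign(col + lo, col + hi + 1);
      std::nth_element(buf.begin(), buf.begin() + n / 2, buf.end());
      double m = buf[n / 2];
      if (n % 2 == 0) {
        double lo2 = *std::max_element(buf.begin(), buf.begin() + n / 2);
        m = 0.5 * (m + lo2);
      }
      oc[t] = m;
    }
  }
  return out;
}

static inline int reflect_idx(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - 1 - i;
  }
  return i;
}

// 1D correlation along the first dimension with symmetric (reflect) padding;
// separable n-D Gaussian smoothing is assembled from this in R by permuting
// axes between passes.
// [[Rcpp::export]]
NumericVector cpp_conv1_reflect(NumericVector arr, NumericVector kernel) {
  IntegerVector d = arr.attr("dim");
  int n = d[0];
  R_xlen_t m = arr.size() / n;
  int kl = kernel.size();
  int r = (kl - 1) / 2;
  NumericVector out(no_init(arr.size()));
  out.attr("dim") = d;
  const double* a = REAL(arr);
  const double* k = REAL(kernel);
  double* o = REAL(out);
  for (R_xlen_t c = 0; c < m; ++c) {
    const double* in = a + c * n;
    double* oc = o + c * n;
    for (int i = 0; i < n; ++i) {
      double s = 0.0;
      for (int j = 0; j < kl; ++j)
        s += k[j] * in[reflect_idx(i + j - r, n)];
      oc[i] = s;
    }
  }
  return out;
}

// Local maxima of a 4D array (e.g. a z-y-x-scale difference-of-Gaussian
// stack): voxels >= every neighbour in the full 3^4 box and > threshold.
// Returns one row per maximum: (i1, i2, i3, i4, value), 1-based indices.
// [[Rcpp::export]]
NumericMatrix cpp_local_maxima4(NumericVector arr, double threshold) {
  IntegerVector d = arr.attr("dim");
  int n1 = d[0], n2 = d[1], n3 = d[2], n4 = d[3];
  const double* a = REAL(arr);
  R_xlen_t s2 = n1, s3 = (R_xlen_t)n1 * n2, s4 = (R_xlen_t)n1 * n2 * n3;
  std::vector<double> rows;
  for (int i4 = 0; i4 < n4; ++i4)
    for (int i3 = 0; i3 < n3; ++i3)
      for (int i2 = 0; i2 < n2; ++i2)
        for (int i1 = 0; i1 < n1; ++i1) {
          R_xlen_t idx = i1 + s2 * i2 + s3 * i3 + s4 * i4;
          double v = a[idx];
          if (!(v > threshold)) continue;
          bool is_max = true;
          for (int d4 = -1; d4 <= 1 && is_max; ++d4) {
            int j4 = i4 + d4; if (j4 < 0 || j4 >= n4) continue;
            for (int d3 = -1; d3 <= 1 && is_max; ++d3) {
              int j3 = i3 + d3; if (j3 < 0 || j3 >= n3) continue;
              for (int d2 = -1; d2 <= 1 && is_max; ++d2) {
                int j2 = i2 + d2; if (j2 < 0 || j2 >= n2) continue;
                for (int d1 = -1; d1 <= 1; ++d1) {
                  int j1 = i1 + d1; if (j1 < 0 || j1 >= n1) continue;
                  if (d1 == 0 && d2 == 0 && d3 == 0 && d4 == 0) continue;
                  if (a[j1 + s2 * j2 + s3 * j3 + s4 * j4] > v) {
                    is_max = false; break;
                  }
                }
              }
            }
          }
          if (is_max) {
            rows.push_back(i1 + 1); rows.push_back(i2 + 1);
            rows.push_back(i3 + 1); rows.push_back(i4 + 1);
            rows.push_back(v);
          }
        }
  int nr = rows.size() / 5;
  NumericMatrix out(nr, 5);
  for (int i = 0; i < nr; ++i)
    for (int j = 0; j < 5; ++j)
      out(i, j) = rows[(R_xlen_t)i * 5 + j];
  return out;
}

// Binary dilation/erosion of a 3D mask by an arbitrary structuring element
// given as voxel offsets (n x 3, 0-based). Voxels outside the array are
// treated as background (the usual border convention).
// [[Rcpp::export]]
LogicalVector cpp_morph3(LogicalVector mask, IntegerMatrix offs, bool dilate) {
  IntegerVector d = mask.attr("dim");
  int n1 = d[0], n2 = d[1], n3 = d[2];
  int no = offs.nrow();
  std::vector<int> o1(no), o2(no), o3(no);
  for (int t = 0; t < no; ++t) {
    o1[t] = offs(t, 0); o2[t] = offs(t, 1); o3[t] = offs(t, 2);
  }
  LogicalVector out(mask.size());
  out.attr("dim") = d;
  const int* m = LOGICAL(mask);
  int* ov = LOGICAL(out);
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j)
      for (int i = 0; i < n1; ++i) {
        R_xlen_t idx = i + (R_xlen_t)n1 * (j + (R_xlen_t)n2 * k);
        bool res = !dilate;
        for (int t = 0; t < no; ++t) {
          int ii = i + o1[t], jj = j + o2[t], kk = k + o3[t];
          bool val = (ii >= 0 && ii < n1 && jj >= 0 && jj < n2 &&
                      kk >= 0 && kk < n3) &&
                     m[ii + (R_xlen_t)n1 * (jj + (R_xlen_t)n2 * kk)];
          if (dilate) { if (val) { res = true; break; } }
          else        { if (!val) { res = false; break; } }
        }
        ov[idx] = res;
      }
  return out;
}

// Fill fully enclosed background cavities of a 3D mask: background voxels
// not reachable from the array border by 6-connected steps become foreground.
// [[Rcpp::export]]
LogicalVector cpp_fill_holes3(LogicalVector mask) {
  IntegerVector d = mask.attr("dim");
  int n1 = d[0], n2 = d[1], n3 = d[2];
  R_xlen_t nv = (R_xlen_t)n1 * n2 * n3;
  const int* m = LOGICAL(mask);
  std::vector<char> vis(nv, 0);
  std::vector<R_xlen_t> stack;
  stack.reserve(1024);
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j)
      for (int i = 0; i < n1; ++i) {
        if (i != 0 && i != n1 - 1 && j != 0 && j != n2 - 1 &&
            k != 0 && k != n3 - 1) continue;
        R_xlen_t idx = i + (R_xlen_t)n1 * (j + (R_xlen_t)n2 * k);
        if (!m[idx] && !vis[idx]) { vis[idx] = 1; stack.push_back(idx); }
      }
  const int di[6] = {-1, 1, 0, 0, 0, 0};
  const int dj[6] = {0, 0, -1, 1, 0, 0};
  const int dk[6] = {0, 0, 0, 0, -1, 1};
  while (!stack.empty()) {
    R_xlen_t idx = stack.back(); stack.pop_back();
    int i = idx % n1;
    int j = (idx / n1) % n2;
    int k = idx / ((R_xlen_t)n1 * n2);
    for (int t = 0; t < 6; ++t) {
      int ii = i + di[t], jj = j + dj[t], kk = k + dk[t];
      if (ii < 0 || ii >= n1 || jj < 0 || jj >= n2 || kk < 0 || kk >= n3)
        continue;
      R_xlen_t nb = ii + (R_xlen_t)n1 * (jj + (R_xlen_t)n2 * kk);
      if (!m[nb] && !vis[nb]) { vis[nb] = 1; stack.push_back(nb); }
    }
  }
  LogicalVector out(mask.size());
  out.attr("dim") = d;
  int* ov = LOGICAL(out);
  for (R_xlen_t idx = 0; idx < nv; ++idx)
    ov[idx] = m[idx] || !vis[idx];
  return out;
}

// Connected-component labelling of a 3D mask (connectivity 6 or 26).
// Labels are assigned in scan order starting at 1; background is 0.
// [[Rcpp::export]]
IntegerVector cpp_label3(LogicalVector mask, int connectivity) {
  IntegerVector d = mask.attr("dim");
  int n1 = d[0], n2 = d[1], n3 = d[2];
  R_xlen_t nv = (R_xlen_t)n1 * n2 * n3;
  const int* m = LOGICAL(mask);
  IntegerVector lab(nv);
  lab.attr("dim") = d;
  int* lv = INTEGER(lab);
  std::vector<int> di, dj, dk;
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        if (a == 0 && b == 0 && c == 0) continue;
        if (connectivity == 6 && std::abs(a) + std::abs(b) + std::abs(c) != 1)
          continue;
        di.push_back(a); dj.push_back(b); dk.push_back(c);
      }
  int nn = di.size();
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t start = 0; start < nv; ++start) {
    if (!m[start] || lv[start]) continue;
    ++next;
    lv[start] = next;
    stack.clear();
    stack.push_back(start);
    while (!stack.empty()) {
      R_xlen_t idx = stack.back(); stack.pop_back();
      int i = idx % n1;
      int j = (idx / n1) % n2;
      int k = idx / ((R_xlen_t)n1 * n2);
      for (int t = 0; t < nn; ++t) {
        int ii = i + di[t], jj = j + dj[t], kk = k + dk[t];
        if (ii < 0 || ii >= n1 || jj < 0 || jj >= n2 || kk < 0 || kk >= n3)
          continue;
        R_xlen_t nb = ii + (R_xlen_t)n1 * (jj + (R_xlen_t)n2 * kk);
        if (m[nb] && !lv[nb]) { lv[nb] = next; stack.push_back(nb); }
      }
    }
  }
  return lab;
}

// Cubic median filter of a 3D array with half-width `radius` (radius 1 gives
// the 3x3x3 neighbourhood); out-of-bounds voxels are clamped to the nearest
// edge voxel.
// [[Rcpp::export]]
NumericVector cpp_median_filter3(NumericVector arr, int radius) {
  IntegerVector d = arr.attr("dim");
  int n1 = d[0], n2 = d[1], n3 = d[2];
  const double* a = REAL(arr);
  NumericVector out(no_init(arr.size()));
  out.attr("dim") = d;
  double* o = REAL(out);
  int w = 2 * radius + 1;
  std::vector<double> buf;
  buf.reserve((size_t)w * w * w);
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j)
      for (int i = 0; i < n1; ++i) {
        buf.clear();
        for (int dk2 = -radius; dk2 <= radius; ++dk2) {
          int kk = std::min(std::max(k + dk2, 0), n3 - 1);
          for (int dj2 = -radius; dj2 <= radius; ++dj2) {
            int jj = std::min(std::max(j + dj2, 0), n2 - 1);
            for (int di2 = -radius; di2 <= radius; ++di2) {
              int ii = std::min(std::max(i + di2, 0), n1 - 1);
              buf.push_back(a[ii + (R_xlen_t)n1 * (jj + (R_xlen_t)n2 * kk)]);
            }
          }
        }
        size_t n = buf.size();
        std::nth_element(buf.begin(), buf.begin() + n / 2, buf.end());
        o[i + (R_xlen_t)n1 * (j + (R_xlen_t)n2 * k)] = buf[n / 2];
      }
  return out;
}
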