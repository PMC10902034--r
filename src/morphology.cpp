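#include <Rcpp.h>
#include <vector>
#include <limits>

using namespace Rcpp;

// 1D squared distance transform (Felzenszwalb & Huttenlocher, lower envelope
// of parabolas). f holds squared distances on input, d receives the result.
static void dt1d(const std::vector<double>& f, std::vector<double>& d) {
  const int n = (int)f.size();
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      --k;
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    d[q] = (double)(q - v[k]) * (q - v[k]) + f[v[k]];
  }
}

// Exact squared Euclidean distance (in pixels) from every pixel to the
// nearest TRUE pixel. Pixels of an all-FALSE input get +Inf. Internally a
// large finite sentinel replaces infinity so the parabola intersections
// in dt1d stay well defined.
// [[Rcpp::export]]
NumericMatrix cpp_edt_sq(const LogicalMatrix& feature) {
  const int nr = feature.nrow(), nc = feature.ncol();
  const double BIG = 1.0 + (double)(nr + nc) * (double)(nr + nc);
  NumericMatrix out(nr, nc);
  bool any_feature = false;

  // pass 1: along columns
  {
    std::vector<double> f(nr), d(nr);
    for (int j = 0; j < nc; ++j) {
      for (int i = 0; i < nr; ++i) {
        f[i] = feature(i, j) ? 0.0 : BIG;
        if (feature(i, j)) any_feature = true;
      }
      dt1d(f, d);
      for (int i = 0; i < nr; ++i) out(i, j) = d[i];
    }
  }
  if (!any_feature) {
    std::fill(out.begin(), out.end(),
              std::numeric_limits<double>::infinity());
    return out;
  }
  // pass 2: along rows
  {
    std::vector<double> f(nc), d(nc);
    for (int i = 0; i < nr; ++i) {
      for (int j = 0; j < nc; ++j) f[j] = out(i, j);
      dt1d(f, d);
      for (int j = 0; j < nc; ++j) out(i, j) = d[j];
    }
  }
  return out;
}

// Connected-component labeling of a binary image, 4- or 8-connectivity.
// Returns an integer matrix with 0 for background and 1..k for components,
// numbered in raster-scan order of their first pixel.
// [[Rcpp::export]]
IntegerMatrix cpp_label(const LogicalMatrix& mask, int connectivity) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::fill(lab.begin(), lab.end(), 0);
  const int dx4[] = {-1, 1, 0, 0};
  const int dy4[] = {0, 0, -1, 1};
  const int dx8[] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dy8[] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int* dx = connectivity == 4 ? dx4 : dx8;
  const int* dy = connectivity == 4 ? dy4 : dy8;
  const int nd = connectivity == 4 ? 4 : 8;
  int next = 0;
  std::vector<int> stack;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j)) continue;
      ++next;
      stack.push_back(i + j * nr);
      lab(i, j) = next;
      while (!stack.empty()) {
        int p = stack.back();
        stack.pop_back();
        int pi = p % nr, pj = p / nr;
        for (int d = 0; d < nd; ++d) {
          int qi = pi + dx[d], qj = pj + dy[d];
          if (qi < 0 || qi >= nr || qj < 0 || qj >= nc) continue;
          if (mask(qi, qj) && !lab(qi, qj)) {
            lab(qi, qj) = next;
            stack.push_back(qi + qj * nr);
          }
        }
      }
    }
  }
  return lab;
}
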