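// Discretized factors of the insert-length diffusion operator acting on
// per-cluster grids in G x G. Matrix rows index the first (x) coordinate,
// columns the second (y) coordinate; one cell = one bin.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Parallel translation by (dx, dy) bins; mass moved off the grid is lost.
// [[Rcpp::export]]
NumericMatrix grid_translate_cpp(NumericMatrix M, int dx, int dy) {
  int nr = M.nrow(), nc = M.ncol();
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; j++) {
    int js = j - dy;
    if (js < 0 || js >= nc) continue;
    for (int i = 0; i < nr; i++) {
      int is = i - dx;
      if (is < 0 || is >= nr) continue;
      out(i, j) = M(is, js);
    }
  }
  return out;
}

// Uniform diffusion over 2h+1 steps along the diagonal (+1,+1) or
// anti-diagonal (+1,-1) direction: sliding-window mean along each line.
// [[Rcpp::export]]
NumericMatrix grid_diag_box_cpp(NumericMatrix M, int h, bool antidiag = false) {
  int nr = M.nrow(), nc = M.ncol();
  NumericMatrix out(nr, nc);
  if (h <= 0) { std::copy(M.begin(), M.end(), out.begin()); return out; }
  double w = 1.0 / (2 * h + 1);
  int dj = antidiag ? -1 : 1;

  std::vector<double> line, pre;
  // enumerate line start cells: for diag, first row and first column;
  // for antidiag, first row and last column
  std::vector<std::pair<int, int>> starts;
  for (int j = 0; j < nc; j++) starts.push_back({0, j});
  for (int i = 1; i < nr; i++) starts.push_back({i, antidiag ? nc - 1 : 0});

  for (size_t s = 0; s < starts.size(); s++) {
    int i0 = starts[s].first, j0 = starts[s].second;
    int len = 0;
    for (int i = i0, j = j0; i < nr && j >= 0 && j < nc; i++, j += dj) len++;
    line.resize(len);
    pre.resize(len + 1);
    pre[0] = 0.0;
    for (int k = 0, i = i0, j = j0; k < len; k++, i++, j += dj) {
      line[k] = M(i, j);
      pre[k + 1] = pre[k] + line[k];
    }
    for (int k = 0, i = i0, j = j0; k < len; k++, i++, j += dj) {
      int a = k - h < 0 ? 0 : k - h;
      int b = k + h + 1 > len ? len : k + h + 1;
      out(i, j) = (pre[b] - pre[a]) * w;
    }
  }
  return out;
}

// Separable Gaussian diffusion, per-axis standard deviation sigma_axis
// (bins), kernel truncated at 4 per-axis sd and renormalized.
// [[Rcpp::export]]
NumericMatrix grid_gauss_cpp(NumericMatrix M, double sigma_axis) {
  int nr = M.nrow(), nc = M.ncol();
  NumericMatrix out(nr, nc);
  if (sigma_axis <= 0) { std::copy(M.begin(), M.end(), out.begin()); return out; }
  int r = (int)std::ceil(4.0 * sigma_axis);
  std::vector<double> ker(2 * r + 1);
  double s = 0.0;
  for (int k = -r; k <= r; k++) {
    ker[k + r] = std::exp(-0.5 * k * k / (sigma_axis * sigma_axis));
    s += ker[k + r];
  }
  for (size_t k = 0; k < ker.size(); k++) ker[k] /= s;

  // 1-D convolution of a contiguous line into an output line
  const double* K = ker.data();
  auto conv_line = [&](const double* src, double* dst, int n) {
    for (int i = 0; i < n; i++) {
      int a = i - r < 0 ? -i : -r;
      int b = i + r >= n ? n - 1 - i : r;
      const double* s = src + i + a;
      const double* k = K + a + r;
      double acc = 0.0;
      int len = b - a + 1;
      for (int t = 0; t < len; t++) acc += s[t] * k[t];
      dst[i] = acc;
    }
  };

  NumericMatrix tmp(nr, nc);
  const double* m = REAL(M);
  double* tp = REAL(tmp);
  double* op = REAL(out);
  // along rows (x axis: contiguous within a column)
  for (int j = 0; j < nc; j++) conv_line(m + (long)j * nr, tp + (long)j * nr, nr);
  // along columns (y axis): gather a row, convolve, scatter
  std::vector<double> buf(nc), res(nc);
  for (int i = 0; i < nr; i++) {
    for (int j = 0; j < nc; j++) buf[j] = tp[(long)j * nr + i];
    conv_line(buf.data(), res.data(), nc);
    for (int j = 0; j < nc; j++) op[(long)j * nr + i] = res[j];
  }
  return out;
}

// 8-connected component labeling of a logical mask (BFS flood fill).
// [[Rcpp::export]]
IntegerMatrix grid_label_cpp(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::vector<std::pair<int, int>> queue;
  for (int j0 = 0; j0 < nc; j0++) {
    for (int i0 = 0; i0 < nr; i0++) {
      if (!mask(i0, j0) || lab(i0, j0) != 0) continue;
      next++;
      queue.clear();
      queue.push_back({i0, j0});
      lab(i0, j0) = next;
      size_t head = 0;
      while (head < queue.size()) {
        int i = queue[head].first, j = queue[head].second;
        head++;
        for (int di = -1; di <= 1; di++) {
          for (int dj = -1; dj <= 1; dj++) {
            if (di == 0 && dj == 0) continue;
            int ii = i + di, jj = j + dj;
            if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
            if (mask(ii, jj) && lab(ii, jj) == 0) {
              lab(ii, jj) = next;
              queue.push_back({ii, jj});
            }
          }
        }
      }
    }
  }
  return lab;
}
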