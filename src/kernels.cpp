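#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <functional>
using namespace Rcpp;

// Separable Gaussian blur with reflective boundary handling.
// sigma <= 0 returns the input unchanged.
// [[Rcpp::export(name = ".cpp_gauss_blur")]]
NumericMatrix cpp_gauss_blur(const NumericMatrix& img, double sigma) {
  int H = img.nrow(), W = img.ncol();
  if (sigma <= 0) return clone(img);
  int r = (int)std::ceil(3.5 * sigma);
  std::vector<double> k(2 * r + 1);
  double s = 0.0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = std::exp(-0.5 * (double)(i * i) / (sigma * sigma));
    s += k[i + r];
  }
  for (int i = 0; i < 2 * r + 1; ++i) k[i] /= s;

  // reflected index lookups, padded by r on both sides
  std::vector<int> ri(H + 2 * r), rj(W + 2 * r);
  for (int i = -r; i < H + r; ++i) {
    int ii = i;
    if (ii < 0) ii = -ii - 1;
    if (ii >= H) ii = 2 * H - ii - 1;
    ri[i + r] = ii;
  }
  for (int j = -r; j < W + r; ++j) {
    int jj = j;
    if (jj < 0) jj = -jj - 1;
    if (jj >= W) jj = 2 * W - jj - 1;
    rj[j + r] = jj;
  }
  NumericMatrix tmp(H, W), out(H, W);
  const double* src = &img(0, 0);
  double* ptmp = &tmp(0, 0);
  // vertical pass (within columns, contiguous)
  for (int j = 0; j < W; ++j) {
    const double* col = src + (size_t)j * H;
    double* dst = ptmp + (size_t)j * H;
    for (int i = 0; i < H; ++i) {
      double acc = 0.0;
      for (int d = 0; d <= 2 * r; ++d) acc += k[d] * col[ri[i + d]];
      dst[i] = acc;
    }
  }
  // horizontal pass (across columns)
  double* pout = &out(0, 0);
  for (int j = 0; j < W; ++j) {
    double* dst = pout + (size_t)j * H;
    for (int d = 0; d <= 2 * r; ++d) {
      const double* col = ptmp + (size_t)rj[j + d] * H;
      const double kd = k[d];
      for (int i = 0; i < H; ++i) dst[i] += kd * col[i];
    }
  }
  return out;
}

// 8-connected component labelling of a logical mask (two-pass union-find).
// Returns an integer matrix of labels, 0 = background, components 1..n.
// [[Rcpp::export(name = ".cpp_label_components")]]
IntegerMatrix cpp_label_components(const LogicalMatrix& mask) {
  int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<int> parent(1, 0); // parent[0] unused sentinel

  std::function<int(int)> find = [&](int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  };
  auto unite = [&](int a, int b) {
    a = find(a); b = find(b);
    if (a != b) parent[std::max(a, b)] = std::min(a, b);
  };

  int next = 0;
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      if (!mask(i, j)) continue;
      // previously visited 8-neighbours (column-major scan)
      int nb[4][2] = {{i - 1, j}, {i - 1, j - 1}, {i, j - 1}, {i + 1, j - 1}};
      int lmin = 0;
      for (int q = 0; q < 4; ++q) {
        int ii = nb[q][0], jj = nb[q][1];
        if (ii < 0 || ii >= H || jj < 0) continue;
        int l = lab(ii, jj);
        if (l > 0 && (lmin == 0 || l < lmin)) lmin = l;
      }
      if (lmin == 0) {
        ++next;
        parent.push_back(next);
        lab(i, j) = next;
      } else {
        lab(i, j) = lmin;
        for (int q = 0; q < 4; ++q) {
          int ii = nb[q][0], jj = nb[q][1];
          if (ii < 0 || ii >= H || jj < 0) continue;
          if (lab(ii, jj) > 0) unite(lab(ii, jj), lmin);
        }
      }
    }
  }
  // flatten labels to 1..n
  std::vector<int> remap(next + 1, 0);
  int n = 0;
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i)
      if (lab(i, j) > 0) {
        int r = find(lab(i, j));
        if (remap[r] == 0) remap[r] = ++n;
        lab(i, j) = remap[r];
      }
  return lab;
}

// Accumulate isotropic Gaussian blobs (centres cx, cy in 1-based pixel
// coordinates, common sigma per call, per-blob amplitude) into an H x W image.
// [[Rcpp::export(name = ".cpp_render_blobs")]]
NumericMatrix cpp_render_blobs(int H, int W, const NumericVector& cy,
                               const NumericVector& cx,
                               const NumericVector& amp, double sigma) {
  NumericMatrix img(H, W);
  int r = (int)std::ceil(3.5 * sigma);
  double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  for (int b = 0; b < cy.size(); ++b) {
    int ic = (int)std::lround(cy[b]) - 1, jc = (int)std::lround(cx[b]) - 1;
    for (int j = std::max(0, jc - r); j <= std::min(W - 1, jc + r); ++j) {
      double dx = (j + 1) - cx[b];
      for (int i = std::max(0, ic - r); i <= std::min(H - 1, ic + r); ++i) {
        double dy = (i + 1) - cy[b];
        img(i, j) += amp[b] * std::exp(-(dx * dx + dy * dy) * inv2s2);
      }
    }
  }
  return img;
}
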