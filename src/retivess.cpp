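#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Half-sample symmetric border: ... c b a | a b c ... | c b a
static inline int reflect_idx(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - 1 - i;
  }
  return i;
}

// Separable correlation (kernels are symmetric or explicitly flipped by the
// caller): x-pass across columns, then y-pass down rows.
// [[Rcpp::export(name = ".sep_conv_cpp")]]
NumericMatrix sep_conv_cpp(const NumericMatrix& img,
                           const NumericVector& kx,
                           const NumericVector& ky) {
  const int nr = img.nrow(), nc = img.ncol();
  const int rx = (kx.size() - 1) / 2, ry = (ky.size() - 1) / 2;
  NumericMatrix tmp(nr, nc), out(nr, nc);
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) {
      double acc = 0.0;
      for (int k = -rx; k <= rx; ++k)
        acc += kx[k + rx] * img(i, reflect_idx(j + k, nc));
      tmp(i, j) = acc;
    }
  }
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double acc = 0.0;
      for (int k = -ry; k <= ry; ++k)
        acc += ky[k + ry] * tmp(reflect_idx(i + k, nr), j);
      out(i, j) = acc;
    }
  }
  return out;
}

// Brute-force bilateral filter: Gaussian spatial kernel of given radius,
// Gaussian range kernel on intensity differences.
// [[Rcpp::export(name = ".bilateral_cpp")]]
NumericMatrix bilateral_cpp(const NumericMatrix& img, double sigma_s,
                            double sigma_r, int radius) {
  const int nr = img.nrow(), nc = img.ncol();
  const double is2 = 1.0 / (2.0 * sigma_s * sigma_s);
  const double ir2 = 1.0 / (2.0 * sigma_r * sigma_r);
  const int w = 2 * radius + 1;
  std::vector<double> sk(w * w);
  for (int dy = -radius; dy <= radius; ++dy)
    for (int dx = -radius; dx <= radius; ++dx)
      sk[(dy + radius) * w + (dx + radius)] =
        std::exp(-(dx * dx + dy * dy) * is2);
  NumericMatrix out(nr, nc);
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) {
      const double c = img(i, j);
      double num = 0.0, den = 0.0;
      for (int dy = -radius; dy <= radius; ++dy) {
        const int ii = reflect_idx(i + dy, nr);
        for (int dx = -radius; dx <= radius; ++dx) {
          const double v = img(ii, reflect_idx(j + dx, nc));
          const double d = v - c;
          const double wgt = sk[(dy + radius) * w + (dx + radius)] *
                             std::exp(-d * d * ir2);
          num += wgt * v;
          den += wgt;
        }
      }
      out(i, j) = num / den;
    }
  }
  return out;
}

// Connected-component labeling, connectivity 4 or 8, BFS, labels 1..K.
// [[Rcpp::export(name = ".label_components_cpp")]]
IntegerMatrix label_components_cpp(const IntegerMatrix& mask,
                                   int connectivity) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  const int dx8[8] = {1, -1, 0, 0, 1, 1, -1, -1};
  const int dy8[8] = {0, 0, 1, -1, 1, -1, 1, -1};
  const int nnb = (connectivity == 8) ? 8 : 4;
  std::vector<int> stack;
  int next = 0;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (mask(i, j) == 0 || lab(i, j) != 0) continue;
      ++next;
      lab(i, j) = next;
      stack.clear();
      stack.push_back(i + j * nr);
      while (!stack.empty()) {
        const int p = stack.back();
        stack.pop_back();
        const int pi = p % nr, pj = p / nr;
        for (int k = 0; k < nnb; ++k) {
          const int qi = pi + dy8[k], qj = pj + dx8[k];
          if (qi < 0 || qi >= nr || qj < 0 || qj >= nc) continue;
          if (mask(qi, qj) != 0 && lab(qi, qj) == 0) {
            lab(qi, qj) = next;
            stack.push_back(qi + qj * nr);
          }
        }
      }
    }
  }
  return lab;
}

// Number of 8-connected foreground components among the 8 neighbors of a
// pixel (adjacency restricted to the 3x3 ring).  Removal of the center is
// connectivity-safe iff this equals 1.
static int ring_components(const int nb[8]) {
  // ring order: E, NE, N, NW, W, SW, S, SE (circular)
  bool seen[8] = {false};
  int comps = 0;
  for (int s = 0; s < 8; ++s) {
    if (!nb[s] || seen[s]) continue;
    ++comps;
    // walk both directions along the ring; diagonal positions connect to
    // adjacent ring slots only via the in-between edge slot for 8-adjacency
    // of the ring cells: consecutive ring cells are always 8-adjacent.
    int q = s;
    seen[q] = true;
    // forward
    int t = s;
    while (true) {
      int u = (t + 1) % 8;
      if (nb[u] && !seen[u]) { seen[u] = true; t = u; } else break;
    }
    // backward
    t = s;
    while (true) {
      int u = (t + 7) % 8;
      if (nb[u] && !seen[u]) { seen[u] = true; t = u; } else break;
    }
  }
  return comps;
}

// Gradient-guided thinning: sequentially peel boundary pixels whose Sobel
// gradient magnitude is below that of the pixel just inside (along the
// quantized inward normal), guarded so no removal disconnects an 8-connected
// component and endpoints (<=1 neighbor) are kept.
// [[Rcpp::export(name = ".thin_gradient_cpp")]]
IntegerMatrix thin_gradient_cpp(const IntegerMatrix& mask_in,
                                const NumericMatrix& grad, int max_iter) {
  const int nr = mask_in.nrow(), nc = mask_in.ncol();
  IntegerMatrix mask = clone(mask_in);
  // ring order E, NE, N, NW, W, SW, S, SE as (dx, dy) with y = row down
  const int rdx[8] = {1, 1, 0, -1, -1, -1, 0, 1};
  const int rdy[8] = {0, -1, -1, -1, 0, 1, 1, 1};
  for (int iter = 0; iter < max_iter; ++iter) {
    bool changed = false;
    for (int j = 0; j < nc; ++j) {
      for (int i = 0; i < nr; ++i) {
        if (!mask(i, j)) continue;
        int nb[8], cnt = 0, bgx = 0, bgy = 0, nbg = 0;
        for (int k = 0; k < 8; ++k) {
          const int qi = i + rdy[k], qj = j + rdx[k];
          const bool inside =
            (qi >= 0 && qi < nr && qj >= 0 && qj < nc);
          const int fg = inside ? (mask(qi, qj) != 0) : 0;
          nb[k] = fg;
          cnt += fg;
          if (inside && !fg) { bgx += rdx[k]; bgy += rdy[k]; ++nbg; }
        }
        if (cnt <= 1) continue;          // endpoint / isolated: keep
        if (nbg == 0) continue;          // interior pixel
        if (ring_components(nb) != 1) continue;  // removal would split
        // inward normal = opposite of mean background direction, quantized
        const int ix = -bgx, iy = -bgy;
        if (ix == 0 && iy == 0) continue;  // symmetric (1-px structure)
        int dx, dy;
        const int ax = std::abs(ix), ay = std::abs(iy);
        if (ax > 2 * ay)       { dx = (ix > 0) - (ix < 0); dy = 0; }
        else if (ay > 2 * ax)  { dx = 0; dy = (iy > 0) - (iy < 0); }
        else                   { dx = (ix > 0) - (ix < 0);
                                 dy = (iy > 0) - (iy < 0); }
        const int qi = i + dy, qj = j + dx;
        if (qi < 0 || qi >= nr || qj < 0 || qj >= nc) continue;
        if (!mask(qi, qj)) continue;     // inward neighbor must be vessel
        if (grad(i, j) < grad(qi, qj)) { // not yet at the gradient crest
          mask(i, j) = 0;
          changed = true;
        }
      }
    }
    if (!changed) break;
  }
  return mask;
}
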