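#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 8-connected component labelling by iterative flood fill.
// mask: logical matrix; returns integer matrix of labels (0 = background),
// labels assigned in column-major scan order of first pixel.
// [[Rcpp::export]]
IntegerMatrix cc_label8(const LogicalMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::vector<int> stack;
  static const int dr[8] = {-1, -1, 0, 1, 1, 1, 0, -1};
  static const int dc[8] = {0, 1, 1, 1, 0, -1, -1, -1};
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(i + j * nr);
      lab(i, j) = next;
      while (!stack.empty()) {
        int p = stack.back(); stack.pop_back();
        int pi = p % nr, pj = p / nr;
        for (int k = 0; k < 8; ++k) {
          int qi = pi + dr[k], qj = pj + dc[k];
          if (qi < 0 || qi >= nr || qj < 0 || qj >= nc) continue;
          if (mask(qi, qj) && lab(qi, qj) == 0) {
            lab(qi, qj) = next;
            stack.push_back(qi + qj * nr);
          }
        }
      }
    }
  }
  lab.attr("n_labels") = next;
  return lab;
}

// Outer-contour perimeter per label via Moore-neighbour tracing with
// Jacob's stopping criterion. The contour polygon passes through
// boundary-pixel centres; perimeter is its closed length (unit steps for
// 4-neighbour moves, sqrt(2) for diagonal moves). Single-pixel components
// have perimeter 0 by this convention.
// [[Rcpp::export]]
NumericVector contour_perimeter(const IntegerMatrix& lab, int n_labels) {
  const int nr = lab.nrow(), nc = lab.ncol();
  NumericVector per(n_labels);
  if (n_labels == 0) return per;
  // clockwise from North
  static const int dr[8] = {-1, -1, 0, 1, 1, 1, 0, -1};
  static const int dc[8] = {0, 1, 1, 1, 0, -1, -1, -1};
  const double SQRT2 = 1.4142135623730951;
  std::vector<bool> seen(n_labels + 1, false);
  for (int j0 = 0; j0 < nc; ++j0) {
    for (int i0 = 0; i0 < nr; ++i0) {
      int L = lab(i0, j0);
      if (L == 0 || seen[L]) continue;
      seen[L] = true;
      // start = first pixel in column-major scan; the previous scan pixel
      // (above, or outside) is background, so backtrack points North.
      int ci = i0, cj = j0;
      int bdir = 0;  // direction from current pixel towards backtrack
      double total = 0.0;
      const int ci0 = ci, cj0 = cj;
      int dir0 = -1;  // first move direction (Jacob's stopping criterion)
      long maxit = 8L * (long)nr * (long)nc + 8;
      for (long it = 0; it < maxit; ++it) {
        int found = -1;
        for (int k = 1; k <= 8; ++k) {
          int d = (bdir + k) % 8;
          int qi = ci + dr[d], qj = cj + dc[d];
          if (qi < 0 || qi >= nr || qj < 0 || qj >= nc) continue;
          if (lab(qi, qj) == L) { found = d; break; }
        }
        if (found < 0) break;  // isolated pixel: perimeter 0
        if (dir0 < 0) dir0 = found;
        else if (ci == ci0 && cj == cj0 && found == dir0) break;
        total += (dr[found] != 0 && dc[found] != 0) ? SQRT2 : 1.0;
        // backtrack for the next scan: the neighbour examined just before
        // `found` (background or out of bounds); consecutive Moore
        // neighbours are mutually 8-adjacent, so it borders the new pixel
        int prev = (found + 7) % 8;
        int bi = ci + dr[prev], bj = cj + dc[prev];
        ci += dr[found]; cj += dc[found];
        int ddr = bi - ci, ddc = bj - cj;
        bdir = 0;
        for (int k = 0; k < 8; ++k)
          if (dr[k] == ddr && dc[k] == ddc) { bdir = k; break; }
      }
      per[L - 1] = total;
    }
  }
  return per;
}

// Compose an RGB frame in one pass: background/film colour per mask,
// global brightness factor, additive horizontal band, shared additive
// noise, clipped to [0, 1]. noise has length nr*nc and is recycled
// across channels.
// [[Rcpp::export]]
NumericVector compose_frame(const LogicalMatrix& mask,
                            const NumericVector& bg_rgb,
                            const NumericVector& film_rgb,
                            double brightness,
                            int band_lo, int band_hi, double band_amp,
                            const NumericVector& noise) {
  const int nr = mask.nrow(), nc = mask.ncol();
  const R_xlen_t npx = (R_xlen_t)nr * nc;
  NumericVector img(npx * 3);
  for (int ch = 0; ch < 3; ++ch) {
    const double bgv = bg_rgb[ch] * brightness;
    const double fgv = film_rgb[ch] * brightness;
    R_xlen_t off = npx * ch;
    for (int j = 0; j < nc; ++j) {
      R_xlen_t col0 = (R_xlen_t)j * nr;
      for (int i = 0; i < nr; ++i) {
        double v = mask(i, j) ? fgv : bgv;
        if (i >= band_lo && i <= band_hi) v += band_amp;
        v += noise[col0 + i];
        if (v < 0) v = 0; else if (v > 1) v = 1;
        img[off + col0 + i] = v;
      }
    }
  }
  img.attr("dim") = IntegerVector::create(nr, nc, 3);
  return img;
}

// Separable binary erosion/dilation with a k x k box (k odd), used for
// morphological opening without per-call S4 dispatch overhead.
static void box_minmax(const LogicalMatrix& in, LogicalMatrix& out,
                       int r, bool erode_op) {
  const int nr = in.nrow(), nc = in.ncol();
  LogicalMatrix tmp(nr, nc);
  // horizontal pass
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) {
      bool v = erode_op;
      for (int dj = -r; dj <= r; ++dj) {
        int jj = j + dj;
        bool x = (jj >= 0 && jj < nc) ? (bool)in(i, jj) : false;
        if (erode_op) v = v && x; else v = v || x;
      }
      tmp(i, j) = v;
    }
  }
  // vertical pass
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      bool v = erode_op;
      for (int di = -r; di <= r; ++di) {
        int ii = i + di;
        bool x = (ii >= 0 && ii < nr) ? (bool)tmp(ii, j) : false;
        if (erode_op) v = v && x; else v = v || x;
      }
      out(i, j) = v;
    }
  }
}

// Morphological opening (erosion then dilation) with a k x k box.
// [[Rcpp::export]]
LogicalMatrix morph_open(const LogicalMatrix& mask, int k) {
  if (k < 2) return clone(mask);
  int r = k / 2;
  LogicalMatrix er(mask.nrow(), mask.ncol());
  LogicalMatrix di(mask.nrow(), mask.ncol());
  box_minmax(mask, er, r, true);
  box_minmax(er, di, r, false);
  return di;
}

// Fill interior holes: background pixels not 4-connected to the image
// border become foreground.
// [[Rcpp::export]]
LogicalMatrix fill_holes(const LogicalMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  LogicalMatrix out = clone(mask);
  std::vector<char> outside((size_t)nr * nc, 0);
  std::vector<int> stack;
  auto push = [&](int i, int j) {
    size_t p = (size_t)j * nr + i;
    if (!mask(i, j) && !outside[p]) { outside[p] = 1; stack.push_back((int)p); }
  };
  for (int j = 0; j < nc; ++j) { push(0, j); push(nr - 1, j); }
  for (int i = 0; i < nr; ++i) { push(i, 0); push(i, nc - 1); }
  while (!stack.empty()) {
    int p = stack.back(); stack.pop_back();
    int i = p % nr, j = p / nr;
    if (i > 0) push(i - 1, j);
    if (i < nr - 1) push(i + 1, j);
    if (j > 0) push(i, j - 1);
    if (j < nc - 1) push(i, j + 1);
  }
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (!mask(i, j) && !outside[(size_t)j * nr + i]) out(i, j) = true;
  return out;
}
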