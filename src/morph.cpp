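#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// Grayscale erosion with a structuring element given as pixel offsets
// (dy, dx) and per-offset heights h: out(p) = min_k img(p + off_k) - h_k.
// Out-of-image offsets are skipped (clipped window), which is the usual
// choice for background estimation on finite frames.
// [[Rcpp::export]]
NumericMatrix cpp_gray_erode(const NumericMatrix& img,
                             const IntegerVector& dy,
                             const IntegerVector& dx,
                             const NumericVector& h) {
  const int nr = img.nrow(), nc = img.ncol(), K = dy.size();
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double m = R_PosInf;
      for (int k = 0; k < K; ++k) {
        const int ii = i + dy[k], jj = j + dx[k];
        if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
        const double v = img(ii, jj) - h[k];
        if (v < m) m = v;
      }
      out(i, j) = m;
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_gray_dilate(const NumericMatrix& img,
                              const IntegerVector& dy,
                              const IntegerVector& dx,
                              const NumericVector& h) {
  const int nr = img.nrow(), nc = img.ncol(), K = dy.size();
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double m = R_NegInf;
      for (int k = 0; k < K; ++k) {
        const int ii = i - dy[k], jj = j - dx[k];
        if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
        const double v = img(ii, jj) + h[k];
        if (v > m) m = v;
      }
      out(i, j) = m;
    }
  }
  return out;
}

// 8-connected component labelling of a logical mask; labels 1..n, 0 background.
// [[Rcpp::export]]
IntegerMatrix cpp_label(const LogicalMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::fill(lab.begin(), lab.end(), 0);
  int cur = 0;
  std::queue<std::pair<int, int> > q;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      lab(i, j) = ++cur;
      q.push(std::make_pair(i, j));
      while (!q.empty()) {
        const int ci = q.front().first, cj = q.front().second;
        q.pop();
        for (int dj = -1; dj <= 1; ++dj) {
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0) continue;
            const int ii = ci + di, jj = cj + dj;
            if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
            if (mask(ii, jj) && lab(ii, jj) == 0) {
              lab(ii, jj) = cur;
              q.push(std::make_pair(ii, jj));
            }
          }
        }
      }
    }
  }
  return lab;
}

static inline int nb(const LogicalMatrix& m, int i, int j) {
  if (i < 0 || i >= m.nrow() || j < 0 || j >= m.ncol()) return 0;
  return m(i, j) ? 1 : 0;
}

// Zhang-Suen thinning to a 1-px skeleton.
// [[Rcpp::export]]
LogicalMatrix cpp_thin(const LogicalMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  LogicalMatrix m = clone(mask);
  bool changed = true;
  std::vector<std::pair<int, int> > del;
  while (changed) {
    changed = false;
    for (int pass = 0; pass < 2; ++pass) {
      del.clear();
      for (int j = 0; j < nc; ++j) {
        for (int i = 0; i < nr; ++i) {
          if (!m(i, j)) continue;
          // neighbours P2..P9 clockwise starting north
          int p[8] = {nb(m, i - 1, j),     nb(m, i - 1, j + 1),
                      nb(m, i, j + 1),     nb(m, i + 1, j + 1),
                      nb(m, i + 1, j),     nb(m, i + 1, j - 1),
                      nb(m, i, j - 1),     nb(m, i - 1, j - 1)};
          int B = 0, A = 0;
          for (int k = 0; k < 8; ++k) {
            B += p[k];
            if (p[k] == 0 && p[(k + 1) % 8] == 1) ++A;
          }
          if (B < 2 || B > 6 || A != 1) continue;
          if (pass == 0) {
            if (p[0] * p[2] * p[4] != 0) continue;
            if (p[2] * p[4] * p[6] != 0) continue;
          } else {
            if (p[0] * p[2] * p[6] != 0) continue;
            if (p[0] * p[4] * p[6] != 0) continue;
          }
          del.push_back(std::make_pair(i, j));
        }
      }
      for (size_t k = 0; k < del.size(); ++k) m(del[k].first, del[k].second) = false;
      if (!del.empty()) changed = true;
    }
  }
  return m;
}
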