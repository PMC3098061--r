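#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <queue>
using namespace Rcpp;

// symmetric ("reflect with edge repeat") index: ... c b a | a b c ... | c b a
static inline int refl(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// 2-D correlation with symmetric border padding; kernel center at
// (floor(kr/2), floor(kc/2)).  Kernels here are symmetric, so correlation
// and convolution coincide.
// [[Rcpp::export]]
NumericMatrix conv2_symm(NumericMatrix img, NumericMatrix ker) {
  int nr = img.nrow(), nc = img.ncol();
  int kr = ker.nrow(), kc = ker.ncol();
  int cr = kr / 2, cc = kc / 2;
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double s = 0.0;
      for (int b = 0; b < kc; ++b) {
        int jj = refl(j + b - cc, nc);
        for (int a = 0; a < kr; ++a) {
          int ii = refl(i + a - cr, nr);
          s += ker(a, b) * img(ii, jj);
        }
      }
      out(i, j) = s;
    }
  }
  return out;
}

// separable filtering: 1-D kernel k applied down columns then across rows,
// symmetric padding.  Equivalent to conv2 with outer(k, k) but O(n k).
// [[Rcpp::export]]
NumericMatrix conv_sep_symm(NumericMatrix img, NumericVector k) {
  int nr = img.nrow(), nc = img.ncol(), kn = k.size(), c = kn / 2;
  NumericMatrix tmp(nr, nc), out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double s = 0.0;
      for (int a = 0; a < kn; ++a) s += k[a] * img(refl(i + a - c, nr), j);
      tmp(i, j) = s;
    }
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double s = 0.0;
      for (int a = 0; a < kn; ++a) s += k[a] * tmp(i, refl(j + a - c, nc));
      out(i, j) = s;
    }
  return out;
}

// kernel profiles for density smoothing; u is distance scaled by h
static inline double kde_kernel(double u, int id) {
  double au = std::fabs(u);
  switch (id) {
  case 0: return au <= 1.0 ? 1.0 : 0.0;                          // uniform
  case 1: return std::exp(-0.5 * u * u);                         // gaussian
  case 2: return au <= 1.0 ? 1.0 - u * u : 0.0;                  // epanechnikov
  case 3: return au <= 1.0 ? 1.0 - au : 0.0;                     // triangle
  case 4: { if (au > 1.0) return 0.0; double v = 1.0 - u * u; return v * v; }       // quartic
  case 5: { if (au > 1.0) return 0.0; double v = 1.0 - u * u; return v * v * v; }   // triweight
  case 6: return au <= 1.0 ? std::cos(M_PI * u / 2.0) : 0.0;     // cosine
  }
  return 0.0;
}

// kernel-weighted local sum over an in-bounds circular window of radius R,
// normalised by the cardinality of the in-bounds window set.
// [[Rcpp::export]]
NumericMatrix kde_smooth_cpp(NumericMatrix img, int R, double h, int kernel_id) {
  int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double s = 0.0; int card = 0;
      for (int dj = -R; dj <= R; ++dj) {
        int jj = j + dj; if (jj < 0 || jj >= nc) continue;
        for (int di = -R; di <= R; ++di) {
          int ii = i + di; if (ii < 0 || ii >= nr) continue;
          double d = std::sqrt((double)(di * di + dj * dj));
          if (d > R) continue;
          card++;
          s += kde_kernel(d / h, kernel_id) * img(ii, jj);
        }
      }
      out(i, j) = card > 0 ? s / card : 0.0;
    }
  return out;
}

// grayscale erosion with a flat structuring element (logical matrix, odd
// dims); pixels outside the image do not constrain the minimum (+Inf pad)
// [[Rcpp::export]]
NumericMatrix gray_erode_cpp(NumericMatrix img, LogicalMatrix se) {
  int nr = img.nrow(), nc = img.ncol();
  int kr = se.nrow(), kc = se.ncol(), cr = kr / 2, cc = kc / 2;
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double m = R_PosInf;
      for (int b = 0; b < kc; ++b) {
        int jj = j + b - cc; if (jj < 0 || jj >= nc) continue;
        for (int a = 0; a < kr; ++a) {
          if (!se(a, b)) continue;
          int ii = i + a - cr; if (ii < 0 || ii >= nr) continue;
          if (img(ii, jj) < m) m = img(ii, jj);
        }
      }
      out(i, j) = m;
    }
  return out;
}

// grayscale dilation with a flat structuring element (-Inf pad)
// [[Rcpp::export]]
NumericMatrix gray_dilate_cpp(NumericMatrix img, LogicalMatrix se) {
  int nr = img.nrow(), nc = img.ncol();
  int kr = se.nrow(), kc = se.ncol(), cr = kr / 2, cc = kc / 2;
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double m = R_NegInf;
      for (int b = 0; b < kc; ++b) {
        int jj = j + b - cc; if (jj < 0 || jj >= nc) continue;
        for (int a = 0; a < kr; ++a) {
          if (!se(a, b)) continue;
          int ii = i + a - cr; if (ii < 0 || ii >= nr) continue;
          if (img(ii, jj) > m) m = img(ii, jj);
        }
      }
      out(i, j) = m;
    }
  return out;
}

// grayscale reconstruction by dilation (8-connected geodesic dilation of
// marker under mask, iterated to stability).  Sequential forward/backward
// raster scans (Vincent's algorithm without the queue stage).
// [[Rcpp::export]]
NumericMatrix reconstruct_dilation_cpp(NumericMatrix marker, NumericMatrix mask) {
  int nr = marker.nrow(), nc = marker.ncol();
  NumericMatrix J = clone(marker);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (J(i, j) > mask(i, j)) J(i, j) = mask(i, j);
  bool changed = true;
  int guard = 0;
  while (changed && guard++ < 10000) {
    changed = false;
    // forward scan: neighbours already visited in raster order
    for (int j = 0; j < nc; ++j)
      for (int i = 0; i < nr; ++i) {
        double m = J(i, j);
        if (i > 0 && J(i - 1, j) > m) m = J(i - 1, j);
        if (j > 0 && J(i, j - 1) > m) m = J(i, j - 1);
        if (i > 0 && j > 0 && J(i - 1, j - 1) > m) m = J(i - 1, j - 1);
        if (i < nr - 1 && j > 0 && J(i + 1, j - 1) > m) m = J(i + 1, j - 1);
        if (m > mask(i, j)) m = mask(i, j);
        if (m > J(i, j)) { J(i, j) = m; changed = true; }
      }
    // backward scan
    for (int j = nc - 1; j >= 0; --j)
      for (int i = nr - 1; i >= 0; --i) {
        double m = J(i, j);
        if (i < nr - 1 && J(i + 1, j) > m) m = J(i + 1, j);
        if (j < nc - 1 && J(i, j + 1) > m) m = J(i, j + 1);
        if (i < nr - 1 && j < nc - 1 && J(i + 1, j + 1) > m) m = J(i + 1, j + 1);
        if (i > 0 && j < nc - 1 && J(i - 1, j + 1) > m) m = J(i - 1, j + 1);
        if (m > mask(i, j)) m = mask(i, j);
        if (m > J(i, j)) { J(i, j) = m; changed = true; }
      }
  }
  return J;
}

// connected component labeling, connectivity 4 or 8
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(IntegerMatrix mask, int connectivity) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::vector<int> qi, qj;
  int di8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  int dj8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  int nn = connectivity == 8 ? 8 : 4;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      if (mask(i, j) == 0 || lab(i, j) != 0) continue;
      lab(i, j) = ++next;
      qi.clear(); qj.clear();
      qi.push_back(i); qj.push_back(j);
      while (!qi.empty()) {
        int ci = qi.back(), cj = qj.back();
        qi.pop_back(); qj.pop_back();
        for (int k = 0; k < nn; ++k) {
          int ii = ci + di8[k], jj = cj + dj8[k];
          if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
          if (mask(ii, jj) != 0 && lab(ii, jj) == 0) {
            lab(ii, jj) = next;
            qi.push_back(ii); qj.push_back(jj);
          }
        }
      }
    }
  return lab;
}

// square-window maximum filter (half = window half-size), symmetric padding
// [[Rcpp::export]]
NumericMatrix window_max_cpp(NumericMatrix img, int half) {
  int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double m = R_NegInf;
      for (int b = -half; b <= half; ++b) {
        int jj = j + b; if (jj < 0 || jj >= nc) continue;
        for (int a = -half; a <= half; ++a) {
          int ii = i + a; if (ii < 0 || ii >= nr) continue;
          if (img(ii, jj) > m) m = img(ii, jj);
        }
      }
      out(i, j) = m;
    }
  return out;
}
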