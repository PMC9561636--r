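#include <Rcpp.h>
#include <queue>
#include <cmath>
using namespace Rcpp;

// Images are R matrices: nrow = y (row 0 at top), ncol = x, column-major.

// ---- separable Gaussian blur, reflective boundary -------------------------

static std::vector<double> gauss_kernel(double sigma) {
  int r = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> k(2 * r + 1);
  double s = 0.0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += k[i + r];
  }
  for (double &v : k) v /= s;
  return k;
}

// [[Rcpp::export(name = ".cpp_gaussian_blur")]]
NumericMatrix cpp_gaussian_blur(NumericMatrix img, double sigma) {
  int nr = img.nrow(), nc = img.ncol();
  if (sigma <= 0) return clone(img);
  std::vector<double> k = gauss_kernel(sigma);
  int r = ((int)k.size() - 1) / 2;
  NumericMatrix tmp(nr, nc), out(nr, nc);
  // vertical pass
  for (int x = 0; x < nc; ++x)
    for (int y = 0; y < nr; ++y) {
      double acc = 0.0;
      for (int d = -r; d <= r; ++d) {
        int yy = y + d;
        if (yy < 0) yy = -yy - 1;
        if (yy >= nr) yy = 2 * nr - yy - 1;
        acc += k[d + r] * img(yy, x);
      }
      tmp(y, x) = acc;
    }
  // horizontal pass
  for (int x = 0; x < nc; ++x)
    for (int y = 0; y < nr; ++y) {
      double acc = 0.0;
      for (int d = -r; d <= r; ++d) {
        int xx = x + d;
        if (xx < 0) xx = -xx - 1;
        if (xx >= nc) xx = 2 * nc - xx - 1;
        acc += k[d + r] * tmp(y, xx);
      }
      out(y, x) = acc;
    }
  return out;
}

// ---- grayscale morphology with a flat disc or ball-topped SE --------------
// height = 0 for flat disc; for a rolling ball of radius R the SE height at
// offset (dy,dx) is sqrt(R^2 - dy^2 - dx^2) - R (<= 0), scaled by `zscale`.

struct SE {
  std::vector<int> dy, dx;
  std::vector<double> h;
};

static SE make_se(int radius, bool ball, double zscale) {
  SE se;
  for (int dy = -radius; dy <= radius; ++dy)
    for (int dx = -radius; dx <= radius; ++dx) {
      double d2 = (double)dy * dy + (double)dx * dx;
      if (d2 <= (double)radius * radius + 1e-9) {
        se.dy.push_back(dy);
        se.dx.push_back(dx);
        double hh = 0.0;
        if (ball)
          hh = (std::sqrt((double)radius * radius - d2) - radius) * zscale;
        se.h.push_back(hh);
      }
    }
  return se;
}

static NumericMatrix morph(const NumericMatrix &img, const SE &se, bool erode) {
  int nr = img.nrow(), nc = img.ncol();
  size_t m = se.dy.size();
  NumericMatrix out(nr, nc);
  for (int x = 0; x < nc; ++x)
    for (int y = 0; y < nr; ++y) {
      double best = erode ? R_PosInf : R_NegInf;
      for (size_t i = 0; i < m; ++i) {
        int yy = y + se.dy[i], xx = x + se.dx[i];
        if (yy < 0 || yy >= nr || xx < 0 || xx >= nc) continue;
        double v = erode ? img(yy, xx) - se.h[i] : img(yy, xx) + se.h[i];
        if (erode ? (v < best) : (v > best)) best = v;
      }
      out(y, x) = best;
    }
  return out;
}

// [[Rcpp::export(name = ".cpp_gray_open")]]
NumericMatrix cpp_gray_open(NumericMatrix img, int radius, bool ball,
                            double zscale) {
  SE se = make_se(radius, ball, zscale);
  NumericMatrix er = morph(img, se, true);
  return morph(er, se, false);
}

// ---- connected components, 8-connectivity ---------------------------------

// [[Rcpp::export(name = ".cpp_label")]]
IntegerMatrix cpp_label(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::fill(lab.begin(), lab.end(), 0);
  int next = 0;
  std::queue<std::pair<int, int> > q;
  for (int x = 0; x < nc; ++x)
    for (int y = 0; y < nr; ++y) {
      if (!mask(y, x) || lab(y, x)) continue;
      ++next;
      lab(y, x) = next;
      q.push(std::make_pair(y, x));
      while (!q.empty()) {
        std::pair<int, int> p = q.front();
        q.pop();
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dy && !dx) continue;
            int yy = p.first + dy, xx = p.second + dx;
            if (yy < 0 || yy >= nr || xx < 0 || xx >= nc) continue;
            if (mask(yy, xx) && !lab(yy, xx)) {
              lab(yy, xx) = next;
              q.push(std::make_pair(yy, xx));
            }
          }
      }
    }
  return lab;
}

// ---- Zhang-Suen thinning ---------------------------------------------------

// [[Rcpp::export(name = ".cpp_thin")]]
LogicalMatrix cpp_thin(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  LogicalMatrix im = clone(mask);
  bool changed = true;
  std::vector<std::pair<int, int> > kill;
  while (changed) {
    changed = false;
    for (int pass = 0; pass < 2; ++pass) {
      kill.clear();
      for (int x = 1; x < nc - 1; ++x)
        for (int y = 1; y < nr - 1; ++y) {
          if (!im(y, x)) continue;
          int p2 = im(y - 1, x), p3 = im(y - 1, x + 1), p4 = im(y, x + 1),
              p5 = im(y + 1, x + 1), p6 = im(y + 1, x), p7 = im(y + 1, x - 1),
              p8 = im(y, x - 1), p9 = im(y - 1, x - 1);
          int B = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
          if (B < 2 || B > 6) continue;
          int A = (!p2 && p3) + (!p3 && p4) + (!p4 && p5) + (!p5 && p6) +
                  (!p6 && p7) + (!p7 && p8) + (!p8 && p9) + (!p9 && p2);
          if (A != 1) continue;
          if (pass == 0) {
            if (p2 * p4 * p6 != 0 || p4 * p6 * p8 != 0) continue;
          } else {
            if (p2 * p4 * p8 != 0 || p2 * p6 * p8 != 0) continue;
          }
          kill.push_back(std::make_pair(y, x));
        }
      if (!kill.empty()) changed = true;
      for (size_t i = 0; i < kill.size(); ++i)
        im(kill[i].first, kill[i].second) = false;
    }
  }
  return im;
}

// ---- linear SVM: dual coordinate descent for L1-loss (hinge) ---------------
// min_w 0.5 ||w||^2 + C sum max(0, 1 - y_i (w.x_i + b));  bias handled by an
// augmented constant column (value 1), standard liblinear trick.

// [[Rcpp::export(name = ".cpp_svm_dcd")]]
NumericVector cpp_svm_dcd(NumericMatrix X, NumericVector y, double C,
                          int max_iter, double tol, int seed) {
  int n = X.nrow(), p = X.ncol();
  int pa = p + 1;  // augmented bias column
  std::vector<double> w(pa, 0.0), alpha(n, 0.0), qii(n);
  for (int i = 0; i < n; ++i) {
    double s = 1.0;  // bias column
    for (int j = 0; j < p; ++j) s += X(i, j) * X(i, j);
    qii[i] = s;
  }
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  unsigned long long state = (unsigned long long)seed * 6364136223846793005ULL + 1442695040888963407ULL;
  for (int it = 0; it < max_iter; ++it) {
    // Fisher-Yates with a private LCG so results are R-RNG independent
    for (int i = n - 1; i > 0; --i) {
      state = state * 6364136223846793005ULL + 1442695040888963407ULL;
      int j = (int)((state >> 33) % (unsigned long long)(i + 1));
      std::swap(idx[i], idx[j]);
    }
    double max_pg = 0.0;
    for (int k = 0; k < n; ++k) {
      int i = idx[k];
      double g = -1.0 + w[p];  // bias term contribution times y later
      double wx = w[p];        // bias column value 1
      for (int j = 0; j < p; ++j) wx += w[j] * X(i, j);
      g = y[i] * wx - 1.0;
      double pg = g;
      if (alpha[i] <= 0.0) pg = std::min(g, 0.0);
      else if (alpha[i] >= C) pg = std::max(g, 0.0);
      if (std::fabs(pg) > max_pg) max_pg = std::fabs(pg);
      if (std::fabs(pg) > 1e-12) {
        double old = alpha[i];
        alpha[i] = std::min(std::max(old - g / qii[i], 0.0), C);
        double d = (alpha[i] - old) * y[i];
        for (int j = 0; j < p; ++j) w[j] += d * X(i, j);
        w[p] += d;
      }
    }
    if (max_pg < tol) break;
  }
  NumericVector out(pa);
  for (int j = 0; j < pa; ++j) out[j] = w[j];
  return out;  // w[1..p], bias last
}
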