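#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Dip statistic: the smallest half-width t such that some nondecreasing
// convex-then-concave distribution function fits inside the band of width
// 2t around the empirical CDF. Feasibility for a given t is decided exactly
// from the greatest convex minorant of the band's upper envelope (left of
// the mode) and, by mirror symmetry, the least concave majorant of its
// lower envelope (right of the mode), together with the slope "momentum"
// that convexity forces across knots. The mode is enumerated over knots;
// the fitted CDF may jump upward at the mode, so each side is solved with
// the mode knot's box relaxed to the CDF's one-sided limit there.

namespace {

const double EPS = 1e-12;

struct PassResult {
  std::vector<char> configOK;  // left piece feasible with the mode at knot j
  std::vector<double> vend;    // minimal feasible value at the mode knot
};

// One convex, nondecreasing pass over knots 0..m-1 with per-knot boxes
//   lo[i] = max(0, F[i] - t),  hi[i] = min(1, F[i-1] + t).
PassResult convex_pass(const std::vector<double>& x,
                       const std::vector<double>& F, double t) {
  int m = (int) x.size();
  PassResult res;
  res.configOK.assign(m, 0);
  res.vend.assign(m, 0.0);

  std::vector<double> lo(m), hi(m), ustar(m), B(m), slope(m);
  for (int i = 0; i < m; ++i) {
    double fprev = (i > 0) ? F[i - 1] : 0.0;
    lo[i] = std::max(0.0, F[i] - t);
    hi[i] = std::min(1.0, fprev + t);
    ustar[i] = hi[i];  // upper bound tightened by the convex hull below
  }

  std::vector<int> hull;
  hull.reserve(m);
  bool okPrev = true;  // knots 0..i-1 jointly feasible with standard boxes

  for (int i = 0; i < m; ++i) {
    // lower bound at x[i] forced by earlier boxes plus convex momentum
    double bound = -1e300;
    for (int q = 0; q < i; ++q) {
      double cand = B[q] + slope[q] * (x[i] - x[q]);
      if (cand > bound) bound = cand;
    }
    double fprev = (i > 0) ? F[i - 1] : 0.0;
    res.vend[i] = std::max(std::max(0.0, fprev - t), bound);

    // grow the lower convex hull of the upper bounds with (x[i], hi[i]);
    // new chords tighten the uppers of interior knots
    bool chordOK = true;
    while (hull.size() >= 2) {
      int u = hull[hull.size() - 2], v = hull[hull.size() - 1];
      double cv = hi[u] + (hi[i] - hi[u]) * (x[v] - x[u]) / (x[i] - x[u]);
      if (hi[v] >= cv - 1e-15) hull.pop_back(); else break;
    }
    if (!hull.empty()) {
      int u = hull.back();
      for (int q = u + 1; q < i; ++q) {
        double cv = hi[u] + (hi[i] - hi[u]) * (x[q] - x[u]) / (x[i] - x[u]);
        if (cv < ustar[q]) ustar[q] = cv;
        if (ustar[q] < lo[q] - EPS || ustar[q] < B[q] - EPS) chordOK = false;
      }
    }
    hull.push_back(i);

    // mode at knot i: lower box relaxed to F[i-1] - t, upper unchanged
    res.configOK[i] = okPrev && chordOK && (res.vend[i] <= hi[i] + EPS);

    // standard box at knot i (knot interior to a longer convex piece)
    B[i] = std::max(lo[i], bound);
    bool okHere = chordOK && (lo[i] <= hi[i] + EPS) && (B[i] <= hi[i] + EPS);

    // exit slope forced by convexity through the tightened upper bounds
    double s = 0.0;
    for (int p = 0; p < i; ++p) {
      double num = B[i] - ustar[p];
      if (num > 0) {
        double cand = num / (x[i] - x[p]);
        if (cand > s) s = cand;
      }
    }
    slope[i] = s;

    okPrev = okPrev && okHere;
  }
  return res;
}

bool feasible(const std::vector<double>& x, const std::vector<double>& F,
              const std::vector<double>& xm, const std::vector<double>& Fm,
              double t) {
  int m = (int) x.size();
  PassResult left = convex_pass(x, F, t);
  PassResult right = convex_pass(xm, Fm, t);
  for (int j = 0; j < m; ++j) {
    int jm = m - 1 - j;
    if (left.configOK[j] && right.configOK[jm]) {
      double wmax = 1.0 - right.vend[jm];
      if (left.vend[j] <= wmax + EPS) return true;
    }
  }
  return false;
}

double dip_of_sorted(const std::vector<double>& xs) {
  int n = (int) xs.size();
  std::vector<double> x, F;
  x.reserve(n); F.reserve(n);
  int i = 0;
  while (i < n) {
    int j = i;
    while (j < n && xs[j] == xs[i]) ++j;
    x.push_back(xs[i]);
    F.push_back((double) j / n);
    i = j;
  }
  int m = (int) x.size();
  if (m == 1) return 0.5 / n;

  // mirrored sample: y_i = -x_{m-1-i}; its ecdf at y_i is 1 - F[m-2-i]
  std::vector<double> xm(m), Fm(m);
  for (int k = 0; k < m; ++k) {
    int jj = m - 1 - k;
    xm[k] = -x[jj];
    Fm[k] = 1.0 - ((jj > 0) ? F[jj - 1] : 0.0);
  }

  double lo = 0.0, hi = 0.5;
  for (int it = 0; it < 48; ++it) {
    double mid = 0.5 * (lo + hi);
    if (feasible(x, F, xm, Fm, mid)) hi = mid; else lo = mid;
  }
  return 0.5 * (lo + hi);
}

} // namespace

// [[Rcpp::export]]
double dip_stat_cpp(NumericVector x_sorted) {
  std::vector<double> xs(x_sorted.begin(), x_sorted.end());
  return dip_of_sorted(xs);
}

// [[Rcpp::export]]
NumericVector dip_many_cpp(NumericMatrix u) {
  int n = u.nrow(), B = u.ncol();
  NumericVector out(B);
  std::vector<double> col(n);
  for (int b = 0; b < B; ++b) {
    for (int i = 0; i < n; ++i) col[i] = u(i, b);
    std::sort(col.begin(), col.end());
    out[b] = dip_of_sorted(col);
  }
  return out;
}
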