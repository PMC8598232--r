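#include <Rcpp.h>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// Weighted least-squares fit of a degree-d polynomial in (x - x0), returning
// the fitted value at x0 (the intercept). Normal equations are solved by
// Gaussian elimination with partial pivoting on the (d+1)x(d+1) system; x is
// rescaled by the window radius so the system stays well conditioned. On a
// (numerically) singular system the degree is reduced, down to the weighted
// mean for degree 0.
static double wls_at_point(const double* z, const double* y, const double* w,
                           int n, int degree) {
  for (int deg = degree; deg >= 1; --deg) {
    const int p = deg + 1;
    double xtx[9] = {0.0}; // up to 3x3
    double xty[3] = {0.0};
    // accumulate moments: xtx[i,j] = sum w z^(i+j), xty[i] = sum w z^i y
    for (int k = 0; k < n; ++k) {
      if (w[k] <= 0.0) continue;
      double zp = 1.0;
      double pow_z[5]; // z^0 .. z^(2*deg)
      for (int m = 0; m <= 2 * deg; ++m) {
        pow_z[m] = zp;
        zp *= z[k];
      }
      for (int i = 0; i < p; ++i) {
        xty[i] += w[k] * pow_z[i] * y[k];
        for (int j = 0; j < p; ++j) xtx[i * p + j] += w[k] * pow_z[i + j];
      }
    }
    // Gaussian elimination with partial pivoting
    double a[12]; // augmented p x (p+1)
    for (int i = 0; i < p; ++i) {
      for (int j = 0; j < p; ++j) a[i * (p + 1) + j] = xtx[i * p + j];
      a[i * (p + 1) + p] = xty[i];
    }
    bool singular = false;
    for (int col = 0; col < p && !singular; ++col) {
      int piv = col;
      for (int r = col + 1; r < p; ++r)
        if (std::fabs(a[r * (p + 1) + col]) > std::fabs(a[piv * (p + 1) + col]))
          piv = r;
      double pv = a[piv * (p + 1) + col];
      if (std::fabs(pv) < 1e-10 * (std::fabs(xtx[0]) + 1e-300)) {
        singular = true;
        break;
      }
      if (piv != col)
        for (int j = 0; j <= p; ++j)
          std::swap(a[col * (p + 1) + j], a[piv * (p + 1) + j]);
      for (int r = 0; r < p; ++r) {
        if (r == col) continue;
        double f = a[r * (p + 1) + col] / a[col * (p + 1) + col];
        for (int j = col; j <= p; ++j)
          a[r * (p + 1) + j] -= f * a[col * (p + 1) + j];
      }
    }
    if (!singular) {
      // fitted value at z = 0 is the intercept
      return a[0 * (p + 1) + p] / a[0 * (p + 1) + 0];
    }
  }
  // degree 0: weighted mean
  double sw = 0.0, swy = 0.0;
  for (int k = 0; k < n; ++k) {
    sw += w[k];
    swy += w[k] * y[k];
  }
  return sw > 0.0 ? swy / sw : NA_REAL;
}

// [[Rcpp::export]]
NumericVector cpp_local_regression(NumericVector x, NumericVector y,
                                   NumericVector w, double span,
                                   NumericVector eval_points, int degree) {
  const int n = x.size();
  if (y.size() != n || w.size() != n)
    stop("x, y and weights must have equal length");
  if (degree < 0 || degree > 2) stop("degree must be 0, 1 or 2");
  int q = (int)std::ceil(span * n);
  if (q > n) q = n;
  if (q < degree + 1)
    stop("local window of %d points cannot support a degree-%d fit; "
         "increase the span", q, degree);
  const int m = eval_points.size();
  NumericVector out(m);
  std::vector<double> z(q), yy(q), ww(q);
  for (int e = 0; e < m; ++e) {
    const double x0 = eval_points[e];
    // window of the q nearest x (x sorted ascending): grow two pointers
    int hi = (int)(std::lower_bound(x.begin(), x.end(), x0) - x.begin());
    int lo = hi - 1;
    for (int taken = 0; taken < q; ++taken) {
      bool take_left;
      if (lo < 0)
        take_left = false;
      else if (hi >= n)
        take_left = true;
      else
        take_left = (x0 - x[lo]) <= (x[hi] - x0);
      if (take_left)
        --lo;
      else
        ++hi;
    }
    ++lo; // window is x[lo..hi-1]
    double dmax = std::max(x0 - x[lo], x[hi - 1] - x0);
    int k = 0;
    // accumulate moments for the degree-2 fast path in the same pass
    double s0 = 0, s1 = 0, s2 = 0, s3 = 0, s4 = 0, t0 = 0, t1 = 0, t2 = 0;
    for (int i = lo; i < hi; ++i) {
      double zi = dmax > 0.0 ? (x[i] - x0) / dmax : 0.0;
      double tw;
      double u = std::fabs(zi);
      if (dmax <= 0.0) {
        tw = 1.0;
      } else if (u >= 1.0) {
        tw = 0.0;
      } else {
        double c = 1.0 - u * u * u;
        tw = c * c * c;
      }
      double wt = tw * w[i];
      if (wt <= 0.0) continue;
      z[k] = zi;
      yy[k] = y[i];
      ww[k] = wt;
      ++k;
      double wz = wt * zi;
      double wz2 = wz * zi;
      s0 += wt;
      s1 += wz;
      s2 += wz2;
      s3 += wz2 * zi;
      s4 += wz2 * zi * zi;
      t0 += wt * y[i];
      t1 += wz * y[i];
      t2 += wz2 * y[i];
    }
    if (degree == 2 && s0 > 0.0) {
      // Cramer's rule on the 3x3 normal equations; z is scaled to [-1, 1]
      // so entries are O(s0) and the determinant test is scale-aware
      double det = s0 * (s2 * s4 - s3 * s3) - s1 * (s1 * s4 - s2 * s3) +
                   s2 * (s1 * s3 - s2 * s2);
      if (std::fabs(det) > 1e-10 * s0 * s0 * s0) {
        double det0 = t0 * (s2 * s4 - s3 * s3) - s1 * (t1 * s4 - t2 * s3) +
                      s2 * (t1 * s3 - t2 * s2);
        out[e] = det0 / det;
        continue;
      }
    }
    out[e] = wls_at_point(z.data(), yy.data(), ww.data(), k, degree);
  }
  return out;
}
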