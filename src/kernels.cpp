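#include <Rcpp.h>
using namespace Rcpp;

// Green-Lagrange strain rates per triangle and consecutive frame pair.
// The deformation gradient F is solved exactly from the affine map of the
// triangle's three vertices between frames t and t+1; E = (F'F - I)/2,
// scaled to %/s by `scale` = frame_rate * 100. Triangles degenerate in the
// reference frame (|det| below tolerance) yield NA for that pair.
// [[Rcpp::export]]
List gl_rates_cpp(NumericMatrix X, NumericMatrix Y, IntegerMatrix tri,
                  double scale, double degenerate_tol) {
  const int ntri = tri.nrow(), T = X.ncol();
  NumericMatrix exx(ntri, T - 1), eyy(ntri, T - 1), exy(ntri, T - 1);
  for (int t = 0; t < T - 1; ++t) {
    for (int k = 0; k < ntri; ++k) {
      const int i1 = tri(k, 0) - 1, i2 = tri(k, 1) - 1, i3 = tri(k, 2) - 1;
      const double a = X(i2, t) - X(i1, t), b = X(i3, t) - X(i1, t);
      const double c = Y(i2, t) - Y(i1, t), d = Y(i3, t) - Y(i1, t);
      const double det = a * d - b * c;
      if (std::fabs(det) < degenerate_tol) {
        exx(k, t) = NA_REAL; eyy(k, t) = NA_REAL; exy(k, t) = NA_REAL;
        continue;
      }
      const double A = X(i2, t + 1) - X(i1, t + 1);
      const double B = X(i3, t + 1) - X(i1, t + 1);
      const double C = Y(i2, t + 1) - Y(i1, t + 1);
      const double D = Y(i3, t + 1) - Y(i1, t + 1);
      const double F11 = (A * d - B * c) / det, F12 = (B * a - A * b) / det;
      const double F21 = (C * d - D * c) / det, F22 = (D * a - C * b) / det;
      exx(k, t) = 0.5 * (F11 * F11 + F21 * F21 - 1.0) * scale;
      eyy(k, t) = 0.5 * (F12 * F12 + F22 * F22 - 1.0) * scale;
      exy(k, t) = 0.5 * (F11 * F12 + F21 * F22) * scale;
    }
  }
  return List::create(_["exx"] = exx, _["eyy"] = eyy, _["exy"] = exy);
}

// Sliding window-3 median per row; endpoints use the shortened two-point
// window (mean of the two values). NaN propagates.
// [[Rcpp::export]]
NumericMatrix median3_cpp(NumericMatrix S) {
  const int n = S.nrow(), T = S.ncol();
  NumericMatrix out(n, T);
  for (int i = 0; i < n; ++i) {
    out(i, 0) = (S(i, 0) + S(i, 1)) / 2.0;
    out(i, T - 1) = (S(i, T - 2) + S(i, T - 1)) / 2.0;
  }
  for (int t = 1; t < T - 1; ++t) {
    for (int i = 0; i < n; ++i) {
      const double a = S(i, t - 1), b = S(i, t), c = S(i, t + 1);
      const double mx = std::max(a, std::max(b, c));
      const double mn = std::min(a, std::min(b, c));
      out(i, t) = a + b + c - mx - mn;
    }
  }
  return out;
}

// Jacobi Laplacian smoothing over triangle adjacency:
// v <- (1 - w) v + w * mean(finite neighbors); rows without finite
// neighbors, and non-finite entries, are left unchanged.
// nb is ntri x 3 with 0 marking "no neighbor".
// [[Rcpp::export]]
NumericMatrix smooth_mesh_cpp(NumericMatrix S, IntegerMatrix nb,
                              int iterations, double weight) {
  const int n = S.nrow(), T = S.ncol();
  NumericMatrix cur = clone(S);
  NumericMatrix nxt(n, T);
  for (int it = 0; it < iterations; ++it) {
    for (int t = 0; t < T; ++t) {
      for (int i = 0; i < n; ++i) {
        const double v = cur(i, t);
        if (!R_finite(v)) { nxt(i, t) = v; continue; }
        double sum = 0.0; int cnt = 0;
        for (int j = 0; j < 3; ++j) {
          const int k = nb(i, j);
          if (k > 0) {
            const double u = cur(k - 1, t);
            if (R_finite(u)) { sum += u; ++cnt; }
          }
        }
        nxt(i, t) = cnt > 0 ? (1.0 - weight) * v + weight * sum / cnt : v;
      }
    }
    std::swap(cur, nxt);
  }
  return cur;
}
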