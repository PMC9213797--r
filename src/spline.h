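#ifndef IDPBD_SPLINE_H
#define IDPBD_SPLINE_H

#include <vector>
#include <cmath>
#include <stdexcept>

// Table kinds. Nonbonded tables are zero at and beyond the last knot;
// every kind continues linearly below the first knot (steep-core wall with
// a continuous force, no NaNs). Angle/dihedral abscissae are in degrees.
enum TableKind { KIND_BOND = 0, KIND_ANGLE = 1, KIND_DIHEDRAL = 2, KIND_NONBONDED = 3 };

struct Spline {
  int kind;
  std::vector<double> x, y, y2;

  // Natural cubic spline: second derivatives by the standard tridiagonal
  // sweep with y''(x0) = y''(xn) = 0.
  void setup() {
    const int n = static_cast<int>(x.size());
    y2.assign(n, 0.0);
    if (n < 3) return;
    std::vector<double> u(n, 0.0);
    for (int i = 1; i < n - 1; ++i) {
      double sig = (x[i] - x[i - 1]) / (x[i + 1] - x[i - 1]);
      double p = sig * y2[i - 1] + 2.0;
      y2[i] = (sig - 1.0) / p;
      u[i] = (y[i + 1] - y[i]) / (x[i + 1] - x[i]) -
             (y[i] - y[i - 1]) / (x[i] - x[i - 1]);
      u[i] = (6.0 * u[i] / (x[i + 1] - x[i - 1]) - sig * u[i - 1]) / p;
    }
    for (int k = n - 2; k >= 0; --k) y2[k] = y2[k] * y2[k + 1] + u[k];
  }

  // In-range cubic evaluation on interval klo.
  inline void eval_interval(int klo, double xi, double &e, double &d) const {
    const int khi = klo + 1;
    const double h = x[khi] - x[klo];
    const double A = (x[khi] - xi) / h, B = (xi - x[klo]) / h;
    e = A * y[klo] + B * y[khi] +
        ((A * A * A - A) * y2[klo] + (B * B * B - B) * y2[khi]) * h * h / 6.0;
    d = (y[khi] - y[klo]) / h -
        (3.0 * A * A - 1.0) / 6.0 * h * y2[klo] +
        (3.0 * B * B - 1.0) / 6.0 * h * y2[khi];
  }

  // Derivative at an endpoint (used for linear continuation).
  inline double end_slope(bool lower) const {
    double e, d;
    eval_interval(lower ? 0 : static_cast<int>(x.size()) - 2,
                  lower ? x.front() : x.back(), e, d);
    return d;
  }

  // Energy and dU/dx with boundary rules.
  void eval(double xi, double &e, double &d) const {
    if (kind == KIND_ANGLE || kind == KIND_DIHEDRAL) {
      xi -= 360.0 * std::floor(xi / 360.0);  // normalize into [0, 360)
    }
    const int n = static_cast<int>(x.size());
    if (xi <= x.front()) {
      const double s = end_slope(true);
      e = y.front() + s * (xi - x.front());
      d = s;
      return;
    }
    if (xi >= x.back()) {
      if (kind == KIND_NONBONDED) { e = 0.0; d = 0.0; return; }
      const double s = end_slope(false);
      e = y.back() + s * (xi - x.back());
      d = s;
      return;
    }
    int klo = 0, khi = n - 1;
    while (khi - klo > 1) {
      int k = (khi + klo) >> 1;
      if (x[k] > xi) khi = k; else klo = k;
    }
    eval_interval(klo, xi, e, d);
  }
};

#endif
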