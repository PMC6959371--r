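#include "mls.h"
#include <cmath>

// Cubic B-spline window on q = d / rs, compactly supported on q < 1.
static inline double spline_w(double q) {
  if (q >= 1.0) return 0.0;
  if (q <= 0.5) return 2.0 / 3.0 - 4.0 * q * q + 4.0 * q * q * q;
  double r = 1.0 - q;
  return 4.0 / 3.0 * r * r * r;
}

static int build_at(double xp, double yp, int Nx, int Ny, double rs,
                    bool wrap_x, MLSStencil &st) {
  st.n = 0;
  int x0 = (int)std::floor(xp - rs), x1 = (int)std::ceil(xp + rs);
  int y0 = (int)std::floor(yp - rs), y1 = (int)std::ceil(yp + rs);
  if (y0 < 0) y0 = 0;
  if (y1 > Ny - 1) y1 = Ny - 1;
  double A[3][3] = {{0}};
  double px[MLSStencil::MAXN], py[MLSStencil::MAXN], wv[MLSStencil::MAXN];
  for (int y = y0; y <= y1; ++y) {
    for (int x = x0; x <= x1; ++x) {
      int xg = x;
      if (wrap_x) {
        xg = ((x % Nx) + Nx) % Nx;
      } else if (x < 0 || x > Nx - 1) {
        continue;
      }
      double dx = x - xp, dy = y - yp;
      double q = std::sqrt(dx * dx + dy * dy) / rs;
      double w = spline_w(q);
      if (w <= 0.0) continue;
      if (st.n >= MLSStencil::MAXN) return 1;
      st.idx[st.n] = xg + Nx * y;
      px[st.n] = dx;
      py[st.n] = dy;
      wv[st.n] = w;
      A[0][0] += w;
      A[0][1] += w * dx;
      A[0][2] += w * dy;
      A[1][1] += w * dx * dx;
      A[1][2] += w * dx * dy;
      A[2][2] += w * dy * dy;
      ++st.n;
    }
  }
  if (st.n < 3) return 1;
  A[1][0] = A[0][1];
  A[2][0] = A[0][2];
  A[2][1] = A[1][2];
  // Invert the 3x3 moment matrix.
  double det = A[0][0] * (A[1][1] * A[2][2] - A[1][2] * A[2][1]) -
               A[0][1] * (A[1][0] * A[2][2] - A[1][2] * A[2][0]) +
               A[0][2] * (A[1][0] * A[2][1] - A[1][1] * A[2][0]);
  if (std::fabs(det) < 1e-12) return 1;
  double inv[3][3];
  inv[0][0] = (A[1][1] * A[2][2] - A[1][2] * A[2][1]) / det;
  inv[0][1] = (A[0][2] * A[2][1] - A[0][1] * A[2][2]) / det;
  inv[0][2] = (A[0][1] * A[1][2] - A[0][2] * A[1][1]) / det;
  inv[1][0] = (A[1][2] * A[2][0] - A[1][0] * A[2][2]) / det;
  inv[1][1] = (A[0][0] * A[2][2] - A[0][2] * A[2][0]) / det;
  inv[1][2] = (A[0][2] * A[1][0] - A[0][0] * A[1][2]) / det;
  inv[2][0] = (A[1][0] * A[2][1] - A[1][1] * A[2][0]) / det;
  inv[2][1] = (A[0][1] * A[2][0] - A[0][0] * A[2][1]) / det;
  inv[2][2] = (A[0][0] * A[1][1] - A[0][1] * A[1][0]) / det;
  for (int j = 0; j < st.n; ++j) {
    double p0 = 1.0, p1 = px[j], p2 = py[j], w = wv[j];
    st.phi[j] = (inv[0][0] * p0 + inv[0][1] * p1 + inv[0][2] * p2) * w;
    st.phx[j] = (inv[1][0] * p0 + inv[1][1] * p1 + inv[1][2] * p2) * w;
    st.phy[j] = (inv[2][0] * p0 + inv[2][1] * p1 + inv[2][2] * p2) * w;
  }
  return 0;
}

int mls_build(double xp, double yp, int Nx, int Ny, double rs,
              bool wrap_x, MLSStencil &st) {
  if (build_at(xp, yp, Nx, Ny, rs, wrap_x, st) == 0) return 0;
  // Degenerate support (e.g. clipped hard at a wall): widen once.
  return build_at(xp, yp, Nx, Ny, 1.6 * rs, wrap_x, st);
}
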