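#include <Rcpp.h>
#include "d2q9.h"
#include "mls.h"
using namespace Rcpp;

// Equilibrium populations for vectors of density and velocity.
// [[Rcpp::export]]
NumericMatrix cpp_equilibrium(NumericVector rho, NumericVector ux,
                              NumericVector uy) {
  int n = rho.size();
  NumericMatrix out(n, 9);
  for (int k = 0; k < n; ++k)
    for (int i = 0; i < 9; ++i)
      out(k, i) = d2q9_feq(i, rho[k], ux[k], uy[k]);
  return out;
}

// Guo forcing contributions for vectors of velocity and body-force density.
// [[Rcpp::export]]
NumericMatrix cpp_guo_forcing(NumericVector ux, NumericVector uy,
                              NumericVector gx, NumericVector gy, double tau) {
  int n = ux.size();
  NumericMatrix out(n, 9);
  for (int k = 0; k < n; ++k)
    for (int i = 0; i < 9; ++i)
      out(k, i) = d2q9_guo(i, ux[k], uy[k], gx[k], gy[k], tau);
  return out;
}

// One BGK collide-and-stream sweep on an Nx x Ny x 9 population array
// (column-major, index x + Nx*(y + Ny*i)).  x is periodic; y is periodic
// when periodic_y, otherwise populations leaving through the wall rows are
// dropped and the incoming unknowns are zeroed (to be reconstructed by the
// Zou-He closure).  gx/gy is an optional body-force density field.
// [[Rcpp::export]]
NumericVector cpp_collide_stream(NumericVector f, int Nx, int Ny, double tau,
                                 Nullable<NumericVector> gx_,
                                 Nullable<NumericVector> gy_,
                                 bool periodic_y) {
  int nn = Nx * Ny;
  NumericVector fnew(f.size());
  const double *g_x = NULL, *g_y = NULL;
  NumericVector gx, gy;
  if (gx_.isNotNull()) {
    gx = gx_.get();
    gy = gy_.get();
    g_x = gx.begin();
    g_y = gy.begin();
  }
  const double *fp = f.begin();
  double *fo = fnew.begin();
  for (int y = 0; y < Ny; ++y) {
    for (int x = 0; x < Nx; ++x) {
      int id = x + Nx * y;
      double fl[9];
      double rho = 0.0, mx = 0.0, my = 0.0;
      for (int i = 0; i < 9; ++i) {
        fl[i] = fp[id + nn * i];
        rho += fl[i];
        mx += fl[i] * D2Q9_EX[i];
        my += fl[i] * D2Q9_EY[i];
      }
      if (!(rho > 0.0) || rho != rho)
        stop("non-positive or NaN density during collision at node (%d, %d)",
             x + 1, y + 1);
      double lgx = g_x ? g_x[id] : 0.0, lgy = g_y ? g_y[id] : 0.0;
      double ux = (mx + 0.5 * lgx) / rho, uy = (my + 0.5 * lgy) / rho;
      for (int i = 0; i < 9; ++i) {
        double post = fl[i] - (fl[i] - d2q9_feq(i, rho, ux, uy)) / tau +
                      d2q9_guo(i, ux, uy, lgx, lgy, tau);
        int xd = x + D2Q9_EX[i];
        int yd = y + D2Q9_EY[i];
        if (xd < 0) xd += Nx; else if (xd >= Nx) xd -= Nx;
        if (periodic_y) {
          if (yd < 0) yd += Ny; else if (yd >= Ny) yd -= Ny;
        } else if (yd < 0 || yd >= Ny) {
          continue;
        }
        fo[xd + Nx * yd + nn * i] = post;
      }
    }
  }
  return fnew;
}

// Zou-He known-velocity closure on the wall rows: reconstructs the three
// populations entering from outside so the row recovers exactly the
// prescribed tangential wall velocity (normal velocity zero).  The channel
// is x-periodic, so wall rows have no corner nodes.
// [[Rcpp::export]]
NumericVector cpp_zou_he(NumericVector f, int Nx, int Ny,
                         double u_bottom, double u_top) {
  NumericVector out = clone(f);
  int nn = Nx * Ny;
  double *fp = out.begin();
  for (int x = 0; x < Nx; ++x) {
    { // bottom row y = 0: unknowns i = 2 (N), 5 (NE), 6 (NW)
      int id = x;
      double f0 = fp[id], f1 = fp[id + nn], f3 = fp[id + 3 * nn];
      double f4 = fp[id + 4 * nn], f7 = fp[id + 7 * nn], f8 = fp[id + 8 * nn];
      double rho = f0 + f1 + f3 + 2.0 * (f4 + f7 + f8);
      fp[id + 2 * nn] = f4;
      fp[id + 5 * nn] = f7 - 0.5 * (f1 - f3) + 0.5 * rho * u_bottom;
      fp[id + 6 * nn] = f8 + 0.5 * (f1 - f3) - 0.5 * rho * u_bottom;
    }
    { // top row y = Ny-1: unknowns i = 4 (S), 7 (SW), 8 (SE)
      int id = x + Nx * (Ny - 1);
      double f0 = fp[id], f1 = fp[id + nn], f3 = fp[id + 3 * nn];
      double f2 = fp[id + 2 * nn], f5 = fp[id + 5 * nn], f6 = fp[id + 6 * nn];
      double rho = f0 + f1 + f3 + 2.0 * (f2 + f5 + f6);
      fp[id + 4 * nn] = f2;
      fp[id + 7 * nn] = f5 + 0.5 * (f1 - f3) - 0.5 * rho * u_top;
      fp[id + 8 * nn] = f6 - 0.5 * (f1 - f3) + 0.5 * rho * u_top;
    }
  }
  return out;
}

// Macroscopic moments with the Guo half-force correction.
// [[Rcpp::export]]
List cpp_moments(NumericVector f, int Nx, int Ny,
                 Nullable<NumericVector> gx_, Nullable<NumericVector> gy_) {
  int nn = Nx * Ny;
  NumericVector rho(nn), ux(nn), uy(nn);
  const double *g_x = NULL, *g_y = NULL;
  NumericVector gx, gy;
  if (gx_.isNotNull()) {
    gx = gx_.get();
    gy = gy_.get();
    g_x = gx.begin();
    g_y = gy.begin();
  }
  const double *fp = f.begin();
  for (int id = 0; id < nn; ++id) {
    double r = 0.0, mx = 0.0, my = 0.0;
    for (int i = 0; i < 9; ++i) {
      double v = fp[id + nn * i];
      r += v;
      mx += v * D2Q9_EX[i];
      my += v * D2Q9_EY[i];
    }
    if (!(r > 0.0))
      stop("non-positive density in compute_moments (node %d)", id + 1);
    rho[id] = r;
    ux[id] = (mx + 0.5 * (g_x ? g_x[id] : 0.0)) / r;
    uy[id] = (my + 0.5 * (g_y ? g_y[id] : 0.0)) / r;
  }
  return List::create(_["rho"] = rho, _["ux"] = ux, _["uy"] = uy);
}

// Pure-fluid channel integrator (no immersed body): collide-stream with a
// uniform body force plus Zou-He walls, for benchmark/convergence runs.
// [[Rcpp::export]]
NumericVector cpp_run_channel(NumericVector f, int Nx, int Ny, double tau,
                              double gx, double gy, double u_bottom,
                              double u_top, int nsteps) {
  int nn = Nx * Ny;
  std::vector<double> a(f.begin(), f.end()), b(f.size());
  NumericVector gxf(nn, gx), gyf(nn, gy);
  bool forced = (gx != 0.0 || gy != 0.0);
  for (int s = 0; s < nsteps; ++s) {
    const double *fp = a.data();
    double *fo = b.data();
    for (int i = 0; i < 9; ++i) { // clear wall-row destinations
      for (int x = 0; x < Nx; ++x) {
        fo[x + nn * i] = 0.0;
        fo[x + Nx * (Ny - 1) + nn * i] = 0.0;
      }
    }
    for (int y = 0; y < Ny; ++y) {
      for (int x = 0; x < Nx; ++x) {
        int id = x + Nx * y;
        double fl[9];
        double rho = 0.0, mx = 0.0, my = 0.0;
        for (int i = 0; i < 9; ++i) {
          fl[i] = fp[id + nn * i];
          rho += fl[i];
          mx += fl[i] * D2Q9_EX[i];
          my += fl[i] * D2Q9_EY[i];
        }
        double ux = (mx + 0.5 * gx) / rho, uy = (my + 0.5 * gy) / rho;
        for (int i = 0; i < 9; ++i) {
          double post = fl[i] - (fl[i] - d2q9_feq(i, rho, ux, uy)) / tau;
          if (forced) post += d2q9_guo(i, ux, uy, gx, gy, tau);
          int xd = x + D2Q9_EX[i];
          int yd = y + D2Q9_EY[i];
          if (xd < 0) xd += Nx; else if (xd >= Nx) xd -= Nx;
          if (yd < 0 || yd >= Ny) continue;
          fo[xd + Nx * yd + nn * i] = post;
        }
      }
    }
    // Zou-He rows
    for (int x = 0; x < Nx; ++x) {
      {
        int id = x;
        double f0 = fo[id], f1 = fo[id + nn], f3 = fo[id + 3 * nn];
        double f4 = fo[id + 4 * nn], f7 = fo[id + 7 * nn],
               f8 = fo[id + 8 * nn];
        double rho = f0 + f1 + f3 + 2.0 * (f4 + f7 + f8);
        fo[id + 2 * nn] = f4;
        fo[id + 5 * nn] = f7 - 0.5 * (f1 - f3) + 0.5 * rho * u_bottom;
        fo[id + 6 * nn] = f8 + 0.5 * (f1 - f3) - 0.5 * rho * u_bottom;
      }
      {
        int id = x + Nx * (Ny - 1);
        double f0 = fo[id], f1 = fo[id + nn], f3 = fo[id + 3 * nn];
        double f2 = fo[id + 2 * nn], f5 = fo[id + 5 * nn],
               f6 = fo[id + 6 * nn];
        double rho = f0 + f1 + f3 + 2.0 * (f2 + f5 + f6);
        fo[id + 4 * nn] = f2;
        fo[id + 7 * nn] = f5 + 0.5 * (f1 - f3) - 0.5 * rho * u_top;
        fo[id + 8 * nn] = f6 - 0.5 * (f1 - f3) + 0.5 * rho * u_top;
      }
    }
    std::swap(a, b);
  }
  NumericVector out(f.size());
  std::copy(a.begin(), a.end(), out.begin());
  return out;
}

// MLS stencil at a point: node indices (1-based, flattened x + Nx*(y-1)
// column-major), interpolation weights and diffuse-derivative weights.
// [[Rcpp::export]]
List cpp_mls_stencil(double xp, double yp, int Nx, int Ny, double rs,
                     bool wrap_x) {
  MLSStencil st;
  if (mls_build(xp, yp, Nx, Ny, rs, wrap_x, st) != 0)
    stop("MLS support is degenerate at point (%g, %g)", xp, yp);
  IntegerVector idx(st.n);
  NumericVector phi(st.n), phx(st.n), phy(st.n);
  for (int j = 0; j < st.n; ++j) {
    idx[j] = st.idx[j] + 1;
    phi[j] = st.phi[j];
    phx[j] = st.phx[j];
    phy[j] = st.phy[j];
  }
  return List::create(_["idx"] = idx, _["phi"] = phi, _["dphi_dx"] = phx,
                      _["dphi_dy"] = phy);
}
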