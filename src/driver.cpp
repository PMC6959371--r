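#include <Rcpp.h>
#include <fstream>
#include <sstream>
#include <iomanip>
#include <cmath>
#include <vector>
#include "d2q9.h"
#include "mls.h"
using namespace Rcpp;

// Fused LB-IB time loop: D2Q9 BGK fluid with Guo forcing and Zou-He walls,
// moving-least-squares immersed boundary with probe-based load evaluation,
// stochastic ligand-receptor bond kinetics, van der Waals wall repulsion,
// and explicit second-order (BDF2-type) rigid-body dynamics with weak
// coupling.  All quantities in lattice units (dx = dt = 1); randomness is
// drawn from the R generator so runs are reproducible via set.seed().

struct Fields {
  int Nx, Ny, nn;
  std::vector<double> fa, fb, gx, gy, rho, ux, uy;
};

static void full_moments(const std::vector<double> &f, Fields &F) {
  for (int id = 0; id < F.nn; ++id) {
    double r = 0, mx = 0, my = 0;
    for (int i = 0; i < 9; ++i) {
      double v = f[id + F.nn * i];
      r += v;
      mx += v * D2Q9_EX[i];
      my += v * D2Q9_EY[i];
    }
    F.rho[id] = r;
    F.ux[id] = (mx + 0.5 * F.gx[id]) / r;
    F.uy[id] = (my + 0.5 * F.gy[id]) / r;
  }
}

static void write_vtk(const std::string &path, const Fields &F) {
  std::ofstream os(path.c_str());
  os << "# vtk DataFile Version 2.0\nlbadhesion fields\nASCII\n";
  os << "DATASET STRUCTURED_POINTS\n";
  os << "DIMENSIONS " << F.Nx << " " << F.Ny << " 1\n";
  os << "ORIGIN 0 0 0\nSPACING 1 1 1\n";
  os << "POINT_DATA " << F.nn << "\n";
  os << std::setprecision(10);
  os << "SCALARS density double 1\nLOOKUP_TABLE default\n";
  for (int id = 0; id < F.nn; ++id) os << F.rho[id] << "\n";
  os << "SCALARS pressure double 1\nLOOKUP_TABLE default\n";
  for (int id = 0; id < F.nn; ++id) os << D2Q9_CS2 * F.rho[id] << "\n";
  os << "VECTORS velocity double\n";
  for (int id = 0; id < F.nn; ++id)
    os << F.ux[id] << " " << F.uy[id] << " 0\n";
}

// [[Rcpp::export]]
List cpp_run_near_wall(List cfg) {
  const int Nx = as<int>(cfg["Nx"]), Ny = as<int>(cfg["Ny"]);
  const double tau = as<double>(cfg["tau"]);
  const double u_top = as<double>(cfg["u_max"]);
  const int nsteps = as<int>(cfg["nsteps"]);
  const int sample_every = as<int>(cfg["sample_every"]);
  const double nu = (tau - 0.5) / 3.0;

  NumericMatrix tmpl = cfg["markers"]; // body frame, CCW, relative centroid
  const int nm = tmpl.nrow();
  LogicalVector lig = cfg["ligand"]; // per element
  double xc = as<double>(cfg["x_c0"]), yc = as<double>(cfg["y_c0"]);
  double th = as<double>(cfg["theta0"]);
  const double mass = as<double>(cfg["mass"]);
  const double inertia = as<double>(cfg["inertia"]);

  const double sigma = as<double>(cfg["sigma_lat"]);
  const double sigma_eq = 0.5 * sigma;
  const double y_cr = as<double>(cfg["y_cr_lat"]);
  const double y_eq = as<double>(cfg["y_eq_lat"]);
  const double kf_dt = as<double>(cfg["kf_dt"]);
  const double kr0_dt = as<double>(cfg["kr0_dt"]);
  const double kBT = as<double>(cfg["kBT_lat"]);
  const double Hk = as<double>(cfg["Hk_lat"]);
  const double r_eq = as<double>(cfg["r_eq_lat"]);
  const double eps_floor = as<double>(cfg["eps_floor"]);
  const double probe_len = as<double>(cfg["probe_len"]);
  const double rs = as<double>(cfg["mls_rs"]);
  const int dump_every = as<int>(cfg["dump_every"]);
  std::string dump_prefix = as<std::string>(cfg["dump_prefix"]);

  Fields F;
  F.Nx = Nx; F.Ny = Ny; F.nn = Nx * Ny;
  const int nn = F.nn;
  F.fa.assign(9 * nn, 0.0); F.fb.assign(9 * nn, 0.0);
  F.gx.assign(nn, 0.0); F.gy.assign(nn, 0.0);
  F.rho.assign(nn, 1.0); F.ux.assign(nn, 0.0); F.uy.assign(nn, 0.0);

  // Initialize at the developed Couette base state (exact LBM solution).
  const double H = Ny - 1.0;
  for (int y = 0; y < Ny; ++y) {
    double u0 = u_top * y / H;
    for (int x = 0; x < Nx; ++x)
      for (int i = 0; i < 9; ++i)
        F.fa[x + Nx * y + nn * i] = d2q9_feq(i, 1.0, u0, 0.0);
  }

  // Rigid body state (BDF2 history).
  double uxp = 0, uyp = 0, omp = 0;    // u(t - dt)
  double uxpp = 0, uypp = 0, ompp = 0; // u(t - 2dt)

  // Bond state per element.
  std::vector<int> active(nm, 0);
  std::vector<double> anchor(nm, 0.0);

  std::vector<double> mx(nm), my(nm), cx(nm), cy(nm), nxv(nm), nyv(nm),
      Sl(nm);

  const int nsamp = nsteps / sample_every + 1;
  NumericMatrix traj(nsamp, 13);
  int srow = 0;

  MLSStencil st;
  double xdisp = 0.0; // cumulative centroid displacement (unwrapped)

  for (int s = 0; s <= nsteps; ++s) {
    // --- geometry: markers and elements from current state ---
    double cth = std::cos(th), sth = std::sin(th);
    double ymin = 1e30;
    for (int k = 0; k < nm; ++k) {
      double bx = tmpl(k, 0), by = tmpl(k, 1);
      double px = xc + cth * bx - sth * by;
      double py = yc + sth * bx + cth * by;
      px -= Nx * std::floor(px / Nx);
      mx[k] = px; my[k] = py;
      if (py < ymin) ymin = py;
    }
    if (ymin < 0.0)
      stop("particle crossed the wall at step %d (y_min = %g)", s, ymin);
    double xbmin = 1e30, xbmax = -1e30, ybmin = 1e30, ybmax = -1e30;
    for (int k = 0; k < nm; ++k) {
      int k2 = (k + 1) % nm;
      double dxe = mx[k2] - mx[k];
      if (dxe > 0.5 * Nx) dxe -= Nx;
      if (dxe < -0.5 * Nx) dxe += Nx;
      double dye = my[k2] - my[k];
      double len = std::sqrt(dxe * dxe + dye * dye);
      cx[k] = mx[k] + 0.5 * dxe;
      cx[k] -= Nx * std::floor(cx[k] / Nx);
      cy[k] = 0.5 * (my[k] + my[k2]);
      nxv[k] = dye / len; nyv[k] = -dxe / len; // outward for CCW perimeter
      Sl[k] = len;
      if (cx[k] < xbmin) xbmin = cx[k];
      if (cx[k] > xbmax) xbmax = cx[k];
      if (cy[k] < ybmin) ybmin = cy[k];
      if (cy[k] > ybmax) ybmax = cy[k];
    }
    // moment box (padded; x wrapped per column)
    const int pad = (int)std::ceil(rs + probe_len) + 4;
    int bx0 = (int)std::floor(xbmin) - pad, bx1 = (int)std::ceil(xbmax) + pad;
    int by0 = (int)std::floor(ybmin) - pad, by1 = (int)std::ceil(ybmax) + pad;
    if (by0 < 0) by0 = 0;
    if (by1 > Ny - 1) by1 = Ny - 1;
    if (bx1 - bx0 >= Nx) { bx0 = 0; bx1 = Nx - 1; }

    // --- pre-force moments in the box (u* without force) ---
    for (int y = by0; y <= by1; ++y) {
      for (int xr = bx0; xr <= bx1; ++xr) {
        int x = ((xr % Nx) + Nx) % Nx;
        int id = x + Nx * y;
        double r = 0, qx = 0, qy = 0;
        for (int i = 0; i < 9; ++i) {
          double v = F.fa[id + nn * i];
          r += v;
          qx += v * D2Q9_EX[i];
          qy += v * D2Q9_EY[i];
        }
        if (!(r > 0.0) || r != r)
          stop("fluid instability (density %g) at step %d", r, s);
        F.rho[id] = r;
        F.ux[id] = qx / r;
        F.uy[id] = qy / r;
        F.gx[id] = 0.0;
        F.gy[id] = 0.0;
      }
    }

    // --- direct-forcing IB: spread momentum correction ---
    for (int k = 0; k < nm; ++k) {
      if (mls_build(cx[k], cy[k], Nx, Ny, rs, true, st) != 0)
        stop("degenerate MLS support at element %d, step %d", k + 1, s);
      double uf = 0, vf = 0;
      for (int j = 0; j < st.n; ++j) {
        uf += st.phi[j] * F.ux[st.idx[j]];
        vf += st.phi[j] * F.uy[st.idx[j]];
      }
      double rx = cx[k] - xc, ry = cy[k] - yc;
      if (rx > 0.5 * Nx) rx -= Nx;
      if (rx < -0.5 * Nx) rx += Nx;
      double Ut = uxp - omp * ry, Vt = uyp + omp * rx;
      double Fx = (Ut - uf) * Sl[k], Fy = (Vt - vf) * Sl[k];
      for (int j = 0; j < st.n; ++j) {
        int idy = st.idx[j] / Nx;
        if (idy == 0 || idy == Ny - 1) continue; // keep Zou-He rows clean
        F.gx[st.idx[j]] += st.phi[j] * Fx;
        F.gy[st.idx[j]] += st.phi[j] * Fy;
      }
    }
    // half-force velocity correction in the box
    for (int y = by0; y <= by1; ++y)
      for (int xr = bx0; xr <= bx1; ++xr) {
        int x = ((xr % Nx) + Nx) % Nx;
        int id = x + Nx * y;
        F.ux[id] += 0.5 * F.gx[id] / F.rho[id];
        F.uy[id] += 0.5 * F.gy[id] / F.rho[id];
      }

    // --- probe-based load evaluation ---
    double Fpx = 0, Fpy = 0, Fvx = 0, Fvy = 0, Mz = 0;
    for (int k = 0; k < nm; ++k) {
      double pxp = cx[k] + probe_len * nxv[k];
      double pyp = cy[k] + probe_len * nyv[k];
      if (pyp < 0.1) pyp = 0.1; // probe clamped inside the fluid
      if (pyp > Ny - 1.1) pyp = Ny - 1.1;
      pxp -= Nx * std::floor(pxp / Nx);
      if (mls_build(pxp, pyp, Nx, Ny, rs, true, st) != 0)
        stop("degenerate MLS support at probe %d, step %d", k + 1, s);
      double pr = 0, dudx = 0, dudy = 0, dvdx = 0, dvdy = 0;
      for (int j = 0; j < st.n; ++j) {
        int id = st.idx[j];
        pr += st.phi[j] * F.rho[id];
        dudx += st.phx[j] * F.ux[id];
        dudy += st.phy[j] * F.ux[id];
        dvdx += st.phx[j] * F.uy[id];
        dvdy += st.phy[j] * F.uy[id];
      }
      double p = D2Q9_CS2 * pr;
      double mu = nu * pr; // dynamic viscosity (rho ~ 1)
      double txx = 2.0 * mu * dudx, tyy = 2.0 * mu * dvdy;
      double txy = mu * (dudy + dvdx);
      double fpx = -p * nxv[k] * Sl[k];
      double fpy = -p * nyv[k] * Sl[k];
      double fvx = (txx * nxv[k] + txy * nyv[k]) * Sl[k];
      double fvy = (txy * nxv[k] + tyy * nyv[k]) * Sl[k];
      Fpx += fpx; Fpy += fpy; Fvx += fvx; Fvy += fvy;
      double rx = cx[k] - xc, ry = cy[k] - yc;
      if (rx > 0.5 * Nx) rx -= Nx;
      if (rx < -0.5 * Nx) rx += Nx;
      Mz += rx * (fpy + fvy) - ry * (fpx + fvx);
    }

    // --- adhesion: formation sweep then rupture sweep ---
    int n_in_range = 0;
    for (int k = 0; k < nm; ++k)
      if (lig[k] && cy[k] < y_cr) ++n_in_range;
    double nl_frac = (double)n_in_range / nm;
    double Pf = 1.0 - std::exp(-kf_dt * nl_frac);
    std::vector<int> newly(nm, 0);
    if (n_in_range > 0 && Pf > 0) {
      for (int k = 0; k < nm; ++k) {
        if (lig[k] && !active[k] && cy[k] < y_cr) {
          if (R::runif(0.0, 1.0) < Pf) {
            active[k] = 1;
            anchor[k] = cx[k];
            newly[k] = 1;
          }
        }
      }
    }
    double Fbx = 0, Fby = 0, Mb = 0;
    int n_active = 0;
    for (int k = 0; k < nm; ++k) {
      if (!active[k]) continue;
      double dxa = anchor[k] - cx[k];
      if (dxa > 0.5 * Nx) dxa -= Nx;
      if (dxa < -0.5 * Nx) dxa += Nx;
      double dya = 0.0 - cy[k];
      double yl = std::sqrt(dxa * dxa + dya * dya);
      if (!newly[k]) {
        double ex = (sigma - sigma_eq) * (yl - y_eq) * (yl - y_eq) /
                    (2.0 * kBT);
        if (ex > 50.0) ex = 50.0;
        double Pr = 1.0 - std::exp(-kr0_dt * std::exp(ex));
        if (R::runif(0.0, 1.0) < Pr) {
          active[k] = 0;
          continue;
        }
      }
      ++n_active;
      double f = sigma * (yl - y_eq); // along element -> anchor direction
      double ux_ = dxa / yl, uy_ = dya / yl;
      double fx = f * ux_ * Sl[k], fy = f * uy_ * Sl[k];
      Fbx += fx; Fby += fy;
      double rx = cx[k] - xc, ry = cy[k] - yc;
      if (rx > 0.5 * Nx) rx -= Nx;
      if (rx < -0.5 * Nx) rx += Nx;
      Mb += rx * fy - ry * fx;
    }

    // van der Waals-like wall repulsion at the centroid
    double eps = ymin < eps_floor ? eps_floor : ymin;
    double Fw = Hk / (8.0 * std::sqrt(2.0)) *
                std::sqrt(r_eq / (eps * eps * eps * eps * eps));

    // --- sampling (state before the step's dynamic update) ---
    if (s % sample_every == 0) {
      traj(srow, 0) = s;
      traj(srow, 1) = xdisp;
      traj(srow, 2) = yc;
      traj(srow, 3) = th;
      traj(srow, 4) = uxp;
      traj(srow, 5) = uyp;
      traj(srow, 6) = omp;
      traj(srow, 7) = ymin;
      traj(srow, 8) = n_active;
      traj(srow, 9) = n_in_range;
      traj(srow, 10) = Fpx + Fvx + Fbx;
      traj(srow, 11) = Fpy + Fvy + Fby + Fw;
      traj(srow, 12) = Mz + Mb;
      ++srow;
    }
    if (dump_every > 0 && s % dump_every == 0) {
      full_moments(F.fa, F);
      std::ostringstream nm_;
      nm_ << dump_prefix << "_" << std::setw(7) << std::setfill('0') << s
          << ".vtk";
      write_vtk(nm_.str(), F);
    }
    if (s == nsteps) break;

    // --- rigid-body update (explicit second-order multistep) ---
    double ax = (Fpx + Fvx + Fbx) / mass;
    double ay = (Fpy + Fvy + Fby + Fw) / mass;
    double aom = (Mz + Mb) / inertia;
    double uxn, uyn, omn;
    if (s < 2) { // bootstrap: forward Euler fills the history
      uxn = uxp + ax; uyn = uyp + ay; omn = omp + aom;
    } else {
      uxn = (2.0 / 3.0) * (2.0 * uxp - 0.5 * uxpp + ax);
      uyn = (2.0 / 3.0) * (2.0 * uyp - 0.5 * uypp + ay);
      omn = (2.0 / 3.0) * (2.0 * omp - 0.5 * ompp + aom);
    }
    if (std::fabs(uxn) > 0.5 || std::fabs(uyn) > 0.5 || uxn != uxn ||
        uyn != uyn || omn != omn)
      stop("rigid-body instability at step %d (u = %g, %g, omega = %g)",
           s, uxn, uyn, omn);
    uxpp = uxp; uypp = uyp; ompp = omp;
    uxp = uxn; uyp = uyn; omp = omn;
    xc += uxn; xdisp += uxn;
    yc += uyn; th += omn;
    xc -= Nx * std::floor(xc / Nx);

    // --- fluid update: collide + stream + Zou-He walls ---
    {
      const double *fp = F.fa.data();
      double *fo = F.fb.data();
      for (int i = 0; i < 9; ++i)
        for (int x = 0; x < Nx; ++x) {
          fo[x + nn * i] = 0.0;
          fo[x + Nx * (Ny - 1) + nn * i] = 0.0;
        }
      for (int y = 0; y < Ny; ++y) {
        for (int x = 0; x < Nx; ++x) {
          int id = x + Nx * y;
          double fl[9];
          double r = 0, qx = 0, qy = 0;
          for (int i = 0; i < 9; ++i) {
            fl[i] = fp[id + nn * i];
            r += fl[i];
            qx += fl[i] * D2Q9_EX[i];
            qy += fl[i] * D2Q9_EY[i];
          }
          double lgx = F.gx[id], lgy = F.gy[id];
          double ux_ = (qx + 0.5 * lgx) / r, uy_ = (qy + 0.5 * lgy) / r;
          bool forced = (lgx != 0.0 || lgy != 0.0);
          for (int i = 0; i < 9; ++i) {
            double post = fl[i] - (fl[i] - d2q9_feq(i, r, ux_, uy_)) / tau;
            if (forced) post += d2q9_guo(i, ux_, uy_, lgx, lgy, tau);
            int xd = x + D2Q9_EX[i];
            int yd = y + D2Q9_EY[i];
            if (xd < 0) xd += Nx; else if (xd >= Nx) xd -= Nx;
            if (yd < 0 || yd >= Ny) continue;
            fo[xd + Nx * yd + nn * i] = post;
          }
        }
      }
      for (int x = 0; x < Nx; ++x) {
        {
          int id = x;
          double f0 = fo[id], f1 = fo[id + nn], f3 = fo[id + 3 * nn];
          double f4 = fo[id + 4 * nn], f7 = fo[id + 7 * nn],
                 f8 = fo[id + 8 * nn];
          (void)f0;
          fo[id + 2 * nn] = f4;
          fo[id + 5 * nn] = f7 - 0.5 * (f1 - f3);
          fo[id + 6 * nn] = f8 + 0.5 * (f1 - f3);
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
      std::swap(F.fa, F.fb);
    }
    if (s % 2000 == 0) Rcpp::checkUserInterrupt();
  }

  full_moments(F.fa, F);
  NumericMatrix rho_out(Nx, Ny), ux_out(Nx, Ny), uy_out(Nx, Ny);
  std::copy(F.rho.begin(), F.rho.end(), rho_out.begin());
  std::copy(F.ux.begin(), F.ux.end(), ux_out.begin());
  std::copy(F.uy.begin(), F.uy.end(), uy_out.begin());
  NumericMatrix markers(nm, 2);
  IntegerVector bond_active(nm);
  int n_lig = 0;
  for (int k = 0; k < nm; ++k) {
    markers(k, 0) = mx[k];
    markers(k, 1) = my[k];
    bond_active[k] = active[k];
    if (lig[k]) ++n_lig;
  }
  return List::create(
      _["trajectory"] = traj, _["rho"] = rho_out, _["ux"] = ux_out,
      _["uy"] = uy_out, _["markers"] = markers,
      _["bond_active"] = bond_active, _["n_elements"] = nm,
      _["n_ligands"] = n_lig);
}
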