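#ifndef LBADHESION_MLS_H
#define LBADHESION_MLS_H

// Moving-least-squares stencil at an off-grid point: linear basis
// (1, x - xp, y - yp), cubic-spline window over a circular support of
// radius rs grid spacings.  Returns shape-function weights (partition of
// unity, linear-complete) and diffuse-derivative weights (slopes of the
// local linear fit).
//
// The grid is Nx columns by Ny rows, x optionally periodic, y clipped to
// [0, Ny-1] (supports touching a wall keep only in-domain nodes).
struct MLSStencil {
  static const int MAXN = 128;
  int n;
  int idx[MAXN];     // flattened 0-based node index x + Nx * y
  double phi[MAXN];  // interpolation weights
  double phx[MAXN];  // d/dx weights
  double phy[MAXN];  // d/dy weights
};

// Returns 0 on success, 1 if the support is degenerate.
int mls_build(double xp, double yp, int Nx, int Ny, double rs,
              bool wrap_x, MLSStencil &st);

#endif
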