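#ifndef LBADHESION_D2Q9_H
#define LBADHESION_D2Q9_H

// D2Q9 velocity set: rest, axis (i = 1-4), diagonal (i = 5-8).
// Ordering matches e_i = (cos((i-1)pi/2), sin((i-1)pi/2)) for i = 1-4 and
// sqrt(2)(cos((2i-9)pi/4), sin((2i-9)pi/4)) for i = 5-8.
static const int D2Q9_EX[9] = {0, 1, 0, -1, 0, 1, -1, -1, 1};
static const int D2Q9_EY[9] = {0, 0, 1, 0, -1, 1, 1, -1, -1};
static const double D2Q9_W[9] = {4.0 / 9.0,
                                 1.0 / 9.0, 1.0 / 9.0, 1.0 / 9.0, 1.0 / 9.0,
                                 1.0 / 36.0, 1.0 / 36.0, 1.0 / 36.0, 1.0 / 36.0};
// cs^2 = 1/3 with dx = dt = 1.
static const double D2Q9_CS2 = 1.0 / 3.0;

// Maxwell-Boltzmann equilibrium truncated at second order in u.
static inline double d2q9_feq(int i, double rho, double ux, double uy) {
  double eu = D2Q9_EX[i] * ux + D2Q9_EY[i] * uy;
  double u2 = ux * ux + uy * uy;
  return D2Q9_W[i] * rho * (1.0 + 3.0 * eu + 4.5 * eu * eu - 1.5 * u2);
}

// Guo forcing contribution for population i given body-force density (gx,gy).
static inline double d2q9_guo(int i, double ux, double uy,
                              double gx, double gy, double tau) {
  double eu = D2Q9_EX[i] * ux + D2Q9_EY[i] * uy;
  double tx = 3.0 * (D2Q9_EX[i] - ux) + 9.0 * eu * D2Q9_EX[i];
  double ty = 3.0 * (D2Q9_EY[i] - uy) + 9.0 * eu * D2Q9_EY[i];
  return (1.0 - 0.5 / tau) * D2Q9_W[i] * (tx * gx + ty * gy);
}

#endif
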