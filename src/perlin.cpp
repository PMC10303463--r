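#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double fade(double t) {
  return t * t * t * (t * (t * 6.0 - 15.0) + 10.0);
}
static inline double lerp(double a, double b, double t) {
  return a + t * (b - a);
}

// Octave-summed classic Perlin noise. `perm` is a doubled 256-entry
// permutation table (0-based values), `grad` the 12 cube-edge gradient
// directions, `off` a (octaves x 3) matrix of per-octave lattice offsets.
// [[Rcpp::export]]
NumericVector cpp_perlin_fractal(NumericVector x, NumericVector y,
                                 NumericVector z, IntegerVector perm,
                                 NumericMatrix grad, NumericMatrix off,
                                 double base_freq, double persistence,
                                 double lacunarity) {
  int n = x.size();
  int octaves = off.nrow();
  NumericVector out(n);
  const int* P = INTEGER(perm);
  for (int i = 0; i < n; ++i) {
    double acc = 0.0, amp = 1.0, freq = base_freq;
    for (int o = 0; o < octaves; ++o) {
      double px = x[i] * freq + off(o, 0);
      double py = y[i] * freq + off(o, 1);
      double pz = z[i] * freq + off(o, 2);
      double fx = std::floor(px), fy = std::floor(py), fz = std::floor(pz);
      int xi = ((int)fx) & 255, yi = ((int)fy) & 255, zi = ((int)fz) & 255;
      double xf = px - fx, yf = py - fy, zf = pz - fz;
      double u = fade(xf), v = fade(yf), w = fade(zf);
      double c[2][2][2];
      for (int dx = 0; dx < 2; ++dx) {
        for (int dy = 0; dy < 2; ++dy) {
          for (int dz = 0; dz < 2; ++dz) {
            int h = P[P[P[xi + dx] + yi + dy] + zi + dz] % 12;
            c[dx][dy][dz] = grad(h, 0) * (xf - dx) + grad(h, 1) * (yf - dy) +
                            grad(h, 2) * (zf - dz);
          }
        }
      }
      double x00 = lerp(c[0][0][0], c[1][0][0], u);
      double x10 = lerp(c[0][1][0], c[1][1][0], u);
      double x01 = lerp(c[0][0][1], c[1][0][1], u);
      double x11 = lerp(c[0][1][1], c[1][1][1], u);
      acc += amp * lerp(lerp(x00, x10, v), lerp(x01, x11, v), w);
      freq *= lacunarity;
      amp *= persistence;
    }
    out[i] = acc;
  }
  return out;
}
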