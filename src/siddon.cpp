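#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Exact ray/voxel-grid traversal (Siddon). The ray is the segment from
// `src` to `dst`; the grid has corner `origin` (mm), isotropic pitch and
// dims voxels per axis. Visited voxels and their intersection lengths are
// appended through the `emit` callback.
namespace {

struct PathSink {
  std::vector<int> ix, iy, iz;
  std::vector<double> len;
};

template <typename F>
void traverse(const double src[3], const double dst[3], const double origin[3],
              double pitch, const int dims[3], F emit) {
  double d[3];
  double amin = 0.0, amax = 1.0;
  for (int a = 0; a < 3; ++a) {
    d[a] = dst[a] - src[a];
    double lo = origin[a], hi = origin[a] + pitch * dims[a];
    if (std::fabs(d[a]) < 1e-300) {
      if (src[a] <= lo || src[a] >= hi) return;  // parallel, outside slab
    } else {
      double a0 = (lo - src[a]) / d[a];
      double a1 = (hi - src[a]) / d[a];
      if (a0 > a1) std::swap(a0, a1);
      if (a0 > amin) amin = a0;
      if (a1 < amax) amax = a1;
    }
  }
  if (amin >= amax) return;
  double norm = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
  if (norm <= 0) return;

  // entry voxel, from a point nudged just inside
  double amid = amin + 1e-12;
  int v[3];
  for (int a = 0; a < 3; ++a) {
    double p = src[a] + amid * d[a];
    int i = (int)std::floor((p - origin[a]) / pitch);
    if (i < 0) i = 0;
    if (i >= dims[a]) i = dims[a] - 1;
    v[a] = i;
  }
  int step[3];
  double tMax[3], tDelta[3];
  const double INF = std::numeric_limits<double>::infinity();
  for (int a = 0; a < 3; ++a) {
    if (d[a] > 0) {
      step[a] = 1;
      tDelta[a] = pitch / d[a];
      tMax[a] = ((origin[a] + (v[a] + 1) * pitch) - src[a]) / d[a];
    } else if (d[a] < 0) {
      step[a] = -1;
      tDelta[a] = -pitch / d[a];
      tMax[a] = ((origin[a] + v[a] * pitch) - src[a]) / d[a];
    } else {
      step[a] = 0;
      tDelta[a] = INF;
      tMax[a] = INF;
    }
  }
  double acur = amin;
  while (acur < amax - 1e-12) {
    int ax = 0;
    if (tMax[1] < tMax[ax]) ax = 1;
    if (tMax[2] < tMax[ax]) ax = 2;
    double anext = tMax[ax] < amax ? tMax[ax] : amax;
    double seg = (anext - acur) * norm;
    if (seg > 0) emit(v[0], v[1], v[2], seg);
    if (anext >= amax) break;
    v[ax] += step[ax];
    if (v[ax] < 0 || v[ax] >= dims[ax]) break;
    tMax[ax] += tDelta[ax];
    acur = anext;
  }
}

}  // namespace

// [[Rcpp::export]]
List cpp_siddon_path(NumericVector src, NumericVector dst, NumericVector origin,
                     double pitch, IntegerVector dims) {
  double s[3] = {src[0], src[1], src[2]};
  double e[3] = {dst[0], dst[1], dst[2]};
  double o[3] = {origin[0], origin[1], origin[2]};
  int dm[3] = {dims[0], dims[1], dims[2]};
  PathSink sink;
  traverse(s, e, o, pitch, dm, [&](int ix, int iy, int iz, double len) {
    sink.ix.push_back(ix + 1);  // 1-based for R
    sink.iy.push_back(iy + 1);
    sink.iz.push_back(iz + 1);
    sink.len.push_back(len);
  });
  return List::create(_["ix"] = wrap(sink.ix), _["iy"] = wrap(sink.iy),
                      _["iz"] = wrap(sink.iz), _["length_mm"] = wrap(sink.len));
}

// Line integral of a voxelized attenuation map for every detector pixel.
// `mu` is a 3D array (nx, ny, nz) of linear attenuation (mm^-1); pixel
// centers are the outer grid of px (x per detector column) and py (y per
// detector row), all at plane z = det_z. Returns matrix [row = v, col = u].
// [[Rcpp::export]]
NumericMatrix cpp_project_lines(NumericVector mu, NumericVector origin,
                                double pitch, NumericVector src,
                                NumericVector px, NumericVector py,
                                double det_z) {
  IntegerVector dims = mu.attr("dim");
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int dm[3] = {nx, ny, nz};
  double o[3] = {origin[0], origin[1], origin[2]};
  double s[3] = {src[0], src[1], src[2]};
  int nu = px.size(), nv = py.size();
  NumericMatrix L(nv, nu);
  const double* m = REAL(mu);
  for (int u = 0; u < nu; ++u) {
    for (int v = 0; v < nv; ++v) {
      double e[3] = {px[u], py[v], det_z};
      double acc = 0.0;
      traverse(s, e, o, pitch, dm, [&](int ix, int iy, int iz, double len) {
        acc += m[ix + (size_t)nx * (iy + (size_t)ny * iz)] * len;
      });
      L(v, u) = acc;
    }
  }
  return L;
}
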