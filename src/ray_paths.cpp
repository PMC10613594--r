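#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Siddon-type incremental voxel traversal: total length of each ray's
// intersection with TRUE voxels of a mask. Voxel (i,j,k) (0-based) has
// center origin + (i,j,k)*spacing and extends +/- spacing/2.
// 'starts' may have one row (broadcast over all rays) or one row per ray.
// [[Rcpp::export]]
NumericVector ray_path_lengths_cpp(NumericMatrix starts, NumericMatrix ends,
                                   LogicalVector mask, IntegerVector dims,
                                   NumericVector origin, NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int nray = ends.nrow();
  const bool broadcast = (starts.nrow() == 1);
  NumericVector out(nray);
  double bmin[3], bmax[3];
  int dim3[3] = {nx, ny, nz};
  for (int a = 0; a < 3; ++a) {
    bmin[a] = origin[a] - 0.5 * spacing[a];
    bmax[a] = origin[a] + (dim3[a] - 0.5) * spacing[a];
  }
  const int *m = LOGICAL(mask);
  for (int rI = 0; rI < nray; ++rI) {
    double s[3], d[3];
    for (int a = 0; a < 3; ++a) {
      s[a] = broadcast ? starts(0, a) : starts(rI, a);
      d[a] = ends(rI, a) - s[a];
    }
    const double len = std::sqrt(d[0]*d[0] + d[1]*d[1] + d[2]*d[2]);
    if (len <= 0.0) { out[rI] = 0.0; continue; }
    // clip [0,1] to the mask bounding box
    double t0 = 0.0, t1 = 1.0;
    bool miss = false;
    for (int a = 0; a < 3; ++a) {
      if (std::fabs(d[a]) < 1e-12) {
        if (s[a] < bmin[a] || s[a] > bmax[a]) { miss = true; break; }
      } else {
        double ta = (bmin[a] - s[a]) / d[a], tb = (bmax[a] - s[a]) / d[a];
        if (ta > tb) std::swap(ta, tb);
        if (ta > t0) t0 = ta;
        if (tb < t1) t1 = tb;
        if (t0 >= t1) { miss = true; break; }
      }
    }
    if (miss) { out[rI] = 0.0; continue; }
    int idx[3], step[3];
    double tMax[3], tDelta[3];
    for (int a = 0; a < 3; ++a) {
      double p = s[a] + (t0 + 1e-10) * d[a];
      int i = (int)std::floor((p - bmin[a]) / spacing[a]);
      if (i < 0) i = 0;
      if (i >= dim3[a]) i = dim3[a] - 1;
      idx[a] = i;
      if (d[a] > 1e-12) {
        step[a] = 1;
        tDelta[a] = spacing[a] / d[a];
        tMax[a] = (bmin[a] + (i + 1) * spacing[a] - s[a]) / d[a];
      } else if (d[a] < -1e-12) {
        step[a] = -1;
        tDelta[a] = -spacing[a] / d[a];
        tMax[a] = (bmin[a] + i * spacing[a] - s[a]) / d[a];
      } else {
        step[a] = 0;
        tMax[a] = R_PosInf;
        tDelta[a] = R_PosInf;
      }
    }
    double total = 0.0, t = t0;
    while (t < t1) {
      int a = 0;
      if (tMax[1] < tMax[a]) a = 1;
      if (tMax[2] < tMax[a]) a = 2;
      double tNext = tMax[a] < t1 ? tMax[a] : t1;
      if (m[idx[0] + idx[1] * nx + idx[2] * nx * ny]) total += (tNext - t) * len;
      t = tNext;
      if (tMax[a] >= t1) break;
      idx[a] += step[a];
      if (idx[a] < 0 || idx[a] >= dim3[a]) break;
      tMax[a] += tDelta[a];
    }
    out[rI] = total;
  }
  return out;
}
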