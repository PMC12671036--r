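#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <limits>
#include <vector>

using namespace Rcpp;

// Amanatides-Woo traversal of one segment in continuous voxel coordinates
// (voxel k occupies [k, k+1) along each axis). Appends 1-based R linear
// indices of every in-bounds voxel the open segment passes through.
static void traverse_segment(const double u[3], const double v[3],
                             const int dim[3], std::vector<int> &out) {
  const double inf = std::numeric_limits<double>::infinity();
  long long i[3], iend[3];
  int step[3];
  double tmax[3], tdelta[3], d[3];

  for (int k = 0; k < 3; ++k) {
    d[k] = v[k] - u[k];
    i[k] = (long long)std::floor(u[k]);
    iend[k] = (long long)std::floor(v[k]);
    if (d[k] > 0) {
      step[k] = 1;
      tdelta[k] = 1.0 / d[k];
      tmax[k] = ((double)(i[k] + 1) - u[k]) / d[k];
    } else if (d[k] < 0) {
      step[k] = -1;
      tdelta[k] = -1.0 / d[k];
      tmax[k] = ((double)i[k] - u[k]) / d[k];
    } else {
      step[k] = 0;
      tdelta[k] = inf;
      tmax[k] = inf;
    }
  }

  long long maxiter = 3;
  for (int k = 0; k < 3; ++k) maxiter += std::llabs(iend[k] - i[k]);

  for (long long it = 0; it <= maxiter; ++it) {
    if (i[0] >= 0 && i[0] < dim[0] && i[1] >= 0 && i[1] < dim[1] &&
        i[2] >= 0 && i[2] < dim[2]) {
      out.push_back((int)(1 + i[0] + (long long)dim[0] * (i[1] + (long long)dim[1] * i[2])));
    }
    int k = 0;
    if (tmax[1] < tmax[k]) k = 1;
    if (tmax[2] < tmax[k]) k = 2;
    if (tmax[k] > 1.0) break;  // segment ends inside current voxel
    i[k] += step[k];
    tmax[k] += tdelta[k];
  }
}

static IntegerVector traverse_polyline(const NumericMatrix &pts,
                                       const NumericVector &origin,
                                       const NumericVector &voxel,
                                       const IntegerVector &dim) {
  const int n = pts.nrow();
  if (n < 2) stop("polyline must have at least 2 points");
  int dm[3] = {dim[0], dim[1], dim[2]};
  std::vector<int> out;
  double u[3], v[3];
  for (int s = 0; s + 1 < n; ++s) {
    for (int k = 0; k < 3; ++k) {
      u[k] = (pts(s, k) - origin[k]) / voxel[k];
      v[k] = (pts(s + 1, k) - origin[k]) / voxel[k];
    }
    traverse_segment(u, v, dm, out);
  }
  std::sort(out.begin(), out.end());
  out.erase(std::unique(out.begin(), out.end()), out.end());
  return wrap(out);
}

// [[Rcpp::export]]
IntegerVector voxels_traversed_cpp(NumericMatrix pts, NumericVector origin,
                                   NumericVector voxel, IntegerVector dim) {
  return traverse_polyline(pts, origin, voxel, dim);
}

// [[Rcpp::export]]
List traverse_streamlines_cpp(List streamlines, NumericVector origin,
                              NumericVector voxel, IntegerVector dim) {
  const int n = streamlines.size();
  List out(n);
  for (int s = 0; s < n; ++s) {
    NumericMatrix pts = streamlines[s];
    out[s] = traverse_polyline(pts, origin, voxel, dim);
  }
  return out;
}
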