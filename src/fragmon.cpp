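#include <Rcpp.h>
using namespace Rcpp;

// Non-paralyzable dead-time filter: an event is kept iff it arrives at least
// tau after the last *kept* event. Sequential by nature.
// [[Rcpp::export(name = ".deadtime_keep")]]
LogicalVector deadtime_keep(NumericVector t_sorted, double tau) {
  int n = t_sorted.size();
  LogicalVector keep(n);
  double last = R_NegInf;
  for (int i = 0; i < n; ++i) {
    if (t_sorted[i] - last >= tau) {
      keep[i] = true;
      last = t_sorted[i];
    } else {
      keep[i] = false;
    }
  }
  return keep;
}

// Water-equivalent path length accumulated along straight rays through a
// voxel density grid, from each start point until the ray leaves the grid.
// dens: 3D array (nx,ny,nz) of densities relative to water; orig: position
// (mm) of the low corner of voxel (1,1,1); vox: voxel edge length (mm).
// Rays are marched at midpoints of fixed geometric steps; voxels outside the
// grid contribute zero but do not terminate the march until the ray has
// exited the grid bounding box for good.
// [[Rcpp::export(name = ".ray_wepl")]]
NumericVector ray_wepl(NumericVector dens, IntegerVector dim,
                       NumericVector orig, double vox,
                       NumericMatrix start, NumericMatrix dir,
                       double step) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int n = start.nrow();
  NumericVector out(n);
  double ex = orig[0] + nx * vox, ey = orig[1] + ny * vox, ez = orig[2] + nz * vox;
  for (int i = 0; i < n; ++i) {
    double px = start(i, 0), py = start(i, 1), pz = start(i, 2);
    double dx = dir(i, 0), dy = dir(i, 1), dz = dir(i, 2);
    // distance at which the ray exits the grid bounding box (slab method)
    double tmax = R_PosInf;
    if (dx > 0) tmax = std::min(tmax, (ex - px) / dx);
    else if (dx < 0) tmax = std::min(tmax, (orig[0] - px) / dx);
    if (dy > 0) tmax = std::min(tmax, (ey - py) / dy);
    else if (dy < 0) tmax = std::min(tmax, (orig[1] - py) / dy);
    if (dz > 0) tmax = std::min(tmax, (ez - pz) / dz);
    else if (dz < 0) tmax = std::min(tmax, (orig[2] - pz) / dz);
    if (!R_finite(tmax) || tmax <= 0) { out[i] = 0.0; continue; }
    double w = 0.0;
    int nstep = (int)std::ceil(tmax / step);
    for (int k = 0; k < nstep; ++k) {
      double s = (k + 0.5) * step;
      if (s > tmax) break;
      int ix = (int)std::floor((px + s * dx - orig[0]) / vox);
      int iy = (int)std::floor((py + s * dy - orig[1]) / vox);
      int iz = (int)std::floor((pz + s * dz - orig[2]) / vox);
      if (ix >= 0 && ix < nx && iy >= 0 && iy < ny && iz >= 0 && iz < nz) {
        w += dens[ix + nx * (iy + (R_xlen_t)ny * iz)] * step;
      }
    }
    out[i] = w;
  }
  return out;
}
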