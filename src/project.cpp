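#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Exact ray-grid traversal (Siddon-style incremental DDA): accumulated
// intersection length (mm) of the ray with occupied voxels.
static double trace_ray(const Rbyte* occ, int nx, int ny, int nz,
                        double bx, double by, double bz, double spacing,
                        double px, double py, double pz,
                        double dx, double dy, double dz) {
  // clip parametric range to the grid AABB [b, b + n*spacing)
  double tmin = -1e30, tmax = 1e30;
  const double lo[3] = {bx, by, bz};
  const double d[3] = {dx, dy, dz};
  const double p[3] = {px, py, pz};
  const int n[3] = {nx, ny, nz};
  for (int a = 0; a < 3; ++a) {
    const double hi = lo[a] + n[a] * spacing;
    if (std::fabs(d[a]) < 1e-12) {
      if (p[a] < lo[a] || p[a] >= hi) return 0.0;
    } else {
      double t0 = (lo[a] - p[a]) / d[a];
      double t1 = (hi - p[a]) / d[a];
      if (t0 > t1) std::swap(t0, t1);
      if (t0 > tmin) tmin = t0;
      if (t1 < tmax) tmax = t1;
    }
  }
  if (tmax <= tmin) return 0.0;

  const double eps = 1e-9 * spacing;
  double t = tmin;
  // entry voxel
  double qx = px + (tmin + eps) * dx, qy = py + (tmin + eps) * dy,
         qz = pz + (tmin + eps) * dz;
  int ix = (int)std::floor((qx - bx) / spacing);
  int iy = (int)std::floor((qy - by) / spacing);
  int iz = (int)std::floor((qz - bz) / spacing);
  if (ix < 0) ix = 0; if (ix >= nx) ix = nx - 1;
  if (iy < 0) iy = 0; if (iy >= ny) iy = ny - 1;
  if (iz < 0) iz = 0; if (iz >= nz) iz = nz - 1;

  const int sx = dx > 0 ? 1 : -1, sy = dy > 0 ? 1 : -1, sz = dz > 0 ? 1 : -1;
  const double tdx = std::fabs(dx) > 1e-12 ? spacing / std::fabs(dx) : 1e30;
  const double tdy = std::fabs(dy) > 1e-12 ? spacing / std::fabs(dy) : 1e30;
  const double tdz = std::fabs(dz) > 1e-12 ? spacing / std::fabs(dz) : 1e30;
  double tmx = std::fabs(dx) > 1e-12
    ? (bx + (ix + (sx > 0 ? 1 : 0)) * spacing - px) / dx : 1e30;
  double tmy = std::fabs(dy) > 1e-12
    ? (by + (iy + (sy > 0 ? 1 : 0)) * spacing - py) / dy : 1e30;
  double tmz = std::fabs(dz) > 1e-12
    ? (bz + (iz + (sz > 0 ? 1 : 0)) * spacing - pz) / dz : 1e30;

  const R_xlen_t stx = sx, sty = (R_xlen_t)sy * nx, stz = (R_xlen_t)sz * nx * ny;
  R_xlen_t idx = (R_xlen_t)iz * nx * ny + (R_xlen_t)iy * nx + ix;
  double acc = 0.0;
  while (t < tmax - eps) {
    double tn;
    int axis;
    if (tmx <= tmy && tmx <= tmz) { tn = tmx; axis = 0; }
    else if (tmy <= tmz) { tn = tmy; axis = 1; }
    else { tn = tmz; axis = 2; }
    if (tn > tmax) tn = tmax;
    if (occ[idx]) acc += tn - t;
    t = tn;
    if (t >= tmax - eps) break;
    if (axis == 0) { ix += sx; if (ix < 0 || ix >= nx) break; tmx += tdx; idx += stx; }
    else if (axis == 1) { iy += sy; if (iy < 0 || iy >= ny) break; tmy += tdy; idx += sty; }
    else { iz += sz; if (iz < 0 || iz >= nz) break; tmz += tdz; idx += stz; }
  }
  return acc;
}

// Forward-project the binary volume onto a detector: per-pixel material
// path length (mm). mode 0 = parallel (all rays share direction dir),
// mode 1 = cone (rays from point source src through each pixel center).
// Detector pixel (i, j) center: det_center + ((i+1)-(nu+1)/2)*pixel*u
//                                          + ((j+1)-(nv+1)/2)*pixel*v.
// [[Rcpp::export(name = ".project_volume")]]
NumericMatrix project_volume(RawVector occ, IntegerVector dims,
                             NumericVector origin, double spacing,
                             int mode, NumericVector dir, NumericVector src,
                             NumericVector det_center, NumericVector uaxis,
                             NumericVector vaxis, double pixel,
                             int nu, int nv) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double bx = origin[0] - spacing / 2.0;
  const double by = origin[1] - spacing / 2.0;
  const double bz = origin[2] - spacing / 2.0;
  const Rbyte* o = occ.begin();
  NumericMatrix out(nu, nv);

  for (int j = 0; j < nv; ++j) {
    const double cv = (j + 1 - (nv + 1) / 2.0) * pixel;
    for (int i = 0; i < nu; ++i) {
      const double cu = (i + 1 - (nu + 1) / 2.0) * pixel;
      const double pxl[3] = {
        det_center[0] + cu * uaxis[0] + cv * vaxis[0],
        det_center[1] + cu * uaxis[1] + cv * vaxis[1],
        det_center[2] + cu * uaxis[2] + cv * vaxis[2]};
      double px, py, pz, dx, dy, dz;
      if (mode == 0) {
        px = pxl[0]; py = pxl[1]; pz = pxl[2];
        dx = dir[0]; dy = dir[1]; dz = dir[2];
      } else {
        px = src[0]; py = src[1]; pz = src[2];
        dx = pxl[0] - px; dy = pxl[1] - py; dz = pxl[2] - pz;
        const double nrm = std::sqrt(dx * dx + dy * dy + dz * dz);
        dx /= nrm; dy /= nrm; dz /= nrm;
      }
      out(i, j) = trace_ray(o, nx, ny, nz, bx, by, bz, spacing,
                            px, py, pz, dx, dy, dz);
    }
  }
  return out;
}
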