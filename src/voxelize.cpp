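#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Rasterize extrusion beads into a binary occupancy grid (in place).
// A bead is the 2-D stadium (capsule) of width w swept along the segment's
// XY path, extruded vertically over (z_end - layer_height, z_end]. A voxel
// is set iff its center lies inside any bead; overlaps union (binary OR).
// occ: raw vector, x fastest, dims (nx, ny, nz); origin = center of voxel 0.
// [[Rcpp::export(name = ".voxelize_segments")]]
void voxelize_segments(RawVector occ, IntegerVector dims,
                       NumericVector origin, double spacing,
                       NumericMatrix seg_start, NumericMatrix seg_end,
                       NumericVector width, double layer_height) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double ox = origin[0], oy = origin[1], oz = origin[2];
  const int nseg = seg_start.nrow();
  Rbyte* o = occ.begin();

  for (int s = 0; s < nseg; ++s) {
    const double x0 = seg_start(s, 0), y0 = seg_start(s, 1);
    const double x1 = seg_end(s, 0), y1 = seg_end(s, 1);
    const double ztop = seg_end(s, 2);
    const double r = width[s] / 2.0;
    const double dx = x1 - x0, dy = y1 - y0;
    const double len2 = dx * dx + dy * dy;

    // voxel index bounds for the bead's AABB
    int ix0 = (int)std::ceil((std::fmin(x0, x1) - r - ox) / spacing - 0.5 - 1e-9);
    int ix1 = (int)std::floor((std::fmax(x0, x1) + r - ox) / spacing + 0.5 + 1e-9);
    int iy0 = (int)std::ceil((std::fmin(y0, y1) - r - oy) / spacing - 0.5 - 1e-9);
    int iy1 = (int)std::floor((std::fmax(y0, y1) + r - oy) / spacing + 0.5 + 1e-9);
    // z centers in (ztop - layer_height, ztop]
    int iz0 = (int)std::ceil((ztop - layer_height - oz) / spacing + 1e-9);
    int iz1 = (int)std::floor((ztop - oz) / spacing + 1e-9);
    if (ix0 < 0) ix0 = 0; if (iy0 < 0) iy0 = 0; if (iz0 < 0) iz0 = 0;
    if (ix1 >= nx) ix1 = nx - 1;
    if (iy1 >= ny) iy1 = ny - 1;
    if (iz1 >= nz) iz1 = nz - 1;
    if (ix1 < ix0 || iy1 < iy0 || iz1 < iz0) continue;

    const double r2 = r * r;
    for (int iy = iy0; iy <= iy1; ++iy) {
      const double yc = oy + iy * spacing;
      for (int ix = ix0; ix <= ix1; ++ix) {
        const double xc = ox + ix * spacing;
        // squared distance from voxel center to segment in XY
        double t = 0.0;
        if (len2 > 0.0) {
          t = ((xc - x0) * dx + (yc - y0) * dy) / len2;
          if (t < 0.0) t = 0.0; else if (t > 1.0) t = 1.0;
        }
        const double px = x0 + t * dx - xc, py = y0 + t * dy - yc;
        if (px * px + py * py > r2) continue;
        const R_xlen_t base = (R_xlen_t)iy * nx + ix;
        for (int iz = iz0; iz <= iz1; ++iz)
          o[base + (R_xlen_t)iz * nx * ny] = 1;
      }
    }
  }
}

// Fill an axis-aligned solid region (used by test phantoms): set voxels
// whose centers satisfy the implicit shape, shape = 0 box, 1 sphere.
// [[Rcpp::export(name = ".fill_shape")]]
void fill_shape(RawVector occ, IntegerVector dims, NumericVector origin,
                double spacing, int shape, NumericVector params) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  Rbyte* o = occ.begin();
  for (int iz = 0; iz < nz; ++iz) {
    const double z = origin[2] + iz * spacing;
    for (int iy = 0; iy < ny; ++iy) {
      const double y = origin[1] + iy * spacing;
      for (int ix = 0; ix < nx; ++ix) {
        const double x = origin[0] + ix * spacing;
        bool in = false;
        if (shape == 0) {
          in = x >= params[0] && x <= params[3] && y >= params[1] &&
               y <= params[4] && z >= params[2] && z <= params[5];
        } else {
          const double dx = x - params[0], dy = y - params[1], dz = z - params[2];
          in = dx * dx + dy * dy + dz * dz <= params[3] * params[3];
        }
        if (in) o[(R_xlen_t)iz * nx * ny + (R_xlen_t)iy * nx + ix] = 1;
      }
    }
  }
}
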