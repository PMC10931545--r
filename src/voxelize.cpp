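#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Closed-mesh voxelization by z-column parity counting: for every grid
// column, collect the z values where the column's ray crosses a triangle,
// sort them, and fill voxels between successive crossing pairs. Column
// sample points carry a tiny sub-voxel offset so rays do not pass exactly
// through mesh vertices or edges of well-behaved meshes.

// [[Rcpp::export(name = ".voxelize_mesh_cpp")]]
LogicalVector voxelize_mesh_cpp(NumericMatrix V, IntegerMatrix F,
                                NumericVector origin, NumericVector spacing,
                                IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double ox = origin[0], oy = origin[1], oz = origin[2];
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  // deterministic irrational sub-voxel shift of the ray lattice
  const double jx = 2.9287243e-5 * sx, jy = 1.7320508e-5 * sy;

  std::vector< std::vector<double> > cross((size_t)nx * ny);

  for (int f = 0; f < F.nrow(); ++f) {
    const int a = F(f,0)-1, b = F(f,1)-1, c = F(f,2)-1;
    const double ax = V(a,0), ay = V(a,1), az = V(a,2);
    const double bx = V(b,0), by = V(b,1), bz = V(b,2);
    const double cx = V(c,0), cy = V(c,1), cz = V(c,2);
    const double xmin = std::min(ax, std::min(bx, cx));
    const double xmax = std::max(ax, std::max(bx, cx));
    const double ymin = std::min(ay, std::min(by, cy));
    const double ymax = std::max(ay, std::max(by, cy));
    int i0 = (int)std::ceil((xmin - ox - jx) / sx);
    int i1 = (int)std::floor((xmax - ox - jx) / sx);
    int j0 = (int)std::ceil((ymin - oy - jy) / sy);
    int j1 = (int)std::floor((ymax - oy - jy) / sy);
    i0 = std::max(i0, 0); i1 = std::min(i1, nx - 1);
    j0 = std::max(j0, 0); j1 = std::min(j1, ny - 1);
    if (i0 > i1 || j0 > j1) continue;
    const double d00x = bx - ax, d00y = by - ay;
    const double d01x = cx - ax, d01y = cy - ay;
    const double den = d00x * d01y - d01x * d00y;
    if (den == 0.0) continue; // triangle vertical in z: no column crossing
    for (int j = j0; j <= j1; ++j) {
      const double py = oy + j * sy + jy;
      for (int i = i0; i <= i1; ++i) {
        const double px = ox + i * sx + jx;
        const double ex = px - ax, ey = py - ay;
        const double u = (ex * d01y - d01x * ey) / den;
        const double v = (d00x * ey - ex * d00y) / den;
        if (u < 0.0 || v < 0.0 || u + v > 1.0) continue;
        cross[(size_t)i + (size_t)nx * j].push_back(
          az + u * (bz - az) + v * (cz - az));
      }
    }
  }

  LogicalVector out((R_xlen_t)nx * ny * nz, false);
  out.attr("dim") = dims;
  int* O = LOGICAL(out);
  for (int j = 0; j < ny; ++j)
  for (int i = 0; i < nx; ++i) {
    std::vector<double>& zc = cross[(size_t)i + (size_t)nx * j];
    if (zc.size() < 2) continue;
    std::sort(zc.begin(), zc.end());
    for (size_t p = 0; p + 1 < zc.size(); p += 2) {
      int k0 = (int)std::ceil((zc[p]   - oz) / sz);
      int k1 = (int)std::floor((zc[p+1] - oz) / sz);
      k0 = std::max(k0, 0); k1 = std::min(k1, nz - 1);
      for (int k = k0; k <= k1; ++k)
        O[(R_xlen_t)i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)] = true;
    }
  }
  return out;
}
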