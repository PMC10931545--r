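#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Isosurface extraction by marching tetrahedra on a regular scalar grid.
// Each grid cube is split into 6 tetrahedra around the (0,0,0)-(1,1,1)
// diagonal; the split is identical in every cube, so face diagonals agree
// between neighbouring cubes and the extracted surface is watertight.
// Surface vertices live on tetrahedron edges and are welded through a map
// keyed by the global ids of the edge's two grid nodes, which also makes
// the output deterministic.

namespace {

const int CORN[8][3] = {
  {0,0,0},{1,0,0},{1,1,0},{0,1,0},
  {0,0,1},{1,0,1},{1,1,1},{0,1,1}
};

const int TETS[6][4] = {
  {0,5,1,6},{0,1,2,6},{0,2,3,6},
  {0,3,7,6},{0,7,4,6},{0,4,5,6}
};

struct MeshBuilder {
  std::unordered_map<uint64_t, int> edge_vertex;
  std::vector<double> vx, vy, vz;       // grid coordinates
  std::vector<int> f1, f2, f3;          // 0-based vertex ids
  uint64_t n_nodes;

  // interpolated vertex on the grid edge (ga, gb); canonical order by node
  // id so both incident tetrahedra compute bit-identical coordinates
  int edge_point(uint64_t ga, uint64_t gb,
                 double va, double vb,
                 const double* pa, const double* pb,
                 double iso) {
    if (ga > gb) {
      std::swap(ga, gb); std::swap(va, vb);
      const double* tmp = pa; pa = pb; pb = tmp;
    }
    uint64_t key = ga * n_nodes + gb;
    auto it = edge_vertex.find(key);
    if (it != edge_vertex.end()) return it->second;
    double w = (iso - va) / (vb - va);
    int id = (int)vx.size();
    vx.push_back(pa[0] + w * (pb[0] - pa[0]));
    vy.push_back(pa[1] + w * (pb[1] - pa[1]));
    vz.push_back(pa[2] + w * (pb[2] - pa[2]));
    edge_vertex.emplace(key, id);
    return id;
  }

  void add_tri(int a, int b, int c,
               const double in_c[3], const double out_c[3]) {
    if (a == b || b == c || a == c) return;  // degenerate (iso hits a node)
    // orient the triangle so its normal points from inside to outside
    double e1x = vx[b]-vx[a], e1y = vy[b]-vy[a], e1z = vz[b]-vz[a];
    double e2x = vx[c]-vx[a], e2y = vy[c]-vy[a], e2z = vz[c]-vz[a];
    double nx_ = e1y*e2z - e1z*e2y;
    double ny_ = e1z*e2x - e1x*e2z;
    double nz_ = e1x*e2y - e1y*e2x;
    double dx = out_c[0]-in_c[0], dy = out_c[1]-in_c[1], dz = out_c[2]-in_c[2];
    if (nx_*dx + ny_*dy + nz_*dz < 0) std::swap(b, c);
    f1.push_back(a); f2.push_back(b); f3.push_back(c);
  }
};

} // namespace

// [[Rcpp::export(name = ".march_tetra_cpp")]]
List march_tetra_cpp(NumericVector field, double iso,
                     NumericVector spacing, NumericVector origin) {
  IntegerVector dims = field.attr("dim");
  if (dims.size() != 3) stop("field must be a 3D array");
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  if (nx < 2 || ny < 2 || nz < 2) stop("grid too small for isosurfacing");
  const double* F = REAL(field);

  MeshBuilder mb;
  mb.n_nodes = (uint64_t)nx * ny * nz;

  double cval[8], cpos[8][3];
  uint64_t gid[8];

  for (int k = 0; k + 1 < nz; ++k)
  for (int j = 0; j + 1 < ny; ++j)
  for (int i = 0; i + 1 < nx; ++i) {
    bool any_in = false, any_out = false;
    for (int c = 0; c < 8; ++c) {
      int ci = i + CORN[c][0], cj = j + CORN[c][1], ck = k + CORN[c][2];
      gid[c] = (uint64_t)ci + (uint64_t)nx * ((uint64_t)cj + (uint64_t)ny * ck);
      cval[c] = F[gid[c]];
      cpos[c][0] = ci; cpos[c][1] = cj; cpos[c][2] = ck;
      if (cval[c] >= iso) any_in = true; else any_out = true;
    }
    if (!any_in || !any_out) continue;

    for (int t = 0; t < 6; ++t) {
      const int* T = TETS[t];
      int ins[4], outs[4], ni = 0, no = 0;
      for (int c = 0; c < 4; ++c) {
        if (cval[T[c]] >= iso) ins[ni++] = T[c]; else outs[no++] = T[c];
      }
      if (ni == 0 || ni == 4) continue;
      double in_c[3] = {0,0,0}, out_c[3] = {0,0,0};
      for (int c = 0; c < ni; ++c)
        for (int d = 0; d < 3; ++d) in_c[d] += cpos[ins[c]][d] / ni;
      for (int c = 0; c < no; ++c)
        for (int d = 0; d < 3; ++d) out_c[d] += cpos[outs[c]][d] / no;

      auto ep = [&](int a, int b) {
        return mb.edge_point(gid[a], gid[b], cval[a], cval[b],
                             cpos[a], cpos[b], iso);
      };
      if (ni == 1) {
        mb.add_tri(ep(ins[0], outs[0]), ep(ins[0], outs[1]),
                   ep(ins[0], outs[2]), in_c, out_c);
      } else if (ni == 3) {
        mb.add_tri(ep(ins[0], outs[0]), ep(ins[1], outs[0]),
                   ep(ins[2], outs[0]), in_c, out_c);
      } else { // 2 in, 2 out -> quad split into two triangles
        int p1 = ep(ins[0], outs[0]), p2 = ep(ins[0], outs[1]);
        int p3 = ep(ins[1], outs[1]), p4 = ep(ins[1], outs[0]);
        mb.add_tri(p1, p2, p3, in_c, out_c);
        mb.add_tri(p1, p3, p4, in_c, out_c);
      }
    }
  }

  const int nv = (int)mb.vx.size(), nf = (int)mb.f1.size();
  if (nv == 0) stop("isosurface is empty at the requested level");
  NumericMatrix V(nv, 3);
  for (int v = 0; v < nv; ++v) {
    V(v, 0) = origin[0] + mb.vx[v] * spacing[0];
    V(v, 1) = origin[1] + mb.vy[v] * spacing[1];
    V(v, 2) = origin[2] + mb.vz[v] * spacing[2];
  }
  IntegerMatrix Fc(nf, 3);
  for (int f = 0; f < nf; ++f) {
    Fc(f, 0) = mb.f1[f] + 1; Fc(f, 1) = mb.f2[f] + 1; Fc(f, 2) = mb.f3[f] + 1;
  }
  return List::create(_["vertices"] = V, _["faces"] = Fc);
}
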