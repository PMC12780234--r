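#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Marching tetrahedra over the voxel grid: each cell cube is split into six
// tetrahedra; the 0.5-level isosurface is triangulated with vertices linearly
// interpolated along tet edges, triangles oriented outward (away from the
// >= level side). Returns total triangle area and the enclosed volume via the
// divergence theorem. Coordinates are physical (index * spacing), so area is
// in mm^2 and volume in mm^3 when spacing is in mm.

static const int CUBE[8][3] = {
  {0,0,0},{1,0,0},{1,1,0},{0,1,0},{0,0,1},{1,0,1},{1,1,1},{0,1,1}};
static const int TETS[6][4] = {
  {0,5,1,6},{0,1,2,6},{0,2,3,6},{0,3,7,6},{0,7,4,6},{0,4,5,6}};

struct Vec3 { double x, y, z; };
static inline Vec3 vsub(const Vec3& a, const Vec3& b) {
  return {a.x - b.x, a.y - b.y, a.z - b.z};
}
static inline Vec3 vcross(const Vec3& a, const Vec3& b) {
  return {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x};
}
static inline double vdot(const Vec3& a, const Vec3& b) {
  return a.x * b.x + a.y * b.y + a.z * b.z;
}
static inline Vec3 interp(const Vec3& p1, double v1, const Vec3& p2, double v2,
                          double level) {
  double t = (level - v1) / (v2 - v1);
  return {p1.x + t * (p2.x - p1.x), p1.y + t * (p2.y - p1.y),
          p1.z + t * (p2.z - p1.z)};
}

//' @noRd
// [[Rcpp::export(name = ".cpp_mesh_area_volume")]]
NumericVector cpp_mesh_area_volume(NumericVector field, IntegerVector dims,
                                   NumericVector spacing, double level) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  double area = 0.0, vol6 = 0.0;

  double cv[8];
  Vec3 cp[8];
  Vec3 tri[2][3];

  for (int k = 0; k < nz - 1; ++k)
    for (int j = 0; j < ny - 1; ++j)
      for (int i = 0; i < nx - 1; ++i) {
        double cmin = 1e300, cmax = -1e300;
        for (int c = 0; c < 8; ++c) {
          int ii = i + CUBE[c][0], jj = j + CUBE[c][1], kk = k + CUBE[c][2];
          double v = field[(R_xlen_t)kk * nx * ny + (R_xlen_t)jj * nx + ii];
          cv[c] = v;
          if (v < cmin) cmin = v;
          if (v > cmax) cmax = v;
          cp[c] = {ii * sx, jj * sy, kk * sz};
        }
        if (cmax < level || cmin >= level) continue;
        for (int t = 0; t < 6; ++t) {
          const int* tet = TETS[t];
          bool inside[4];
          int nin = 0;
          Vec3 insc = {0, 0, 0};
          for (int a = 0; a < 4; ++a) {
            inside[a] = cv[tet[a]] >= level;
            if (inside[a]) {
              ++nin;
              insc.x += cp[tet[a]].x; insc.y += cp[tet[a]].y;
              insc.z += cp[tet[a]].z;
            }
          }
          if (nin == 0 || nin == 4) continue;
          insc.x /= nin; insc.y /= nin; insc.z /= nin;
          int ntri = 0;
          if (nin == 1 || nin == 3) {
            int apex = -1;
            for (int a = 0; a < 4; ++a)
              if (inside[a] == (nin == 1)) { apex = a; break; }
            int m = 0;
            for (int a = 0; a < 4; ++a) {
              if (a == apex) continue;
              tri[0][m++] = interp(cp[tet[apex]], cv[tet[apex]],
                                   cp[tet[a]], cv[tet[a]], level);
            }
            ntri = 1;
          } else { // 2 in / 2 out -> quad split into two triangles
            int ins[2], outs[2], ni = 0, no = 0;
            for (int a = 0; a < 4; ++a)
              if (inside[a]) ins[ni++] = a; else outs[no++] = a;
            Vec3 p00 = interp(cp[tet[ins[0]]], cv[tet[ins[0]]],
                              cp[tet[outs[0]]], cv[tet[outs[0]]], level);
            Vec3 p01 = interp(cp[tet[ins[0]]], cv[tet[ins[0]]],
                              cp[tet[outs[1]]], cv[tet[outs[1]]], level);
            Vec3 p10 = interp(cp[tet[ins[1]]], cv[tet[ins[1]]],
                              cp[tet[outs[0]]], cv[tet[outs[0]]], level);
            Vec3 p11 = interp(cp[tet[ins[1]]], cv[tet[ins[1]]],
                              cp[tet[outs[1]]], cv[tet[outs[1]]], level);
            tri[0][0] = p00; tri[0][1] = p01; tri[0][2] = p11;
            tri[1][0] = p00; tri[1][1] = p11; tri[1][2] = p10;
            ntri = 2;
          }
          for (int q = 0; q < ntri; ++q) {
            Vec3 p0 = tri[q][0], p1 = tri[q][1], p2 = tri[q][2];
            Vec3 n = vcross(vsub(p1, p0), vsub(p2, p0));
            Vec3 cen = {(p0.x + p1.x + p2.x) / 3.0,
                        (p0.y + p1.y + p2.y) / 3.0,
                        (p0.z + p1.z + p2.z) / 3.0};
            if (vdot(n, vsub(insc, cen)) > 0) { // flip so normal points outward
              Vec3 tmp = p1; p1 = p2; p2 = tmp;
              n.x = -n.x; n.y = -n.y; n.z = -n.z;
            }
            area += 0.5 * std::sqrt(vdot(n, n));
            vol6 += vdot(p0, vcross(p1, p2));
          }
        }
      }
  return NumericVector::create(area, std::fabs(vol6) / 6.0);
}
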