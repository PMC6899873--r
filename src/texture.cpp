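#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// 13 unique 3D direction pairs at Chebyshev distance 1 (one per +/- pair)
static const int DIRS[13][3] = {
  {1, 0, 0}, {0, 1, 0}, {1, 1, 0}, {-1, 1, 0},
  {0, 0, 1}, {1, 0, 1}, {-1, 0, 1}, {0, 1, 1}, {0, -1, 1},
  {1, 1, 1}, {-1, 1, 1}, {1, -1, 1}, {-1, -1, 1}
};

// all 26 neighbour offsets
static void offsets26(std::vector<std::array<int, 3>> &offs) {
  offs.clear();
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx)
        if (dx != 0 || dy != 0 || dz != 0)
          offs.push_back({dx, dy, dz});
}

static inline int idx3(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

static void get_dims(const IntegerVector &levels, int &nx, int &ny, int &nz) {
  IntegerVector d = levels.attr("dim");
  if (d.size() != 3) stop("levels must be a 3D array");
  nx = d[0]; ny = d[1]; nz = d[2];
}

// Co-occurrence counts: ng x ng x 13, symmetrized per direction.
// [[Rcpp::export]]
NumericVector cpp_glcm_counts(IntegerVector levels, int ng) {
  int nx, ny, nz;
  get_dims(levels, nx, ny, nz);
  NumericVector out(ng * ng * 13);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int a = levels[idx3(x, y, z, nx, ny)];
        if (a <= 0) continue;
        for (int d = 0; d < 13; ++d) {
          int xx = x + DIRS[d][0], yy = y + DIRS[d][1], zz = z + DIRS[d][2];
          if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
            continue;
          int b = levels[idx3(xx, yy, zz, nx, ny)];
          if (b <= 0) continue;
          out[(a - 1) + ng * (b - 1) + ng * ng * d] += 1.0;
          out[(b - 1) + ng * (a - 1) + ng * ng * d] += 1.0;
        }
      }
  out.attr("dim") = IntegerVector::create(ng, ng, 13);
  return out;
}

// Run-length counts: ng x maxrun x 13.
// [[Rcpp::export]]
NumericVector cpp_glrlm_counts(IntegerVector levels, int ng) {
  int nx, ny, nz;
  get_dims(levels, nx, ny, nz);
  int maxrun = std::max(nx, std::max(ny, nz));
  NumericVector out(ng * maxrun * 13);
  for (int d = 0; d < 13; ++d) {
    int dx = DIRS[d][0], dy = DIRS[d][1], dz = DIRS[d][2];
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          int a = levels[idx3(x, y, z, nx, ny)];
          if (a <= 0) continue;
          // run starts here iff predecessor is outside volume/mask or differs
          int px = x - dx, py = y - dy, pz = z - dz;
          if (px >= 0 && py >= 0 && pz >= 0 && px < nx && py < ny && pz < nz) {
            if (levels[idx3(px, py, pz, nx, ny)] == a) continue;
          }
          int len = 1;
          int cx = x + dx, cy = y + dy, cz = z + dz;
          while (cx >= 0 && cy >= 0 && cz >= 0 && cx < nx && cy < ny &&
                 cz < nz && levels[idx3(cx, cy, cz, nx, ny)] == a) {
            ++len; cx += dx; cy += dy; cz += dz;
          }
          out[(a - 1) + ng * (len - 1) + ng * maxrun * d] += 1.0;
        }
  }
  out.attr("dim") = IntegerVector::create(ng, maxrun, 13);
  return out;
}

// Size-zone enumeration (26-connectivity flood fill): matrix of (level, size).
// [[Rcpp::export]]
IntegerMatrix cpp_glszm_zones(IntegerVector levels, int ng) {
  int nx, ny, nz;
  get_dims(levels, nx, ny, nz);
  std::vector<std::array<int, 3>> offs;
  offsets26(offs);
  int n = nx * ny * nz;
  std::vector<char> seen(n, 0);
  std::vector<int> zl, zs, stack;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int i0 = idx3(x, y, z, nx, ny);
        int a = levels[i0];
        if (a <= 0 || seen[i0]) continue;
        int size = 0;
        stack.clear();
        stack.push_back(i0);
        seen[i0] = 1;
        while (!stack.empty()) {
          int i = stack.back(); stack.pop_back();
          ++size;
          int cx = i % nx, cy = (i / nx) % ny, cz = i / (nx * ny);
          for (size_t k = 0; k < offs.size(); ++k) {
            int xx = cx + offs[k][0], yy = cy + offs[k][1], zz = cz + offs[k][2];
            if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
              continue;
            int j = idx3(xx, yy, zz, nx, ny);
            if (!seen[j] && levels[j] == a) { seen[j] = 1; stack.push_back(j); }
          }
        }
        zl.push_back(a); zs.push_back(size);
      }
  IntegerMatrix out(zl.size(), 2);
  for (size_t i = 0; i < zl.size(); ++i) { out(i, 0) = zl[i]; out(i, 1) = zs[i]; }
  colnames(out) = CharacterVector::create("level", "size");
  return out;
}

// NGTDM accumulators: per level i, n_i (valid voxel count) and
// s_i = sum |i - mean(26-neighbourhood levels within mask)|.
// Voxels with no in-mask neighbour are excluded from n_i.
// [[Rcpp::export]]
NumericMatrix cpp_ngtdm_stats(IntegerVector levels, int ng) {
  int nx, ny, nz;
  get_dims(levels, nx, ny, nz);
  std::vector<std::array<int, 3>> offs;
  offsets26(offs);
  NumericMatrix out(ng, 2);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int a = levels[idx3(x, y, z, nx, ny)];
        if (a <= 0) continue;
        double sum = 0.0; int cnt = 0;
        for (size_t k = 0; k < offs.size(); ++k) {
          int xx = x + offs[k][0], yy = y + offs[k][1], zz = z + offs[k][2];
          if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
            continue;
          int b = levels[idx3(xx, yy, zz, nx, ny)];
          if (b > 0) { sum += b; ++cnt; }
        }
        if (cnt == 0) continue;
        out(a - 1, 0) += 1.0;
        out(a - 1, 1) += std::fabs(a - sum / cnt);
      }
  return out;
}

// Dependence counts (alpha = 0, Chebyshev distance 1): ng x 27 matrix,
// column j = number of voxels whose dependence (centre + equal neighbours)
// equals j.
// [[Rcpp::export]]
NumericMatrix cpp_gldm_counts(IntegerVector levels, int ng) {
  int nx, ny, nz;
  get_dims(levels, nx, ny, nz);
  std::vector<std::array<int, 3>> offs;
  offsets26(offs);
  NumericMatrix out(ng, 27);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int a = levels[idx3(x, y, z, nx, ny)];
        if (a <= 0) continue;
        int dep = 1; // centre voxel counts as dependent on itself
        for (size_t k = 0; k < offs.size(); ++k) {
          int xx = x + offs[k][0], yy = y + offs[k][1], zz = z + offs[k][2];
          if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
            continue;
          if (levels[idx3(xx, yy, zz, nx, ny)] == a) ++dep;
        }
        out(a - 1, dep - 1) += 1.0;
      }
  return out;
}

// ---- surface mesh via marching tetrahedra (Kuhn cube decomposition) ----

struct Vec3 { double x, y, z; };
static inline Vec3 vsub(const Vec3 &a, const Vec3 &b) {
  return {a.x - b.x, a.y - b.y, a.z - b.z};
}
static inline Vec3 vcross(const Vec3 &a, const Vec3 &b) {
  return {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x};
}
static inline double vdot(const Vec3 &a, const Vec3 &b) {
  return a.x * b.x + a.y * b.y + a.z * b.z;
}
static inline Vec3 vmid(const Vec3 &a, const Vec3 &b) {
  return {(a.x + b.x) / 2, (a.y + b.y) / 2, (a.z + b.z) / 2};
}

static void add_tri(Vec3 p0, Vec3 p1, Vec3 p2, const Vec3 &inC, const Vec3 &outC,
                    double &area, double &vol6) {
  Vec3 n = vcross(vsub(p1, p0), vsub(p2, p0));
  Vec3 ref = vsub(outC, inC);
  if (vdot(n, ref) < 0) { Vec3 t = p1; p1 = p2; p2 = t; n = vcross(vsub(p1, p0), vsub(p2, p0)); }
  area += 0.5 * std::sqrt(vdot(n, n));
  vol6 += vdot(p0, vcross(p1, p2));
}

// linear interpolation of the `level` crossing between tet vertices
static inline Vec3 vlerp(const Vec3 &a, const Vec3 &b, double va, double vb,
                         double level) {
  double t = (level - va) / (vb - va);
  if (t < 0) t = 0; else if (t > 1) t = 1;
  return {a.x + t * (b.x - a.x), a.y + t * (b.y - a.y),
          a.z + t * (b.z - a.z)};
}

// Surface area (mm^2) and enclosed mesh volume (mm^3) of the `level`
// isosurface of a scalar field (outside the array the field is 0), voxel
// centres at (i + 0.5) * spacing. Marching tetrahedra on the Kuhn 6-tet
// cube decomposition with linear edge interpolation.
// [[Rcpp::export]]
NumericVector cpp_mesh_area_volume(NumericVector field, NumericVector spacing,
                                   double level = 0.5) {
  int nx, ny, nz;
  IntegerVector dd = field.attr("dim");
  if (dd.size() != 3) stop("field must be a 3D array");
  nx = dd[0]; ny = dd[1]; nz = dd[2];
  double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  // Kuhn: 6 axis-permutation paths from corner (0,0,0) to (1,1,1)
  static const int PERMS[6][3] = {
    {0, 1, 2}, {0, 2, 1}, {1, 0, 2}, {1, 2, 0}, {2, 0, 1}, {2, 1, 0}
  };
  double area = 0.0, vol6 = 0.0;
  for (int z = -1; z < nz; ++z)
    for (int y = -1; y < ny; ++y)
      for (int x = -1; x < nx; ++x) {
        double val[8];
        bool anyIn = false, anyOut = false;
        for (int c = 0; c < 8; ++c) {
          int cx = x + (c & 1), cy = y + ((c >> 1) & 1), cz = z + ((c >> 2) & 1);
          double v = 0;
          if (cx >= 0 && cy >= 0 && cz >= 0 && cx < nx && cy < ny && cz < nz)
            v = field[idx3(cx, cy, cz, nx, ny)];
          val[c] = v;
          if (v > level) anyIn = true; else anyOut = true;
        }
        if (!anyIn || !anyOut) continue;
        for (int p = 0; p < 6; ++p) {
          int corner[4];
          corner[0] = 0;
          int bits = 0;
          for (int s = 0; s < 3; ++s) {
            bits |= (1 << PERMS[p][s]);
            corner[s + 1] = bits;
          }
          Vec3 pos[4];
          double tvv[4];
          int tv[4], nin = 0;
          for (int s = 0; s < 4; ++s) {
            int c = corner[s];
            pos[s] = {(x + (c & 1) + 0.5) * sx,
                      (y + ((c >> 1) & 1) + 0.5) * sy,
                      (z + ((c >> 2) & 1) + 0.5) * sz};
            tvv[s] = val[c];
            tv[s] = val[c] > level ? 1 : 0;
            nin += tv[s];
          }
          if (nin == 0 || nin == 4) continue;
          Vec3 inC = {0, 0, 0}, outC = {0, 0, 0};
          for (int s = 0; s < 4; ++s) {
            if (tv[s]) { inC.x += pos[s].x; inC.y += pos[s].y; inC.z += pos[s].z; }
            else { outC.x += pos[s].x; outC.y += pos[s].y; outC.z += pos[s].z; }
          }
          inC.x /= nin; inC.y /= nin; inC.z /= nin;
          outC.x /= (4 - nin); outC.y /= (4 - nin); outC.z /= (4 - nin);
          int ins[4], outs[4], ni = 0, no = 0;
          for (int s = 0; s < 4; ++s) { if (tv[s]) ins[ni++] = s; else outs[no++] = s; }
          if (nin == 1) {
            Vec3 a = vlerp(pos[ins[0]], pos[outs[0]], tvv[ins[0]], tvv[outs[0]], level);
            Vec3 b = vlerp(pos[ins[0]], pos[outs[1]], tvv[ins[0]], tvv[outs[1]], level);
            Vec3 c = vlerp(pos[ins[0]], pos[outs[2]], tvv[ins[0]], tvv[outs[2]], level);
            add_tri(a, b, c, inC, outC, area, vol6);
          } else if (nin == 3) {
            Vec3 a = vlerp(pos[outs[0]], pos[ins[0]], tvv[outs[0]], tvv[ins[0]], level);
            Vec3 b = vlerp(pos[outs[0]], pos[ins[1]], tvv[outs[0]], tvv[ins[1]], level);
            Vec3 c = vlerp(pos[outs[0]], pos[ins[2]], tvv[outs[0]], tvv[ins[2]], level);
            add_tri(a, b, c, inC, outC, area, vol6);
          } else { // 2 in, 2 out -> quad
            Vec3 a = vlerp(pos[ins[0]], pos[outs[0]], tvv[ins[0]], tvv[outs[0]], level);
            Vec3 b = vlerp(pos[ins[0]], pos[outs[1]], tvv[ins[0]], tvv[outs[1]], level);
            Vec3 c = vlerp(pos[ins[1]], pos[outs[1]], tvv[ins[1]], tvv[outs[1]], level);
            Vec3 d = vlerp(pos[ins[1]], pos[outs[0]], tvv[ins[1]], tvv[outs[0]], level);
            add_tri(a, b, c, inC, outC, area, vol6);
            add_tri(a, c, d, inC, outC, area, vol6);
          }
        }
      }
  return NumericVector::create(_["surface_area"] = area,
                               _["mesh_volume"] = vol6 / 6.0);
}

// Column-wise 1D convolution with a centred kernel, zero padding outside.
// [[Rcpp::export]]
NumericMatrix cpp_conv_cols(NumericMatrix m, NumericVector kernel) {
  int n = m.nrow(), nc = m.ncol(), len = kernel.size();
  int r = (len - 1) / 2;
  NumericMatrix out(n, nc);
  for (int c = 0; c < nc; ++c)
    for (int i = 0; i < n; ++i) {
      double s = 0;
      int k0 = std::max(0, r - i), k1 = std::min(len, n - i + r);
      for (int k = k0; k < k1; ++k)
        s += m(i + k - r, c) * kernel[k];
      out(i, c) = s;
    }
  return out;
}

// Maximum pairwise Euclidean distance over candidate points, restricted to
// pairs sharing a group label (pass a constant group for no restriction).
// coords may have 2 or 3 columns.
// [[Rcpp::export]]
double cpp_max_dist(NumericMatrix coords, IntegerVector group) {
  int n = coords.nrow(), m = coords.ncol();
  double best = 0;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      if (group[i] != group[j]) continue;
      double q = 0;
      for (int c = 0; c < m; ++c) {
        double d = coords(j, c) - coords(i, c);
        q += d * d;
      }
      if (q > best) best = q;
    }
  return std::sqrt(best);
}
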