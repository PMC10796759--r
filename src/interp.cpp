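#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Trilinear sampling on an axis-aligned grid. Continuous voxel coordinates are
// 0-based; the voxel value sits at the voxel center. Fractional weights within
// 1e-9 of 0/1 are snapped so that sampling exactly at voxel centers (or at
// whole-voxel translations) reproduces stored values bit-exactly.
static inline double sample_voxel(const double* v, const int nx, const int ny,
                                  const int nz, double x, double y, double z,
                                  const double fill) {
  const double eps = 1e-9;
  if (x < -eps || y < -eps || z < -eps ||
      x > nx - 1 + eps || y > ny - 1 + eps || z > nz - 1 + eps)
    return fill;
  if (x < 0) x = 0;
  if (y < 0) y = 0;
  if (z < 0) z = 0;
  if (x > nx - 1) x = nx - 1;
  if (y > ny - 1) y = ny - 1;
  if (z > nz - 1) z = nz - 1;
  int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
  if (i0 > nx - 2) i0 = nx - 2;
  if (i0 < 0) i0 = 0;
  if (j0 > ny - 2) j0 = ny - 2;
  if (j0 < 0) j0 = 0;
  if (k0 > nz - 2) k0 = nz - 2;
  if (k0 < 0) k0 = 0;
  double fx = x - i0, fy = y - j0, fz = z - k0;
  if (fx < eps) fx = 0; else if (fx > 1 - eps) fx = 1;
  if (fy < eps) fy = 0; else if (fy > 1 - eps) fy = 1;
  if (fz < eps) fz = 0; else if (fz > 1 - eps) fz = 1;
  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
  const double* p = v + i0 * sx + j0 * sy + k0 * sz;
  const double c000 = p[0], c100 = p[sx], c010 = p[sy], c110 = p[sx + sy];
  const double c001 = p[sz], c101 = p[sx + sz], c011 = p[sy + sz],
               c111 = p[sx + sy + sz];
  const double c00 = c000 * (1 - fx) + c100 * fx;
  const double c10 = c010 * (1 - fx) + c110 * fx;
  const double c01 = c001 * (1 - fx) + c101 * fx;
  const double c11 = c011 * (1 - fx) + c111 * fx;
  const double c0 = c00 * (1 - fy) + c10 * fy;
  const double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

// [[Rcpp::export]]
NumericVector cpp_sample_points(const NumericVector& data,
                                const IntegerVector& dim,
                                const NumericVector& spacing,
                                const NumericVector& origin,
                                const NumericMatrix& pts, const double fill) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double* v = data.begin();
  const R_xlen_t n = pts.nrow();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    const double x = (pts(i, 0) - origin[0]) / spacing[0];
    const double y = (pts(i, 1) - origin[1]) / spacing[1];
    const double z = (pts(i, 2) - origin[2]) / spacing[2];
    out[i] = sample_voxel(v, nx, ny, nz, x, y, z, fill);
  }
  return out;
}

// Resample a volume under a rigid map: output voxel at world position w takes
// the value of the input volume at R (w - c) + c + t.
// [[Rcpp::export]]
NumericVector cpp_resample_rigid(const NumericVector& data,
                                 const IntegerVector& dim,
                                 const NumericVector& spacing,
                                 const NumericVector& origin,
                                 const NumericMatrix& rot,
                                 const NumericVector& trans,
                                 const NumericVector& center,
                                 const double fill) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double* v = data.begin();
  NumericVector out((R_xlen_t)nx * ny * nz);
  const double r00 = rot(0, 0), r01 = rot(0, 1), r02 = rot(0, 2);
  const double r10 = rot(1, 0), r11 = rot(1, 1), r12 = rot(1, 2);
  const double r20 = rot(2, 0), r21 = rot(2, 1), r22 = rot(2, 2);
  R_xlen_t idx = 0;
  for (int k = 0; k < nz; ++k) {
    const double wz = origin[2] + k * spacing[2] - center[2];
    for (int j = 0; j < ny; ++j) {
      const double wy = origin[1] + j * spacing[1] - center[1];
      for (int i = 0; i < nx; ++i, ++idx) {
        const double wx = origin[0] + i * spacing[0] - center[0];
        const double px = r00 * wx + r01 * wy + r02 * wz + center[0] + trans[0];
        const double py = r10 * wx + r11 * wy + r12 * wz + center[1] + trans[1];
        const double pz = r20 * wx + r21 * wy + r22 * wz + center[2] + trans[2];
        out[idx] = sample_voxel(v, nx, ny, nz,
                                (px - origin[0]) / spacing[0],
                                (py - origin[1]) / spacing[1],
                                (pz - origin[2]) / spacing[2], fill);
      }
    }
  }
  return out;
}

// Masked mean squared difference between fixed values at world points and the
// moving volume sampled at the rigidly transformed points.
// [[Rcpp::export]]
double cpp_msd(const NumericVector& fixed_vals, const NumericMatrix& pts,
               const NumericVector& data, const IntegerVector& dim,
               const NumericVector& spacing, const NumericVector& origin,
               const NumericMatrix& rot, const NumericVector& trans,
               const NumericVector& center, const double fill) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double* v = data.begin();
  const double r00 = rot(0, 0), r01 = rot(0, 1), r02 = rot(0, 2);
  const double r10 = rot(1, 0), r11 = rot(1, 1), r12 = rot(1, 2);
  const double r20 = rot(2, 0), r21 = rot(2, 1), r22 = rot(2, 2);
  const R_xlen_t n = pts.nrow();
  double acc = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    const double wx = pts(i, 0) - center[0];
    const double wy = pts(i, 1) - center[1];
    const double wz = pts(i, 2) - center[2];
    const double px = r00 * wx + r01 * wy + r02 * wz + center[0] + trans[0];
    const double py = r10 * wx + r11 * wy + r12 * wz + center[1] + trans[1];
    const double pz = r20 * wx + r21 * wy + r22 * wz + center[2] + trans[2];
    const double m = sample_voxel(v, nx, ny, nz,
                                  (px - origin[0]) / spacing[0],
                                  (py - origin[1]) / spacing[1],
                                  (pz - origin[2]) / spacing[2], fill);
    const double d = fixed_vals[i] - m;
    acc += d * d;
  }
  return acc / (double)n;
}

// Factor-2 block-mean downsampling (trailing odd voxels are dropped).
// [[Rcpp::export]]
NumericVector cpp_downsample2(const NumericVector& data,
                              const IntegerVector& dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int mx = nx / 2, my = ny / 2, mz = nz / 2;
  const double* v = data.begin();
  NumericVector out((R_xlen_t)mx * my * mz);
  out.attr("dim") = IntegerVector::create(mx, my, mz);
  const R_xlen_t sy = nx, sz = (R_xlen_t)nx * ny;
  R_xlen_t idx = 0;
  for (int k = 0; k < mz; ++k)
    for (int j = 0; j < my; ++j)
      for (int i = 0; i < mx; ++i, ++idx) {
        const double* p = v + 2 * i + 2 * j * sy + 2 * k * sz;
        out[idx] = (p[0] + p[1] + p[sy] + p[sy + 1] + p[sz] + p[sz + 1] +
                    p[sz + sy] + p[sz + sy + 1]) / 8.0;
      }
  return out;
}

// 26-connected component labels for a sparse voxel set given as 0-based linear
// indices into a grid of dimension `dim`. Labels are 1-based, assigned in
// order of first visit (deterministic).
// [[Rcpp::export]]
IntegerVector cpp_components26(const IntegerVector& dim,
                               const NumericVector& idx0) {
  const int nx = dim[0], ny = dim[1];
  const R_xlen_t n = idx0.size();
  std::unordered_map<long long, R_xlen_t> pos;
  pos.reserve(n * 2);
  for (R_xlen_t i = 0; i < n; ++i) pos[(long long)idx0[i]] = i;
  IntegerVector labels(n, 0);
  std::vector<R_xlen_t> stack;
  int next_label = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (labels[i]) continue;
    ++next_label;
    labels[i] = next_label;
    stack.push_back(i);
    while (!stack.empty()) {
      const R_xlen_t cur = stack.back();
      stack.pop_back();
      const long long lin = (long long)idx0[cur];
      const long long k = lin / ((long long)nx * ny);
      const long long rem = lin - k * (long long)nx * ny;
      const long long j = rem / nx;
      const long long ii = rem - j * nx;
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (!di && !dj && !dk) continue;
            const long long ni = ii + di, nj = j + dj, nk = k + dk;
            if (ni < 0 || nj < 0 || nk < 0 || ni >= nx || nj >= ny ||
                nk >= dim[2])
              continue;
            const long long nlin = ni + nx * (nj + (long long)ny * nk);
            auto it = pos.find(nlin);
            if (it != pos.end() && !labels[it->second]) {
              labels[it->second] = next_label;
              stack.push_back(it->second);
            }
          }
    }
  }
  return labels;
}
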