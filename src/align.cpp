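#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Trilinear sampling of vol at (x, y, z) in 0-based voxel coordinates;
// returns 0 outside the grid.
static inline double sample_trilinear(const double *vol, int nx, int ny,
                                      int nz, double x, double y, double z) {
  if (x < 0 || y < 0 || z < 0 || x > nx - 1 || y > ny - 1 || z > nz - 1)
    return 0.0;
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
  int x1 = x0 + 1 < nx ? x0 + 1 : x0;
  int y1 = y0 + 1 < ny ? y0 + 1 : y0;
  int z1 = z0 + 1 < nz ? z0 + 1 : z0;
  double fx = x - x0, fy = y - y0, fz = z - z0;
  const long sx = 1, sy = nx, sz = (long)nx * ny;
#define V(i, j, k) vol[(i) * sx + (j) * sy + (k) * sz]
  double c00 = V(x0, y0, z0) * (1 - fx) + V(x1, y0, z0) * fx;
  double c10 = V(x0, y1, z0) * (1 - fx) + V(x1, y1, z0) * fx;
  double c01 = V(x0, y0, z1) * (1 - fx) + V(x1, y0, z1) * fx;
  double c11 = V(x0, y1, z1) * (1 - fx) + V(x1, y1, z1) * fx;
#undef V
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

// Rotate the object in `vol` by rotation matrix R (about the grid center):
// out(x) = vol(R^T (x - c) + c). R is 3x3, column-major, acting on column
// vectors (the package's reference-to-tomogram convention).
// [[Rcpp::export]]
NumericVector cpp_rotate_vol(NumericVector vol, IntegerVector dim,
                             NumericMatrix R) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  double cx = (nx - 1) / 2.0, cy = (ny - 1) / 2.0, cz = (nz - 1) / 2.0;
  NumericVector out((long)nx * ny * nz);
  const double *v = vol.begin();
  double *o = out.begin();
  // rows of R^T are columns of R
  double r00 = R(0, 0), r10 = R(1, 0), r20 = R(2, 0);
  double r01 = R(0, 1), r11 = R(1, 1), r21 = R(2, 1);
  double r02 = R(0, 2), r12 = R(1, 2), r22 = R(2, 2);
  long idx = 0;
  for (int k = 0; k < nz; ++k) {
    double dz = k - cz;
    for (int j = 0; j < ny; ++j) {
      double dy = j - cy;
      for (int i = 0; i < nx; ++i, ++idx) {
        double dx = i - cx;
        // R^T * d
        double sx = r00 * dx + r10 * dy + r20 * dz + cx;
        double sy = r01 * dx + r11 * dy + r21 * dz + cy;
        double sz = r02 * dx + r12 * dy + r22 * dz + cz;
        o[idx] = sample_trilinear(v, nx, ny, nz, sx, sy, sz);
      }
    }
  }
  return out;
}

// Best circular integer shift of `b` against `a` within +/- shift_max,
// zero-mean normalized cross-correlation. Returns (score, sx, sy, sz).
static void best_shift_score(const double *a, const double *b, int nx, int ny,
                             int nz, int shift_max, double a_mean,
                             double a_ss, double *best_score, int *best_sh) {
  long n = (long)nx * ny * nz;
  double b_sum = 0, b_ss = 0;
  for (long t = 0; t < n; ++t) { b_sum += b[t]; b_ss += b[t] * b[t]; }
  double b_mean = b_sum / n;
  double b_var = b_ss - n * b_mean * b_mean;
  double denom = std::sqrt(a_ss * b_var);
  *best_score = -2.0;
  best_sh[0] = best_sh[1] = best_sh[2] = 0;
  if (denom <= 0) { *best_score = 0.0; return; }
  int s = shift_max;
  for (int dx = -s; dx <= s; ++dx) {
    int dxm = ((dx % nx) + nx) % nx;      // circular x shift, split into
    int n1 = nx - dxm;                    // two contiguous segments
    for (int dy = -s; dy <= s; ++dy) {
      for (int dz = -s; dz <= s; ++dz) {
        double num = 0;
        for (int k = 0; k < nz; ++k) {
          int ks = ((k + dz) % nz + nz) % nz;
          long ofk = (long)ks * nx * ny;
          long ak = (long)k * nx * ny;
          for (int j = 0; j < ny; ++j) {
            int js = ((j + dy) % ny + ny) % ny;
            const double *arow = a + ak + (long)j * nx;
            const double *brow = b + ofk + (long)js * nx;
            double acc = 0;
            for (int i = 0; i < n1; ++i) acc += arow[i] * brow[i + dxm];
            for (int i = n1; i < nx; ++i) acc += arow[i] * brow[i + dxm - nx];
            num += acc;
          }
        }
        double score = (num - n * a_mean * b_mean) / denom;
        if (score > *best_score + 1e-15) {
          *best_score = score;
          best_sh[0] = dx; best_sh[1] = dy; best_sh[2] = dz;
        }
      }
    }
  }
}

// Exhaustive alignment of `vol` against `ref` over a list of candidate
// rotations (rotmats: N x 9, row r holds R column-major). For each rotation
// the reference is rotated (optionally masked), and the best circular shift
// within shift_max is found by zero-mean normalized cross-correlation.
// Ties resolve to the earliest rotation in the list (strict improvement
// required), so callers control tie-breaking by candidate order.
// [[Rcpp::export]]
List cpp_align(NumericVector vol, NumericVector ref, IntegerVector dim,
               NumericMatrix rotmats, int shift_max,
               Nullable<NumericVector> mask = R_NilValue) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  long n = (long)nx * ny * nz;
  int nrot = rotmats.nrow();
  const double *a = vol.begin();
  double a_sum = 0, a_ss = 0;
  for (long t = 0; t < n; ++t) { a_sum += a[t]; a_ss += a[t] * a[t]; }
  double a_mean = a_sum / n;
  double a_var = a_ss - n * a_mean * a_mean;
  bool has_mask = mask.isNotNull();
  NumericVector maskv;
  if (has_mask) maskv = mask.get();

  NumericVector scores(nrot);
  double best = -2.0;
  int best_idx = -1, best_sh[3] = {0, 0, 0};
  NumericMatrix R(3, 3);
  for (int r = 0; r < nrot; ++r) {
    for (int c = 0; c < 9; ++c) R[c] = rotmats(r, c);
    NumericVector rot = cpp_rotate_vol(ref, dim, R);
    if (has_mask)
      for (long t = 0; t < n; ++t) rot[t] *= maskv[t];
    double sc; int sh[3];
    best_shift_score(a, rot.begin(), nx, ny, nz, shift_max, a_mean, a_var,
                     &sc, sh);
    scores[r] = sc;
    if (sc > best + 1e-15) {
      best = sc; best_idx = r;
      best_sh[0] = sh[0]; best_sh[1] = sh[1]; best_sh[2] = sh[2];
    }
  }
  return List::create(_["best_index"] = best_idx + 1,
                      _["shift"] = IntegerVector::create(best_sh[0], best_sh[1],
                                                         best_sh[2]),
                      _["score"] = best,
                      _["scores"] = scores);
}

// Circular integer shift: out(x) = vol(x - shift).
// [[Rcpp::export]]
NumericVector cpp_shift_vol(NumericVector vol, IntegerVector dim,
                            IntegerVector shift) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out((long)nx * ny * nz);
  int sx = shift[0], sy = shift[1], sz = shift[2];
  for (int k = 0; k < nz; ++k) {
    int ks = ((k - sz) % nz + nz) % nz;
    for (int j = 0; j < ny; ++j) {
      int js = ((j - sy) % ny + ny) % ny;
      long of = (long)ks * nx * ny + (long)js * nx;
      long oo = (long)k * nx * ny + (long)j * nx;
      for (int i = 0; i < nx; ++i) {
        int is = ((i - sx) % nx + nx) % nx;
        out[oo + i] = vol[of + is];
      }
    }
  }
  return out;
}

// Zero-mean normalized cross-correlation at zero shift.
// [[Rcpp::export]]
double cpp_ncc(NumericVector a, NumericVector b) {
  long n = a.size();
  double sa = 0, sb = 0, saa = 0, sbb = 0, sab = 0;
  for (long t = 0; t < n; ++t) {
    sa += a[t]; sb += b[t];
    saa += a[t] * a[t]; sbb += b[t] * b[t]; sab += a[t] * b[t];
  }
  double num = sab - sa * sb / n;
  double den = std::sqrt((saa - sa * sa / n) * (sbb - sb * sb / n));
  if (den <= 0) return 0.0;
  return num / den;
}
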