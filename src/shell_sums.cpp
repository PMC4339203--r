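#include <Rcpp.h>
using namespace Rcpp;

// Whole-sample symmetric (mirror) reflection of a 0-based index into [0, n).
static inline int mirror0(int i, int n) {
  if (n == 1) return 0;
  const int period = 2 * n - 2;
  i %= period;
  if (i < 0) i += period;
  if (i >= n) i = period - i;
  return i;
}

// Per-voxel sums of |v(q) - v(c)| over Chebyshev (max-norm) shells of
// radius d = 1..scales around each center voxel c. Out-of-volume neighbors
// are mirror-reflected (mirror = true) or skipped (mirror = false); the
// per-voxel pair counts are returned alongside the sums so the caller can
// form mean absolute differences either way. Offsets iterate in the outer
// loop with per-axis mirror lookup tables, keeping the inner voxel sweep
// contiguous.
// [[Rcpp::export]]
List shell_increment_sums(NumericVector vol, IntegerVector dims, int scales,
                          bool mirror) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t nxy = (R_xlen_t)nx * ny;
  const R_xlen_t nvox = nxy * nz;
  const double* v = vol.begin();
  List sums(scales), counts(scales);

  std::vector<int> mx(nx), my(ny), mz(nz);
  for (int d = 1; d <= scales; ++d) {
    NumericVector s(nvox);
    IntegerVector cnt(nvox);
    double* sp = s.begin();
    int* cp = cnt.begin();
    for (int dz = -d; dz <= d; ++dz) {
      for (int dy = -d; dy <= d; ++dy) {
        for (int dx = -d; dx <= d; ++dx) {
          const int cheb =
              std::max(std::abs(dx), std::max(std::abs(dy), std::abs(dz)));
          if (cheb != d) continue;
          if (mirror) {
            for (int x = 0; x < nx; ++x) mx[x] = mirror0(x + dx, nx);
            for (int y = 0; y < ny; ++y) my[y] = mirror0(y + dy, ny);
            for (int z = 0; z < nz; ++z) mz[z] = mirror0(z + dz, nz);
            for (int z = 0; z < nz; ++z) {
              const R_xlen_t zb = (R_xlen_t)z * nxy;
              const R_xlen_t qzb = (R_xlen_t)mz[z] * nxy;
              for (int y = 0; y < ny; ++y) {
                const R_xlen_t yb = zb + (R_xlen_t)y * nx;
                const R_xlen_t qyb = qzb + (R_xlen_t)my[y] * nx;
                // interior x-run: q index advances with x, no lookup
                const int x_lo = std::max(0, -dx);
                const int x_hi = std::min(nx, nx - dx);
                for (int x = 0; x < x_lo; ++x) {
                  sp[yb + x] += std::fabs(v[qyb + mx[x]] - v[yb + x]);
                  ++cp[yb + x];
                }
                const double* vq = v + qyb + dx;
                const double* vc = v + yb;
                double* sr = sp + yb;
                int* cr = cp + yb;
                for (int x = x_lo; x < x_hi; ++x) {
                  sr[x] += std::fabs(vq[x] - vc[x]);
                  ++cr[x];
                }
                for (int x = x_hi; x < nx; ++x) {
                  sp[yb + x] += std::fabs(v[qyb + mx[x]] - v[yb + x]);
                  ++cp[yb + x];
                }
              }
            }
          } else {
            const int z_lo = std::max(0, -dz), z_hi = std::min(nz, nz - dz);
            const int y_lo = std::max(0, -dy), y_hi = std::min(ny, ny - dy);
            const int x_lo = std::max(0, -dx), x_hi = std::min(nx, nx - dx);
            for (int z = z_lo; z < z_hi; ++z) {
              const R_xlen_t zb = (R_xlen_t)z * nxy;
              const R_xlen_t qzb = (R_xlen_t)(z + dz) * nxy;
              for (int y = y_lo; y < y_hi; ++y) {
                const R_xlen_t yb = zb + (R_xlen_t)y * nx;
                const R_xlen_t qyb = qzb + (R_xlen_t)(y + dy) * nx + dx;
                for (int x = x_lo; x < x_hi; ++x) {
                  sp[yb + x] += std::fabs(v[qyb + x] - v[yb + x]);
                  ++cp[yb + x];
                }
              }
            }
          }
        }
      }
    }
    sums[d - 1] = s;
    counts[d - 1] = cnt;
  }
  return List::create(_["sums"] = sums, _["counts"] = counts);
}
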