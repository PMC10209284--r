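#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Voxel arrays are column-major with dim = c(nz, ny, nx):
// linear index = z + nz * (y + ny * x), all 0-based here.

static inline int lin(int z, int y, int x, int nz, int ny) {
  return z + nz * (y + ny * x);
}

// 3D connected-component labelling by iterative flood fill.
// conn must be 6 or 26. Labels are 1..k in first-encounter order.
// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector mask, IntegerVector dims, int conn) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  IntegerVector labels(n, 0);

  std::vector<int> dz, dy, dx;
  for (int az = -1; az <= 1; ++az)
    for (int ay = -1; ay <= 1; ++ay)
      for (int ax = -1; ax <= 1; ++ax) {
        if (az == 0 && ay == 0 && ax == 0) continue;
        int manh = std::abs(az) + std::abs(ay) + std::abs(ax);
        if (conn == 6 && manh != 1) continue;
        dz.push_back(az); dy.push_back(ay); dx.push_back(ax);
      }
  const int k = (int)dz.size();

  std::vector<int> stack;
  int next = 0;
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        int p = lin(z, y, x, nz, ny);
        if (!mask[p] || labels[p] != 0) continue;
        ++next;
        labels[p] = next;
        stack.clear();
        stack.push_back(p);
        while (!stack.empty()) {
          int q = stack.back(); stack.pop_back();
          int qx = q / (nz * ny);
          int rem = q - qx * nz * ny;
          int qy = rem / nz;
          int qz = rem - qy * nz;
          for (int m = 0; m < k; ++m) {
            int wz = qz + dz[m], wy = qy + dy[m], wx = qx + dx[m];
            if (wz < 0 || wz >= nz || wy < 0 || wy >= ny || wx < 0 || wx >= nx)
              continue;
            int w = lin(wz, wy, wx, nz, ny);
            if (mask[w] && labels[w] == 0) {
              labels[w] = next;
              stack.push_back(w);
            }
          }
        }
      }
  return labels;
}

// Binary dilation (op = 1) or erosion (op = 0) by an explicit offset set.
// offsets: integer matrix with columns (dz, dy, dx); out-of-bounds voxels are
// treated as background (so erosion shrinks objects at the volume border).
// [[Rcpp::export]]
LogicalVector cpp_binary_morph(LogicalVector mask, IntegerVector dims,
                               IntegerMatrix offsets, int op) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  const int k = offsets.nrow();
  LogicalVector out(n);

  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        int p = lin(z, y, x, nz, ny);
        bool acc = (op == 1) ? false : true;
        for (int m = 0; m < k; ++m) {
          int wz = z + offsets(m, 0), wy = y + offsets(m, 1), wx = x + offsets(m, 2);
          bool v;
          if (wz < 0 || wz >= nz || wy < 0 || wy >= ny || wx < 0 || wx >= nx)
            v = false;
          else
            v = mask[lin(wz, wy, wx, nz, ny)];
          if (op == 1) { if (v) { acc = true; break; } }
          else         { if (!v) { acc = false; break; } }
        }
        out[p] = acc;
      }
  return out;
}
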