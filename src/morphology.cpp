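#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// Binary dilation of a 3-D mask by an explicit list of integer voxel offsets.
// Offsets are rows of an n x 3 matrix (dx, dy, dz in voxels). Out-of-grid
// targets are clipped (the caller guarantees the grid has enough headroom
// when clipping would matter).
// [[Rcpp::export]]
LogicalVector dilate_mask_cpp(LogicalVector mask, IntegerVector dim,
                              IntegerMatrix offsets) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dim");
  LogicalVector out(n, false);
  const int noff = offsets.nrow();
  for (int z = 0; z < nz; ++z) {
    for (int y = 0; y < ny; ++y) {
      const R_xlen_t base = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx;
      for (int x = 0; x < nx; ++x) {
        if (!mask[base + x]) continue;
        for (int k = 0; k < noff; ++k) {
          const int xx = x + offsets(k, 0);
          if (xx < 0 || xx >= nx) continue;
          const int yy = y + offsets(k, 1);
          if (yy < 0 || yy >= ny) continue;
          const int zz = z + offsets(k, 2);
          if (zz < 0 || zz >= nz) continue;
          out[(R_xlen_t)zz * nx * ny + (R_xlen_t)yy * nx + xx] = true;
        }
      }
    }
  }
  return out;
}

// 6-connected component labelling of a 3-D boolean grid. Labels are
// 1-based in discovery order; background is 0.
// [[Rcpp::export]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dim");
  IntegerVector labels(n, 0);
  int current = 0;
  std::queue<R_xlen_t> q;
  for (R_xlen_t start = 0; start < n; ++start) {
    if (!mask[start] || labels[start] != 0) continue;
    labels[start] = ++current;
    q.push(start);
    while (!q.empty()) {
      const R_xlen_t idx = q.front();
      q.pop();
      const int x = idx % nx;
      const int y = (idx / nx) % ny;
      const int z = idx / ((R_xlen_t)nx * ny);
      const int dx[6] = {-1, 1, 0, 0, 0, 0};
      const int dy[6] = {0, 0, -1, 1, 0, 0};
      const int dz[6] = {0, 0, 0, 0, -1, 1};
      for (int k = 0; k < 6; ++k) {
        const int xx = x + dx[k], yy = y + dy[k], zz = z + dz[k];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        const R_xlen_t nidx = (R_xlen_t)zz * nx * ny + (R_xlen_t)yy * nx + xx;
        if (mask[nidx] && labels[nidx] == 0) {
          labels[nidx] = current;
          q.push(nidx);
        }
      }
    }
  }
  labels.attr("n_components") = current;
  return labels;
}
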