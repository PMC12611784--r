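#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

// Label connected components of a 3D logical mask (26- or 6-connectivity).
// Returns an integer array of component labels (0 = background), numbered in
// first-encounter raster order.
// [[Rcpp::export(name = ".cc3d_label")]]
IntegerVector cc3d_label(LogicalVector mask, IntegerVector dims, int connectivity = 26) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);

  std::vector<std::array<int,3>> nb;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int m = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && m != 1) continue;
        nb.push_back({dx, dy, dz});
      }

  int next = 0;
  std::queue<R_xlen_t> q;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i] || lab[i] != 0) continue;
    ++next;
    lab[i] = next;
    q.push(i);
    while (!q.empty()) {
      R_xlen_t cur = q.front(); q.pop();
      int x = cur % nx, y = (cur / nx) % ny, z = cur / ((R_xlen_t)nx * ny);
      for (auto &d : nb) {
        int xx = x + d[0], yy = y + d[1], zz = z + d[2];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
        R_xlen_t j = xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
        if (mask[j] && lab[j] == 0) { lab[j] = next; q.push(j); }
      }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}
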