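// 3-d connected-component labelling with 26-connectivity (BFS).
// Components are labelled in discovery order (scan order: z fastest);
// callers relabel by size where needed.

#include <Rcpp.h>
#include <vector>

using namespace Rcpp;

// [[Rcpp::export]]
IntegerVector label_components_3d(LogicalVector mask, IntegerVector dims) {
  if (dims.size() != 3) stop("dims must have length 3");
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  if (mask.size() != n) stop("mask length does not match dims");

  IntegerVector lab(n, 0);
  std::vector<R_xlen_t> stack;
  int next = 0;

  for (R_xlen_t start = 0; start < n; ++start) {
    if (!mask[start] || lab[start]) continue;
    ++next;
    lab[start] = next;
    stack.push_back(start);
    while (!stack.empty()) {
      const R_xlen_t v = stack.back();
      stack.pop_back();
      const int z = v % nz;
      const int y = (v / nz) % ny;
      const int x = v / ((R_xlen_t)nz * ny);
      for (int dx = -1; dx <= 1; ++dx) {
        const int xx = x + dx;
        if (xx < 0 || xx >= nx) continue;
        for (int dy = -1; dy <= 1; ++dy) {
          const int yy = y + dy;
          if (yy < 0 || yy >= ny) continue;
          for (int dz = -1; dz <= 1; ++dz) {
            if (!dx && !dy && !dz) continue;
            const int zz = z + dz;
            if (zz < 0 || zz >= nz) continue;
            const R_xlen_t w = zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx);
            if (mask[w] && !lab[w]) {
              lab[w] = next;
              stack.push_back(w);
            }
          }
        }
      }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}
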