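#include <Rcpp.h>
#include <vector>

using namespace Rcpp;

// 3D connected-component labelling, 6-connectivity, iterative BFS.
// mask: logical vector in column-major (z, x, y) order; dims: c(nz, nx, ny).
// Returns integer labels (0 = background), components numbered from 1 in
// decreasing voxel-count order so label 1 is always the largest component.
// [[Rcpp::export(name = ".label_components_3d")]]
IntegerVector label_components_3d(LogicalVector mask, IntegerVector dims) {
  if (dims.size() != 3) stop("dims must have length 3");
  const int nz = dims[0], nx = dims[1], ny = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * nx * ny;
  if (mask.size() != n) stop("mask length does not match dims");

  IntegerVector labels(n, 0);
  std::vector<R_xlen_t> queue;
  std::vector<R_xlen_t> sizes; // per component
  int next_label = 0;

  for (R_xlen_t start = 0; start < n; ++start) {
    if (!mask[start] || labels[start] != 0) continue;
    ++next_label;
    R_xlen_t count = 0;
    queue.clear();
    queue.push_back(start);
    labels[start] = next_label;
    while (!queue.empty()) {
      R_xlen_t idx = queue.back();
      queue.pop_back();
      ++count;
      int z = (int)(idx % nz);
      R_xlen_t rest = idx / nz;
      int x = (int)(rest % nx);
      int y = (int)(rest / nx);
      const int dz[6] = {-1, 1, 0, 0, 0, 0};
      const int dx[6] = {0, 0, -1, 1, 0, 0};
      const int dy[6] = {0, 0, 0, 0, -1, 1};
      for (int k = 0; k < 6; ++k) {
        int zz = z + dz[k], xx = x + dx[k], yy = y + dy[k];
        if (zz < 0 || zz >= nz || xx < 0 || xx >= nx || yy < 0 || yy >= ny)
          continue;
        R_xlen_t nidx = (R_xlen_t)yy * nx * nz + (R_xlen_t)xx * nz + zz;
        if (mask[nidx] && labels[nidx] == 0) {
          labels[nidx] = next_label;
          queue.push_back(nidx);
        }
      }
    }
    sizes.push_back(count);
  }

  // relabel in decreasing size order
  if (next_label > 1) {
    std::vector<int> order(next_label);
    for (int i = 0; i < next_label; ++i) order[i] = i;
    std::sort(order.begin(), order.end(),
              [&sizes](int a, int b) { return sizes[a] > sizes[b]; });
    std::vector<int> remap(next_label + 1, 0);
    for (int rank = 0; rank < next_label; ++rank) remap[order[rank] + 1] = rank + 1;
    for (R_xlen_t i = 0; i < n; ++i)
      if (labels[i] != 0) labels[i] = remap[labels[i]];
  }

  labels.attr("dim") = dims;
  return labels;
}
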