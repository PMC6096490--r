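#include <Rcpp.h>
#include <vector>

// 6-connectivity (face-neighbour) connected-component labelling of a 3D
// logical grid. Iterative stack-based flood fill; labels are 1..n_regions,
// 0 outside. Points beyond the grid bounds are treated as background.
// [[Rcpp::export(name = ".label_components6")]]
Rcpp::IntegerVector label_components6(Rcpp::LogicalVector inside,
                                      Rcpp::IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  Rcpp::IntegerVector labels(n, 0);
  labels.attr("dim") = dims;
  int current = 0;
  std::vector<R_xlen_t> stack;
  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
  for (R_xlen_t start = 0; start < n; ++start) {
    if (!inside[start] || labels[start]) continue;
    ++current;
    stack.push_back(start);
    labels[start] = current;
    while (!stack.empty()) {
      R_xlen_t p = stack.back();
      stack.pop_back();
      int iz = (int)(p / sz), rem = (int)(p % sz);
      int iy = rem / nx, ix = rem % nx;
      const R_xlen_t nb[6] = {p - sx, p + sx, p - sy, p + sy, p - sz, p + sz};
      const bool ok[6] = {ix > 0, ix < nx - 1, iy > 0, iy < ny - 1,
                          iz > 0, iz < nz - 1};
      for (int k = 0; k < 6; ++k) {
        if (ok[k] && inside[nb[k]] && !labels[nb[k]]) {
          labels[nb[k]] = current;
          stack.push_back(nb[k]);
        }
      }
    }
  }
  labels.attr("n_regions") = current;
  return labels;
}
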