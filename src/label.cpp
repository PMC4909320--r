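#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Label connected components of TRUE cells in a logical matrix by
// breadth-first search. connectivity must be 4 or 8. Returns an integer
// matrix: 0 for FALSE cells, 1..k component labels for TRUE cells.
// Labels are assigned in column-major scan order of the first cell met,
// so output is fully deterministic.
// [[Rcpp::export(name = ".label_components_cpp")]]
IntegerMatrix label_components_cpp(LogicalMatrix mask, int connectivity) {
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  const int dr4[] = {-1, 1, 0, 0};
  const int dc4[] = {0, 0, -1, 1};
  const int dr8[] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc8[] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int *dr = connectivity == 4 ? dr4 : dr8;
  const int *dc = connectivity == 4 ? dc4 : dc8;
  const int ndir = connectivity;
  int next = 0;
  std::vector<int> queue;
  queue.reserve(nr * nc);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next;
      lab(r, c) = next;
      queue.clear();
      queue.push_back(r + c * nr);
      while (!queue.empty()) {
        int idx = queue.back();
        queue.pop_back();
        int cr = idx % nr, cc = idx / nr;
        for (int d = 0; d < ndir; ++d) {
          int r2 = cr + dr[d], c2 = cc + dc[d];
          if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
          if (mask(r2, c2) && lab(r2, c2) == 0) {
            lab(r2, c2) = next;
            queue.push_back(r2 + c2 * nr);
          }
        }
      }
    }
  }
  return lab;
}
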