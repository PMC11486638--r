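// 26-connected component labeling for 3D binary masks (SPM convention).
#include <Rcpp.h>
#include <vector>

// [[Rcpp::export]]
Rcpp::IntegerVector label_components_26(Rcpp::LogicalVector mask,
                                        Rcpp::IntegerVector dims) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const long N = (long)n1 * n2 * n3;
  if ((long)mask.size() != N) Rcpp::stop("mask length does not match dims");
  Rcpp::IntegerVector lab(N, 0);
  std::vector<long> stack;
  int next = 0;
  for (long s = 0; s < N; ++s) {
    if (mask[s] != TRUE || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      const long v = stack.back();
      stack.pop_back();
      const int i1 = v % n1, i2 = (v / n1) % n2, i3 = v / ((long)n1 * n2);
      for (int d3 = -1; d3 <= 1; ++d3) {
        const int j3 = i3 + d3;
        if (j3 < 0 || j3 >= n3) continue;
        for (int d2 = -1; d2 <= 1; ++d2) {
          const int j2 = i2 + d2;
          if (j2 < 0 || j2 >= n2) continue;
          for (int d1 = -1; d1 <= 1; ++d1) {
            if (d1 == 0 && d2 == 0 && d3 == 0) continue;
            const int j1 = i1 + d1;
            if (j1 < 0 || j1 >= n1) continue;
            const long w = j1 + (long)n1 * (j2 + (long)n2 * j3);
            if (mask[w] == TRUE && lab[w] == 0) {
              lab[w] = next;
              stack.push_back(w);
            }
          }
        }
      }
    }
  }
  lab.attr("n_components") = next;
  return lab;
}
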