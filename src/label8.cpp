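#include <Rcpp.h>
#include <vector>

// 8-connected component labelling of a binary matrix by breadth-first
// search. Foreground is any non-zero entry; labels are 1..k in scan order
// (column-major, as R stores matrices), background stays 0.
// [[Rcpp::export(name = ".label8")]]
Rcpp::IntegerMatrix label8(Rcpp::NumericMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  Rcpp::IntegerMatrix lab(nr, nc);
  std::vector<int> qr, qc;
  int next = 0;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (mask(i, j) == 0 || lab(i, j) != 0) continue;
      ++next;
      lab(i, j) = next;
      qr.clear(); qc.clear();
      qr.push_back(i); qc.push_back(j);
      for (size_t h = 0; h < qr.size(); ++h) {
        const int r = qr[h], c = qc[h];
        for (int dr = -1; dr <= 1; ++dr) {
          for (int dc = -1; dc <= 1; ++dc) {
            const int rr = r + dr, cc = c + dc;
            if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
            if (mask(rr, cc) != 0 && lab(rr, cc) == 0) {
              lab(rr, cc) = next;
              qr.push_back(rr); qc.push_back(cc);
            }
          }
        }
      }
    }
  }
  return lab;
}
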