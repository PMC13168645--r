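// Raster helpers: connected-component labelling (flood fill) and row
// medians with NA removal for medoid compositing.
#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Label connected components of equal non-zero values.
// `x`: integer matrix, 0 = background. connectivity: 4 or 8.
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(IntegerMatrix x, int connectivity) {
  const int nr = x.nrow(), nc = x.ncol();
  IntegerMatrix lab(nr, nc);
  std::fill(lab.begin(), lab.end(), 0);
  const int dr8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int dr4[4] = {-1, 0, 0, 1};
  const int dc4[4] = {0, -1, 1, 0};
  const int *dr = (connectivity == 8) ? dr8 : dr4;
  const int *dc = (connectivity == 8) ? dc8 : dc4;
  const int nd = (connectivity == 8) ? 8 : 4;

  int next_id = 0;
  std::vector<int> stack;
  stack.reserve(256);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (x(r, c) == 0 || lab(r, c) != 0) continue;
      const int val = x(r, c);
      ++next_id;
      lab(r, c) = next_id;
      stack.push_back(r + c * nr);
      while (!stack.empty()) {
        int p = stack.back();
        stack.pop_back();
        int pr = p % nr, pc = p / nr;
        for (int k = 0; k < nd; ++k) {
          int qr = pr + dr[k], qc = pc + dc[k];
          if (qr < 0 || qr >= nr || qc < 0 || qc >= nc) continue;
          if (x(qr, qc) == val && lab(qr, qc) == 0) {
            lab(qr, qc) = next_id;
            stack.push_back(qr + qc * nr);
          }
        }
      }
    }
  }
  return lab;
}

// Row medians ignoring NA; all-NA rows yield NA.
// [[Rcpp::export]]
NumericVector row_medians_cpp(NumericMatrix x) {
  const int n = x.nrow(), k = x.ncol();
  NumericVector out(n);
  std::vector<double> buf;
  buf.reserve(k);
  for (int i = 0; i < n; ++i) {
    buf.clear();
    for (int j = 0; j < k; ++j) {
      double v = x(i, j);
      if (!ISNAN(v)) buf.push_back(v);
    }
    int m = (int)buf.size();
    if (m == 0) {
      out[i] = NA_REAL;
    } else {
      std::sort(buf.begin(), buf.end());
      out[i] = (m % 2 == 1) ? buf[m / 2]
                            : (buf[m / 2 - 1] + buf[m / 2]) / 2.0;
    }
  }
  return out;
}
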